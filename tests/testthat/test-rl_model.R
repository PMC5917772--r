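test_that("initial values follow the pre-familiarization flag", {
  p <- model_params(alpha = 0.39, beta = 7.58,
                    q_init_familiar = 0.52, q_init_novel = 0.57)
  expect_equal(initial_value(TRUE, p), 0.52)
  expect_equal(initial_value(FALSE, p), 0.57)
  pc <- model_params(alpha = 0.5, beta = 5, q_init_familiar = 0.5,
                     constrained = TRUE)
  expect_equal(initial_value(c(TRUE, FALSE), pc), c(0.5, 0.5))
  expect_error(model_params(0.5, 5, 0.4, 0.6, constrained = TRUE),
               "constrained")
})

test_that("prediction error and delta-rule update are the stated arithmetic", {
  expect_equal(prediction_error(0.5, 1), 0.5)
  expect_equal(prediction_error(0, 0), 0)
  expect_equal(prediction_error(1, 0), -1)
  expect_equal(update_value(0.5, 0.5, 0.5), 0.75)
  expect_equal(update_value(0.3, 0, 0.9), 0.3)     # no-learning limit
  expect_equal(update_value(0.123, 1, prediction_error(0.123, 1)), 1)
})

test_that("softmax probabilities are correct, stable, and normalized", {
  expect_equal(choice_probabilities(c(0.7, 0.7, 0.7), 12), rep(1 / 3, 3))
  expect_equal(choice_probabilities(c(0.1, 0.9, 0.4), 0), rep(1 / 3, 3))
  p <- choice_probabilities(c(1, 0, 0), 1)
  expect_equal(p, c(exp(1), 1, 1) / (exp(1) + 2), tolerance = 1e-12)
  expect_equal(p[1L], 0.5761169, tolerance = 1e-6)
  # max-subtraction keeps huge beta finite
  p_big <- choice_probabilities(c(0.9, 0.1, 0.1), 5000)
  expect_true(all(is.finite(p_big)))
  expect_equal(sum(p_big), 1)
  expect_error(choice_probabilities(c(Inf, 0, 0), 1), "non-finite")
})

test_that("one uniform trial costs ln 3 and all-missed sessions cost nothing", {
  fx <- toy_fixture()
  one <- fx$design
  one$trials <- one$trials[1L, ]
  one$config <- task_config(n_runs = 1L, trials_per_run = 1L,
                            replacement_fraction = 0,
                            pool_size = 6L, n_prefamiliarized = 3L,
                            min_replacement_gap = 1L)
  p_flat <- model_params(alpha = 0.3, beta = 4, q_init_familiar = 0.5,
                         constrained = TRUE)
  log1 <- data.frame(run = 1L, trial = 1L, chosen_id = "N1", reward = 1)
  out <- sequence_negloglik(one, log1, p_flat)
  expect_equal(out$nll, log(3), tolerance = 1e-12)
  expect_equal(out$n_trials_used, 1L)

  log_missed <- fx$log
  log_missed$chosen_id <- NA_character_
  log_missed$reward <- 0
  expect_warning(out0 <- sequence_negloglik(fx$design, log_missed,
                                            toy_params()),
                 "all trials missed")
  expect_equal(out0$nll, 0)
  expect_equal(out0$n_trials_used, 0L)
})

test_that("fixture likelihood matches the frozen hand-computed oracle value", {
  fx <- toy_fixture()
  out <- sequence_negloglik(fx$design, fx$log, toy_params())
  expect_equal(out$nll, 3.037961645381, tolerance = 1e-9)
  expect_equal(out$n_trials_used, 3L)
  oracle <- naive_negloglik(fx$design, fx$log, toy_params())
  expect_equal(out$nll, oracle$nll, tolerance = 1e-12)
})

test_that("a chosen image that was not on screen is a data error naming the trial", {
  fx <- toy_fixture()
  bad <- fx$log
  bad$chosen_id[2L] <- "F2"     # retired on trial 2
  expect_error(sequence_negloglik(fx$design, bad, toy_params()),
               "trial 2")
})

test_that("likelihood matches the naive oracle on random tiny instances", {
  for (seed in 1:120) {
    toy <- make_random_toy(seed)
    # short instances can come out all-missed; the empty likelihood warns
    got <- suppressWarnings(sequence_negloglik(toy$design, toy$log,
                                               toy$params))
    want <- naive_negloglik(toy$design, toy$log, toy$params)
    expect_equal(got$nll, want$nll, tolerance = 1e-9)
    expect_equal(got$n_trials_used, want$n_trials_used)
  }
})

test_that("values stay in [0,1] and prediction errors in [-1,1] with 0/1 rewards", {
  for (seed in 1:25) {
    toy <- make_random_toy(seed)
    tr <- compute_trace(toy$design, toy$log, toy$params)
    qs <- c(tr$trials$q1, tr$trials$q2, tr$trials$q3, tr$values)
    expect_true(all(qs >= 0 & qs <= 1))
    d <- tr$trials$delta
    expect_true(all(is.na(d) | (d >= -1 & d <= 1)))
  }
})

test_that("raising beta strictly favours the unique max-value option", {
  q <- c(0.6, 0.3, 0.2)
  p_seq <- vapply(c(0, 1, 3, 8, 20), function(b)
    choice_probabilities(q, b)[1L], numeric(1L))
  expect_true(all(diff(p_seq) > 0))
})

test_that("trace reproduces the closed-form geometric value approach", {
  # one option chosen and rewarded every trial: Q_n = 1 - (1 - alpha)^n
  catalog <- data.frame(image_id = c("A", "B", "C"),
                        prefamiliarized = c(TRUE, TRUE, FALSE),
                        reward_prob = c(0.33, 0.2, 0.46),
                        stringsAsFactors = FALSE)
  slates <- replicate(6L, c("A", "B", "C"), simplify = FALSE)
  design <- make_design(slates, catalog)
  log <- data.frame(run = 1L, trial = 1:6, chosen_id = "C", reward = 1,
                    stringsAsFactors = FALSE)
  p <- model_params(alpha = 0.5, beta = 3, q_init_familiar = 0,
                    q_init_novel = 0)
  tr <- compute_trace(design, log, p)
  expect_equal(tr$values[, "C"], 1 - (1 - 0.5)^(0:6), tolerance = 1e-12)
  # alpha = 0: every value pinned at its initial value
  tr0 <- compute_trace(design, log,
                       model_params(0, 3, 0.4, 0.6))
  expect_true(all(tr0$values[, "A"] == 0.4))
  expect_equal(unique(c(tr0$values[, "C"])), 0.6)
})

test_that("trace probabilities normalize and its nll matches sequence_negloglik", {
  for (seed in c(2L, 9L)) {
    d <- generate_session(task_config(), seed = seed)
    log <- simulate_agent(d, model_params(0.45, 8, 0.45, 0.55),
                          seed = seed + 100L)
    p <- model_params(0.3, 6, 0.5, 0.6)
    tr <- compute_trace(d, log, p)
    expect_equal(tr$trials$p1 + tr$trials$p2 + tr$trials$p3,
                 rep(1, 240L), tolerance = 1e-12)
    nll <- sequence_negloglik(d, log, p)
    expect_equal(tr$nll, nll$nll, tolerance = 1e-10)
    # recompute nll from the per-trial probabilities
    expect_equal(-sum(log(tr$trials$p_chosen), na.rm = TRUE), nll$nll,
                 tolerance = 1e-10)
  }
})

test_that("novelty decomposition is the elementwise trace difference", {
  fx <- toy_fixture()
  full <- compute_trace(fx$design, fx$log, toy_params())
  base <- compute_trace(fx$design, fx$log,
                        model_params(0.5, 2, 0.4, constrained = TRUE))
  add <- decompose_novelty(full, base)
  expect_equal(add$trials$q_add1, full$trials$q1 - base$trials$q1)
  expect_equal(add$trials$delta_add, full$trials$delta - base$trials$delta)
  # identical parents give an all-zero additive trace
  zero <- decompose_novelty(full, full)
  expect_true(all(unlist(zero$trials[, c("q_add1", "q_add2", "q_add3",
                                         "delta_add")]) == 0, na.rm = TRUE))
})

test_that("with no learning the additive value is the constant class offset", {
  fx <- toy_fixture()
  full <- compute_trace(fx$design, fx$log, model_params(0, 2, 0.4, 0.6))
  base <- compute_trace(fx$design, fx$log,
                        model_params(0, 2, 0.4, constrained = TRUE))
  add <- decompose_novelty(full, base)
  fam <- setNames(fx$design$catalog$prefamiliarized,
                  fx$design$catalog$image_id)
  for (t in seq_len(4L)) {
    slate <- unlist(fx$design$trials[t, c("img1", "img2", "img3")])
    expected <- ifelse(fam[slate], 0, 0.2)
    expect_equal(unname(unlist(add$trials[t, c("q_add1", "q_add2", "q_add3")])),
                 unname(expected), tolerance = 1e-12)
  }
})

test_that("misaligned parent traces are rejected", {
  fx <- toy_fixture()
  full <- compute_trace(fx$design, fx$log, toy_params())
  other_log <- fx$log
  other_log$chosen_id[1L] <- "F1"
  base <- compute_trace(fx$design, other_log,
                        model_params(0.5, 2, 0.4, constrained = TRUE))
  expect_error(decompose_novelty(full, base), "misalignment")
})
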