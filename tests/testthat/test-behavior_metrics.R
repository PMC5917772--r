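test_that("amount won is the reward sum times the magnitude", {
  fx <- toy_fixture()
  expect_equal(amount_won(fx$log, fx$design$config), 2)
  log0 <- fx$log; log0$reward <- 0
  expect_equal(amount_won(log0, fx$design$config), 0)
  d <- generate_session(task_config(), seed = 1L)
  log_all <- data.frame(run = d$trials$run, trial = d$trials$trial,
                        chosen_id = d$trials$img1, reward = 1)
  expect_equal(amount_won(log_all, d$config), 240)
})

test_that("first-presentation rates count replacement introductions only", {
  fx <- toy_fixture()
  # N2 introduced on trial 2 and chosen -> 100%; F3 introduced on trial 4,
  # F1 chosen instead -> 0%
  expect_equal(first_presentation_choice_rate(fx$design, fx$log, "novel"), 100)
  expect_equal(first_presentation_choice_rate(fx$design, fx$log, "familiar"), 0)
})

test_that("missed introduction trials leave the denominator", {
  fx <- toy_fixture()
  log <- fx$log
  log$chosen_id[2L] <- NA_character_   # miss the one novel introduction
  log$reward[2L] <- 0
  expect_true(is.na(first_presentation_choice_rate(fx$design, log, "novel")))
  # a design with no replacements has no introductions at all
  d0 <- generate_session(task_config(replacement_fraction = 0), seed = 2L)
  log0 <- simulate_agent(d0, model_params(0.4, 5, 0.5, 0.5), seed = 3L)
  expect_true(is.na(first_presentation_choice_rate(d0, log0, "novel")))
  expect_length(persistence_runs(d0, log0, "novel"), 0L)
})

test_that("always/never picking the introduced image gives 100% / 0%", {
  d <- generate_session(task_config(), seed = 6L)
  intro_trials <- which(d$trials$replacement)
  always <- data.frame(run = d$trials$run, trial = d$trials$trial,
                       chosen_id = d$trials$img1, reward = 0,
                       stringsAsFactors = FALSE)
  always$chosen_id[intro_trials] <- d$trials$introduced_id[intro_trials]
  expect_equal(first_presentation_choice_rate(d, always, "novel"), 100)
  expect_equal(first_presentation_choice_rate(d, always, "familiar"), 100)
  never <- always
  never$chosen_id[intro_trials] <- vapply(intro_trials, function(t) {
    slate <- unlist(d$trials[t, c("img1", "img2", "img3")])
    setdiff(slate, d$trials$introduced_id[t])[1L]
  }, character(1L))
  expect_equal(first_presentation_choice_rate(d, never, "novel"), 0)
})

test_that("persistence runs follow the definitional hand trace", {
  catalog <- data.frame(
    image_id = c("F1", "F2", "N1", "N2"),
    prefamiliarized = c(TRUE, TRUE, FALSE, FALSE),
    reward_prob = c(0.46, 0.2, 0.33, 0.46), stringsAsFactors = FALSE)
  slates <- list(c("F1", "F2", "N2"), c("F1", "N1", "N2"),
                 c("F1", "N1", "N2"), c("F1", "N1", "N2"),
                 c("F1", "N1", "N2"))
  design <- make_design(slates, catalog,
                        introduced = c(NA, "N1", NA, NA, NA))
  # chosen at introduction and the next two trials, then not -> run 3
  log <- data.frame(run = 1L, trial = 1:5,
                    chosen_id = c("F1", "N1", "N1", "N1", "F1"),
                    reward = 0, stringsAsFactors = FALSE)
  expect_equal(persistence_runs(design, log, "novel"), c(N1 = 3))
  # not chosen at introduction -> 0
  log0 <- log; log0$chosen_id[2L] <- "F1"
  expect_equal(persistence_runs(design, log0, "novel"), c(N1 = 0))
  # a missed trial breaks the run
  logm <- log; logm$chosen_id[3L] <- NA_character_
  expect_equal(persistence_runs(design, logm, "novel"), c(N1 = 1))
  # retirement ends the run: N1 replaced on trial 4
  design2 <- make_design(list(c("F1", "F2", "N2"), c("F1", "N1", "N2"),
                              c("F1", "N1", "N2"), c("F1", "F2", "N2"),
                              c("F1", "F2", "N2")),
                         catalog, introduced = c(NA, "N1", NA, "F2", NA))
  expect_equal(unname(persistence_runs(design2, log, "novel")[1L]), 2)
})

test_that("optimality labels use strict-max with ties non-optimal", {
  fx <- toy_fixture()
  # trial 2 slate F1 (0.46), N1 (0.33), N2 (0.46): tie -> non_optimal
  expect_equal(optimality_label(fx$design, "N2", 2L), "non_optimal")
  expect_equal(optimality_label(fx$design, "F1", 1L), "optimal")  # 0.46 unique max
  expect_equal(optimality_label(fx$design, "N1", 1L), "non_optimal")
  expect_error(optimality_label(fx$design, "N3", 1L), "not displayed")
})

test_that("the fixture summary equals the hand-computed reference", {
  fx <- toy_fixture()
  s <- summarize_behavior(fx$design, fx$log,
                          fit = model_params(0.5, 2, 0.4, 0.6))
  expect_equal(s$amount_won, 2)
  expect_equal(s$novelty_bonus, 0.2)
  expect_equal(s$pct_novel_first, 100)
  expect_equal(s$pct_familiar_first, 0)
  # both introductions are non-optimal on their introduction trial
  expect_true(is.na(s$persistence_novel_optimal))
  expect_equal(s$persistence_novel_non_optimal, 1)  # N2: chosen t2, missed t3
  expect_equal(s$persistence_familiar_non_optimal, 0)
  expect_equal(s$n_missed, 1L)
  s0 <- summarize_behavior(fx$design, fx$log,
                           fit = model_params(0.5, 2, 0.4, constrained = TRUE))
  expect_equal(s0$novelty_bonus, 0)
})

test_that("a novelty bonus raises first-presentation novel picks (paired designs)", {
  diffs <- vapply(1:6, function(seed) {
    d <- generate_session(task_config(), seed = seed)
    with_bonus <- simulate_agent(d, model_params(0.4, 8, 0.4, 0.7),
                                 seed = 1000L + seed)
    no_bonus <- simulate_agent(d, model_params(0.4, 8, 0.4, 0.4),
                               seed = 1000L + seed)
    first_presentation_choice_rate(d, with_bonus, "novel") -
      first_presentation_choice_rate(d, no_bonus, "novel")
  }, numeric(1L))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.5)
})

test_that("zero-bonus agents treat novel and familiar introductions alike", {
  diffs <- vapply(1:8, function(seed) {
    d <- generate_session(task_config(), seed = seed)
    log <- simulate_agent(d, model_params(0.45, 8, 0.5, 0.5),
                          seed = 2000L + seed)
    first_presentation_choice_rate(d, log, "novel") -
      first_presentation_choice_rate(d, log, "familiar")
  }, numeric(1L))
  # paired difference centred on zero: mean well inside its sampling noise
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-9)
})

test_that("reward-sensitive agents persist longer with optimal novel options", {
  tot_opt <- c(); tot_non <- c()
  for (seed in 1:6) {
    d <- generate_session(task_config(), seed = 300L + seed)
    log <- simulate_agent(d, model_params(0.5, 12, 0.4, 0.6),
                          seed = 400L + seed)
    runs <- persistence_runs(d, log, "novel")
    intro <- d$trials[d$trials$replacement, ]
    fam <- d$catalog$prefamiliarized[match(intro$introduced_id,
                                           d$catalog$image_id)]
    intro <- intro[!fam, ]
    opt <- vapply(seq_len(nrow(intro)), function(i)
      optimality_label(d, intro$introduced_id[i], intro$trial[i]),
      character(1L))
    tot_opt <- c(tot_opt, runs[opt == "optimal"])
    tot_non <- c(tot_non, runs[opt == "non_optimal"])
  }
  expect_gte(mean(tot_opt), mean(tot_non))
})
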