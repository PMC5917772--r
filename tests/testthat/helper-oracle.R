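# Intentionally naive re-implementation of the delta-rule/softmax forward
# pass, sharing no code with the package: data-frame lookups, named vectors,
# and the softmax written in its unstabilized textbook form. Serves as the
# independent likelihood oracle.
naive_negloglik <- function(design, log, params) {
  q <- ifelse(design$catalog$prefamiliarized,
              params$q_init_familiar, params$q_init_novel)
  names(q) <- design$catalog$image_id
  nll <- 0
  used <- 0L
  for (t in seq_len(nrow(design$trials))) {
    row <- design$trials[t, ]
    disp <- c(row$img1, row$img2, row$img3)
    ch <- log$chosen_id[t]
    if (is.na(ch)) next
    pr <- exp(params$beta * q[disp])
    pr <- pr / sum(pr)
    nll <- nll - log(pr[[ch]])
    used <- used + 1L
    q[ch] <- q[ch] + params$alpha * (log$reward[t] - q[ch])
  }
  list(nll = nll, n_trials_used = used)
}

# Hand-build a session_design from explicit trial slates; replacement
# bookkeeping is optional because the likelihood only needs the slates.
make_design <- function(slates, catalog, config = NULL,
                        introduced = rep(NA_character_, length(slates))) {
  n <- length(slates)
  if (is.null(config))
    config <- task_config(n_runs = 1L, trials_per_run = n,
                          replacement_fraction = mean(!is.na(introduced)),
                          pool_size = nrow(catalog),
                          n_prefamiliarized = sum(catalog$prefamiliarized),
                          min_replacement_gap = 1L)
  m <- do.call(rbind, slates)
  trials <- data.frame(
    run = rep(1L, n), trial = seq_len(n),
    img1 = m[, 1L], img2 = m[, 2L], img3 = m[, 3L],
    replacement = !is.na(introduced), introduced_id = introduced,
    stringsAsFactors = FALSE)
  structure(list(config = config, catalog = catalog, trials = trials),
            class = "session_design")
}

# A random tiny (<= 10 trial) design + choice log with occasional misses,
# for oracle-equivalence sweeps.
make_random_toy <- function(seed) {
  withr::with_seed(seed, {
    n_img <- 5L
    catalog <- data.frame(
      image_id = sprintf("I%d", seq_len(n_img)),
      prefamiliarized = sample(c(TRUE, TRUE, FALSE, FALSE, FALSE)),
      reward_prob = sample(c(0.20, 0.33, 0.46), n_img, replace = TRUE),
      stringsAsFactors = FALSE)
    n <- sample(1:10, 1L)
    slates <- replicate(n, sample(catalog$image_id, 3L), simplify = FALSE)
    design <- make_design(slates, catalog)
    chosen <- vapply(slates, function(s)
      if (stats::runif(1L) < 0.15) NA_character_ else sample(s, 1L),
      character(1L))
    log <- data.frame(run = 1L, trial = seq_len(n), chosen_id = chosen,
                      reward = ifelse(is.na(chosen), 0,
                                      stats::rbinom(n, 1L, 0.33)),
                      stringsAsFactors = FALSE)
    params <- model_params(alpha = stats::runif(1L),
                           beta = stats::runif(1L, 0, 15),
                           q_init_familiar = stats::runif(1L),
                           q_init_novel = stats::runif(1L))
    list(design = design, log = log, params = params)
  })
}

toy_design_path <- function() {
  system.file("extdata", "toy_design.tsv", package = "noveltybandit",
              mustWork = TRUE)
}

toy_fixture <- function() {
  list(design = read_design(toy_design_path()),
       log = read_choices(system.file("extdata", "toy_choices.tsv",
                                      package = "noveltybandit",
                                      mustWork = TRUE)))
}

toy_params <- function() model_params(alpha = 0.5, beta = 2,
                                      q_init_familiar = 0.4,
                                      q_init_novel = 0.6)
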