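#' Generative agent specification
#'
#' A simulated participant: the true [model_params()] driving choice, plus
#' a probability of missing (not responding on) any given trial.
#'
#' @param params True generative [model_params()].
#' @param miss_rate Per-trial probability of a missed trial, in `[0, 1)`.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(params, miss_rate = 0) {
  stopifnot(inherits(params, "model_params"),
            miss_rate >= 0, miss_rate < 1)
  structure(list(params = params, miss_rate = miss_rate),
            class = "agent_spec")
}

#' Simulate an agent's choices on a session design
#'
#' Runs the learning model generatively: on each trial the agent misses
#' with probability `miss_rate`; otherwise it samples its choice from the
#' softmax over the three displayed options' current values, draws the
#' reward from the chosen image's fixed Bernoulli payoff probability, and
#' updates the chosen value by the delta rule.
#'
#' @param design A `session_design`.
#' @param spec An [agent_spec()] (a bare [model_params()] is promoted with
#'   `miss_rate = 0`).
#' @param seed Integer seed; the same seed reproduces the identical log.
#' @return A choice-log data frame (`run`, `trial`, `chosen_id`, `reward`)
#'   aligned with `design$trials`.
#' @export
simulate_agent <- function(design, spec, seed = NULL) {
  if (inherits(spec, "model_params")) spec <- agent_spec(spec)
  stopifnot(inherits(spec, "agent_spec"), inherits(design, "session_design"))
  p <- spec$params
  run <- function() {
    tr <- design$trials
    n <- nrow(tr)
    ids <- design$catalog$image_id
    rp <- design$catalog$reward_prob
    fam <- design$catalog$prefamiliarized
    q <- ifelse(fam, p$q_init_familiar, p$q_init_novel)
    disp <- cbind(match(tr$img1, ids), match(tr$img2, ids),
                  match(tr$img3, ids))
    chosen <- rep(NA_character_, n)
    reward <- numeric(n)
    for (t in seq_len(n)) {
      if (spec$miss_rate > 0 && stats::runif(1L) < spec$miss_rate) next
      idx <- disp[t, ]
      probs <- choice_probabilities(q[idx], p$beta)
      c_idx <- idx[sample.int(3L, 1L, prob = probs)]
      r <- as.numeric(stats::runif(1L) < rp[c_idx])
      chosen[t] <- ids[c_idx]
      reward[t] <- r * design$config$reward_magnitude
      q[c_idx] <- update_value(q[c_idx], p$alpha,
                               prediction_error(q[c_idx], r))
    }
    data.frame(run = tr$run, trial = tr$trial, chosen_id = chosen,
               reward = reward, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

default_cohort_cells <- function() {
  # per-cell parameter means (SE in parentheses in the source table) for
  # the ADHD/control x placebo/drug crossover; SDs reconstructed as
  # SE * sqrt(30). Qn and Qf are strongly coupled within subject, so the
  # generator draws (Qf, bonus) and sets Qn = Qf + bonus; bonus SDs come
  # from the reported placebo bonus dispersion (~0.1) rather than from
  # independent Qn/Qf draws, which would overstate it five-fold.
  n <- 30
  data.frame(
    group = rep(c("ADHD", "control"), each = 2L),
    condition = rep(c("placebo", "drug"), 2L),
    alpha_mean = c(0.39, 0.48, 0.54, 0.46),
    alpha_sd = c(0.04, 0.06, 0.05, 0.06) * sqrt(n),
    beta_mean = c(7.58, 7.18, 8.69, 7.58),
    beta_sd = c(2.06, 1.54, 2.29, 1.27) * sqrt(n),
    qf_mean = c(0.52, 0.56, 0.45, 0.49),
    qf_sd = c(0.06, 0.06, 0.06, 0.05) * sqrt(n),
    bonus_mean = c(0.57 - 0.52, 0.62 - 0.56, 0.46 - 0.45, 0.53 - 0.49),
    bonus_sd = c(0.018, 0.018, 0.015, 0.015) * sqrt(n),
    stringsAsFactors = FALSE
  )
}

#' Cohort specification for the group-by-drug crossover
#'
#' Describes a synthetic cohort patterned on the study: two groups (ADHD,
#' control) of `n_subjects` each, every subject tested once on placebo and
#' once on drug, each session on an independently generated design (the
#' counterbalanced image sets). Per-cell parameter distributions default to
#' the study's fitted cell means with SDs reconstructed from the reported
#' standard errors (`SE * sqrt(30)`). Subject parameters are drawn as
#' truncated normals within the model bounds; `Qn` is constructed as
#' `Qf + bonus` so the cohort reproduces the printed dispersion of the
#' novelty bonus (independent `Qn`/`Qf` draws would overstate it).
#'
#' @param cells Data frame with one row per group-by-condition cell and
#'   columns `group`, `condition`, `alpha_mean`, `alpha_sd`, `beta_mean`,
#'   `beta_sd`, `qf_mean`, `qf_sd`, `bonus_mean`, `bonus_sd`.
#' @param n_subjects Subjects per group.
#' @param config [task_config()] for every session.
#' @param miss_rate Per-trial miss probability for all agents.
#' @param rng_seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = default_cohort_cells(), n_subjects = 30L,
                        config = task_config(), miss_rate = 0,
                        rng_seed = 1L) {
  needed <- c("group", "condition", "alpha_mean", "alpha_sd", "beta_mean",
              "beta_sd", "qf_mean", "qf_sd", "bonus_mean", "bonus_sd")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols))
    stop(sprintf("spec error: cells is missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  sd_cols <- grep("_sd$", names(cells), value = TRUE)
  if (any(as.matrix(cells[sd_cols]) < 0))
    stop("spec error: SDs must be >= 0", call. = FALSE)
  structure(list(cells = cells, n_subjects = as.integer(n_subjects),
                 config = config, miss_rate = miss_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# truncated-normal draws by inverse-CDF; errors when the truncation window
# has no mass (e.g. mean far outside bounds with sd = 0)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop(sprintf(
        "spec error: degenerate distribution (mean %.3g, sd 0) outside [%g, %g]",
        mean, lower, upper), call. = FALSE)
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12)
    stop(sprintf(
      "spec error: truncation window [%g, %g] has no mass under N(%.3g, %.3g)",
      lower, upper, mean, sd), call. = FALSE)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

sample_cell_params <- function(cell, n, beta_max = 50) {
  alpha <- rtruncnorm(n, cell$alpha_mean, cell$alpha_sd, 0, 1)
  beta <- rtruncnorm(n, cell$beta_mean, cell$beta_sd, 0, beta_max)
  qf <- rtruncnorm(n, cell$qf_mean, cell$qf_sd, 0, 1)
  bonus <- rtruncnorm(n, cell$bonus_mean, cell$bonus_sd, -1, 1)
  qn <- pmin(pmax(qf + bonus, 0), 1)
  lapply(seq_len(n), function(i)
    model_params(alpha = alpha[i], beta = beta[i], q_init_familiar = qf[i],
                 q_init_novel = qn[i]))
}

#' Generate a synthetic cohort
#'
#' Samples every subject's per-condition parameters from the cell
#' distributions, generates an independent session design per
#' subject-condition, and simulates the subject's choices. Fully
#' reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$rng_seed`.
#' @return An object of class `cohort`: list with `sessions` (each a list
#'   with `subject`, `group`, `condition`, `true_params`, `design`, `log`)
#'   and `manifest` (data frame of subject, group, condition and true
#'   parameters, for recovery scoring).
#' @export
generate_cohort <- function(spec, seed = spec$rng_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  build <- function() {
    cells <- spec$cells
    sessions <- list()
    manifest <- list()
    k <- 0L
    for (g in unique(cells$group)) {
      for (s in seq_len(spec$n_subjects)) {
        subject <- sprintf("%s_%02d", g, s)
        for (cond in unique(cells$condition[cells$group == g])) {
          cell <- cells[cells$group == g & cells$condition == cond, ]
          params <- sample_cell_params(cell, 1L)[[1L]]
          design <- generate_session(
            spec$config,
            seed = sample.int(.Machine$integer.max - 1L, 1L))
          log <- simulate_agent(design, agent_spec(params, spec$miss_rate),
                                seed = sample.int(.Machine$integer.max - 1L, 1L))
          k <- k + 1L
          sessions[[k]] <- list(subject = subject, group = g,
                                condition = cond, true_params = params,
                                design = design, log = log)
          manifest[[k]] <- data.frame(
            subject = subject, group = g, condition = cond,
            alpha = params$alpha, beta = params$beta,
            q_init_familiar = params$q_init_familiar,
            q_init_novel = params$q_init_novel,
            novelty_bonus = novelty_bonus(params),
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(sessions = sessions, manifest = do.call(rbind, manifest),
                   spec = spec), class = "cohort")
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cohort> %d sessions: %d subjects x %d condition(s)\n",
              nrow(m), length(unique(m$subject)),
              length(unique(m$condition))))
  invisible(x)
}
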