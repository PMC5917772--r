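#' Options for maximum-likelihood fitting
#'
#' Fitting is bounded multi-start local optimization (L-BFGS-B) of the
#' session negative log-likelihood. Starting points are a space-filling
#' Latin hypercube over the box constraints; the best start wins. `beta`
#' is capped (default 50) because near-deterministic choosers otherwise
#' drive it to infinity; fits ending on a bound are flagged, not errors.
#'
#' @param n_starts Number of starting points (`>= 1`).
#' @param beta_max Upper bound on the inverse temperature.
#' @param tol Convergence tolerance on the negative log-likelihood.
#' @param rng_seed Integer seed controlling the start points; identical
#'   inputs and seed give a bit-identical fit.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10L, beta_max = 50, tol = 1e-6,
                        rng_seed = 1L) {
  stopifnot(n_starts >= 1L, beta_max > 0, tol > 0)
  structure(list(n_starts = as.integer(n_starts), beta_max = beta_max,
                 tol = tol, rng_seed = as.integer(rng_seed)),
            class = "fit_options")
}

# parameter vectors: full = (alpha, beta, qf, qn); constrained = (alpha, beta, q0)
fit_bounds <- function(constrained, options) {
  if (constrained)
    list(lower = c(0, 0, 0), upper = c(1, options$beta_max, 1),
         names = c("alpha", "beta", "q0"))
  else
    list(lower = c(0, 0, 0, 0), upper = c(1, options$beta_max, 1, 1),
         names = c("alpha", "beta", "q_init_familiar", "q_init_novel"))
}

par_to_params <- function(par, constrained) {
  if (constrained)
    model_params(alpha = par[1L], beta = par[2L], q_init_familiar = par[3L],
                 constrained = TRUE)
  else
    model_params(alpha = par[1L], beta = par[2L], q_init_familiar = par[3L],
                 q_init_novel = par[4L])
}

#' Fit the learning model to one session by maximum likelihood
#'
#' Minimizes the session negative log-likelihood over the bounded parameter
#' box from `options$n_starts` space-filling starting points and returns
#' the best local optimum. The full model estimates four parameters
#' (`alpha`, `beta`, `Qf`, `Qn`); the constrained model three (`alpha`,
#' `beta`, and a single shared initial value).
#'
#' @param design A `session_design`.
#' @param log A choice log aligned with the design; at least one responded
#'   trial is required.
#' @param constrained Fit the constrained (`Qn = Qf`) model?
#' @param options A [fit_options()].
#' @param extra_starts Optional numeric matrix of additional starting
#'   points (one row per start, columns in parameter order). Used, e.g., to
#'   seed the full model with the constrained optimum so the nested-model
#'   inequality `nll_constrained >= nll_full` holds to optimizer precision.
#' @return An object of class `fit_result`: `params` ([model_params()]),
#'   `nll`, `n_trials_used`, `n_params_free` (4 full / 3 constrained),
#'   `start_nlls`, `converged`, and `boundary` (`TRUE` when the optimum
#'   sits on a box bound, typically `beta_max`).
#' @export
fit_session <- function(design, log, constrained = FALSE,
                        options = fit_options(), extra_starts = NULL) {
  stopifnot(inherits(options, "fit_options"))
  enc <- encode_session(design, log)
  n_used <- sum(enc$chosen != 0L)
  if (n_used == 0L)
    stop("fit error: no usable (responded) trials in the choice log",
         call. = FALSE)
  b <- fit_bounds(constrained, options)
  npar <- length(b$lower)

  objective <- function(par) {
    qn <- if (constrained) par[3L] else par[4L]
    .rl_forward_nll(enc$displayed, enc$chosen, enc$reward, enc$familiar,
                    par[1L], par[2L], par[3L], qn)$nll
  }

  starts <- withr::with_seed(options$rng_seed, {
    u <- lhs::randomLHS(options$n_starts, npar)
    sweep(sweep(u, 2L, b$upper - b$lower, "*"), 2L, b$lower, "+")
  })
  if (!is.null(extra_starts)) {
    extra_starts <- matrix(as.numeric(extra_starts), ncol = npar)
    starts <- rbind(starts, extra_starts)
  }

  best <- NULL
  start_nlls <- rep(NA_real_, nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(factr = min(options$tol / .Machine$double.eps,
                                              1e7))),
      error = function(e) NULL)
    if (is.null(fit)) next
    start_nlls[s] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("fit error: optimization failed from every starting point",
         call. = FALSE)

  on_bound <- any(abs(best$par - b$lower) < 1e-8 |
                    abs(best$par - b$upper) < 1e-8)
  structure(list(
    params = par_to_params(best$par, constrained),
    nll = best$value,
    n_trials_used = n_used,
    n_params_free = if (constrained) 3L else 4L,
    start_nlls = start_nlls,
    converged = best$convergence == 0L,
    boundary = on_bound,
    options = options
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model: nll = %.4f over %d trials%s\n",
              if (x$params$constrained) "constrained" else "full",
              x$nll, x$n_trials_used,
              if (x$boundary) " [on bound]" else ""))
  print(x$params)
  invisible(x)
}

#' Fit the full and constrained models to the same session
#'
#' Fits the constrained model first, then the full model with the
#' constrained optimum injected as an extra starting point (so the nested
#' models satisfy `nll_constrained >= nll_full` up to optimizer tolerance).
#'
#' @inheritParams fit_session
#' @return List with elements `full` and `constrained`, both `fit_result`s.
#' @export
fit_models <- function(design, log, options = fit_options()) {
  base <- fit_session(design, log, constrained = TRUE, options = options)
  p <- base$params
  full <- fit_session(design, log, constrained = FALSE, options = options,
                      extra_starts = matrix(c(p$alpha, p$beta,
                                              p$q_init_familiar,
                                              p$q_init_familiar), nrow = 1L))
  list(full = full, constrained = base)
}

#' Novelty bonus
#'
#' `Qn - Qf`: the excess initial value of novel over pre-familiarized
#' stimuli. Positive values bias first-presentation choice toward novel
#' options; the constrained model's bonus is 0 by definition.
#'
#' @param x A [model_params()] or `fit_result`.
#' @return The novelty bonus (currency-normalized units).
#' @export
#' @examples
#' novelty_bonus(model_params(0.39, 7.58, 0.52, 0.57))  # 0.05
novelty_bonus <- function(x) {
  if (inherits(x, "fit_result")) x <- x$params
  stopifnot(inherits(x, "model_params"))
  x$q_init_novel - x$q_init_familiar
}

#' Likelihood-ratio test between the full and constrained models
#'
#' The deviance `2 * sum(nll_constrained - nll_full)` is compared to a
#' chi-square upper tail. Modes: `"per_session"` tests one session pair
#' (df = 1, the freed `Qn` parameter); `"pooled"` sums the deviance over
#' all pairs with df = number of pairs (one freed parameter per fitted
#' session); `"paper"` uses the pooled deviance with df = 1 (a single
#' novelty-bonus parameter treated as shared across sessions). Tiny
#' negative deviances from finite-precision optimization are clamped to 0.
#'
#' @param fits_full `fit_result` or list of `fit_result`s for the full
#'   model.
#' @param fits_constrained Matching (same sessions, same order) constrained
#'   fits.
#' @param mode `"per_session"`, `"pooled"`, or `"paper"`.
#' @return An object of class `lrt_result`: `statistic`, `df`, `p`,
#'   `mode`, `n_sessions`.
#' @export
likelihood_ratio_test <- function(fits_full, fits_constrained,
                                  mode = c("per_session", "pooled", "paper")) {
  mode <- match.arg(mode)
  if (inherits(fits_full, "fit_result")) fits_full <- list(fits_full)
  if (inherits(fits_constrained, "fit_result"))
    fits_constrained <- list(fits_constrained)
  if (length(fits_full) != length(fits_constrained))
    stop("misaligned fit lists: lengths differ", call. = FALSE)
  if (mode == "per_session" && length(fits_full) != 1L)
    stop("per_session mode takes exactly one pair of fits", call. = FALSE)
  ok <- vapply(seq_along(fits_full), function(i) {
    fits_full[[i]]$n_params_free == 4L &&
      fits_constrained[[i]]$n_params_free == 3L &&
      fits_full[[i]]$n_trials_used == fits_constrained[[i]]$n_trials_used
  }, logical(1L))
  if (!all(ok))
    stop("misaligned fit lists: each pair must be (full, constrained) on the same data",
         call. = FALSE)
  nll_f <- vapply(fits_full, `[[`, numeric(1L), "nll")
  nll_c <- vapply(fits_constrained, `[[`, numeric(1L), "nll")
  stat <- 2 * sum(nll_c - nll_f)
  if (stat < 0) stat <- 0
  df <- switch(mode, per_session = 1L, pooled = length(fits_full),
               paper = 1L)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 mode = mode, n_sessions = length(fits_full)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "<lrt_result> mode=%s: chi-square = %.4f, df = %d, p = %.4g (%d session%s)\n",
    x$mode, x$statistic, x$df, x$p, x$n_sessions,
    if (x$n_sessions == 1L) "" else "s"))
  invisible(x)
}

#' Parameter-recovery harness
#'
#' Standard validation of the fitting procedure: simulate agents with known
#' parameters, fit each with the full model, and score how well fitting
#' retrieves the truth.
#'
#' @param param_sampler Function of no arguments returning a
#'   [model_params()] (the true generative parameters for one agent).
#' @param config [task_config()] used to generate each agent's design.
#' @param n_agents Number of agents (`>= 2`).
#' @param options [fit_options()] for the fits.
#' @param seed Master seed; drives the sampler, designs, and simulations.
#' @return An object of class `recovery_report`: `agents` (data frame of
#'   true and fitted parameters), `summary` (per-parameter correlation,
#'   bias, RMSE; correlation is `NA` with a note when the truth is
#'   degenerate), `bonus_sign_rate` (share of agents whose fitted bonus
#'   sign matches the true sign, among agents with `|bonus| >= min_bonus`),
#'   and `min_bonus`.
#' @param min_bonus Absolute true-bonus threshold for the sign-recovery
#'   rate (agents with near-zero bonus have no meaningful sign).
#' @export
recover_parameters <- function(param_sampler, config = task_config(),
                               n_agents, options = fit_options(),
                               seed = 1L, min_bonus = 0.1) {
  stopifnot(n_agents >= 2L)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L,
                                       2L * n_agents + 1L))
  truths <- withr::with_seed(seeds[2L * n_agents + 1L],
                             replicate(n_agents, param_sampler(),
                                       simplify = FALSE))
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    design <- generate_session(config, seed = seeds[2L * i - 1L])
    log <- simulate_agent(design, agent_spec(truths[[i]]),
                          seed = seeds[2L * i])
    fit <- fit_session(design, log, constrained = FALSE, options = options)
    p <- fit$params; tp <- truths[[i]]
    rows[[i]] <- data.frame(
      agent = i,
      true_alpha = tp$alpha, true_beta = tp$beta,
      true_qf = tp$q_init_familiar, true_qn = tp$q_init_novel,
      true_bonus = novelty_bonus(tp),
      fit_alpha = p$alpha, fit_beta = p$beta,
      fit_qf = p$q_init_familiar, fit_qn = p$q_init_novel,
      fit_bonus = novelty_bonus(p),
      nll = fit$nll, boundary = fit$boundary
    )
  }
  agents <- do.call(rbind, rows)

  summarize_param <- function(name) {
    tv <- agents[[paste0("true_", name)]]
    fv <- agents[[paste0("fit_", name)]]
    degenerate <- stats::sd(tv) < 1e-12
    data.frame(
      parameter = name,
      correlation = if (degenerate) NA_real_ else stats::cor(tv, fv),
      bias = mean(fv - tv),
      rmse = sqrt(mean((fv - tv)^2)),
      note = if (degenerate) "zero-variance truth: correlation undefined"
             else "",
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, lapply(c("alpha", "beta", "qf", "qn", "bonus"),
                                   summarize_param))
  eligible <- abs(agents$true_bonus) >= min_bonus
  bonus_sign_rate <- if (any(eligible))
    mean(sign(agents$fit_bonus[eligible]) == sign(agents$true_bonus[eligible]))
  else NA_real_
  structure(list(agents = agents, summary = summary,
                 bonus_sign_rate = bonus_sign_rate, min_bonus = min_bonus),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d agents\n", nrow(x$agents)))
  print(x$summary, row.names = FALSE)
  cat(sprintf("novelty-bonus sign recovered (|bonus| >= %.2g): %s\n",
              x$min_bonus,
              if (is.na(x$bonus_sign_rate)) "NA"
              else sprintf("%.1f%%", 100 * x$bonus_sign_rate)))
  invisible(x)
}
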