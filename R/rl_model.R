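#' Model parameters for the novelty-bonus learning model
#'
#' The model has four free parameters: a learning rate `alpha`, a softmax
#' inverse temperature `beta`, and separate initial values for
#' pre-familiarized (`q_init_familiar`) and never-seen (`q_init_novel`)
#' stimuli. The difference `q_init_novel - q_init_familiar` is the novelty
#' bonus. The constrained (baseline) variant forces the two initial values
#' to be equal, leaving three free parameters.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`; 0 is a uniform-random chooser.
#' @param q_init_familiar Initial value of pre-familiarized images, in
#'   `[0, 1]` currency-normalized units.
#' @param q_init_novel Initial value of novel images, in `[0, 1]`; defaults
#'   to `q_init_familiar`.
#' @param constrained If `TRUE`, forces `q_init_novel == q_init_familiar`
#'   (supplying two different values is an error).
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(alpha = 0.39, beta = 7.58,
#'              q_init_familiar = 0.52, q_init_novel = 0.57)
model_params <- function(alpha, beta, q_init_familiar,
                         q_init_novel = q_init_familiar,
                         constrained = FALSE) {
  if (constrained) {
    if (!missing(q_init_novel) &&
        abs(q_init_novel - q_init_familiar) > 1e-12)
      stop("constrained model requires q_init_novel == q_init_familiar",
           call. = FALSE)
    q_init_novel <- q_init_familiar
  }
  p <- list(alpha = as.numeric(alpha), beta = as.numeric(beta),
            q_init_familiar = as.numeric(q_init_familiar),
            q_init_novel = as.numeric(q_init_novel),
            constrained = isTRUE(constrained))
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (p$beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (p$q_init_familiar < 0 || p$q_init_familiar > 1 ||
      p$q_init_novel < 0 || p$q_init_novel > 1)
    stop("initial values must lie in [0, 1]", call. = FALSE)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params%s> alpha=%.4g beta=%.4g Qf=%.4g Qn=%.4g (bonus %.4g)\n",
    if (x$constrained) ", constrained" else "",
    x$alpha, x$beta, x$q_init_familiar, x$q_init_novel, novelty_bonus(x)))
  invisible(x)
}

#' Initial value of an image under the model
#'
#' Pre-familiarized images start at `q_init_familiar`, never-seen images at
#' `q_init_novel`; the constrained model assigns the shared value to both.
#'
#' @param prefamiliarized Logical (vectorized): was the image shown in the
#'   familiarization phase?
#' @param params A [model_params()].
#' @return Numeric initial value(s).
#' @export
initial_value <- function(prefamiliarized, params) {
  stopifnot(inherits(params, "model_params"), is.logical(prefamiliarized))
  ifelse(prefamiliarized, params$q_init_familiar, params$q_init_novel)
}

#' Reward prediction error
#'
#' `delta = r - q`: the difference between the obtained reward and the
#' current value of the chosen option.
#'
#' @param q Current value of the chosen option.
#' @param r Obtained reward.
#' @return The prediction error.
#' @export
prediction_error <- function(q, r) r - q

#' Delta-rule value update
#'
#' `q + alpha * delta`, applied to the chosen option only; unchosen options
#' and missed trials carry their values over unchanged.
#'
#' @param q Current value.
#' @param alpha Learning rate.
#' @param delta Prediction error.
#' @return The updated value.
#' @export
update_value <- function(q, alpha, delta) q + alpha * delta

#' Softmax choice probabilities
#'
#' `p_k = exp(beta * q_k) / sum_j exp(beta * q_j)`, computed with
#' max-subtraction for numerical stability. `beta = 0` gives uniform choice.
#'
#' @param q_values Numeric vector of option values.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(1, 0, 0), beta = 1)  # ~ (0.576, 0.212, 0.212)
choice_probabilities <- function(q_values, beta) {
  if (!all(is.finite(q_values)) || !is.finite(beta))
    stop("computation error: non-finite input to choice_probabilities",
         call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  z <- beta * (q_values - max(q_values))
  e <- exp(z)
  e / sum(e)
}

# Encode a (design, log) pair into integer matrices for the C++ forward
# pass: image ids -> 1-based indices, missed trials -> chosen index 0.
encode_session <- function(design, log) {
  stopifnot(inherits(design, "session_design"))
  tr <- design$trials
  if (nrow(log) != nrow(tr))
    stop(sprintf("choice log has %d rows but the design has %d trials",
                 nrow(log), nrow(tr)), call. = FALSE)
  ids <- design$catalog$image_id
  disp <- cbind(match(tr$img1, ids), match(tr$img2, ids), match(tr$img3, ids))
  if (anyNA(disp))
    stop("design error: displayed image missing from catalog", call. = FALSE)
  chosen <- match(log$chosen_id, ids)
  chosen[is.na(log$chosen_id)] <- 0L
  if (anyNA(chosen))
    stop(sprintf("data error: chosen image '%s' on trial %d is not in the catalog",
                 log$chosen_id[which(is.na(chosen))[1L]],
                 tr$trial[which(is.na(chosen))[1L]]), call. = FALSE)
  in_slate <- chosen == 0L | chosen == disp[, 1L] | chosen == disp[, 2L] |
    chosen == disp[, 3L]
  if (!all(in_slate)) {
    t_bad <- tr$trial[which(!in_slate)[1L]]
    stop(sprintf("data error: chosen image on trial %d was not displayed",
                 t_bad), call. = FALSE)
  }
  reward <- as.numeric(log$reward)
  reward[chosen == 0L] <- 0
  list(displayed = disp, chosen = as.integer(chosen), reward = reward,
       familiar = design$catalog$prefamiliarized, ids = ids)
}

#' Negative log-likelihood of a choice sequence
#'
#' Runs the delta-rule/softmax forward pass over the session: every image
#' starts at its class's initial value, each responded trial contributes
#' `-log P(chosen)` under the softmax over the three displayed options, and
#' the chosen option's value is then updated by `alpha * delta`. Missed
#' trials contribute no likelihood term and trigger no update.
#'
#' @param design A `session_design`.
#' @param log A choice log aligned 1:1 with `design$trials` (columns
#'   `chosen_id`, `reward`; `chosen_id = NA` marks a missed trial).
#' @param params A [model_params()].
#' @return A list with `nll` (total negative log-likelihood) and
#'   `n_trials_used` (responded trials). Warns when every trial is missed.
#' @export
sequence_negloglik <- function(design, log, params) {
  stopifnot(inherits(params, "model_params"))
  enc <- encode_session(design, log)
  out <- .rl_forward_nll(enc$displayed, enc$chosen, enc$reward, enc$familiar,
                         params$alpha, params$beta,
                         params$q_init_familiar, params$q_init_novel)
  if (out$n_trials_used == 0L)
    warning("all trials missed: likelihood is empty (nll = 0 over 0 trials)",
            call. = FALSE)
  out
}

#' Per-trial value and prediction-error trace
#'
#' Same forward pass as [sequence_negloglik()], returning the full per-trial
#' record: values and softmax probabilities of the three displayed options
#' at decision time, the chosen option's value and probability, the
#' prediction error (NA on missed trials), and the complete per-image value
#' history.
#'
#' @inheritParams sequence_negloglik
#' @return An object of class `value_trace`: list with `trials` (data frame
#'   with columns `run`, `trial`, `chosen_id`, `reward`, `missed`,
#'   `q1..q3`, `p1..p3`, `q_chosen`, `p_chosen`, `delta`; the `qk`/`pk`
#'   columns follow the `img1..img3` screen order of the design), `values`
#'   (`(n_trials+1) x n_images` matrix of pre-trial values), `nll`,
#'   `n_trials_used`, and `params`.
#' @export
compute_trace <- function(design, log, params) {
  stopifnot(inherits(params, "model_params"))
  enc <- encode_session(design, log)
  out <- .rl_forward_trace(enc$displayed, enc$chosen, enc$reward, enc$familiar,
                           params$alpha, params$beta,
                           params$q_init_familiar, params$q_init_novel)
  tr <- design$trials
  trials <- data.frame(
    run = tr$run, trial = tr$trial,
    chosen_id = log$chosen_id, reward = enc$reward,
    missed = enc$chosen == 0L,
    q1 = out$q_displayed[, 1L], q2 = out$q_displayed[, 2L],
    q3 = out$q_displayed[, 3L],
    p1 = out$choice_probs[, 1L], p2 = out$choice_probs[, 2L],
    p3 = out$choice_probs[, 3L],
    q_chosen = out$q_chosen, p_chosen = out$p_chosen, delta = out$delta,
    stringsAsFactors = FALSE
  )
  values <- out$values
  colnames(values) <- enc$ids
  structure(list(trials = trials, values = values, nll = out$nll,
                 n_trials_used = out$n_trials_used, params = params),
            class = "value_trace")
}

#' @export
print.value_trace <- function(x, ...) {
  cat(sprintf("<value_trace> %d trials (%d responded), nll = %.4f\n",
              nrow(x$trials), x$n_trials_used, x$nll))
  invisible(x)
}

#' Additive (novelty-attributable) value and prediction-error trace
#'
#' Element-wise differences between a full-model trace and a
#' constrained-model (baseline) trace computed on the same design and
#' choices: `Q_add = Q - Q_base` for each displayed option and
#' `delta_add = delta - delta_base` for the outcome. These are the novelty
#' components used as parametric modulators in model-based fMRI.
#'
#' @param trace_full `value_trace` under the full (novelty-bonus) model.
#' @param trace_base `value_trace` under the constrained model, built from
#'   the same design and choice log.
#' @return An object of class `additive_trace`: list with `trials` (data
#'   frame: `run`, `trial`, `missed`, `q_add1..q_add3`, `q_add_chosen`,
#'   `delta_add`) and the two parent traces.
#' @export
decompose_novelty <- function(trace_full, trace_base) {
  stopifnot(inherits(trace_full, "value_trace"),
            inherits(trace_base, "value_trace"))
  f <- trace_full$trials; b <- trace_base$trials
  if (nrow(f) != nrow(b) ||
      !identical(f$chosen_id, b$chosen_id) ||
      !identical(f$reward, b$reward))
    stop("trace misalignment: parents must share design and choice log",
         call. = FALSE)
  trials <- data.frame(
    run = f$run, trial = f$trial, missed = f$missed,
    q_add1 = f$q1 - b$q1, q_add2 = f$q2 - b$q2, q_add3 = f$q3 - b$q3,
    q_add_chosen = f$q_chosen - b$q_chosen,
    delta_add = f$delta - b$delta,
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials, full = trace_full, base = trace_base),
            class = "additive_trace")
}

#' @export
print.additive_trace <- function(x, ...) {
  cat(sprintf("<additive_trace> %d trials, mean |q_add(chosen)| = %.4g\n",
              nrow(x$trials), mean(abs(x$trials$q_add_chosen), na.rm = TRUE)))
  invisible(x)
}
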