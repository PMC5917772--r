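#' Trial timing configuration
#'
#' Event timing of one trial: stimulus presentation 3.5 s, choice feedback
#' 3 s, reward feedback 1.5 s presented 3 s after the key press, a 4.5 s
#' "No response" display on missed trials, and a jittered 1.5-3 s
#' intertrial interval.
#'
#' @param stimulus_duration Stimulus (cue) presentation, seconds.
#' @param feedback_duration Choice-feedback period, seconds.
#' @param outcome_duration Reward-feedback display, seconds.
#' @param outcome_delay Outcome onset relative to the key press, seconds.
#' @param iti_min,iti_max Bounds of the uniform intertrial jitter, seconds.
#' @param no_response_duration "No response" display on missed trials,
#'   seconds.
#' @return An object of class `timing_config`.
#' @export
timing_config <- function(stimulus_duration = 3.5, feedback_duration = 3,
                          outcome_duration = 1.5, outcome_delay = 3,
                          iti_min = 1.5, iti_max = 3,
                          no_response_duration = 4.5) {
  tc <- list(stimulus_duration = stimulus_duration,
             feedback_duration = feedback_duration,
             outcome_duration = outcome_duration,
             outcome_delay = outcome_delay,
             iti_min = iti_min, iti_max = iti_max,
             no_response_duration = no_response_duration)
  if (any(unlist(tc) <= 0) || iti_max < iti_min)
    stop("timing error: durations must be positive and iti_max >= iti_min",
         call. = FALSE)
  class(tc) <- "timing_config"
  tc
}

#' Build the parametric-modulator event table
#'
#' Constructs the model-based fMRI event table: one cue row per trial
#' carrying the chosen option's baseline value `Q_base` and novelty
#' component `Q_add` as modulators, and one outcome row per responded
#' trial carrying `delta_base` and `delta_add`. Missed trials produce a cue
#' row flagged `response = 0` and no outcome row. When no measured onsets
#' or response times are supplied they are synthesized from the timing
#' config: onsets restart at 0 in each run, response times are drawn
#' uniform on (0.3 s, stimulus duration), and the intertrial interval is
#' jittered uniformly. Modulators are exported uncentered; mean-centering
#' is a GLM-side choice.
#'
#' @param trace_full `value_trace` under the full model.
#' @param trace_base `value_trace` under the constrained model (same design
#'   and choices).
#' @param additive Optional [decompose_novelty()] result; computed from the
#'   parents when `NULL`.
#' @param timing A [timing_config()].
#' @param seed Integer seed for the synthesized response times and jitter.
#' @return An object of class `event_table`: data frame with columns
#'   `onset`, `duration`, `run`, `trial`, `trial_type` (`cue`/`outcome`),
#'   `response` (0/1), `q_base`, `q_add`, `delta_base`, `delta_add`
#'   (modulator columns are `NA` on rows of the other event type).
#' @export
build_events <- function(trace_full, trace_base, additive = NULL,
                         timing = timing_config(), seed = 1L) {
  if (is.null(additive)) additive <- decompose_novelty(trace_full, trace_base)
  stopifnot(inherits(additive, "additive_trace"),
            inherits(timing, "timing_config"))
  f <- trace_full$trials; b <- trace_base$trials; a <- additive$trials
  if (nrow(f) != nrow(a) || !identical(f$trial, a$trial))
    stop("trace misalignment: additive trace does not match parents",
         call. = FALSE)
  n <- nrow(f)
  build <- function() {
    rt <- stats::runif(n, 0.3, timing$stimulus_duration)
    iti <- stats::runif(n, timing$iti_min, timing$iti_max)
    rows <- vector("list", n)
    onset <- 0
    prev_run <- f$run[1L]
    for (t in seq_len(n)) {
      if (f$run[t] != prev_run) { onset <- 0; prev_run <- f$run[t] }
      missed <- f$missed[t]
      cue <- data.frame(
        onset = onset,
        duration = if (missed) timing$no_response_duration
                   else timing$stimulus_duration,
        run = f$run[t], trial = f$trial[t], trial_type = "cue",
        response = as.integer(!missed),
        q_base = if (missed) NA_real_ else b$q_chosen[t],
        q_add = if (missed) NA_real_ else a$q_add_chosen[t],
        delta_base = NA_real_, delta_add = NA_real_,
        stringsAsFactors = FALSE)
      if (missed) {
        rows[[t]] <- cue
        onset <- onset + timing$no_response_duration + iti[t]
      } else {
        outcome <- data.frame(
          onset = onset + rt[t] + timing$outcome_delay,
          duration = timing$outcome_duration,
          run = f$run[t], trial = f$trial[t], trial_type = "outcome",
          response = 1L,
          q_base = NA_real_, q_add = NA_real_,
          delta_base = b$delta[t], delta_add = a$delta_add[t],
          stringsAsFactors = FALSE)
        rows[[t]] <- rbind(cue, outcome)
        onset <- onset + timing$stimulus_duration +
          timing$feedback_duration + timing$outcome_duration + iti[t]
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("event_table", "data.frame")
    out
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' Write / read an event table
#'
#' BIDS-style events TSV: `onset`, `duration`, `trial_type` and the
#' modulator columns, tab-separated with `NA` for missing modulators and
#' `n/a`-free full-precision numbers, so a round trip preserves onsets to
#' well under 1 ms and modulators to 1e-9.
#'
#' @param events An `event_table`.
#' @param path File path.
#' @return `write_events` invisibly returns `path`; `read_events` the
#'   `event_table`.
#' @export
write_events <- function(events, path) {
  out <- as.data.frame(events)
  for (col in c("onset", "duration", "q_base", "q_add", "delta_base",
                "delta_add"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         sprintf("%.12g", out[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(onset = "numeric",
                                          duration = "numeric",
                                          run = "integer", trial = "integer",
                                          trial_type = "character",
                                          response = "integer",
                                          q_base = "numeric",
                                          q_add = "numeric",
                                          delta_base = "numeric",
                                          delta_add = "numeric"))
  class(out) <- c("event_table", "data.frame")
  out
}

#' Shared variance between two series
#'
#' Squared Pearson correlation expressed as percent, the collinearity
#' diagnostic for a pair of parametric-modulator series.
#'
#' @param x,y Numeric vectors (pairs with `NA` are dropped).
#' @return List with `r_squared_pct`, `n` (pairs used), and `note`
#'   (non-empty when a series has zero variance, in which case
#'   `r_squared_pct` is `NA`).
#' @export
shared_variance <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    return(list(r_squared_pct = NA_real_, n = length(x),
                note = "fewer than 3 complete pairs"))
  if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14)
    return(list(r_squared_pct = NA_real_, n = length(x),
                note = "zero-variance series: correlation undefined"))
  list(r_squared_pct = 100 * stats::cor(x, y)^2, n = length(x), note = "")
}

#' Value / prediction-error collinearity of an event table
#'
#' The design does not fully decorrelate values from prediction errors, so
#' this reports the percent shared variance (squared Pearson correlation)
#' between the per-trial chosen-option value series (`q_base + q_add`, the
#' full-model Q) and the prediction-error series (`delta_base +
#' delta_add`, the full-model delta), paired by trial over responded
#' trials.
#'
#' @param events An `event_table` from [build_events()].
#' @return As [shared_variance()].
#' @export
collinearity_check <- function(events) {
  cue <- events[events$trial_type == "cue" & events$response == 1L, ]
  out <- events[events$trial_type == "outcome", ]
  m <- match(cue$trial, out$trial)
  q <- cue$q_base + cue$q_add
  d <- out$delta_base[m] + out$delta_add[m]
  shared_variance(q, d)
}
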