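#' Total amount won in a session
#'
#' Sum of rewards times the reward magnitude (default £1 per win).
#'
#' @param log Choice log.
#' @param config The session's [task_config()].
#' @return Currency amount.
#' @export
amount_won <- function(log, config = task_config()) {
  sum(log$reward, na.rm = TRUE) * config$reward_magnitude
}

match_class <- function(novelty_class) {
  novelty_class <- match.arg(novelty_class, c("novel", "familiar"))
  novelty_class == "familiar"
}

# replacement-trial introductions of one novelty class; trial-1 images are
# a bootstrap (three simultaneous new images), not introductions
class_introductions <- function(design, novelty_class) {
  intro <- session_introductions(design)
  intro[intro$prefamiliarized == match_class(novelty_class), , drop = FALSE]
}

#' First-presentation choice rate
#'
#' Of the images of one novelty class introduced by replacement events, the
#' percentage chosen on the very trial they first appeared. Introduction
#' trials with no response are removed from the denominator. "First
#' presentation" of a familiar (pre-familiarized) image means its first
#' in-task appearance; its pre-task exposure is what makes it familiar.
#'
#' @param design A `session_design`.
#' @param log Choice log aligned with the design.
#' @param novelty_class `"novel"` or `"familiar"`.
#' @return Percentage in `[0, 100]`, or `NA` if the class has no
#'   introductions (or all its introduction trials were missed).
#' @export
first_presentation_choice_rate <- function(design, log, novelty_class) {
  intro <- class_introductions(design, novelty_class)
  if (nrow(intro) == 0L) return(NA_real_)
  chosen <- log$chosen_id[intro$trial]
  responded <- !is.na(chosen)
  if (!any(responded)) return(NA_real_)
  100 * mean(chosen[responded] == intro$image_id[responded])
}

#' Persistence runs after introduction
#'
#' For each image of a novelty class introduced by a replacement event: the
#' number of consecutive trials, starting at the introduction trial, on
#' which it was chosen. The run is 0 if the image was not chosen at
#' introduction, and breaks at the first trial where it is displayed but
#' not chosen, at a missed trial, or at its retirement from the screen.
#'
#' @inheritParams first_presentation_choice_rate
#' @return Named numeric vector of run lengths (names are image ids); empty
#'   when the class has no introductions.
#' @export
persistence_runs <- function(design, log, novelty_class) {
  intro <- class_introductions(design, novelty_class)
  if (nrow(intro) == 0L) return(stats::setNames(numeric(0), character(0)))
  tr <- design$trials
  disp <- as.matrix(tr[, c("img1", "img2", "img3")])
  n_trials <- nrow(tr)
  runs <- vapply(seq_len(nrow(intro)), function(i) {
    img <- intro$image_id[i]
    len <- 0L
    for (t in seq(intro$trial[i], n_trials)) {
      if (!img %in% disp[t, ]) break                     # retired
      if (is.na(log$chosen_id[t]) || log$chosen_id[t] != img) break
      len <- len + 1L
    }
    as.numeric(len)
  }, numeric(1L))
  stats::setNames(runs, intro$image_id)
}

#' Optimality of a displayed image
#'
#' An image is `"optimal"` on a trial iff its true reward probability is
#' strictly the greatest among the three displayed options; ties are
#' labelled `"non_optimal"`.
#'
#' @param design A `session_design`.
#' @param image Image id.
#' @param trial Session-global trial number on which the image is
#'   displayed.
#' @return `"optimal"` or `"non_optimal"`.
#' @export
optimality_label <- function(design, image, trial) {
  tr <- design$trials
  row <- which(tr$trial == trial)
  if (length(row) != 1L)
    stop(sprintf("trial %s not in design", format(trial)), call. = FALSE)
  disp <- unlist(tr[row, c("img1", "img2", "img3")], use.names = FALSE)
  if (!image %in% disp)
    stop(sprintf("image %s not displayed on trial %d", image, trial),
         call. = FALSE)
  probs <- design$catalog$reward_prob[match(disp, design$catalog$image_id)]
  p_img <- probs[disp == image][1L]
  if (sum(probs == max(probs)) == 1L && p_img == max(probs)) "optimal"
  else "non_optimal"
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

#' Behavioural summary of a session
#'
#' One row of the study's behavioural outcome measures: amount won, the
#' fitted novelty bonus (if a fit is supplied), first-presentation choice
#' rates for novel and familiar introductions, and mean persistence run
#' lengths split by novelty class and by whether the introduced image was
#' the optimal option on its introduction trial.
#'
#' @param design A `session_design`.
#' @param log Choice log.
#' @param fit Optional `fit_result` (or [model_params()]) supplying the
#'   novelty bonus.
#' @return A one-row data frame with columns `amount_won`, `novelty_bonus`,
#'   `pct_novel_first`, `pct_familiar_first`,
#'   `persistence_novel_optimal`, `persistence_novel_non_optimal`,
#'   `persistence_familiar_optimal`, `persistence_familiar_non_optimal`,
#'   `n_missed`.
#' @export
summarize_behavior <- function(design, log, fit = NULL) {
  bonus <- if (is.null(fit)) NA_real_ else novelty_bonus(fit)
  persist <- function(novelty_class) {
    runs <- persistence_runs(design, log, novelty_class)
    intro <- class_introductions(design, novelty_class)
    opt <- vapply(seq_len(nrow(intro)), function(i)
      optimality_label(design, intro$image_id[i], intro$trial[i]),
      character(1L))
    c(optimal = mean_or_na(runs[opt == "optimal"]),
      non_optimal = mean_or_na(runs[opt == "non_optimal"]))
  }
  pn <- persist("novel"); pf <- persist("familiar")
  data.frame(
    amount_won = amount_won(log, design$config),
    novelty_bonus = bonus,
    pct_novel_first = first_presentation_choice_rate(design, log, "novel"),
    pct_familiar_first = first_presentation_choice_rate(design, log, "familiar"),
    persistence_novel_optimal = pn[["optimal"]],
    persistence_novel_non_optimal = pn[["non_optimal"]],
    persistence_familiar_optimal = pf[["optimal"]],
    persistence_familiar_non_optimal = pf[["non_optimal"]],
    n_missed = sum(is.na(log$chosen_id))
  )
}
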