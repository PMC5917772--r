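#' Task configuration for the three-armed bandit with novelty manipulation
#'
#' Describes the bandit environment: three 80-trial runs, a 64-image pool of
#' which half was pre-familiarized before the task, a fixed per-image win
#' probability (mean 33%) paying 1 currency unit, and replacement of one
#' displayed option by a never-seen image on 25% of trials.
#'
#' @param n_runs Number of task runs per session.
#' @param trials_per_run Trials in each run.
#' @param n_options Options displayed per trial (the task uses 3).
#' @param replacement_fraction Fraction of trials on which one displayed
#'   option is replaced by a fresh image. Enforced as an exact count,
#'   `round(replacement_fraction * n_runs * trials_per_run)`, so the design
#'   statistic is deterministic rather than Bernoulli-per-trial.
#' @param pool_size Total images available per session.
#' @param n_prefamiliarized Images shown in the pre-task familiarization
#'   phase ("familiar" stimuli); the remainder are "novel" on first in-task
#'   appearance.
#' @param reward_prob_values Multiset of per-image win probabilities,
#'   assigned in balanced rotation within each novelty class; its mean must
#'   be 0.33 so both classes share the task's mean payoff rate.
#' @param reward_magnitude Currency units per win.
#' @param min_replacement_gap Minimum number of trials between consecutive
#'   replacement events (2 keeps at least one quiet trial between
#'   introductions).
#' @param balance_runs If `TRUE`, replacement events are split as evenly as
#'   possible across runs.
#' @param rng_seed Optional integer seed carried by the config;
#'   [generate_session()] uses it when no explicit seed is passed.
#'
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_runs * cfg$trials_per_run  # 240 trials
task_config <- function(n_runs = 3L,
                        trials_per_run = 80L,
                        n_options = 3L,
                        replacement_fraction = 0.25,
                        pool_size = 64L,
                        n_prefamiliarized = 32L,
                        reward_prob_values = c(0.20, 0.33, 0.46),
                        reward_magnitude = 1.0,
                        min_replacement_gap = 2L,
                        balance_runs = TRUE,
                        rng_seed = NULL) {
  cfg <- list(
    n_runs = as.integer(n_runs),
    trials_per_run = as.integer(trials_per_run),
    n_options = as.integer(n_options),
    replacement_fraction = replacement_fraction,
    pool_size = as.integer(pool_size),
    n_prefamiliarized = as.integer(n_prefamiliarized),
    reward_prob_values = as.numeric(reward_prob_values),
    reward_magnitude = as.numeric(reward_magnitude),
    min_replacement_gap = as.integer(min_replacement_gap),
    balance_runs = isTRUE(balance_runs),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$n_runs < 1L || cfg$trials_per_run < 1L)
    stop("config error: n_runs and trials_per_run must be >= 1", call. = FALSE)
  if (cfg$n_options != 3L)
    stop("config error: the task displays exactly 3 options per trial", call. = FALSE)
  if (cfg$replacement_fraction < 0 || cfg$replacement_fraction > 1)
    stop("config error: replacement_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$n_prefamiliarized > cfg$pool_size)
    stop("config error: n_prefamiliarized exceeds pool_size", call. = FALSE)
  if (any(cfg$reward_prob_values < 0 | cfg$reward_prob_values > 1))
    stop("config error: every reward probability must lie in [0, 1]", call. = FALSE)
  if (abs(mean(cfg$reward_prob_values) - 0.33) > 1e-9)
    stop("config error: mean(reward_prob_values) must equal 0.33", call. = FALSE)
  if (cfg$min_replacement_gap < 1L)
    stop("config error: min_replacement_gap must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  n <- x$n_runs * x$trials_per_run
  cat(sprintf(
    "<task_config> %d runs x %d trials (%d total), %d replacement trials,\n",
    x$n_runs, x$trials_per_run, n, round(x$replacement_fraction * n)))
  cat(sprintf("  pool %d images (%d pre-familiarized), reward probs {%s}, %.2f per win\n",
              x$pool_size, x$n_prefamiliarized,
              paste(format(x$reward_prob_values), collapse = ", "),
              x$reward_magnitude))
  invisible(x)
}

# Sample k positions from 2..n_trials with pairwise spacing >= gap, via the
# order-statistics shift trick so feasibility is decided up front.
sample_spaced_positions <- function(n_trials, k, gap) {
  if (k == 0L) return(integer(0))
  m <- n_trials - 1L                      # candidates are trials 2..n_trials
  span <- m - (k - 1L) * (gap - 1L)
  if (span < k)
    stop(sprintf(
      "design error: cannot place %d replacement events in %d trials with gap %d",
      k, n_trials, gap), call. = FALSE)
  base <- sort(sample.int(span, k))
  base + (seq_len(k) - 1L) * (gap - 1L) + 1L
}

#' Generate a session design
#'
#' Builds the full trial-by-trial environment for one session: which three
#' images are displayed on every trial, which trials carry a replacement
#' event and which fresh image each introduces, and the per-image fixed
#' reward probabilities. Introduced images alternate between the
#' pre-familiarized and novel pools so both classes are introduced equally
#' often; reward probabilities are assigned within each class by cycling
#' shuffled copies of `reward_prob_values`, keeping class-wise mean payoff
#' at 0.33. Once introduced an image stays on screen until it is itself
#' replaced, and replaced images are retired for the session.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; defaults to `config$rng_seed`. The same seed
#'   reproduces the identical design.
#' @return An object of class `session_design`: a list with elements
#'   `config`, `catalog` (data frame: `image_id`, `prefamiliarized`,
#'   `reward_prob`) and `trials` (data frame: `run`, `trial`, `img1`,
#'   `img2`, `img3`, `replacement`, `introduced_id`). `trial` is 1-based
#'   and session-global; `img1..img3` record screen position left-to-right
#'   (positions are reshuffled every trial and carry no value).
#' @export
#' @examples
#' d <- generate_session(task_config(), seed = 1)
#' nrow(d$trials)            # 240
#' sum(d$trials$replacement) # 60
generate_session <- function(config = task_config(), seed = config$rng_seed) {
  validate_task_config(config)
  n_trials <- config$n_runs * config$trials_per_run
  n_rep <- as.integer(round(config$replacement_fraction * n_trials))
  if (3L + n_rep > config$pool_size)
    stop(sprintf(
      "design error: schedule needs %d images but the pool holds %d",
      3L + n_rep, config$pool_size), call. = FALSE)

  build <- function() {
    n_fam <- config$n_prefamiliarized
    n_nov <- config$pool_size - n_fam
    fam_ids <- sprintf("F%02d", seq_len(n_fam))
    nov_ids <- sprintf("N%02d", seq_len(n_nov))

    # replacement trial positions (session-global, never trial 1)
    if (config$balance_runs && config$n_runs > 1L) {
      per_run <- rep(n_rep %/% config$n_runs, config$n_runs)
      extra <- n_rep %% config$n_runs
      if (extra > 0L)
        per_run[sample.int(config$n_runs, extra)] <- per_run[1L] + 1L
      rep_trials <- unlist(lapply(seq_len(config$n_runs), function(r) {
        (r - 1L) * config$trials_per_run +
          sample_spaced_positions(config$trials_per_run, per_run[r],
                                  config$min_replacement_gap)
      }))
    } else {
      rep_trials <- sample_spaced_positions(n_trials, n_rep,
                                            config$min_replacement_gap)
    }
    rep_trials <- sort(rep_trials)

    # introduction order per pool, and balanced-rotation reward probabilities
    fam_order <- sample(fam_ids)
    nov_order <- sample(nov_ids)
    prob_seq <- function(n) {
      k <- length(config$reward_prob_values)
      out <- unlist(replicate(ceiling(n / k),
                              sample(config$reward_prob_values),
                              simplify = FALSE))
      out[seq_len(n)]
    }
    catalog <- data.frame(
      image_id = c(fam_order, nov_order),
      prefamiliarized = rep(c(TRUE, FALSE), c(n_fam, n_nov)),
      reward_prob = c(prob_seq(n_fam), prob_seq(n_nov)),
      stringsAsFactors = FALSE
    )
    catalog <- catalog[order(catalog$image_id), , drop = FALSE]
    rownames(catalog) <- NULL

    # class of each introduction: strict alternation, random starting class
    intro_class <- rep(c("familiar", "novel"), length.out = n_rep)
    if (n_rep > 0L && sample(c(TRUE, FALSE), 1L))
      intro_class <- rev(rep(c("novel", "familiar"), length.out = n_rep))

    next_fam <- 1L; next_nov <- 1L
    take <- function(class) {
      if (class == "familiar") {
        if (next_fam > n_fam)
          stop(sprintf(
            "design error: familiar pool exhausted (needed > %d images)",
            n_fam), call. = FALSE)
        id <- fam_order[next_fam]; next_fam <<- next_fam + 1L
      } else {
        if (next_nov > n_nov)
          stop(sprintf(
            "design error: novel pool exhausted (needed > %d images)",
            n_nov), call. = FALSE)
        id <- nov_order[next_nov]; next_nov <<- next_nov + 1L
      }
      id
    }

    # trial 1 bootstrap: one image from each class plus one at random
    displayed <- c(take("familiar"), take("novel"),
                   take(sample(c("familiar", "novel"), 1L)))

    img <- matrix(NA_character_, n_trials, 3L)
    replacement <- rep(FALSE, n_trials)
    introduced <- rep(NA_character_, n_trials)
    is_rep <- logical(n_trials); is_rep[rep_trials] <- TRUE
    rep_i <- 1L
    for (t in seq_len(n_trials)) {
      if (is_rep[t]) {
        slot <- sample.int(3L, 1L)
        new_id <- take(intro_class[rep_i])
        displayed[slot] <- new_id
        replacement[t] <- TRUE
        introduced[t] <- new_id
        rep_i <- rep_i + 1L
      }
      img[t, ] <- sample(displayed)   # screen positions shuffle every trial
    }
    trials <- data.frame(
      run = rep(seq_len(config$n_runs), each = config$trials_per_run),
      trial = seq_len(n_trials),
      img1 = img[, 1L], img2 = img[, 2L], img3 = img[, 3L],
      replacement = replacement,
      introduced_id = introduced,
      stringsAsFactors = FALSE
    )
    structure(list(config = config, catalog = catalog, trials = trials),
              class = "session_design")
  }

  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %d trials (%d runs), %d replacement trials, %d images used\n",
              nrow(x$trials), x$config$n_runs, sum(x$trials$replacement),
              length(session_images_used(x))))
  invisible(x)
}

# image ids that appear on screen at least once
session_images_used <- function(design) {
  unique(c(t(as.matrix(design$trials[, c("img1", "img2", "img3")]))))
}

# trial-1 images plus every replacement introduction, with novelty class
session_introductions <- function(design, include_bootstrap = FALSE) {
  tr <- design$trials
  fam <- stats::setNames(design$catalog$prefamiliarized, design$catalog$image_id)
  rep_rows <- which(tr$replacement)
  out <- data.frame(
    trial = tr$trial[rep_rows],
    image_id = tr$introduced_id[rep_rows],
    stringsAsFactors = FALSE
  )
  if (include_bootstrap) {
    boot <- data.frame(trial = 1L,
                       image_id = unlist(tr[1L, c("img1", "img2", "img3")],
                                         use.names = FALSE),
                       stringsAsFactors = FALSE)
    out <- rbind(boot, out)
  }
  out$prefamiliarized <- unname(fam[out$image_id])
  out
}

#' Write / read a session design
#'
#' The design is serialized as a tab-separated trial table (one row per
#' trial: `run`, `trial`, `img1`, `img2`, `img3`, `replacement`,
#' `introduced_id`) preceded by `#`-prefixed header lines carrying the
#' config, plus a catalog sidecar (`image_id`, `prefamiliarized`,
#' `reward_prob`) written next to it. `read_design(write_design(d))`
#' reproduces `d` field for field.
#'
#' @param design A `session_design`.
#' @param path Path of the trial table; the catalog sidecar is written to
#'   `catalog_path`.
#' @param catalog_path Path of the catalog sidecar (default: `path` with
#'   `_catalog` inserted before the extension).
#' @return `write_design` invisibly returns `path`; `read_design` returns
#'   the reconstructed `session_design`.
#' @export
write_design <- function(design, path,
                         catalog_path = default_catalog_path(path)) {
  stopifnot(inherits(design, "session_design"))
  cfg <- design$config
  hdr <- c(
    sprintf("# n_runs=%d", cfg$n_runs),
    sprintf("# trials_per_run=%d", cfg$trials_per_run),
    sprintf("# n_options=%d", cfg$n_options),
    sprintf("# replacement_fraction=%.17g", cfg$replacement_fraction),
    sprintf("# pool_size=%d", cfg$pool_size),
    sprintf("# n_prefamiliarized=%d", cfg$n_prefamiliarized),
    sprintf("# reward_prob_values=%s",
            paste(sprintf("%.17g", cfg$reward_prob_values), collapse = ",")),
    sprintf("# reward_magnitude=%.17g", cfg$reward_magnitude),
    sprintf("# min_replacement_gap=%d", cfg$min_replacement_gap),
    sprintf("# balance_runs=%s", cfg$balance_runs),
    if (!is.null(cfg$rng_seed)) sprintf("# rng_seed=%d", cfg$rng_seed)
  )
  tr <- design$trials
  tr$replacement <- as.integer(tr$replacement)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tr, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  utils::write.table(design$catalog, catalog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

default_catalog_path <- function(path) {
  sub("(\\.[^./\\\\]+)?$", "_catalog\\1", path)
}

#' @rdname write_design
#' @export
read_design <- function(path, catalog_path = default_catalog_path(path)) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE))
  conf <- stats::setNames(as.list(kv[, 2L]), kv[, 1L])
  cfg <- task_config(
    n_runs = as.integer(conf$n_runs),
    trials_per_run = as.integer(conf$trials_per_run),
    n_options = as.integer(conf$n_options),
    replacement_fraction = as.numeric(conf$replacement_fraction),
    pool_size = as.integer(conf$pool_size),
    n_prefamiliarized = as.integer(conf$n_prefamiliarized),
    reward_prob_values = as.numeric(strsplit(conf$reward_prob_values, ",")[[1L]]),
    reward_magnitude = as.numeric(conf$reward_magnitude),
    min_replacement_gap = as.integer(conf$min_replacement_gap),
    balance_runs = as.logical(conf$balance_runs),
    rng_seed = if (is.null(conf$rng_seed)) NULL else as.integer(conf$rng_seed)
  )
  tr <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  needed <- c("run", "trial", "img1", "img2", "img3", "replacement",
              "introduced_id")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols))
    stop(sprintf("parse error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tr$run <- as.integer(tr$run)
  tr$trial <- as.integer(tr$trial)
  for (col in c("img1", "img2", "img3", "introduced_id"))
    tr[[col]] <- as.character(tr[[col]])
  bad <- which(is.na(tr$run) | is.na(tr$trial) | is.na(tr$img1) |
                 is.na(tr$img2) | is.na(tr$img3) | is.na(tr$replacement))
  if (length(bad))
    stop(sprintf("parse error in %s: malformed row %d", path, bad[1L]),
         call. = FALSE)
  tr$replacement <- as.logical(tr$replacement)
  cat <- utils::read.table(catalog_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(image_id = "character",
                                          prefamiliarized = "logical",
                                          reward_prob = "numeric"))
  if (!all(c("image_id", "prefamiliarized", "reward_prob") %in% names(cat)))
    stop(sprintf("parse error in %s: catalog needs image_id, prefamiliarized, reward_prob",
                 catalog_path), call. = FALSE)
  structure(list(config = cfg, catalog = cat, trials = tr),
            class = "session_design")
}

#' Write / read a choice log
#'
#' Tab-separated, columns `run`, `trial`, `chosen_id` (`NA` on missed
#' trials), `reward`; joins to the design file by (`run`, `trial`).
#'
#' @param log A choice-log data frame.
#' @param path File path.
#' @return `write_choices` invisibly returns `path`; `read_choices` the
#'   choice-log data frame.
#' @export
write_choices <- function(log, path) {
  utils::write.table(log[, c("run", "trial", "chosen_id", "reward")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  log <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(run = "integer", trial = "integer",
                                          chosen_id = "character",
                                          reward = "numeric"))
  needed <- c("run", "trial", "chosen_id", "reward")
  missing_cols <- setdiff(needed, names(log))
  if (length(missing_cols))
    stop(sprintf("parse error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  log
}
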