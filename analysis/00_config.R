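# Shared settings for the analysis drivers. Cohort sizes here are chosen
# to keep each driver in the minutes range on a laptop; the package
# functions scale to the full 30-per-group crossover unchanged.

library(noveltybandit)

ANALYSIS_SEED <- 20260924L
N_SUBJECTS <- 12L          # per group; the study itself had 30 per group
FIT_OPTS <- fit_options(n_starts = 10L, rng_seed = 1L)
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

result_path <- function(...) file.path(RESULTS_DIR, ...)
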