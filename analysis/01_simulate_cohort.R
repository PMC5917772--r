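#!/usr/bin/env Rscript

# Simulate the group-by-drug crossover cohort: ADHD and control groups,
# each subject tested on placebo and drug, parameters drawn from the
# fitted cell means/SEs, each session on a fresh 240-trial design.
# Writes the cohort manifest (true parameters per session); the later
# drivers regenerate the identical cohort from the same seed.

source("analysis/00_config.R")

spec <- cohort_spec(n_subjects = N_SUBJECTS, rng_seed = ANALYSIS_SEED)
cohort <- generate_cohort(spec)

write.table(cohort$manifest, result_path("cohort_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

m <- cohort$manifest
cat(sprintf("simulated %d sessions (%d subjects x 2 conditions)\n",
            length(cohort$sessions), 2L * N_SUBJECTS))
for (g in c("ADHD", "control")) for (cond in c("placebo", "drug"))
  cat(sprintf("  %-7s %-7s  mean true alpha %.2f, beta %5.2f, bonus %+.3f\n",
              g, cond,
              mean(m$alpha[m$group == g & m$condition == cond]),
              mean(m$beta[m$group == g & m$condition == cond]),
              mean(m$novelty_bonus[m$group == g & m$condition == cond])))
cat("wrote", result_path("cohort_manifest.tsv"), "\n")
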