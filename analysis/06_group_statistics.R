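#!/usr/bin/env Rscript
# Step 6 — group comparisons.
#
# The comparison set on 75% thresholds: speed change vs each speed-
# discrimination condition (pooled two-sample t, Bonferroni alpha 0.0167
# for the three-comparison family) and duration vs distance (paired t),
# each with a JZS default Bayes factor (Cauchy scale 0.707); plus the
# cross-condition correlation of catch-interval percentages, which indexes
# whether simulated participants keep the same catch cue in both blocks.

suppressPackageStartupMessages(library(loomdiscrim))

trials <- read_cohort("results/cohort")
bundle <- run_pipeline(trials, out_dir = "results")
print(bundle)

cat("\nReading of the result: under analysis I the speed-change thresholds\n")
cat("sit well above the speed-discrimination thresholds, but under analysis\n")
cat("II (end-speed difference) the gap closes - the signature of observers\n")
cat("comparing speeds between intervals rather than detecting the change.\n")
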