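#!/usr/bin/env Rscript
# Step 5 — catch-trial cue classification.
#
# On catch trials both intervals share the standard speed but the catch
# interval lasts longer and travels further. A participant using only
# speed picks it ~50% of the time; the exact binomial region at n = 30
# (reject at <= 9 or >= 21, i.e. outside 30-70%) classifies each
# participant as a duration, speed, or distance user.

suppressPackageStartupMessages(library(loomdiscrim))

trials <- read_cohort("results/cohort")
tab <- catch_table(trials)
write.csv(tab, "results/catch.csv", row.names = FALSE)

r <- rejection_region(30)
cat(sprintf("Rejection region at n = 30: <= %d or >= %d picks (%.0f%% / %.0f%%)\n\n",
            r$k_lo, r$k_hi, 100 * r$k_lo / 30, 100 * r$k_hi / 30))
cat("Per-participant classification:\n")
print(transform(tab, percent = round(percent, 1)), row.names = FALSE)
cat("\nCue counts by condition:\n")
print(table(tab$condition, tab$category))
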