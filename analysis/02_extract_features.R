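#!/usr/bin/env Rscript
# Step 2: extract the three physiological features from the raw signals.
#
# Pupil dilation (% change from the first-second baseline, blinks excluded),
# blink rate (maximal missing-sample runs per second) and normalized GSR
# (per-second ratio to the participant's pooled mean, divided by task length)
# are computed for every participant-task, then checked against the
# generator's recorded targets: extraction must invert synthesis.

suppressMessages(library(bcirisk))
cohort <- readRDS("scratch/cohort.rds")

features <- build_feature_table(cohort)
write_feature_table(features, "results/features.csv")

rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-8)
err <- c(pupil = max(rel(features$pupil_pct, cohort$features$pupil_pct)),
         blink = max(rel(features$blink_rate, cohort$features$blink_rate)),
         gsr = max(rel(features$gsr_norm, cohort$features$gsr_norm)))
cat("Worst relative round-trip error per feature:\n")
print(signif(err, 3))
stopifnot(all(err < 0.01))

cat("\nPer-task feature means (extracted):\n")
agg <- aggregate(features[, c("pupil_pct", "blink_rate", "gsr_norm")],
                 by = list(task = features$task), mean)
print(cbind(agg[1], signif(agg[-1], 3)), row.names = FALSE)
cat("\nFeature table written to results/features.csv\n")
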