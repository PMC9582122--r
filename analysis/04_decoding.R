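#!/usr/bin/env Rscript
# Stage 4: population decoding of the stimulus condition.
#
# Sites are ranked by encoding accuracy; for each ensemble size a random
# half-subgroup's measured projection pattern on each held-out test trial is
# matched (Pearson correlation) against the per-condition patterns predicted
# by leave-one-trial-out condition regressions. Chance is 50%.

library(narrband)

seed <- 20260920L
out <- "results/run"

enc <- tibble::as_tibble(read.csv(file.path(out, "encoding_results.csv")))
proj <- tibble::as_tibble(read.csv(file.path(out, "projections.csv")))
split_lines <- readLines(file.path(out, "trial_split.txt"))
test_ids <- strsplit(split_lines[2], ",")[[1]]

ranking <- rank_sites(enc)
curve <- accuracy_curve(proj, ranking, test_ids,
                        sizes = seq(4, nrow(ranking), by = 2),
                        repeats = 10, seed = seed + 404L)

best <- curve[which.max(curve$mean_accuracy), ]
cat(sprintf("peak decoding accuracy: %.1f%% (SEM %.1f) at %d sites\n",
            best$mean_accuracy, best$sem, best$size))
cat(sprintf("accuracy at the largest ensemble (%d sites): %.1f%%\n",
            max(curve$size), curve$mean_accuracy[which.max(curve$size)]))

write.csv(curve, file.path(out, "decoding_curve.csv"), row.names = FALSE)
cat("wrote decoding_curve.csv\n")
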