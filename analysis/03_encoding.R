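#!/usr/bin/env Rscript
# Stage 3: PCA of the pooled spectra and the PC1-projection encoding model.
#
# Pooled centered PCA on the condition-averaged spectra shows a dominant
# broadband PC1; leave-one-subject-out PCA yields single-trial PC1
# projections, which the condition-indicator regression turns into per-site
# encoding accuracies (Monte-Carlo cross-validation, 10 folds of 17 train /
# 27 validation from the 44-trial pool) with a condition-swap permutation
# null. The first-vs-rest grouping probes the habituation/novelty motif.

library(narrband)

seed <- 20260920L
out <- "results/run"

rec <- read_recording("scratch/run/recording")
rec <- common_average_reference(rec)
epochs <- epoch_transitions(
  rec, classes = c("first_of_experiment", "isi_to_image", "image_to_image"))
psds <- normalize_psd_set(compute_psds(epochs))
main <- psds$meta$transition_class == "image_to_image"
main_psds <- structure(list(values = psds$values[main, , drop = FALSE],
                            grid = psds$grid, meta = psds$meta[main, ]),
                       class = "narr_psd")
cond_avg <- condition_average(main_psds)

pooled <- fit_psd_pca(cond_avg)
cat(sprintf("pooled PCA: PC1 %.1f%% of variance, PC2 %.1f%%\n",
            100 * pooled$variance_fractions[1],
            100 * pooled$variance_fractions[2]))

proj <- loso_project_all(cond_avg, psds)
main_proj <- proj[proj$transition_class == "image_to_image", ]
split <- trial_split(unique(main_proj[, c("trial_id", "condition")]),
                     seed = seed + 202L)

enc <- encode_sites(main_proj, split$pool, n_perm = 1000, seed = seed + 303L)
cat(sprintf("high-encoding sites: %d of %d (alpha = 0.05)\n",
            sum(enc$significant), nrow(enc)))
sig <- enc[enc$significant, ]
cat("by region:\n")
print(table(sig$region, ifelse(sig$w_scr > sig$w_seq, "Scr>Seq", "Seq>Scr")))

fr <- first_vs_rest_contrast(proj)
cat("\nfirst-vs-rest contrasts (frontal/temporal):\n")
print(as.data.frame(fr$tests), digits = 3)

write.csv(enc, file.path(out, "encoding_results.csv"), row.names = FALSE)
write.csv(main_proj, file.path(out, "projections.csv"), row.names = FALSE)
write.csv(proj, file.path(out, "projections_all_classes.csv"),
          row.names = FALSE)
write.csv(fr$cells, file.path(out, "first_vs_rest_cells.csv"),
          row.names = FALSE)
write.csv(fr$tests, file.path(out, "first_vs_rest_tests.csv"),
          row.names = FALSE)
writeLines(c(paste(split$pool, collapse = ","),
             paste(split$test, collapse = ",")),
           file.path(out, "trial_split.txt"))
cat("wrote encoding_results.csv, projections.csv, first_vs_rest_*.csv\n")
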