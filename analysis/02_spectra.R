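#!/usr/bin/env Rscript
# Stage 2: preprocess the cohort and compute normalized single-trial spectra.
#
# Common-average reference per subject, peri-transition epochs (-100..+500 ms
# around image onsets), single-trial Welch PSDs on the 2-100 Hz grid
# (56-63 Hz excluded), per-site normalization to the all-trial mean, and
# condition averages (one Scr and one Seq spectrum per site).

library(narrband)

out <- "results/run"
rec <- read_recording("scratch/run/recording")
rec <- common_average_reference(rec)

epochs <- epoch_transitions(
  rec, classes = c("first_of_experiment", "isi_to_image", "image_to_image"))
cat("epochs:", nrow(epochs$data), " (",
    length(unique(epochs$meta$site_id)), "sites x",
    nrow(epochs$data) / length(unique(epochs$meta$site_id)),
    "image transitions )\n")

psds <- normalize_psd_set(compute_psds(epochs))
main <- psds$meta$transition_class == "image_to_image"
main_psds <- structure(list(values = psds$values[main, , drop = FALSE],
                            grid = psds$grid, meta = psds$meta[main, ]),
                       class = "narr_psd")
cond_avg <- condition_average(main_psds)
cat("condition-averaged PSDs:", nrow(cond_avg$values),
    "( = sites x 2 conditions )\n")

dir.create(out, showWarnings = FALSE, recursive = TRUE)
write.csv(cbind(psds$meta, as.data.frame(psds$values)),
          "scratch/run/trial_psds.csv", row.names = FALSE)
write.csv(cbind(cond_avg$meta, as.data.frame(cond_avg$values)),
          file.path(out, "condition_avg_psds.csv"), row.names = FALSE)
cat("wrote scratch/run/trial_psds.csv and condition_avg_psds.csv\n")
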