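#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort under the default study conditions.
#
# Thirteen subjects view two blocks of seven five-image series (scrambled
# then sequential; 2 s images, 6 s gray inter-series screens). Each subject
# contributes six depth-electrode sites (2 frontal, 2 temporal, 1 parietal,
# 1 insular) recorded at 1 kHz: 1/f background plus a 10-100 Hz broadband
# component whose post-onset (100-500 ms) amplitude carries the injected
# region x condition gains, with directed temporal-led coupling during
# sequential viewing and parietal-led coupling during scrambled viewing.

library(narrband)

seed <- 20260920L
out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

rec <- simulate_recording(
  sites = make_sites(13, c(frontal = 2, temporal = 2, parietal = 1,
                           insula = 1)),
  schedule = generate_schedule(),
  effects = effect_spec(),
  coupling = coupling_spec(),
  noise = noise_spec(),
  seed = seed)

print(rec)
cat("image events:", sum(rec$events$kind == "image"),
    " (", sum(rec$events$condition == "Scr" & rec$events$kind == "image"),
    "per condition )\n")
cat("injected coupling edges (site pairs):",
    nrow(rec$ground_truth$edges), "\n")

write_recording(rec, "scratch/run/recording")
cat("wrote scratch/run/recording\n")
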