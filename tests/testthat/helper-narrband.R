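# simulate a small cohort on the full default schedule
sim_cohort <- function(seed, n_subjects = 2,
                       per_region = c(frontal = 2, temporal = 2),
                       effects = effect_spec(null = TRUE),
                       coupling = no_coupling(),
                       noise = noise_spec(),
                       car = TRUE) {
  rec <- simulate_recording(make_sites(n_subjects, per_region),
                            generate_schedule(), effects, coupling, noise,
                            seed = seed)
  if (car) rec <- common_average_reference(rec)
  rec
}

# independent periodogram oracle: raw one-sided FFT power of a z-scored
# epoch, mean over a Hz band (no segmentation, no windowing -- deliberately
# different from the Welch path it cross-checks)
band_power_oracle <- function(epoch, band = c(10, 100), fs = 1000) {
  z <- (epoch - mean(epoch)) / sd(epoch)
  n <- length(z)
  p <- Mod(fft(z))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  mean(p[f >= band[1] & f <= band[2] & f <= fs / 2])
}

# stimulus-indexed synthetic projection records over the default 56-trial
# image-to-image universe: site i carries condition contrast delta * w_i
# (+ toward Seq) plus unit noise, with site weights w_i spread over [-1, 1]
# so the population pattern is heterogeneous (pattern correlation decoding
# needs site-to-site weight variation to have signal)
synthetic_projections <- function(n_sites, delta = 0, seed = 1,
                                  region = "temporal") {
  sched <- generate_schedule()
  img <- sched[sched$transition_class == "image_to_image", ]
  tid <- paste(img$condition, img$series_index, img$position_in_series,
               sep = "_")
  w <- if (n_sites == 1) 1 else seq(-1, 1, length.out = n_sites)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_sites), function(i) {
      tibble::tibble(
        subject_id = "S01", site_id = sprintf("S01_c%02d", i),
        region = region, hemisphere = "L",
        condition = img$condition, transition_class = img$transition_class,
        onset_ms = img$onset_ms, trial_id = tid,
        y = ifelse(img$condition == "Seq", 1, -1) * delta * w[i] / 2 +
          rnorm(nrow(img)))
    })
    dplyr::bind_rows(rows)
  })
}

simulate_var1 <- function(n_trials, n_samples, a = 0.3, c = 0.5, seed = 1) {
  # y_t = a*y_{t-1} + c*x_{t-1} + e_t, x white noise, unit innovations
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_trials * n_samples), n_trials, n_samples)
    y <- matrix(0, n_trials, n_samples)
    e <- matrix(rnorm(n_trials * n_samples), n_trials, n_samples)
    for (t in 2:n_samples)
      y[, t] <- a * y[, t - 1] + c * x[, t - 1] + e[, t]
    list(x = x, y = y)
  })
}

# closed-form log variance ratio for the VAR(1) above at AR order 1:
# gamma0 = (c^2 + 1)/(1 - a^2), gamma1 = a*gamma0, full residual variance 1,
# restricted AR(1) residual variance gamma0*(1 - a^2) = c^2 + 1
var1_gc_oracle <- function(a = 0.3, c = 0.5) log(c^2 + 1)

# brute-force two-sided Fisher p: enumerate all 2x2 tables with the observed
# margins, sum probabilities <= the observed table's probability
fisher_exact_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  dh <- function(a) dhyper(a, r1, r2, c1)
  p_obs <- dh(tab[1, 1])
  sum(vapply(max(0, c1 - r2):min(r1, c1), dh, numeric(1))[
    vapply(max(0, c1 - r2):min(r1, c1), dh, numeric(1)) <=
      p_obs * (1 + 1e-7)])
}
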