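BRAIN_REGIONS <- c("frontal", "temporal", "parietal", "insula",
                   "occipital", "basal_ganglia")

#' Build a site table for a synthetic cohort
#'
#' @param n_subjects Number of subjects.
#' @param per_region Named integer vector: sites per region for every subject.
#'   Names must be among the six region labels.
#' @return Tibble with `subject_id`, `site_id`, `region`, `hemisphere`,
#'   `excluded` (all FALSE). Hemispheres alternate L/R within region.
#' @export
make_sites <- function(n_subjects = 13L,
                       per_region = c(frontal = 2L, temporal = 2L)) {
  stopifnot(n_subjects >= 1, all(names(per_region) %in% BRAIN_REGIONS),
            all(per_region >= 0))
  rows <- lapply(seq_len(n_subjects), function(s) {
    region <- rep(names(per_region), times = per_region)
    n <- length(region)
    tibble::tibble(
      subject_id = sprintf("S%02d", s),
      site_id = sprintf("%s_c%02d", sprintf("S%02d", s), seq_len(n)),
      region = region,
      hemisphere = rep_len(c("L", "R"), n),
      excluded = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Region/condition broadband gain specification
#'
#' Multiplicative gains applied to the band-limited broadband component in the
#' 100-500 ms post-onset window, split by transition phase: "first" (the first
#' transition of a series, i.e. gray-screen to image, plus the experiment's
#' very first image) versus "rest" (within-series image-to-image transitions).
#' Defaults encode the habituation motif: frontal broadband is higher for
#' scrambled than sequential images after the first transition, temporal is
#' higher for sequential, and first transitions are condition-equal.
#'
#' @param overrides Optional data frame with columns `region`, `condition`,
#'   `phase`, `gain` replacing default cells.
#' @param null If TRUE all gains are 1 (no condition information).
#' @return Tibble with one row per region x condition x phase.
#' @export
effect_spec <- function(overrides = NULL, null = FALSE) {
  grid <- expand.grid(region = BRAIN_REGIONS, condition = c("Scr", "Seq"),
                      phase = c("first", "rest"), stringsAsFactors = FALSE)
  grid$gain <- 1
  if (!null) {
    set_gain <- function(g, region, condition, phase, gain) {
      i <- g$region == region & g$condition == condition & g$phase == phase
      g$gain[i] <- gain
      g
    }
    grid <- set_gain(grid, "frontal", "Scr", "rest", 1.5)
    grid <- set_gain(grid, "frontal", "Seq", "rest", 1.0)
    grid <- set_gain(grid, "temporal", "Seq", "rest", 1.5)
    grid <- set_gain(grid, "temporal", "Scr", "rest", 1.0)
    # first transitions: elevated but equal across conditions
    for (cc in c("Scr", "Seq")) {
      grid <- set_gain(grid, "frontal", cc, "first", 1.25)
      grid <- set_gain(grid, "temporal", cc, "first", 1.25)
    }
  }
  if (!is.null(overrides)) {
    for (r in seq_len(nrow(overrides))) {
      i <- grid$region == overrides$region[r] &
        grid$condition == overrides$condition[r] &
        grid$phase == overrides$phase[r]
      if (!any(i)) stop("unknown effect cell in overrides, row ", r)
      grid$gain[i] <- overrides$gain[r]
    }
  }
  if (any(grid$gain <= 0)) stop("all gains must be > 0")
  tibble::as_tibble(grid)
}

#' Directed inter-regional coupling specification
#'
#' Each edge adds a lagged, scaled copy of a source-region site's signal to a
#' sink-region site, only inside the 100-500 ms post-onset windows of the
#' edge's condition, giving a well-defined Granger-causal ground truth.
#' Defaults mirror the narrative-network motif: temporal leads frontal,
#' parietal and insula during sequential viewing; parietal leads temporal
#' during scrambled viewing.
#'
#' @param edges Data frame with columns `source_region`, `sink_region`,
#'   `condition`, `lag` (samples, >= 1), `coefficient` (|c| < 1). NULL gives
#'   the default edge set; use `coupling_spec(edges = no_coupling())` for none.
#' @return Tibble of validated edges.
#' @export
coupling_spec <- function(edges = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(
      source_region = c("temporal", "temporal", "temporal", "parietal"),
      sink_region = c("frontal", "parietal", "insula", "temporal"),
      condition = c("Seq", "Seq", "Seq", "Scr"),
      lag = 5L,
      coefficient = 0.5)
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    stopifnot(all(c("source_region", "sink_region", "condition", "lag",
                    "coefficient") %in% names(edges)))
    if (any(abs(edges$coefficient) >= 1))
      stop("unstable coupling: |coefficient| must be < 1")
    if (any(edges$lag < 1)) stop("lag must be >= 1 sample")
  }
  edges
}

#' Empty coupling table (no directed edges).
#' @return Zero-row edge tibble.
#' @export
no_coupling <- function() {
  tibble::tibble(source_region = character(), sink_region = character(),
                 condition = character(), lag = integer(),
                 coefficient = numeric())
}

#' Background-noise specification for the LFP generator
#'
#' @param exponent 1/f spectral exponent of the background (power ~ f^-exponent).
#' @param amplitude Background standard deviation (arbitrary units).
#' @param broadband_amplitude Standard deviation of the band-limited broadband
#'   component the condition gains act on.
#' @param band Hz range of the broadband component.
#' @param fs Sampling rate, fixed at 1000 Hz for generated data.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(exponent = 1, amplitude = 1, broadband_amplitude = 1,
                       band = c(10, 100), fs = 1000) {
  stopifnot(exponent >= 0, amplitude > 0, broadband_amplitude >= 0,
            length(band) == 2, band[1] < band[2], fs == 1000)
  structure(list(exponent = exponent, amplitude = amplitude,
                 broadband_amplitude = broadband_amplitude,
                 band = band, fs = fs),
            class = "noise_spec")
}

# Colored noise via spectral shaping: unit-variance series whose power
# spectrum follows f^-exponent (exponent = 0 gives white noise). Generated
# at a highly composite length (fast mixed-radix FFT) and truncated.
colored_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  m <- stats::nextn(n, c(2, 3, 5))
  w <- c(w, stats::rnorm(m - n))
  f <- c(0, seq_len(m - 1))
  f <- pmin(f, m - f)  # two-sided frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Band-limited unit-variance noise (flat inside band, zero outside).
bandlimited_noise <- function(n, band, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  f <- c(0, seq_len(m - 1))
  f <- pmin(f, m - f) * fs / m
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

#' Simulate a multi-subject sEEG recording with known ground truth
#'
#' Each site's signal is 1/f background plus a band-limited broadband
#' component whose amplitude is multiplied by the region/condition/phase gain
#' inside the 100-500 ms window after every image onset. Directed coupling
#' edges add lagged source contributions to sink sites inside the same
#' windows of the edge's condition. All subjects share one stimulus schedule.
#'
#' @param sites Site table from [make_sites()] (or same columns).
#' @param schedule Event table from [generate_schedule()].
#' @param effects Gain table from [effect_spec()].
#' @param coupling Edge table from [coupling_spec()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param duration_ms Recording length; default spans the schedule plus 1 s
#'   lead-in/out.
#' @return A `narr_recording`: list with `signals` (sites x samples matrix,
#'   rownames = site_id), `sites`, `fs`, `events`, and `ground_truth`
#'   (injected gains and realized edges).
#' @export
simulate_recording <- function(sites, schedule, effects = effect_spec(),
                               coupling = coupling_spec(), noise = noise_spec(),
                               seed = 1L, duration_ms = NULL) {
  sites <- tibble::as_tibble(sites)
  if (anyDuplicated(sites[c("subject_id", "site_id")]))
    stop("(subject_id, site_id) must be unique")
  if (!any(!sites$excluded)) stop("need at least one non-excluded site")
  coupling <- coupling_spec(coupling)  # re-validate (stability, lags)
  if (is.null(duration_ms))
    duration_ms <- max(schedule$onset_ms) + 8000
  n <- as.integer(duration_ms)  # 1 kHz: one sample per ms
  fs <- noise$fs

  images <- schedule[schedule$kind == "image", ]
  phase <- ifelse(images$transition_class == "image_to_image", "rest", "first")
  win_idx <- function(onset_ms) {
    i0 <- as.integer(onset_ms) + 100L + 1L
    i0:(i0 + 399L)
  }

  gain_lookup <- effects
  key <- function(region, condition, ph)
    paste(region, condition, ph, sep = "|")
  gains <- stats::setNames(gain_lookup$gain,
                           key(gain_lookup$region, gain_lookup$condition,
                               gain_lookup$phase))

  signals <- withr::with_seed(seed, {
    m <- matrix(0, nrow = nrow(sites), ncol = n,
                dimnames = list(sites$site_id, NULL))
    for (i in seq_len(nrow(sites))) {
      bg <- noise$amplitude * colored_noise(n, noise$exponent)
      bb <- noise$broadband_amplitude *
        bandlimited_noise(n, noise$band, fs)
      g <- rep(1, n)
      for (e in seq_len(nrow(images))) {
        idx <- win_idx(images$onset_ms[e])
        g[idx] <- gains[[key(sites$region[i], images$condition[e], phase[e])]]
      }
      m[i, ] <- bg + g * bb
    }
    m
  })

  # directed coupling: sink += coef * source(t - lag) inside the edge
  # condition's post-onset windows; sources taken pre-coupling (acyclic).
  realized <- list()
  if (nrow(coupling)) {
    base <- signals
    for (sj in unique(sites$subject_id)) {
      ssites <- sites[sites$subject_id == sj, ]
      for (e in seq_len(nrow(coupling))) {
        src <- ssites$site_id[ssites$region == coupling$source_region[e]]
        snk <- ssites$site_id[ssites$region == coupling$sink_region[e]]
        npair <- min(length(src), length(snk))
        if (npair == 0) next
        ev <- images[images$condition == coupling$condition[e], ]
        lag <- coupling$lag[e]
        for (p in seq_len(npair)) {
          for (k in seq_len(nrow(ev))) {
            idx <- win_idx(ev$onset_ms[k])
            signals[snk[p], idx] <- signals[snk[p], idx] +
              coupling$coefficient[e] * base[src[p], idx - lag]
          }
          realized[[length(realized) + 1L]] <- tibble::tibble(
            subject_id = sj, source_site = src[p], sink_site = snk[p],
            condition = coupling$condition[e], lag = lag,
            coefficient = coupling$coefficient[e])
        }
      }
    }
  }
  realized <- if (length(realized)) dplyr::bind_rows(realized) else
    tibble::tibble(subject_id = character(), source_site = character(),
                   sink_site = character(), condition = character(),
                   lag = integer(), coefficient = numeric())

  structure(
    list(signals = signals, sites = sites, fs = fs, events = schedule,
         ground_truth = list(effects = effects, edges = realized)),
    class = "narr_recording")
}

#' @export
print.narr_recording <- function(x, ...) {
  cat(sprintf("<narr_recording> %d sites (%d excluded), %d subjects, %.1f s @ %d Hz\n",
              nrow(x$sites), sum(x$sites$excluded),
              length(unique(x$sites$subject_id)),
              ncol(x$signals) / x$fs, x$fs))
  invisible(x)
}
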