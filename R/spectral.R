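#' Analysis frequency grid: 2-100 Hz at 1 Hz, line-noise bins 56-63 removed
#' @return Integer vector of 91 frequencies (Hz).
#' @export
psd_grid <- function() setdiff(2:100, 56:63)

# Welch segmentation for a 600-sample epoch: eight Hamming-tapered segments
# with 50% overlap (length floor(600/4.5) = 133), each zero-padded to
# fs samples so the periodogram lands exactly on the 1 Hz grid.
welch_params <- function(n = 600, n_seg = 8, fs = 1000) {
  seg_len <- floor(n / (n_seg / 2 + 0.5))
  step <- floor((n - seg_len) / (n_seg - 1))
  starts <- 1 + (seq_len(n_seg) - 1) * step
  k <- seq_len(seg_len) - 1
  win <- 0.54 - 0.46 * cos(2 * pi * k / (seg_len - 1))
  list(seg_len = seg_len, starts = starts, win = win, nfft = fs)
}

#' Single-trial Welch power spectral density
#'
#' The epoch is z-scored (so absolute amplitude never carries information;
#' differences downstream reflect spectral shape only), split into eight
#' Hamming-windowed 50%-overlapping segments, each zero-padded to 1000
#' samples, and the one-sided periodograms are averaged and read off on the
#' 2-100 Hz grid with the 56-63 Hz line-noise bins dropped.
#'
#' @param epoch Numeric vector of 600 samples at 1 kHz.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of 91 non-negative power values on [psd_grid()].
#' @export
welch_psd <- function(epoch, fs = 1000) {
  if (length(epoch) != 600) stop("epoch must have exactly 600 samples")
  s <- stats::sd(epoch)
  if (s == 0) stop("constant epoch: zero variance, PSD undefined")
  z <- (epoch - mean(epoch)) / s
  wp <- welch_params(600, 8, fs)
  acc <- numeric(wp$nfft)
  for (st in wp$starts) {
    seg <- z[st:(st + wp$seg_len - 1)] * wp$win
    X <- stats::fft(c(seg, numeric(wp$nfft - wp$seg_len)))
    acc <- acc + Mod(X)^2
  }
  p <- 2 * acc / (length(wp$starts) * fs * sum(wp$win^2))
  p[psd_grid() + 1]
}

#' Welch PSDs for a whole epoch set
#'
#' Vectorized (batched `mvfft`) equivalent of applying [welch_psd()] to every
#' epoch row.
#'
#' @param epochs A `narr_epochs`.
#' @param chunk Epochs per FFT batch (memory/speed trade-off).
#' @return A `narr_psd`: list with `values` (epochs x 91 matrix), `grid`,
#'   `meta` (the epochs' metadata).
#' @export
compute_psds <- function(epochs, chunk = 512L) {
  stopifnot(inherits(epochs, "narr_epochs"), ncol(epochs$data) == 600)
  fs <- epochs$fs
  wp <- welch_params(600, 8, fs)
  sds <- apply(epochs$data, 1, stats::sd)
  if (any(sds == 0)) stop("constant epoch(s): zero variance, PSD undefined")
  z <- (epochs$data - rowMeans(epochs$data)) / sds
  n_ep <- nrow(z)
  keep <- psd_grid() + 1
  out <- matrix(NA_real_, n_ep, length(keep))
  n_seg <- length(wp$starts)
  scale <- 2 / (n_seg * fs * sum(wp$win^2))
  for (c0 in seq(1, n_ep, by = chunk)) {
    ii <- c0:min(c0 + chunk - 1, n_ep)
    # columns: all segments of all epochs in the chunk
    segs <- matrix(0, wp$nfft, length(ii) * n_seg)
    col <- 0L
    for (i in ii) {
      for (st in wp$starts) {
        col <- col + 1L
        segs[seq_len(wp$seg_len), col] <- z[i, st:(st + wp$seg_len - 1)] * wp$win
      }
    }
    P <- Mod(stats::mvfft(segs)[keep, , drop = FALSE])^2
    for (j in seq_along(ii)) {
      cols <- (j - 1) * n_seg + seq_len(n_seg)
      out[ii[j], ] <- scale * rowSums(P[, cols, drop = FALSE])
    }
  }
  structure(list(values = out, grid = psd_grid(), meta = epochs$meta),
            class = "narr_psd")
}

#' Per-site PSD normalization
#'
#' Divides, for every site and frequency bin, each trial's power by the mean
#' power of that bin across all of the site's trials (all experimental
#' conditions pooled), so the per-bin mean of the normalized values is 1.
#'
#' @param psds A `narr_psd` of single-trial spectra.
#' @return A `narr_psd` of normalized spectra.
#' @export
normalize_psd_set <- function(psds) {
  stopifnot(inherits(psds, "narr_psd"))
  for (sid in unique(psds$meta$site_id)) {
    i <- which(psds$meta$site_id == sid)
    denom <- colMeans(psds$values[i, , drop = FALSE])
    if (any(denom == 0))
      stop("site ", sid, ": zero mean power in some bin, cannot normalize")
    psds$values[i, ] <- sweep(psds$values[i, , drop = FALSE], 2, denom, "/")
  }
  psds
}

#' Condition-averaged PSDs
#'
#' One averaged spectrum per site x condition (arithmetic mean per bin).
#'
#' @param psds A `narr_psd` of (normalized) single-trial spectra.
#' @param conditions Conditions every site must have; a site missing one is an
#'   error.
#' @return A `narr_psd` with one row per site x condition; metadata keeps
#'   subject, site, region, hemisphere, condition.
#' @export
condition_average <- function(psds, conditions = c("Scr", "Seq")) {
  stopifnot(inherits(psds, "narr_psd"))
  m <- psds$meta
  grp <- paste(m$site_id, m$condition, sep = "\r")
  site_conds <- split(m$condition, m$site_id)
  missing <- vapply(site_conds,
                    function(cc) !all(conditions %in% cc), logical(1))
  if (any(missing))
    stop("site(s) missing a condition: ",
         paste(names(site_conds)[missing], collapse = ", "))
  ug <- unique(grp)
  vals <- matrix(NA_real_, length(ug), ncol(psds$values))
  meta <- vector("list", length(ug))
  for (j in seq_along(ug)) {
    i <- which(grp == ug[j])
    vals[j, ] <- colMeans(psds$values[i, , drop = FALSE])
    meta[[j]] <- m[i[1], c("subject_id", "site_id", "region", "hemisphere",
                           "condition")]
  }
  structure(list(values = vals, grid = psds$grid,
                 meta = dplyr::bind_rows(meta)),
            class = "narr_psd")
}

#' @export
print.narr_psd <- function(x, ...) {
  cat(sprintf("<narr_psd> %d spectra x %d bins (%d-%d Hz)\n",
              nrow(x$values), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}
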