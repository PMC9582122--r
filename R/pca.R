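#' Fit pooled PCA over a PSD matrix
#'
#' Centered PCA (full deterministic decomposition, no randomized
#' approximation) of spectra on the normalized linear scale, as used for the
#' pooled condition-averaged set. PC1 is sign-oriented with [orient_pc1()].
#'
#' @param psds A `narr_psd` (or bare matrix) with >= 2 rows.
#' @return A `narr_pca`: `rotation` (91 x k orthonormal columns),
#'   `variance_fractions` (non-increasing, sum 1), `center` (per-bin mean),
#'   `grid`.
#' @export
fit_psd_pca <- function(psds) {
  x <- if (inherits(psds, "narr_psd")) psds$values else as.matrix(psds)
  grid <- if (inherits(psds, "narr_psd")) psds$grid else psd_grid()
  if (nrow(x) < 2) stop("need at least 2 spectra to fit a PCA")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop("rank-0 input: all spectra identical after centering")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  model <- structure(list(rotation = pc$rotation,
                          variance_fractions = vf,
                          center = ctr, grid = grid),
                     class = "narr_pca")
  orient_pc1(model)
}

#' Fix the sign of PC1
#'
#' Orients PC1 so that its mean loading over bins above 10 Hz is positive,
#' matching the broadband (power-increase) reading of the component. A zero
#' mean loading is kept as-is with a warning (deterministic tie-break).
#'
#' @param model A `narr_pca`.
#' @return The model with PC1 (only) possibly sign-flipped.
#' @export
orient_pc1 <- function(model) {
  stopifnot(inherits(model, "narr_pca"))
  hi <- model$grid > 10
  m <- mean(model$rotation[hi, 1])
  if (m < 0) {
    model$rotation[, 1] <- -model$rotation[, 1]
  } else if (m == 0) {
    warning("PC1 high-band mean loading exactly zero; sign kept as-is")
  }
  model
}

#' Project spectra onto oriented PC1
#'
#' @param model A `narr_pca`.
#' @param psds A `narr_psd` or matrix of spectra.
#' @return Numeric vector of projections `y = (q - center) . p1`.
#' @export
project_pc1 <- function(model, psds) {
  x <- if (inherits(psds, "narr_psd")) psds$values else as.matrix(psds)
  drop(sweep(x, 2, model$center) %*% model$rotation[, 1])
}

#' Leave-one-subject-out PC1 projections
#'
#' For a held-out subject, PCA is fitted on the condition-averaged spectra of
#' all other subjects and the held-out subject's single-trial spectra are
#' centered with the fitted mean and projected onto the oriented PC1.
#'
#' @param cond_avg `narr_psd` of condition-averaged spectra (the PCA fitting
#'   set; rows from all subjects).
#' @param trial_psds `narr_psd` of normalized single-trial spectra.
#' @param subject Held-out subject id; must be present in both sets.
#' @return Tibble: the held-out trials' metadata plus projection `y`.
#' @export
loso_project <- function(cond_avg, trial_psds, subject) {
  stopifnot(inherits(cond_avg, "narr_psd"), inherits(trial_psds, "narr_psd"))
  if (!subject %in% cond_avg$meta$subject_id)
    stop("held-out subject ", subject, " absent from the fitting set")
  if (!subject %in% trial_psds$meta$subject_id)
    stop("held-out subject ", subject, " absent from the trial set")
  keep <- cond_avg$meta$subject_id != subject
  fit_rows <- cond_avg$values[keep, , drop = FALSE]
  if (nrow(fit_rows) < 2) stop("need >= 2 subjects to leave one out")
  model <- fit_psd_pca(structure(list(values = fit_rows, grid = cond_avg$grid,
                                      meta = cond_avg$meta[keep, ]),
                                 class = "narr_psd"))
  i <- trial_psds$meta$subject_id == subject
  out <- trial_psds$meta[i, ]
  out$y <- project_pc1(model, trial_psds$values[i, , drop = FALSE])
  out
}

#' Leave-one-subject-out projections for every subject
#'
#' @inheritParams loso_project
#' @return Tibble of projection records pooled over all subjects (each
#'   projected through the PCA fitted without that subject). With a single
#'   fitting model impossible (one subject), an error is raised.
#' @export
loso_project_all <- function(cond_avg, trial_psds) {
  subjects <- unique(trial_psds$meta$subject_id)
  if (length(unique(cond_avg$meta$subject_id)) < 2)
    stop("need >= 2 subjects for leave-one-subject-out projection")
  dplyr::bind_rows(lapply(subjects, function(s)
    loso_project(cond_avg, trial_psds, s)))
}
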