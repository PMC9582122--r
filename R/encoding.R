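#' Condition-indicator linear regression on PC1 projections
#'
#' Fits `y = X beta + eps` where X has a scrambled indicator, a sequential
#' indicator and an intercept column. The two indicators are exhaustive, so X
#' is rank-deficient; the minimum-norm least-squares solution is used. The
#' model's prediction for a trial, and hence everything downstream, is
#' invariant to this parameterization and equals the per-condition training
#' mean; the exported "predicted weight" of a condition is that predicted
#' projection (indicator weight + intercept).
#'
#' @param y Numeric vector of training projections.
#' @param labels Condition labels ("Scr"/"Seq") aligned with `y`.
#' @return List: `beta` (3-vector), `weights` (named predicted projections per
#'   condition).
#' @export
fit_condition_regression <- function(y, labels) {
  if (length(unique(labels)) < 2)
    stop("both conditions must be present in the training set")
  X <- cbind(Scr = as.numeric(labels == "Scr"),
             Seq = as.numeric(labels == "Seq"),
             intercept = 1)
  beta <- drop(MASS::ginv(X) %*% y)
  names(beta) <- colnames(X)
  weights <- c(Scr = beta[["Scr"]] + beta[["intercept"]],
               Seq = beta[["Seq"]] + beta[["intercept"]])
  list(beta = beta, weights = weights)
}

# mean fold correlation for given labels over fixed fold index sets;
# degenerate folds (zero variance on either side, or an empty condition
# group making predictions undefined) score 0
mean_fold_r <- function(y, labels, fold_sets) {
  r <- vapply(fold_sets, function(f) {
    lt <- labels[f$train]
    yt <- y[f$train]
    m_scr <- mean(yt[lt == "Scr"])
    m_seq <- mean(yt[lt == "Seq"])
    if (is.nan(m_scr) || is.nan(m_seq)) return(0)
    pred <- ifelse(labels[f$val] == "Scr", m_scr, m_seq)
    obs <- y[f$val]
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
    stats::cor(pred, obs)
  }, numeric(1))
  list(fold_r = r, mean_r = mean(r))
}

# draw fold train/validation index sets: n_train sampled without replacement
# per fold (independently across folds), both conditions enforced by
# redrawing; remainder is the validation set
draw_folds <- function(labels, folds, n_train) {
  n <- length(labels)
  if (n_train >= n) stop("n_train must be smaller than the trial pool")
  lapply(seq_len(folds), function(i) {
    repeat {
      tr <- sample.int(n, n_train)
      if (length(unique(labels[tr])) == 2) break
    }
    list(train = tr, val = setdiff(seq_len(n), tr))
  })
}

#' Monte-Carlo cross-validated encoding accuracy
#'
#' Ten random folds: each fold trains the condition regression on `n_train`
#' trials sampled without replacement from the pool and scores the Pearson
#' correlation between predicted and observed projections on the left-out
#' trials (27 under the default 44-trial pool). A fold with zero variance on
#' either side scores 0 with a warning. Accuracy is the mean fold
#' correlation.
#'
#' @param y Projections of the train/validate pool.
#' @param labels Condition labels aligned with `y`.
#' @param folds Number of random folds.
#' @param n_train Training trials per fold.
#' @param seed Integer seed for fold sampling.
#' @return List: `fold_r`, `mean_r`.
#' @export
mc_cross_validate <- function(y, labels, folds = 10, n_train = 17,
                              seed = 1L) {
  if (length(unique(labels)) < 2)
    stop("both conditions must be present in the trial pool")
  fold_sets <- withr::with_seed(seed, draw_folds(labels, folds, n_train))
  res <- mean_fold_r(y, labels, fold_sets)
  if (any(res$fold_r == 0))
    warning("degenerate fold(s): correlation set to 0")
  res
}

#' Permutation selection of high-encoding sites
#'
#' The observed cross-validated accuracy is compared against a null built by
#' recomputing it under uniformly permuted condition labels (conditions
#' swapping), using the same fold index sets. The p-value uses the add-one
#' estimator `p = (1 + #{null >= observed}) / (n_perm + 1)` so it is never 0.
#'
#' @inheritParams mc_cross_validate
#' @param n_perm Number of label permutations.
#' @param alpha Significance level.
#' @return List: `mean_r`, `fold_r`, `p_value`, `significant`, `null_mean`,
#'   `null_q95`, `weights` (full-pool condition regression weights).
#' @export
permutation_select <- function(y, labels, n_perm = 10000, alpha = 0.05,
                               folds = 10, n_train = 17, seed = 1L) {
  if (n_perm < 100)
    warning("n_perm < 100: permutation p-value has very coarse resolution")
  fold_sets <- withr::with_seed(seed, draw_folds(labels, folds, n_train))
  obs <- mean_fold_r(y, labels, fold_sets)
  null_r <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(i) {
      mean_fold_r(y, sample(labels), fold_sets)$mean_r
    }, numeric(1))
  })
  p <- (1 + sum(null_r >= obs$mean_r)) / (n_perm + 1)
  fit <- fit_condition_regression(y, labels)
  list(mean_r = obs$mean_r, fold_r = obs$fold_r, p_value = p,
       significant = p < alpha,
       null_mean = mean(null_r),
       null_q95 = unname(stats::quantile(null_r, 0.95)),
       weights = fit$weights)
}

#' Per-site encoding analysis over a projection table
#'
#' Runs [permutation_select()] for every site on its train/validate-pool
#' trials.
#'
#' @param projections Tibble of projection records (from
#'   [loso_project_all()]), one row per site x trial, with column `y`.
#' @param pool_trials Trial ids forming the train/validate pool (from
#'   [trial_split()]); other trials are ignored here.
#' @param n_perm,alpha,folds,n_train,seed See [permutation_select()]; each
#'   site uses a seed offset deterministically from `seed`.
#' @return Tibble: one row per site with `mean_r`, `p_value`, `significant`,
#'   `w_scr`, `w_seq` plus site metadata.
#' @export
encode_sites <- function(projections, pool_trials, n_perm = 1000,
                         alpha = 0.05, folds = 10, n_train = 17, seed = 1L) {
  pp <- projections[projections$trial_id %in% pool_trials, ]
  sids <- unique(pp$site_id)
  rows <- lapply(seq_along(sids), function(k) {
    d <- pp[pp$site_id == sids[k], ]
    r <- permutation_select(d$y, d$condition, n_perm = n_perm, alpha = alpha,
                            folds = folds, n_train = n_train,
                            seed = seed + 7L * k)
    tibble::tibble(subject_id = d$subject_id[1], site_id = sids[k],
                   region = d$region[1], hemisphere = d$hemisphere[1],
                   mean_r = r$mean_r, p_value = r$p_value,
                   significant = r$significant,
                   w_scr = r$weights[["Scr"]], w_seq = r$weights[["Seq"]])
  })
  dplyr::bind_rows(rows)
}

#' First-transition versus within-series contrast of projections
#'
#' Groups single-trial projections into condition x phase cells per region
#' ("first" = gray-to-image transitions including the experiment's first
#' image; "rest" = image-to-image transitions) and compares cells with
#' rank-based (Kruskal-Wallis) tests: Seq vs Scr within each phase and first
#' vs rest within each condition.
#'
#' @param projections Projection records including the `isi_to_image` class
#'   trials (see [epoch_transitions()]).
#' @param regions Regions to summarize (default frontal and temporal).
#' @return List: `cells` (region x condition x phase n/mean/sem) and `tests`
#'   (region, contrast, statistic, p_value).
#' @export
first_vs_rest_contrast <- function(projections,
                                   regions = c("frontal", "temporal")) {
  pr <- projections[projections$region %in% regions, ]
  pr$phase <- ifelse(pr$transition_class == "image_to_image", "rest", "first")
  cells <- list(); tests <- list()
  for (rg in regions) {
    d <- pr[pr$region == rg, ]
    for (cc in c("Scr", "Seq")) for (ph in c("first", "rest")) {
      yy <- d$y[d$condition == cc & d$phase == ph]
      if (length(yy) == 0)
        stop("empty cell: region=", rg, " condition=", cc, " phase=", ph)
      cells[[length(cells) + 1L]] <- tibble::tibble(
        region = rg, condition = cc, phase = ph, n = length(yy),
        mean = mean(yy), sem = stats::sd(yy) / sqrt(length(yy)))
    }
    contrast <- function(name, a, b) {
      kt <- stats::kruskal.test(list(a, b))
      tibble::tibble(region = rg, contrast = name,
                     statistic = unname(kt$statistic),
                     p_value = kt$p.value,
                     direction = sign(mean(a) - mean(b)))
    }
    g <- function(cc, ph) d$y[d$condition == cc & d$phase == ph]
    tests[[length(tests) + 1L]] <- dplyr::bind_rows(
      contrast("first_Scr_vs_Seq", g("Scr", "first"), g("Seq", "first")),
      contrast("rest_Scr_vs_Seq", g("Scr", "rest"), g("Seq", "rest")),
      contrast("Scr_first_vs_rest", g("Scr", "first"), g("Scr", "rest")),
      contrast("Seq_first_vs_rest", g("Seq", "first"), g("Seq", "rest")))
  }
  list(cells = dplyr::bind_rows(cells), tests = dplyr::bind_rows(tests))
}
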