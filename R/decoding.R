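#' Stratified train/test split of the trial universe
#'
#' Splits stimulus-indexed trials once per run into an 80% train/validate
#' pool and a 20% held-out test set, stratified by condition with floor
#' rounding (56 trials -> 44 pool / 12 test).
#'
#' @param trials Tibble with unique `trial_id` and `condition`.
#' @param test_frac Held-out fraction.
#' @param seed Integer seed for the shuffle.
#' @return List: `pool` and `test` trial-id vectors.
#' @export
trial_split <- function(trials, test_frac = 0.2, seed = 1L) {
  trials <- unique(trials[, c("trial_id", "condition")])
  withr::with_seed(seed, {
    pool <- character(0); test <- character(0)
    for (cc in unique(trials$condition)) {
      ids <- sample(trials$trial_id[trials$condition == cc])
      n_pool <- floor((1 - test_frac) * length(ids))
      pool <- c(pool, ids[seq_len(n_pool)])
      test <- c(test, ids[-seq_len(n_pool)])
    }
    list(pool = pool, test = test)
  })
}

#' Rank sites by encoding accuracy
#'
#' Descending cross-validated mean correlation; exact ties break
#' lexicographically by (subject_id, site_id) so the ranking is deterministic
#' under any input order.
#'
#' @param results Per-site encoding results (from [encode_sites()]).
#' @return The results tibble reordered, best site first.
#' @export
rank_sites <- function(results) {
  stopifnot(nrow(results) > 0)
  results[order(-results$mean_r, results$subject_id, results$site_id), ]
}

#' Decode one trial by correlation pattern matching
#'
#' Correlates the measured projection pattern across a site ensemble with the
#' predicted pattern of each condition; the predicted condition is the one
#' with the larger Pearson correlation. An exact correlation tie or a
#' zero-variance measured pattern is scored as unsuccessful (conservative)
#' with a warning.
#'
#' @param measured Measured projections (one per site, fixed site order).
#' @param pred_scr,pred_seq Predicted per-condition patterns on the same
#'   sites.
#' @param true_condition The trial's true label ("Scr"/"Seq").
#' @return List: `predicted` (label or NA), `success`.
#' @export
decode_trial <- function(measured, pred_scr, pred_seq, true_condition) {
  if (stats::sd(measured) == 0) {
    warning("zero-variance measured pattern: decoding unsuccessful")
    return(list(predicted = NA_character_, success = FALSE))
  }
  r_scr <- stats::cor(measured, pred_scr)
  r_seq <- stats::cor(measured, pred_seq)
  if (is.na(r_scr) || is.na(r_seq)) {
    warning("undefined pattern correlation: decoding unsuccessful")
    return(list(predicted = NA_character_, success = FALSE))
  }
  if (r_scr == r_seq) {
    warning("exact correlation tie: decoding unsuccessful")
    return(list(predicted = NA_character_, success = FALSE))
  }
  pred <- if (r_seq > r_scr) "Seq" else "Scr"
  list(predicted = pred, success = pred == true_condition)
}

# site x trial projection matrix plus per-trial condition lookup
proj_matrix <- function(projections) {
  sids <- unique(projections$site_id)
  tids <- unique(projections$trial_id)
  Y <- matrix(NA_real_, length(sids), length(tids),
              dimnames = list(sids, tids))
  Y[cbind(match(projections$site_id, sids),
          match(projections$trial_id, tids))] <- projections$y
  cond <- projections$condition[match(tids, projections$trial_id)]
  names(cond) <- tids
  list(Y = Y, condition = cond)
}

# leave-one-trial-out predicted condition weights for every site:
# condition means over all trials except the held-out one
loo_weights <- function(Y, cond, trial) {
  out <- matrix(NA_real_, nrow(Y), 2, dimnames = list(rownames(Y),
                                                      c("Scr", "Seq")))
  for (cc in c("Scr", "Seq")) {
    cols <- which(cond == cc & colnames(Y) != trial)
    out[, cc] <- rowMeans(Y[, cols, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Decoding accuracy versus site-ensemble size
#'
#' For each group size n, the top-n ranked sites are taken, a uniform random
#' half (floor(n/2) sites) is drawn, and every held-out test trial is decoded
#' by correlation matching against per-condition patterns predicted by
#' leave-one-trial-out condition regressions over the full trial pool.
#' Repeated `repeats` times per size; reports mean accuracy (%) and SEM.
#'
#' @param projections Projection records (all trials, all sites).
#' @param ranking Ranked site results from [rank_sites()].
#' @param test_ids Held-out test trial ids (from [trial_split()]).
#' @param sizes Group sizes; default 4 to the number of ranked sites in
#'   steps of 2.
#' @param repeats Random half-subgroups per size.
#' @param seed Integer seed.
#' @return Tibble: `size`, `mean_accuracy` (%), `sem`.
#' @export
accuracy_curve <- function(projections, ranking, test_ids,
                           sizes = NULL, repeats = 10, seed = 1L) {
  if (length(test_ids) == 0) stop("test set is empty")
  pm <- proj_matrix(projections)
  Y <- pm$Y[ranking$site_id, , drop = FALSE]
  cond <- pm$condition
  if (is.null(sizes)) sizes <- seq(4, nrow(Y), by = 2)
  if (min(sizes) < 4 || max(sizes) > nrow(Y))
    stop("sizes must lie in [4, number of ranked sites]")
  # leave-one-trial-out weights per test trial (independent of subgroup)
  W <- lapply(test_ids, function(t) loo_weights(Y, cond, t))
  names(W) <- test_ids
  withr::with_seed(seed, {
    rows <- lapply(sizes, function(n) {
      acc <- vapply(seq_len(repeats), function(rep) {
        sub <- sample.int(n, floor(n / 2))
        ok <- vapply(test_ids, function(t) {
          suppressWarnings(decode_trial(Y[sub, t], W[[t]][sub, "Scr"],
                                        W[[t]][sub, "Seq"],
                                        cond[[t]])$success)
        }, logical(1))
        100 * mean(ok)
      }, numeric(1))
      tibble::tibble(size = n, mean_accuracy = mean(acc),
                     sem = stats::sd(acc) / sqrt(repeats))
    })
    dplyr::bind_rows(rows)
  })
}
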