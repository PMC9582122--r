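# pooled lagged design across trials (rows never cross trial boundaries);
# t_start lets callers fix a common estimation sample across orders
lagged_design <- function(xmat, ymat, order, t_start = order + 1) {
  T_len <- ncol(ymat)
  if (order >= T_len) stop("AR order must be smaller than the window length")
  t_idx <- t_start:T_len
  yv <- as.vector(t(ymat[, t_idx, drop = FALSE]))
  ylags <- do.call(cbind, lapply(seq_len(order), function(l)
    as.vector(t(ymat[, t_idx - l, drop = FALSE]))))
  xlags <- do.call(cbind, lapply(seq_len(order), function(l)
    as.vector(t(xmat[, t_idx - l, drop = FALSE]))))
  list(y = yv, ylags = ylags, xlags = xlags)
}

rss_of <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular regression: predictor lags are collinear")
  sum(qr.resid(qrX, y)^2)
}

# one-directional GC (x -> y): log ratio of restricted (own lags only) to
# full (own + source lags) residual variance, with an F-test p-value for the
# added lags
gc_one_direction <- function(xmat, ymat, order) {
  d <- lagged_design(xmat, ymat, order)
  n <- length(d$y)
  X_full <- cbind(1, d$ylags, d$xlags)
  X_rest <- cbind(1, d$ylags)
  rss_f <- rss_of(X_full, d$y)
  rss_r <- rss_of(X_rest, d$y)
  gc <- log(rss_r / rss_f)
  df2 <- n - ncol(X_full)
  f <- ((rss_r - rss_f) / order) / (rss_f / df2)
  p <- stats::pf(f, order, df2, lower.tail = FALSE)
  list(gc = gc, p = p)
}

#' Pairwise Granger causality between two sites' trial windows
#'
#' Bivariate autoregressive model comparison pooled across trials (lagged
#' rows never cross trial boundaries): for each direction, the full model
#' predicts the target from its own and the source's past, the restricted
#' model from its own past only, and the statistic is
#' `gc = ln(sigma2_restricted / sigma2_full)` with a one-directional F-test
#' per direction. Inputs should be DC-offset corrected
#' ([baseline_correct()] with the -100..+100 ms window).
#'
#' @param xmat,ymat Trials x samples matrices (equal dimensions) for the two
#'   sites, restricted to the analysis window.
#' @param order AR model order (samples).
#' @return List: `gc_xy`, `gc_yx`, `p_xy`, `p_yx`, `order`.
#' @export
pairwise_gc <- function(xmat, ymat, order = 5) {
  stopifnot(all(dim(xmat) == dim(ymat)))
  xy <- gc_one_direction(xmat, ymat, order)
  yx <- gc_one_direction(ymat, xmat, order)
  list(gc_xy = xy$gc, gc_yx = yx$gc, p_xy = xy$p, p_yx = yx$p,
       order = order)
}

#' AIC selection of the AR model order
#'
#' Minimizes the summed Gaussian AIC of the two full-model regressions over
#' candidate orders on the pooled trial windows.
#'
#' @inheritParams pairwise_gc
#' @param orders Candidate orders.
#' @return The selected order.
#' @export
select_gc_order <- function(xmat, ymat, orders = 1:20) {
  t0 <- max(orders) + 1  # common estimation sample for comparable AICs
  aics <- vapply(orders, function(p) {
    a <- 0
    for (dir in 1:2) {
      d <- if (dir == 1) lagged_design(xmat, ymat, p, t_start = t0) else
        lagged_design(ymat, xmat, p, t_start = t0)
      n <- length(d$y)
      rss <- rss_of(cbind(1, d$ylags, d$xlags), d$y)
      a <- a + n * log(rss / n) + 2 * (2 * p + 1)
    }
    a
  }, numeric(1))
  orders[which.min(aics)]
}

# trials x samples matrix of one site's epochs inside the GC window
gc_window_matrix <- function(epochs, site_id, condition,
                             window = c(100, 500)) {
  t_ms <- seq(epochs$window[1], epochs$window[2] - 1)
  cols <- which(t_ms >= window[1] & t_ms < window[2])
  rows <- which(epochs$meta$site_id == site_id &
                  epochs$meta$condition == condition)
  epochs$data[rows, cols, drop = FALSE]
}

#' Granger causality for all within-subject site pairs
#'
#' Computes [pairwise_gc()] per condition for every unordered pair of
#' included sites of the same subject, on the 100-500 ms post-onset portion
#' of the supplied epochs (DC-offset corrected internally with the
#' -100..+100 ms baseline).
#'
#' @param epochs A `narr_epochs` of image-onset epochs.
#' @param order AR order, or "aic" to select once per subject with
#'   [select_gc_order()] on the first pair.
#' @param conditions Conditions to analyze.
#' @param window ms window relative to onset.
#' @return Tibble: subject, site_x, site_y, condition, gc_xy, gc_yx, p_xy,
#'   p_yx, order.
#' @export
gc_all_pairs <- function(epochs, order = 5, conditions = c("Scr", "Seq"),
                         window = c(100, 500)) {
  epochs <- baseline_correct(epochs, c(-100, 100))
  meta <- epochs$meta
  rows <- list()
  for (sj in unique(meta$subject_id)) {
    sids <- unique(meta$site_id[meta$subject_id == sj])
    if (length(sids) < 2) next
    pairs <- utils::combn(sids, 2)
    ord <- order
    for (k in seq_len(ncol(pairs))) {
      sx <- pairs[1, k]; sy <- pairs[2, k]
      for (cc in conditions) {
        xm <- gc_window_matrix(epochs, sx, cc, window)
        ym <- gc_window_matrix(epochs, sy, cc, window)
        if (nrow(xm) == 0 || nrow(xm) != nrow(ym)) next
        if (identical(ord, "aic"))
          ord <- select_gc_order(xm, ym)
        g <- pairwise_gc(xm, ym, ord)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sj, site_x = sx, site_y = sy, condition = cc,
          gc_xy = g$gc_xy, gc_yx = g$gc_yx, p_xy = g$p_xy, p_yx = g$p_yx,
          order = g$order)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Call source-sink couplets from pairwise GC results
#'
#' For each unordered pair and condition: the direction with the larger GC
#' value is the candidate source; a couplet is called iff that direction's
#' p-value is below `alpha`. An exact GC tie yields no couplet
#' (conservative) with a warning.
#'
#' @param gc_results Output of [gc_all_pairs()].
#' @param alpha Significance level.
#' @return Tibble: subject, source_site, sink_site, condition, gc, p.
#' @export
identify_couplets <- function(gc_results, alpha = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(gc_results))) {
    r <- gc_results[i, ]
    if (r$gc_xy == r$gc_yx) {
      warning("exact GC tie for pair (", r$site_x, ", ", r$site_y,
              "): no couplet called")
      next
    }
    if (r$gc_xy > r$gc_yx) {
      src <- r$site_x; snk <- r$site_y; gc <- r$gc_xy; p <- r$p_xy
    } else {
      src <- r$site_y; snk <- r$site_x; gc <- r$gc_yx; p <- r$p_yx
    }
    if (p < alpha)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = r$subject_id, source_site = src, sink_site = snk,
        condition = r$condition, gc = gc, p = p)
  }
  if (!length(rows))
    return(tibble::tibble(subject_id = character(), source_site = character(),
                          sink_site = character(), condition = character(),
                          gc = numeric(), p = numeric()))
  dplyr::bind_rows(rows)
}

#' Region-pair contingency tables of couplet counts
#'
#' @param couplets Output of [identify_couplets()].
#' @param sites Site table (all sites must be region-labeled).
#' @param conditions Conditions to tabulate.
#' @return Named list (per condition) of 6x6 matrices: rows = source region,
#'   columns = sink region.
#' @export
region_contingency <- function(couplets, sites,
                               conditions = c("Scr", "Seq")) {
  reg <- stats::setNames(sites$region, sites$site_id)
  src_reg <- reg[couplets$source_site]
  snk_reg <- reg[couplets$sink_site]
  if (any(is.na(src_reg)) || any(is.na(snk_reg)))
    stop("couplet references a site missing from the site table")
  out <- lapply(conditions, function(cc) {
    i <- couplets$condition == cc
    table(factor(src_reg[i], levels = BRAIN_REGIONS),
          factor(snk_reg[i], levels = BRAIN_REGIONS))
  })
  stats::setNames(lapply(out, function(t) unclass(as.matrix(t))), conditions)
}

#' Omnibus chi-square contrast of two region-pair tables
#'
#' Flattens the source-sink cells into a 2 x cells layout (condition x cell),
#' drops cells empty under both conditions (zero expected count, reported),
#' computes the Pearson chi-square, and post-hoc per-cell standardized
#' adjusted residuals converted to two-sided normal p-values with Bonferroni
#' correction over the tested cells.
#'
#' @param table_seq,table_scr Same-shape count matrices (rows = source
#'   region, columns = sink region).
#' @return List: `statistic`, `df`, `p_value`, `n_cells_tested`,
#'   `dropped_cells`, `cells` tibble (source, sink, n_seq, n_scr,
#'   adj_residual, p_adj, direction: "Seq>Scr"/"Seq<Scr").
#' @export
chi_square_contrast <- function(table_seq, table_scr) {
  stopifnot(all(dim(table_seq) == dim(table_scr)))
  seq_v <- as.vector(table_seq)
  scr_v <- as.vector(table_scr)
  if (sum(seq_v) + sum(scr_v) == 0) stop("both tables are all-zero")
  cell_names <- as.vector(outer(rownames(table_seq), colnames(table_seq),
                                paste, sep = "->"))
  keep <- seq_v + scr_v > 0
  dropped <- cell_names[!keep]
  M <- rbind(Seq = seq_v[keep], Scr = scr_v[keep])
  ct <- suppressWarnings(stats::chisq.test(M, correct = FALSE))
  k <- sum(keep)
  adj <- ct$stdres["Seq", ]
  p_adj <- pmin(1, 2 * stats::pnorm(-abs(adj)) * k)
  src_snk <- do.call(rbind, strsplit(cell_names[keep], "->", fixed = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, n_cells_tested = k, dropped_cells = dropped,
       cells = tibble::tibble(
         source = src_snk[, 1], sink = src_snk[, 2],
         n_seq = seq_v[keep], n_scr = scr_v[keep],
         adj_residual = unname(adj), p_adj = unname(p_adj),
         direction = ifelse(adj > 0, "Seq>Scr", "Seq<Scr")))
}

#' Fisher exact test of lateralized connectivity
#'
#' Builds the 2x2 table condition x (couplet matches the given lateralized
#' source-sink pair vs any other couplet) and returns the two-sided exact
#' p-value from the hypergeometric distribution.
#'
#' @param couplets Output of [identify_couplets()].
#' @param sites Site table with `region` and `hemisphere`.
#' @param source,sink Length-2 vectors `c(region, hemisphere)`.
#' @return List: `table` (2x2), `p_value`.
#' @export
fisher_lateralization <- function(couplets, sites, source, sink) {
  reg <- stats::setNames(sites$region, sites$site_id)
  hem <- stats::setNames(sites$hemisphere, sites$site_id)
  is_pair <- reg[couplets$source_site] == source[1] &
    hem[couplets$source_site] == source[2] &
    reg[couplets$sink_site] == sink[1] &
    hem[couplets$sink_site] == sink[2]
  tab <- table(factor(couplets$condition, levels = c("Seq", "Scr")),
               factor(is_pair, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: empty margin")
  ft <- stats::fisher.test(tab)
  list(table = unclass(as.matrix(tab)), p_value = ft$p.value)
}
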