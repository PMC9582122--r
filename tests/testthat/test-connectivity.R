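test_that("GC matches the closed-form VAR(1) variance ratio", {
  d <- simulate_var1(56, 400, seed = 101)
  g <- pairwise_gc(d$x, d$y, order = 1)
  expect_equal(g$gc_xy, var1_gc_oracle(), tolerance = 0.1)
  expect_gt(g$gc_xy, g$gc_yx)
  expect_lt(g$p_xy, 0.05)
  expect_gt(g$gc_xy, 0)
  expect_gte(g$gc_yx, 0)
})

test_that("GC direction is recovered across seeds and null pairs stay flat", {
  hits <- vapply(1:12, function(s) {
    d <- simulate_var1(20, 200, seed = 200 + s)
    g <- pairwise_gc(d$x, d$y, order = 1)
    g$gc_xy > g$gc_yx && g$p_xy < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  null_p <- withr::with_seed(57, vapply(1:60, function(s) {
    x <- matrix(rnorm(20 * 200), 20, 200)
    y <- matrix(rnorm(20 * 200), 20, 200)
    pairwise_gc(x, y, order = 1)$p_xy
  }, numeric(1)))
  # parametric p-values roughly uniform: false-positive rate near alpha
  expect_lt(mean(null_p < 0.05), 0.15)
  expect_gt(mean(null_p < 0.5), 0.3)
})

test_that("degenerate regressions and orders are rejected", {
  d <- simulate_var1(10, 50, seed = 301)
  expect_error(pairwise_gc(d$x, d$x, order = 2), "singular")
  expect_error(pairwise_gc(d$x, d$y, order = 50), "order")
})

test_that("GC p-value agrees with lmtest::grangertest on one long trial", {
  skip_if_not_installed("lmtest")
  d <- simulate_var1(1, 2000, seed = 401)
  for (ord in c(1, 3)) {
    mine <- pairwise_gc(d$x, d$y, order = ord)
    ref <- lmtest::grangertest(d$x[1, ], d$y[1, ], order = ord)
    expect_equal(mine$p_xy, ref$`Pr(>F)`[2], tolerance = 1e-6)
  }
})

test_that("AIC order selection finds a low order for a VAR(1) system", {
  d <- simulate_var1(20, 200, seed = 501)
  expect_lte(select_gc_order(d$x, d$y, orders = 1:6), 3)
})

test_that("couplets follow the larger-GC-and-significant rule", {
  gcres <- tibble::tibble(
    subject_id = "S01", site_x = c("a", "a", "a"), site_y = c("b", "c", "d"),
    condition = "Seq",
    gc_xy = c(0.4, 0.4, 0.2), gc_yx = c(0.1, 0.1, 0.2),
    p_xy = c(0.01, 0.20, 0.01), p_yx = c(0.5, 0.5, 0.01), order = 1)
  expect_warning(cp <- identify_couplets(gcres), "tie")
  expect_equal(nrow(cp), 1)
  expect_equal(cp$source_site, "a")
  expect_equal(cp$sink_site, "b")
  # reversed direction wins when gc_yx is larger
  gc2 <- gcres[1, ]; gc2$gc_xy <- 0.05; gc2$p_yx <- 0.01
  cp2 <- identify_couplets(gc2)
  expect_equal(cp2$source_site, "b")
})

test_that("region contingency tables keep exact couplet bookkeeping", {
  sites <- make_sites(1, c(temporal = 2, frontal = 2))
  cp <- tibble::tibble(
    subject_id = "S01",
    source_site = sites$site_id[c(1, 1, 2)],
    sink_site = sites$site_id[c(3, 4, 3)],
    condition = "Seq", gc = 0.3, p = 0.01)
  tabs <- region_contingency(cp, sites)
  expect_equal(tabs$Seq["temporal", "frontal"], 3)
  expect_equal(sum(tabs$Seq), 3)
  expect_equal(sum(tabs$Scr), 0)
  empty <- region_contingency(cp[0, ], sites)
  expect_true(all(empty$Seq == 0))
})

test_that("chi-square contrast matches a hand-computed Pearson oracle", {
  t_seq <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE,
                  dimnames = list(c("temporal", "frontal"),
                                  c("temporal", "frontal")))
  t_scr <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE,
                  dimnames = dimnames(t_seq))
  res <- chi_square_contrast(t_seq, t_scr)
  # independent oracle: sum (O-E)^2/E over the 2 x 4 condition-by-cell table
  O <- rbind(as.vector(t_seq), as.vector(t_scr))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$statistic, 40 / 3, tolerance = 1e-12)
  expect_equal(res$df, 3)
  # per-cell direction bookkeeping
  cell <- res$cells[res$cells$source == "temporal" &
                      res$cells$sink == "temporal", ]
  expect_equal(cell$direction, "Seq<Scr")
  # identical tables: statistic 0, all adjusted p = 1
  same <- chi_square_contrast(t_seq, t_seq)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_true(all(same$cells$p_adj == 1))
  # invariance under simultaneous relabeling of the region axes
  perm <- c(2, 1)
  res2 <- chi_square_contrast(t_seq[perm, perm], t_scr[perm, perm])
  expect_equal(res2$statistic, res$statistic)
  expect_error(chi_square_contrast(0 * t_seq, 0 * t_scr), "all-zero")
})

test_that("single-table Pearson chi-square sanity value", {
  # the 2x2 table [[10,20],[20,10]] has chi-square 100/15 = 6.666...
  ct <- suppressWarnings(
    chisq.test(matrix(c(10, 20, 20, 10), 2), correct = FALSE))
  expect_equal(unname(ct$statistic), 100 / 15, tolerance = 1e-12)
})

test_that("Fisher lateralization matches hypergeometric enumeration", {
  sites <- make_sites(1, c(temporal = 2, frontal = 2, parietal = 2))
  lt <- sites$site_id[sites$region == "temporal" & sites$hemisphere == "L"]
  lf <- sites$site_id[sites$region == "frontal" & sites$hemisphere == "L"]
  pp <- sites$site_id[sites$region == "parietal"]
  mk <- function(n_pair_seq, n_pair_scr, n_other_seq, n_other_scr) {
    dplyr::bind_rows(
      tibble::tibble(subject_id = "S01", source_site = lt[1],
                     sink_site = lf[1],
                     condition = rep(c("Seq", "Scr"),
                                     c(n_pair_seq, n_pair_scr))),
      tibble::tibble(subject_id = "S01", source_site = pp[1],
                     sink_site = pp[2],
                     condition = rep(c("Seq", "Scr"),
                                     c(n_other_seq, n_other_scr))))
  }
  # balanced table [[5,5],[5,5]] -> p = 1
  r1 <- fisher_lateralization(mk(5, 5, 5, 5), sites,
                              source = c("temporal", "L"),
                              sink = c("frontal", "L"))
  expect_equal(r1$p_value, 1)
  # maximally unbalanced [[10,0],[0,10]] -> p = 2 / C(20,10)
  r2 <- fisher_lateralization(mk(10, 0, 0, 10), sites,
                              source = c("temporal", "L"),
                              sink = c("frontal", "L"))
  expect_equal(r2$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # brute-force enumeration oracle on assorted small tables
  for (cfg in list(c(3, 7, 6, 2), c(1, 9, 4, 8), c(6, 2, 3, 9))) {
    r <- fisher_lateralization(mk(cfg[1], cfg[2], cfg[3], cfg[4]), sites,
                               source = c("temporal", "L"),
                               sink = c("frontal", "L"))
    expect_equal(r$p_value, fisher_exact_oracle(r$table), tolerance = 1e-10)
  }
  expect_error(fisher_lateralization(mk(5, 5, 0, 0)[1:10, ], sites,
                                     source = c("temporal", "L"),
                                     sink = c("frontal", "L")),
               "margin")
})
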