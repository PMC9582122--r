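test_that("condition regression predicts per-condition training means", {
  fit <- fit_condition_regression(c(1, 1, 0, 0),
                                  c("Scr", "Scr", "Seq", "Seq"))
  expect_equal(unname(fit$weights["Scr"]), 1)
  expect_equal(unname(fit$weights["Seq"]), 0)
  # any parameterization must reproduce the group means (normal equations)
  y <- withr::with_seed(3, rnorm(30))
  lab <- rep(c("Scr", "Seq"), 15)
  fit2 <- fit_condition_regression(y, lab)
  expect_equal(unname(fit2$weights["Scr"]), mean(y[lab == "Scr"]))
  expect_equal(unname(fit2$weights["Seq"]), mean(y[lab == "Seq"]))
  # constant response: zero condition contrast
  fit3 <- fit_condition_regression(rep(4, 10), rep(c("Scr", "Seq"), 5))
  expect_equal(unname(diff(fit3$weights)), 0)
  expect_error(fit_condition_regression(1:5, rep("Scr", 5)),
               "both conditions")
})

test_that("cross-validation leaves 27 of 44 out and scores separation", {
  lab <- rep(c("Scr", "Seq"), 22)
  y <- as.numeric(lab == "Scr")  # perfectly separated, no noise
  r <- mc_cross_validate(y, lab, folds = 10, n_train = 17, seed = 5)
  expect_equal(r$mean_r, 1)
  expect_length(r$fold_r, 10)
  # fold geometry: validation size = pool - n_train = 27
  folds <- withr::with_seed(5, narrband:::draw_folds(lab, 10, 17))
  expect_true(all(vapply(folds, function(f) length(f$val), numeric(1)) == 27))
  expect_true(all(vapply(folds, function(f)
    length(unique(lab[f$train])) == 2, logical(1))))
})

test_that("prediction accuracy is invariant to affine projection rescaling", {
  y <- synthetic_projections(1, delta = 1, seed = 11)$y[1:44]
  lab <- synthetic_projections(1, delta = 1, seed = 11)$condition[1:44]
  a <- mc_cross_validate(y, lab, seed = 9)$mean_r
  b <- mc_cross_validate(3.7 * y + 12, lab, seed = 9)$mean_r
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("label-independent projections give near-zero mean accuracy", {
  lab <- rep(c("Scr", "Seq"), 22)
  rs <- withr::with_seed(13, vapply(1:300, function(i) {
    suppressWarnings(
      mc_cross_validate(rnorm(44), lab, seed = i)$mean_r)
  }, numeric(1)))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("permutation selection separates signal from null sites", {
  lab <- rep(c("Scr", "Seq"), 22)
  y_sig <- withr::with_seed(17, as.numeric(lab == "Seq") + rnorm(44, sd = 0.3))
  r_sig <- permutation_select(y_sig, lab, n_perm = 500, seed = 21)
  expect_lt(r_sig$p_value, 0.05)
  expect_true(r_sig$significant)
  y_null <- withr::with_seed(19, rnorm(44))
  r_null <- suppressWarnings(
    permutation_select(y_null, lab, n_perm = 500, seed = 23))
  expect_gt(r_null$p_value, 0.05)
  # add-one estimator never returns 0 and warns at coarse resolution
  expect_gte(r_sig$p_value, 1 / 501)
  expect_warning(permutation_select(y_sig, lab, n_perm = 50, seed = 2),
                 "resolution")
})

test_that("first-vs-rest contrast summarizes cells and flags differences", {
  pr <- synthetic_projections(4, delta = 0, seed = 25)
  # add the first-transition trials with a Seq-specific rest effect instead:
  # rest trials (image_to_image) get +1 under Seq, first trials stay equal
  pr$y <- pr$y + ifelse(pr$condition == "Seq", 1, 0)
  first_ids <- c(unique(pr$trial_id[pr$condition == "Scr"])[1],
                 unique(pr$trial_id[pr$condition == "Seq"])[1])
  first <- pr[pr$trial_id %in% first_ids, ]
  first$transition_class <- "isi_to_image"
  first$y <- withr::with_seed(27, rnorm(nrow(first)))
  res <- first_vs_rest_contrast(dplyr::bind_rows(pr, first),
                                regions = "temporal")
  expect_equal(nrow(res$cells), 4)
  tst <- res$tests
  expect_lt(tst$p_value[tst$contrast == "rest_Scr_vs_Seq"], 0.01)
  expect_equal(tst$direction[tst$contrast == "rest_Scr_vs_Seq"], -1)
  expect_gt(tst$p_value[tst$contrast == "first_Scr_vs_Seq"], 0.05)
  # identical groups: rank statistic at its minimum
  same <- stats::kruskal.test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(same$statistic), 0)
  pr2 <- pr[pr$condition == "Scr", ]
  expect_error(first_vs_rest_contrast(pr2, regions = "temporal"),
               "empty cell")
})
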