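test_that("the stratified split reproduces the 44/12 trial bookkeeping", {
  trials <- unique(synthetic_projections(1)[, c("trial_id", "condition")])
  expect_equal(nrow(trials), 56)
  sp <- trial_split(trials, seed = 3)
  expect_length(sp$pool, 44)
  expect_length(sp$test, 12)
  cond <- setNames(trials$condition, trials$trial_id)
  expect_equal(unname(table(cond[sp$test])), c(6L, 6L), ignore_attr = TRUE)
  expect_length(intersect(sp$pool, sp$test), 0)
  expect_identical(trial_split(trials, seed = 3), sp)
})

test_that("site ranking is by accuracy with deterministic tie-break", {
  res <- tibble::tibble(
    subject_id = c("S01", "S01", "S02"),
    site_id = c("a", "b", "c"),
    mean_r = c(0.2, 0.9, 0.5))
  expect_equal(rank_sites(res)$site_id, c("b", "c", "a"))
  res$mean_r <- 0.4
  expect_equal(rank_sites(res)$site_id, c("a", "b", "c"))
  shuffled <- res[c(3, 1, 2), ]
  expect_equal(rank_sites(shuffled), rank_sites(res))
})

test_that("correlation matching decodes patterns and handles degeneracy", {
  # measured equals the Seq prediction exactly
  r <- decode_trial(c(1, 0, 2), pred_scr = c(2, 1, 0), pred_seq = c(1, 0, 2),
                    true_condition = "Seq")
  expect_true(r$success)
  # two-site hand case: r = +1 vs -1
  r2 <- decode_trial(c(0.9, 0.1), pred_scr = c(0, 1), pred_seq = c(1, 0),
                     true_condition = "Seq")
  expect_equal(r2$predicted, "Seq")
  expect_true(r2$success)
  expect_warning(
    r3 <- decode_trial(c(1, 1), pred_scr = c(0, 1), pred_seq = c(1, 0),
                       true_condition = "Seq"),
    "zero-variance")
  expect_false(r3$success)
  expect_warning(
    r4 <- decode_trial(c(1, 2), pred_scr = c(1, 2), pred_seq = c(2, 4),
                       true_condition = "Seq"),
    "tie")
  expect_false(r4$success)
})

test_that("strong condition contrast gives near-perfect decoding", {
  pr <- synthetic_projections(12, delta = 4, seed = 31)
  enc <- encode_sites(pr, unique(pr$trial_id), n_perm = 100, seed = 33)
  sp <- trial_split(unique(pr[, c("trial_id", "condition")]), seed = 35)
  curve <- accuracy_curve(pr, rank_sites(enc), sp$test,
                          sizes = c(8, 12), repeats = 10, seed = 37)
  expect_true(all(curve$mean_accuracy >= 85))
  expect_true(all(curve$mean_accuracy <= 100))
})

test_that("decoding accuracy is invariant to a global PC1 sign flip", {
  pr <- synthetic_projections(10, delta = 1.5, seed = 41)
  enc <- encode_sites(pr, unique(pr$trial_id), n_perm = 100, seed = 43)
  sp <- trial_split(unique(pr[, c("trial_id", "condition")]), seed = 45)
  a <- accuracy_curve(pr, rank_sites(enc), sp$test, sizes = c(6, 10),
                      repeats = 5, seed = 47)
  pr_f <- pr; pr_f$y <- -pr_f$y
  b <- accuracy_curve(pr_f, rank_sites(enc), sp$test, sizes = c(6, 10),
                      repeats = 5, seed = 47)
  expect_equal(a$mean_accuracy, b$mean_accuracy)
})

test_that("decoding power grows monotonically with the injected contrast", {
  deltas <- c(0, 0.6, 1.6)
  acc <- vapply(deltas, function(d) {
    pr <- synthetic_projections(10, delta = d, seed = 49)
    enc <- encode_sites(pr, unique(pr$trial_id), n_perm = 100, seed = 51)
    sp <- trial_split(unique(pr[, c("trial_id", "condition")]), seed = 53)
    mean(accuracy_curve(pr, rank_sites(enc), sp$test, sizes = c(6, 10),
                        repeats = 5, seed = 55)$mean_accuracy)
  }, numeric(1))
  expect_equal(cor(deltas, acc, method = "spearman"), 1)
})

test_that("an empty test set is rejected", {
  pr <- synthetic_projections(6, seed = 57)
  enc <- encode_sites(pr, unique(pr$trial_id), n_perm = 100, seed = 59)
  expect_error(accuracy_curve(pr, rank_sites(enc), character(0)),
               "empty")
})
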