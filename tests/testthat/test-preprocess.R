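make_manual_recording <- function(signals, sites, sched = generate_schedule()) {
  structure(list(signals = signals, sites = sites, fs = 1000,
                 events = sched, ground_truth = NULL),
            class = "narr_recording")
}

test_that("common average reference zeroes the cross-site mean", {
  sites <- make_sites(1, c(frontal = 2))
  s <- sin(seq_len(5000) / 50)
  # antisymmetric pair: already zero-mean, must be unchanged
  rec <- make_manual_recording(rbind(s, -s), sites)
  rownames(rec$signals) <- sites$site_id
  out <- common_average_reference(rec)
  expect_equal(out$signals, rec$signals)
  # identical sites: self-subtraction gives all zeros
  rec2 <- make_manual_recording(rbind(s, s), sites)
  rownames(rec2$signals) <- sites$site_id
  expect_true(all(common_average_reference(rec2)$signals == 0))
  # general case: defining property
  rec3 <- sim_cohort(41, n_subjects = 2, car = FALSE)
  out3 <- common_average_reference(rec3)
  for (sj in unique(out3$sites$subject_id)) {
    idx <- out3$sites$subject_id == sj
    expect_lt(max(abs(colMeans(out3$signals[idx, ]))), 1e-10)
  }
})

test_that("referencing excludes flagged sites and fails on singletons", {
  rec <- sim_cohort(43, n_subjects = 1, per_region = c(frontal = 3),
                    car = FALSE)
  rec <- exclude_sites(rec, rec$sites$site_id[3], quiet = TRUE)
  before <- rec$signals[3, ]
  out <- common_average_reference(rec)
  expect_identical(out$signals[3, ], before)  # excluded site untouched
  idx <- which(!out$sites$excluded)
  expect_lt(max(abs(colMeans(out$signals[idx, ]))), 1e-10)
  rec2 <- exclude_sites(rec, rec$sites$site_id[2], quiet = TRUE)
  expect_error(common_average_reference(rec2), "fewer than 2")
})

test_that("site exclusion bookkeeping and errors", {
  rec <- sim_cohort(45, n_subjects = 1, per_region = c(frontal = 4),
                    car = FALSE)
  expect_identical(exclude_sites(rec, character(0)), rec)
  expect_error(exclude_sites(rec, "nope", quiet = TRUE), "unknown site")
  expect_message(exclude_sites(rec, rec$sites$site_id[1]), "3 analyzed")
  expect_error(exclude_sites(rec, rec$sites$site_id, quiet = TRUE),
               "zero analyzable")
})

test_that("epoching yields the documented trial counts per class", {
  rec <- sim_cohort(47, n_subjects = 1, per_region = c(frontal = 2))
  ep <- epoch_transitions(rec)  # default: image_to_image
  expect_equal(ncol(ep$data), 600)
  counts <- table(ep$meta$condition, ep$meta$site_id)
  expect_true(all(counts == 28))
  # the Fig-5 "First" set adds one transition per series: 7 per condition
  ep_first <- epoch_transitions(rec, classes = c("isi_to_image",
                                                 "first_of_experiment"))
  expect_true(all(table(ep_first$meta$condition,
                        ep_first$meta$site_id) == 7))
  # gray-screen onsets as ISI controls
  ep_isi <- epoch_transitions(rec, classes = "image_to_isi")
  expect_true(all(table(ep_isi$meta$condition, ep_isi$meta$site_id) == 7))
  expect_equal(nrow(epoch_transitions(rec, classes = character(0))$data), 0)
})

test_that("epoching is order-invariant and commutes with referencing", {
  rec <- sim_cohort(49, n_subjects = 1, per_region = c(frontal = 2),
                    car = FALSE)
  ev <- rec$events
  shuffled <- ev[withr::with_seed(1, sample(nrow(ev))), ]
  a <- epoch_transitions(rec, ev)
  b <- epoch_transitions(rec, shuffled)
  oa <- order(a$meta$site_id, a$meta$onset_ms)
  ob <- order(b$meta$site_id, b$meta$onset_ms)
  expect_equal(a$data[oa, ], b$data[ob, ])
  expect_equal(a$meta[oa, ], b$meta[ob, ], ignore_attr = TRUE)
  # reference-then-epoch == epoch-then-subtract-cross-site-mean
  ref_ep <- epoch_transitions(common_average_reference(rec))
  raw_ep <- epoch_transitions(rec)
  for (tid in unique(raw_ep$meta$trial_id)[1:5]) {
    rows <- which(raw_ep$meta$trial_id == tid)
    block <- raw_ep$data[rows, ]
    manual <- sweep(block, 2, colMeans(block))
    expect_equal(ref_ep$data[rows, ], manual, tolerance = 1e-10)
  }
})

test_that("epochs near the recording edge raise a named error", {
  rec <- sim_cohort(51, n_subjects = 1, per_region = c(frontal = 2))
  ev <- rec$events[rec$events$transition_class == "image_to_image", ][1, ]
  ev$onset_ms <- 50  # window would start before sample 1
  expect_error(epoch_transitions(rec, ev), "recording edge")
})

test_that("baseline correction subtracts the window mean", {
  ramp <- 0:599
  out <- baseline_correct(ramp, c(-100, 100))
  expect_equal(out, ramp - 99.5)  # mean of first 200 samples
  expect_equal(baseline_correct(rep(3, 600), c(-100, 50)), rep(0, 600))
  # shift invariance
  x <- withr::with_seed(5, rnorm(600))
  expect_equal(baseline_correct(x + 42, c(-100, 50)),
               baseline_correct(x, c(-100, 50)))
  expect_error(baseline_correct(x, c(600, 700)), "intersect")
})
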