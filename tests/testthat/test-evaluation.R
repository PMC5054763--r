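# small hand-built estimate/truth tables used across blocks
toy_est <- function(yaw, pitch, roll, confidence = 1, tracked = TRUE) {
  n <- length(yaw)
  tibble::tibble(frame_id = seq_len(n), yaw_deg = yaw, pitch_deg = pitch,
                 roll_deg = roll, confidence = confidence,
                 tracked = tracked)
}
toy_truth <- function(yaw, pitch, roll) {
  n <- length(yaw)
  tibble::tibble(frame_id = seq_len(n), yaw_deg = yaw, pitch_deg = pitch,
                 roll_deg = roll)
}

test_that("absolute errors use the angular metric with wrap-around", {
  est <- toy_est(179, 0, 0)
  tru <- toy_truth(-179, 0, 0)
  e <- absolute_errors(est, tru)
  expect_equal(e$yaw_err_deg, 2)

  est2 <- toy_est(c(1, 3, 5), c(0, 0, 0), c(0, 0, 0))
  tru2 <- toy_truth(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  e2 <- absolute_errors(est2, tru2)
  expect_equal(e2$yaw_err_deg, c(1, 3, 5))
  s <- summarize_errors(e2)
  expect_equal(s$yaw_mean_deg, 3)
  expect_equal(s$yaw_median_deg, 3)

  # perfect estimates give all-zero errors
  e3 <- absolute_errors(toy_est(5, -5, 10), toy_truth(5, -5, 10))
  expect_equal(e3$combined_err_deg, 0)
})

test_that("frame misalignment is rejected", {
  est <- toy_est(c(1, 2), c(0, 0), c(0, 0))
  tru <- toy_truth(c(1, 2, 3), c(0, 0, 0), c(0, 0, 0))
  expect_error(absolute_errors(est, tru), "alignment")
})

test_that("the combined mean is the grand mean of all per-axis errors", {
  est <- toy_est(c(1, 3), c(2, 4), c(3, 5))
  tru <- toy_truth(c(0, 0), c(0, 0), c(0, 0))
  s <- summarize_errors(absolute_errors(est, tru))
  expect_equal(s$combined_mean_deg, 3)  # grand mean of {1,2,3,3,4,5}
  expect_equal(s$combined_mean_deg,
               mean(c(s$yaw_mean_deg, s$pitch_mean_deg, s$roll_mean_deg)))
})

test_that("confidence filtering controls which frames are summarized", {
  est <- toy_est(c(1, 3), c(2, 4), c(3, 5), confidence = c(0.9, 0.5))
  tru <- toy_truth(c(0, 0), c(0, 0), c(0, 0))
  errs <- absolute_errors(est, tru)
  s <- summarize_errors(errs, min_confidence = 0.75)
  expect_equal(s$n_frames_used, 1)
  expect_equal(s$n_frames_total, 2)
  expect_equal(s$combined_mean_deg, 2)
  # filter-identity: no filter equals summarizing all tracked frames
  expect_equal(summarize_errors(errs), summarize_errors(errs, NULL))
  expect_error(summarize_errors(errs, min_confidence = 0.99), "empty")
})

test_that("untracked frames are excluded but counted", {
  est <- toy_est(c(1, 100), c(1, 100), c(1, 100), tracked = c(TRUE, FALSE))
  tru <- toy_truth(c(0, 0), c(0, 0), c(0, 0))
  s <- summarize_errors(absolute_errors(est, tru))
  expect_equal(s$n_frames_used, 1)
  expect_equal(s$retained_fraction, 0.5)
  expect_equal(s$combined_mean_deg, 1)
})

test_that("operational range applies the per-bin threshold rule", {
  # constructed bins: |yaw| 10 and 20 have 2 deg error, 30 has 6 deg
  yaw_true <- c(-30, -20, -10, 0, 10, 20, 30)
  err <- c(6, 2, 2, 1, 2, 2, 6)
  est <- toy_est(yaw_true + err, rep(0, 7), rep(0, 7))
  tru <- toy_truth(yaw_true, rep(0, 7), rep(0, 7))
  errs <- absolute_errors(est, tru)
  # make the combined error equal the yaw error alone
  errs$combined_err_deg <- errs$yaw_err_deg
  rng <- operational_range(errs, threshold_deg = 5, bin_width_deg = 10)
  expect_equal(rng$range_deg[rng$axis == "yaw"], 20)
  expect_false(rng$warning[rng$axis == "yaw"])

  # a threshold below every bin's error gives range 0 with a warning flag
  rng0 <- operational_range(errs, threshold_deg = 0.5, bin_width_deg = 10)
  expect_equal(rng0$range_deg[rng0$axis == "yaw"], 0)
  expect_true(rng0$warning[rng0$axis == "yaw"])

  # uniform small errors extend the range to the full simulated extent
  est_u <- toy_est(yaw_true + 1, rep(0, 7), rep(0, 7))
  errs_u <- absolute_errors(est_u, tru)
  rng_u <- operational_range(errs_u, threshold_deg = 5, bin_width_deg = 10)
  expect_equal(rng_u$range_deg[rng_u$axis == "yaw"], 30)
})

test_that("operational range is monotone in the threshold", {
  withr::with_seed(21, {
    yaw_true <- rep(seq(-40, 40, 5), each = 4)
    n <- length(yaw_true)
    err <- abs(rnorm(n, mean = abs(yaw_true) / 8))
    est <- toy_est(yaw_true + err, rep(0, n), rep(0, n))
    tru <- toy_truth(yaw_true, rep(0, n), rep(0, n))
    errs <- absolute_errors(est, tru)
    ranges <- vapply(c(1, 2, 3, 5, 8), function(th) {
      r <- operational_range(errs, threshold_deg = th, bin_width_deg = 5)
      r$range_deg[r$axis == "yaw"]
    }, numeric(1))
    expect_true(all(diff(ranges) >= 0))
  })
})

test_that("single-axis dominance labelling follows the rule", {
  frames <- tibble::tibble(
    yaw_deg = c(25, 25, 2, 0), pitch_deg = c(2, 15, 1, 0),
    roll_deg = c(1, 1, 30, 0))
  lab <- single_axis_subset(frames, dominance_threshold_deg = 10)
  expect_equal(lab$dominant_axis, c("yaw", NA, "roll", NA))

  # a grid of pure-axis poses is recovered exactly
  prot <- crom_protocol_poses()
  prot_lab <- single_axis_subset(prot, dominance_threshold_deg = 2)
  nonzero <- prot$target_deg != 0 & abs(prot$target_deg) > 2
  expect_equal(prot_lab$dominant_axis[nonzero], prot$axis[nonzero])
})

test_that("heat-map bins conserve counts and keep diagonals diagonal", {
  hm <- heatmap_bins(c(0, 10), c(0, 10), bin_width_deg = 5)
  expect_equal(nrow(hm), 2)
  expect_true(all(hm$actual_center_deg == hm$predicted_center_deg))
  expect_equal(sum(hm$n), 2)

  withr::with_seed(8, {
    a <- runif(200, -40, 40)
    p <- a + rnorm(200)
    hm2 <- heatmap_bins(a, p, bin_width_deg = 5)
    expect_equal(sum(hm2$n), 200)
  })

  # perfect predictions put all mass on the diagonal
  hm3 <- heatmap_bins(seq(-40, 40, 5), seq(-40, 40, 5), bin_width_deg = 5)
  expect_true(all(hm3$actual_center_deg == hm3$predicted_center_deg))
})

test_that("repeated-pose extraction builds the reliability matrix", {
  pitches <- seq(-30, 35, 5)
  frames <- tidyr::expand_grid(rep = 1:8, pitch = pitches)
  tru <- tibble::tibble(frame_id = seq_len(nrow(frames)), yaw_deg = 0,
                        pitch_deg = frames$pitch, roll_deg = 0)
  est <- tibble::tibble(frame_id = tru$frame_id, yaw_deg = 0,
                        pitch_deg = tru$pitch_deg, roll_deg = 0,
                        confidence = 1, tracked = TRUE)
  mat <- repeated_pose_icc_prep(est, tru, "pitch", pitches, 2.4, 8)
  expect_equal(dim(mat), c(14, 8))
  # zero-noise estimates give a perfectly reliable matrix
  expect_equal(icc(mat)$icc_average_measures, 1)
  expect_equal(icc(mat)$icc_single_measures, 1)
  # asking for more repeats than exist names the offending pose
  expect_error(repeated_pose_icc_prep(est, tru, "pitch", pitches, 2.4, 9),
               "insufficient repeats")
})
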