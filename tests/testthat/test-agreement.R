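test_that("pearson matches hand-computed values and validates input", {
  expect_equal(pearson(1:4, c(2, 1, 4, 3))$r, 0.6)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson(c(1, 2, 4), c(1, 2, 4))$r, 1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("regression recovers exact lines and flags singular designs", {
  lr <- linear_regression(c(0, 1, 2), c(1, 3, 5))
  expect_equal(lr$gradient, 2)
  expect_equal(lr$intercept_deg, 1)
  expect_equal(lr$r_squared, 1)
  lr2 <- linear_regression(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(lr2$gradient, 1)
  expect_equal(lr2$intercept_deg, 0)
  expect_error(linear_regression(c(2, 2, 2), c(1, 2, 3)), "singular")
})

test_that("r-squared equals the squared correlation on arbitrary data", {
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- rnorm(30); y <- 0.8 * x + rnorm(30)
      expect_equal(linear_regression(x, y)$r_squared, pearson(x, y)$r^2,
                   tolerance = 1e-12)
    }
  })
})

test_that("bland_altman reproduces hand arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias_deg, 0)
  expect_equal(ba0$loa_low_deg, 0)
  expect_equal(ba0$loa_high_deg, 0)

  # d = (1, -1): bias 0, sample SD sqrt(2), limits +/- 1.96 sqrt(2)
  ba <- bland_altman(c(0, 0), c(1, -1))
  expect_equal(ba$bias_deg, 0)
  expect_equal(ba$sd_diff_deg, sqrt(2))
  expect_equal(ba$loa_high_deg, 1.96 * sqrt(2))
  expect_equal(ba$loa_low_deg, -1.96 * sqrt(2))

  # translation equivariance
  x <- c(1, 4, 2, 8); y <- c(2, 3, 1, 9)
  b1 <- bland_altman(x, y)
  b2 <- bland_altman(x, y + 5)
  expect_equal(b2$bias_deg, b1$bias_deg + 5)
  expect_equal(b2$loa_low_deg, b1$loa_low_deg + 5)
  expect_equal(b2$loa_high_deg, b1$loa_high_deg + 5)
})

test_that("bland_altman limits cover about 95% of Gaussian differences", {
  withr::with_seed(99, {
    x <- rnorm(10000, sd = 5)
    d <- rnorm(10000, mean = 1, sd = 2)
    ba <- bland_altman(x, x + d)
    inside <- mean(ba$pairs$diff_deg >= ba$loa_low_deg &
                     ba$pairs$diff_deg <= ba$loa_high_deg)
    expect_gte(inside, 0.94)
    expect_lte(inside, 0.96)
  })
})

test_that("operational-range restriction filters on the comparator", {
  pairs <- tibble::tibble(axis = "yaw",
                          instrument_a_deg = c(-40, -30, 0, 30, 40),
                          instrument_b_deg = 0)
  kept <- restrict_to_operational_range(pairs, c(yaw = 30))
  expect_equal(nrow(kept), 3)
  expect_equal(attr(kept, "n_discarded"), 2)
  expect_equal(sort(kept$instrument_a_deg), c(-30, 0, 30))

  all_kept <- restrict_to_operational_range(pairs, c(yaw = 40))
  expect_equal(nrow(all_kept), 5)
  zero <- restrict_to_operational_range(pairs, c(yaw = 0))
  expect_equal(zero$instrument_a_deg, 0)
})

test_that("ICC matches the brute-force ANOVA oracle to 1e-12", {
  mat <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2))
  want <- oracle_icc(mat)
  got <- icc(mat, type = "agreement")
  expect_equal(got$icc_single_measures, want$single, tolerance = 1e-12)
  expect_equal(got$icc_average_measures, want$average, tolerance = 1e-12)

  # a second, seeded matrix to guard against coincidental agreement
  withr::with_seed(13, {
    m2 <- matrix(rnorm(14 * 8, mean = rep(seq(-30, 35, 5), 8), sd = 2), 14, 8)
    w2 <- oracle_icc(m2)
    g2 <- icc(m2)
    expect_equal(g2$icc_single_measures, w2$single, tolerance = 1e-12)
    expect_equal(g2$icc_average_measures, w2$average, tolerance = 1e-12)
  })
})

test_that("ICC cross-checks against aov mean squares", {
  withr::with_seed(17, {
    mat <- matrix(rnorm(6 * 4, mean = rep(1:6 * 3, 4)), 6, 4)
  })
  df <- data.frame(value = as.vector(mat),
                   pose = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   repeat_ = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  ms <- summary(aov(value ~ pose + repeat_, data = df))[[1]]$`Mean Sq`
  got <- icc(mat)
  expect_equal(got$mean_squares$msr, ms[1], tolerance = 1e-10)
  expect_equal(got$mean_squares$msc, ms[2], tolerance = 1e-10)
  expect_equal(got$mean_squares$mse, ms[3], tolerance = 1e-10)
})

test_that("ICC forms behave as reliability theory predicts", {
  withr::with_seed(23, {
    mat <- matrix(rnorm(14 * 8, mean = rep(rnorm(14, sd = 20), 8), sd = 2),
                  14, 8)
  })
  res <- icc(mat)
  expect_gte(res$icc_average_measures, res$icc_single_measures)
  expect_lte(res$icc_average_measures, 1)
  # a systematic per-repeat offset hurts absolute agreement but not
  # consistency
  shifted <- sweep(mat, 2, c(0, 4, 8, 12, 16, 0, 4, 8))
  expect_gt(icc(shifted, type = "consistency")$icc_single_measures,
            icc(shifted, type = "agreement")$icc_single_measures)

  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "missing cell")
  expect_error(icc(matrix(1, 3, 3)), "zero total variance")
  expect_error(icc(matrix(1:3, 3, 1)), ">= 2")
})

test_that("simulated reliability matrices give the expected ICC magnitudes", {
  reps <- t(vapply(1:100, function(i) {
    withr::with_seed(5000 + i, {
      truth <- rnorm(14, sd = 20)
      mat <- matrix(rnorm(14 * 8, mean = rep(truth, 8), sd = 2), 14, 8)
    })
    r <- icc(mat)
    c(r$icc_average_measures, r$icc_single_measures)
  }, numeric(2)))
  expect_gt(mean(reps[, 1]), 0.99)
  expect_gt(mean(reps[, 2]), 0.95)
  expect_lt(mean(reps[, 2]), 1)
})

test_that("the full protocol emulation shows the expected agreement pattern", {
  tab <- simulate_protocol_study(4, pose_execution_sd_deg = 3,
                                 instrument_noise_a_sd = 1,
                                 instrument_noise_b_sd = 1, seed = 42)
  res <- agreement_analysis(tab)
  expect_equal(nrow(res$summary), 3)
  expect_true(all(res$summary$pearson_r >= 0.95))
  expect_true(all(res$summary$gradient >= 0.9 & res$summary$gradient <= 1.1))
  expect_true(all(res$summary$loa_low_deg <= res$summary$bias_deg))
  expect_true(all(res$summary$bias_deg <= res$summary$loa_high_deg))

  # restriction to the operational range drops extreme yaw/pitch targets
  res_r <- agreement_analysis(tab, restrict = c(yaw = 30, pitch = 20, roll = 50))
  expect_lt(sum(res_r$summary$n_pairs), nrow(tab))
})

test_that("tidiers expose the result objects as tibbles", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1.5, 2, 3.5, 4))
  expect_named(glance(ba),
               c("bias_deg", "loa_low_deg", "loa_high_deg", "sd_diff_deg",
                 "loa_multiplier", "n"))
  expect_equal(nrow(tidy(ba)), 4)

  mat <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2))
  ti <- tidy(icc(mat))
  expect_equal(ti$measure, c("single_measures", "average_measures"))
  tab <- simulate_protocol_study(2, seed = 1)
  res <- agreement_analysis(tab)
  expect_equal(nrow(tidy(res)), 3)
  expect_equal(glance(res)$n_pairs, nrow(tab))
})
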