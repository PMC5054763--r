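# Shared fixtures: everything is generated in code, no stored data.

pose_cols <- c("yaw_deg", "pitch_deg", "roll_deg", "tx_mm", "ty_mm", "tz_mm")

fx_model <- canonical_model()
fx_camera <- default_camera()   # 1920x1080, focal 1920 px

# noiseless single-frame observation at a pose
fx_obs <- function(pose, model = fx_model, camera = fx_camera) {
  project(model, pose, camera)
}

# observation with seeded Gaussian pixel noise
fx_noisy_obs <- function(pose, sd_px, seed, model = fx_model,
                         camera = fx_camera) {
  obs <- project(model, pose, camera)
  withr::with_seed(seed, {
    obs$u_px <- obs$u_px + rnorm(nrow(obs), sd = sd_px)
    obs$v_px <- obs$v_px + rnorm(nrow(obs), sd = sd_px)
  })
  obs
}

# mean absolute angle error (over the three axes) of an estimate vs truth
fx_angle_err <- function(est, truth) {
  truth <- as_head_pose(truth)
  mean(abs(wrap_angle(c(
    est$pose[["yaw_deg"]] - truth[["yaw_deg"]],
    est$pose[["pitch_deg"]] - truth[["pitch_deg"]],
    est$pose[["roll_deg"]] - truth[["roll_deg"]]))))
}

# independent brute-force two-way ANOVA mean squares via explicit sums
oracle_mean_squares <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- sum(mat) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) {
    ri <- sum(mat[i, ]) / k
    ssr <- ssr + k * (ri - grand)^2
  }
  for (j in seq_len(k)) {
    cj <- sum(mat[, j]) / n
    ssc <- ssc + n * (cj - grand)^2
  }
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (mat[i, j] - grand)^2
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = (sst - ssr - ssc) / ((n - 1) * (k - 1)))
}

# oracle ICC(2,1) / ICC(2,k), absolute agreement, classical formulas
oracle_icc <- function(mat) {
  ms <- oracle_mean_squares(mat)
  n <- nrow(mat); k <- ncol(mat)
  list(
    single = (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)),
    average = (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  )
}
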