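# Per-frame pose estimation: weak-perspective initialization followed by
# damped Gauss-Newton refinement of the reprojection error, with a
# residual-based goodness-of-fit confidence.

#' Estimator configuration
#'
#' @param max_iterations Gauss-Newton iteration cap.
#' @param convergence_tol_deg stop when every angle update falls below this
#'   (degrees) ...
#' @param convergence_tol_mm ... and every translation update below this (mm).
#' @param min_visible_landmarks minimum visible landmarks to attempt a fit;
#'   at least 6 so the six pose parameters stay over-determined.
#' @param confidence_threshold confidence (fraction) at or above which a
#'   frame counts as tracked.
#' @param residual_scale normalized RMS reprojection error at which
#'   confidence reaches 0. Residuals are normalized by the projected
#'   inter-pupil pixel distance, making the confidence invariant to subject
#'   distance and image resolution.
#' @return list of class `estimator_config`.
#' @export
estimator_config <- function(max_iterations = 50,
                             convergence_tol_deg = 1e-6,
                             convergence_tol_mm = 1e-4,
                             min_visible_landmarks = 6,
                             confidence_threshold = 0.75,
                             residual_scale = 0.10) {
  cfg <- list(max_iterations = max_iterations,
              convergence_tol_deg = convergence_tol_deg,
              convergence_tol_mm = convergence_tol_mm,
              min_visible_landmarks = as.integer(min_visible_landmarks),
              confidence_threshold = confidence_threshold,
              residual_scale = residual_scale)
  if (any(unlist(cfg) <= 0)) stop("all estimator_config fields must be positive")
  if (cfg$min_visible_landmarks < 6) stop("min_visible_landmarks must be >= 6")
  structure(cfg, class = "estimator_config")
}

# visible, finite landmark rows of a one-frame observation table
visible_rows <- function(obs) {
  stopifnot(all(c("landmark_index", "u_px", "v_px", "visible") %in% names(obs)))
  obs[obs$visible & is.finite(obs$u_px) & is.finite(obs$v_px), , drop = FALSE]
}

#' Closed-form weak-perspective pose initialization
#'
#' Fits an affine map from model coordinates to centred pixel coordinates by
#' least squares, orthonormalizes its linear part to the nearest rotation
#' (scaled-orthographic, i.e. weak-perspective, camera approximation), and
#' reads off translation from the scale: `tz = focal_px / s`.
#'
#' @param obs one frame of landmarks: tibble with `landmark_index`, `u_px`,
#'   `v_px`, `visible`.
#' @param model a `face_model`.
#' @param camera a `camera_model`.
#' @param min_visible minimum number of visible landmarks.
#' @return a `head_pose` (approximate; refine with [refine_pose()]).
#' @export
initialize_weak_perspective <- function(obs, model, camera = default_camera(),
                                        min_visible = 6) {
  vis <- visible_rows(obs)
  if (nrow(vis) < min_visible) {
    stop("insufficient landmarks: ", nrow(vis), " visible, need ", min_visible)
  }
  P <- model$points[vis$landmark_index + 1L, , drop = FALSE]
  X <- cbind(P, 1)
  if (qr(X)$rank < 4) {
    stop("degenerate landmark configuration: visible model points are coplanar/collinear")
  }
  uc <- vis$u_px - camera$principal_point_px[1]
  vc <- vis$v_px - camera$principal_point_px[2]
  cu <- qr.solve(X, uc)
  cv <- qr.solve(X, vc)
  A <- rbind(cu[1:3], cv[1:3])
  s1 <- sqrt(sum(A[1, ]^2)); s2 <- sqrt(sum(A[2, ]^2))
  if (s1 < 1e-12 || s2 < 1e-12) stop("degenerate landmark configuration: zero scale")
  s <- (s1 + s2) / 2
  r1 <- A[1, ] / s1; r2 <- A[2, ] / s2
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  Rapx <- rbind(r1, r2, r3)
  sv <- svd(Rapx)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    sv$u[, 3] <- -sv$u[, 3]
    R <- sv$u %*% t(sv$v)
  }
  ang <- rotation_to_euler(R, tol = 1e-3)
  head_pose(yaw_deg = ang[["yaw_deg"]], pitch_deg = ang[["pitch_deg"]],
            roll_deg = ang[["roll_deg"]],
            tx_mm = cu[4] / s, ty_mm = cv[4] / s,
            tz_mm = camera$focal_px / s)
}

#' Map a normalized reprojection residual to a confidence fraction
#'
#' `confidence = clamp(1 - residual / residual_scale, 0, 1)`: 1 for a
#' perfect fit, 0 once the RMS reprojection error reaches `residual_scale`
#' times the projected inter-pupil pixel distance. Monotonically
#' non-increasing in the residual.
#'
#' @param residual_rms_norm RMS reprojection error divided by the projected
#'   inter-pupil pixel distance (dimensionless, >= 0).
#' @param cfg an `estimator_config`.
#' @export
compute_confidence <- function(residual_rms_norm, cfg = estimator_config()) {
  if (any(!is.finite(residual_rms_norm)) || any(residual_rms_norm < 0)) {
    stop("residual_rms_norm must be finite and non-negative")
  }
  pmin(1, pmax(0, 1 - residual_rms_norm / cfg$residual_scale))
}

# residual vector (stacked u then v errors) at a parameter vector, or NULL
# if the pose puts any visible point at non-positive depth
reproj_residual <- function(theta, P, uobs, vobs, camera) {
  R <- euler_to_rotation(theta[1], theta[2], theta[3])
  pc <- t(R %*% t(P))
  Z <- pc[, 3] + theta[6]
  if (theta[6] <= 0 || any(Z <= 0)) return(NULL)
  u <- camera$principal_point_px[1] + camera$focal_px * (pc[, 1] + theta[4]) / Z
  v <- camera$principal_point_px[2] + camera$focal_px * (pc[, 2] + theta[5]) / Z
  c(u - uobs, v - vobs)
}

# projected inter-pupil pixel distance at a fitted pose
projected_ipd_px <- function(model, pose, camera) {
  pc <- pupil_centers(model)
  cam <- transform_points(pc, pose)
  if (any(cam[, 3] <= 0)) return(NA_real_)
  f <- camera$focal_px
  uv <- cbind(f * cam[, 1] / cam[, 3], f * cam[, 2] / cam[, 3])
  sqrt(sum((uv[1, ] - uv[2, ])^2))
}

untracked_estimate <- function(n_visible, reason = "untracked") {
  structure(
    list(pose = head_pose(NaN, NaN, NaN, NaN, NaN, NaN),
         confidence = 0, residual_rms_norm = Inf, tracked = FALSE,
         converged = FALSE, n_visible = as.integer(n_visible),
         n_iterations = 0L, reason = reason),
    class = "pose_estimate"
  )
}

#' Refine a head pose by damped Gauss-Newton on the reprojection error
#'
#' Minimizes the sum of squared pixel reprojection errors over the six pose
#' parameters (yaw, pitch, roll in degrees; tx, ty, tz in mm) with
#' Levenberg-style multiplicative damping (factor 10 up on a rejected step,
#' 10 down on an accepted one) and central-difference Jacobians. Divergence
#' never raises: the frame is returned with `tracked = FALSE`.
#'
#' @inheritParams initialize_weak_perspective
#' @param init starting `head_pose` (e.g. from
#'   [initialize_weak_perspective()]).
#' @param cfg an `estimator_config`.
#' @return A `pose_estimate`: list with `pose`, `confidence` (fraction),
#'   `residual_rms_norm`, `tracked`, `converged`, `n_visible`,
#'   `n_iterations`.
#' @export
refine_pose <- function(obs, model, camera = default_camera(),
                        init, cfg = estimator_config()) {
  vis <- visible_rows(obs)
  if (nrow(vis) < cfg$min_visible_landmarks) {
    return(untracked_estimate(nrow(vis), "insufficient landmarks"))
  }
  init <- as_head_pose(init)
  if (!all(is.finite(init))) return(untracked_estimate(nrow(vis), "non-finite init"))
  P <- model$points[vis$landmark_index + 1L, , drop = FALSE]
  uobs <- vis$u_px; vobs <- vis$v_px
  theta <- as.numeric(init)[1:6]
  r <- reproj_residual(theta, P, uobs, vobs, camera)
  if (is.null(r)) return(untracked_estimate(nrow(vis), "behind camera at init"))
  cost <- sum(r^2)
  lambda <- 1e-3
  steps <- c(1e-4, 1e-4, 1e-4, 1e-2, 1e-2, 1e-2)  # deg / mm FD steps
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    J <- matrix(0, length(r), 6)
    for (j in 1:6) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + steps[j]; tm[j] <- tm[j] - steps[j]
      rp <- reproj_residual(tp, P, uobs, vobs, camera)
      rm <- reproj_residual(tm, P, uobs, vobs, camera)
      if (is.null(rp) || is.null(rm)) {
        rp <- reproj_residual(tp, P, uobs, vobs, camera)
        J[, j] <- if (is.null(rp)) 0 else (rp - r) / steps[j]
      } else {
        J[, j] <- (rp - rm) / (2 * steps[j])
      }
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    while (lambda <= 1e12) {
      H <- JtJ + lambda * diag(diag(JtJ) + 1e-12, 6)
      d <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (!is.null(d)) {
        theta_new <- theta + as.numeric(d)
        r_new <- reproj_residual(theta_new, P, uobs, vobs, camera)
        if (!is.null(r_new) && sum(r_new^2) < cost) {
          theta <- theta_new; r <- r_new; cost <- sum(r_new^2)
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (all(abs(d[1:3]) < cfg$convergence_tol_deg) &&
              all(abs(d[4:6]) < cfg$convergence_tol_mm)) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) break
  }
  pose <- head_pose(theta[1], theta[2], theta[3], theta[4], theta[5], theta[6])
  rms <- sqrt(cost / nrow(vis))
  ipd_px <- projected_ipd_px(model, pose, camera)
  res_norm <- if (is.finite(ipd_px) && ipd_px > 0) rms / ipd_px else Inf
  conf <- if (is.finite(res_norm)) compute_confidence(res_norm, cfg) else 0
  structure(
    list(pose = pose, confidence = conf, residual_rms_norm = res_norm,
         tracked = isTRUE(converged) && conf >= cfg$confidence_threshold,
         converged = converged, n_visible = nrow(vis), n_iterations = iter,
         reason = if (converged) "converged" else "no convergence"),
    class = "pose_estimate"
  )
}

#' Estimate head pose from one frame of 2D landmarks
#'
#' The public per-frame entry point: weak-perspective initialization
#' followed by Gauss-Newton refinement. Never raises on bad data — empty,
#' under-determined or untrackable frames come back with `tracked = FALSE`
#' and NaN pose fields.
#'
#' @inheritParams refine_pose
#' @return A `pose_estimate`.
#' @export
#' @examples
#' model <- canonical_model()
#' cam <- default_camera()
#' obs <- project(model, head_pose(yaw_deg = 20, tz_mm = 1200), cam)
#' est <- estimate_pose(obs, model, cam)
#' est$pose
estimate_pose <- function(obs, model = canonical_model(),
                          camera = default_camera(),
                          cfg = estimator_config()) {
  vis <- visible_rows(obs)
  if (nrow(vis) < cfg$min_visible_landmarks) {
    return(untracked_estimate(nrow(vis), "insufficient landmarks"))
  }
  init <- tryCatch(
    initialize_weak_perspective(obs, model, camera,
                                min_visible = cfg$min_visible_landmarks),
    error = function(e) NULL
  )
  if (is.null(init)) return(untracked_estimate(nrow(vis), "initialization failed"))
  refine_pose(obs, model, camera, init, cfg)
}

#' Metric distance of the head from the camera
#'
#' Euclidean norm of the fitted translation, in millimetres. The scale is
#' anchored by the model's 65 mm interpupillary distance: a subject whose
#' true IPD differs from 65 mm is reported at a distance biased by the
#' ratio (true IPD / 65).
#'
#' @param estimate a tracked `pose_estimate`.
#' @export
estimate_distance <- function(estimate) {
  stopifnot(inherits(estimate, "pose_estimate"))
  if (!isTRUE(estimate$tracked)) stop("not tracked: no reliable pose to measure")
  p <- estimate$pose
  sqrt(p[["tx_mm"]]^2 + p[["ty_mm"]]^2 + p[["tz_mm"]]^2)
}

#' @export
print.pose_estimate <- function(x, ...) {
  if (x$tracked) {
    cat(sprintf(
      "<pose_estimate> yaw %.2f pitch %.2f roll %.2f deg | dist %.0f mm | conf %.0f%%\n",
      x$pose[["yaw_deg"]], x$pose[["pitch_deg"]], x$pose[["roll_deg"]],
      estimate_distance(x), 100 * x$confidence))
  } else {
    cat("<pose_estimate> untracked (", x$reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Track head pose over a table of landmark frames
#'
#' Tidy front end to [estimate_pose()]: takes the long landmark table
#' (one row per frame x landmark) and returns one row per frame.
#'
#' @param landmarks tibble with columns `frame_id`, `landmark_index`,
#'   `u_px`, `v_px`, `visible`.
#' @param model,camera,cfg see [estimate_pose()].
#' @return tibble with columns `frame_id`, `yaw_deg`, `pitch_deg`,
#'   `roll_deg`, `tx_mm`, `ty_mm`, `tz_mm`, `distance_mm`, `confidence`,
#'   `tracked` (NaN pose fields where untracked), one row per input frame
#'   in order.
#' @export
track_head_pose <- function(landmarks, model = canonical_model(),
                            camera = default_camera(),
                            cfg = estimator_config()) {
  stopifnot("frame_id" %in% names(landmarks))
  frames <- split(landmarks, factor(landmarks$frame_id,
                                    levels = unique(landmarks$frame_id)))
  rows <- purrr::map(frames, function(fr) {
    est <- estimate_pose(fr, model, camera, cfg)
    p <- est$pose
    tibble::tibble(
      frame_id = fr$frame_id[1],
      yaw_deg = p[["yaw_deg"]], pitch_deg = p[["pitch_deg"]],
      roll_deg = p[["roll_deg"]], tx_mm = p[["tx_mm"]],
      ty_mm = p[["ty_mm"]], tz_mm = p[["tz_mm"]],
      distance_mm = if (est$tracked) estimate_distance(est) else NaN,
      confidence = est$confidence,
      tracked = est$tracked
    )
  })
  dplyr::bind_rows(rows)
}
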