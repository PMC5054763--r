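# Euler-angle conventions and the forward pinhole projection.
#
# Intrinsic rotation order: yaw (about the model vertical axis), then pitch
# (about the model left-right axis), then roll (about the face-normal axis).
# With the camera frame x right / y down / z forward and the model frame
# aligned to it at the null pose (+x subject's left, +y down, +z into the
# head), the clinical sign conventions — positive yaw = face turn to the
# subject's left, positive pitch = chin up, positive roll = tilt to the
# subject's right shoulder — correspond to right-handed rotations by
# (-yaw, -pitch, -roll) about the y, x and z axes respectively.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from clinical Euler angles
#'
#' Composes the intrinsic yaw -> pitch -> roll rotation that carries model
#' coordinates into the camera frame.
#'
#' @param yaw_deg,pitch_deg,roll_deg angles in degrees; alternatively pass a
#'   single `head_pose` (or one-row pose data frame) as `yaw_deg`.
#' @return 3 x 3 rotation matrix (determinant +1, orthonormal).
#' @export
#' @examples
#' euler_to_rotation(0, 0, 0)        # identity
#' euler_to_rotation(head_pose(yaw_deg = 25, pitch_deg = -10, roll_deg = 5))
euler_to_rotation <- function(yaw_deg, pitch_deg = NULL, roll_deg = NULL) {
  if (is.null(pitch_deg) && is.null(roll_deg)) {
    p <- as_head_pose(yaw_deg)
    yaw_deg <- p[["yaw_deg"]]; pitch_deg <- p[["pitch_deg"]]; roll_deg <- p[["roll_deg"]]
  }
  stopifnot(is.finite(yaw_deg), is.finite(pitch_deg), is.finite(roll_deg))
  rot_y(deg2rad(-yaw_deg)) %*% rot_x(deg2rad(-pitch_deg)) %*% rot_z(deg2rad(-roll_deg))
}

#' Clinical Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_rotation()]. At gimbal lock (|pitch| = 90 degrees)
#' the in-plane ambiguity is folded into yaw and roll is reported as 0.
#'
#' @param R 3 x 3 rotation matrix; must be orthonormal within `tol`.
#' @param tol orthonormality tolerance (Frobenius) for input validation.
#' @return Named numeric vector `(yaw_deg, pitch_deg, roll_deg)`.
#' @export
rotation_to_euler <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) || !all(is.finite(R))) {
    stop("invalid rotation: expected a finite 3x3 matrix")
  }
  if (norm(crossprod(R) - diag(3), "F") > tol || det(R) < 0) {
    stop("invalid rotation: matrix is not orthonormal with det +1 (tol ",
         format(tol), ")")
  }
  sp <- max(-1, min(1, R[2, 3]))
  pitch <- asin(sp)
  cp <- sqrt(R[2, 1]^2 + R[2, 2]^2)
  if (cp > 1e-9) {
    u <- atan2(R[1, 3], R[3, 3])
    r <- atan2(R[2, 1], R[2, 2])
    yaw <- -u
    roll <- -r
  } else {
    # gimbal lock: fold everything into yaw, report roll = 0
    yaw <- -atan2(-R[3, 1], R[1, 1])
    roll <- 0
  }
  c(yaw_deg = wrap_angle(rad2deg(yaw)),
    pitch_deg = wrap_angle(rad2deg(pitch)),
    roll_deg = wrap_angle(rad2deg(roll)))
}

# model -> camera coordinates (n x 3), for internal reuse
transform_points <- function(points, pose) {
  pose <- as_head_pose(pose)
  R <- euler_to_rotation(pose)
  t(R %*% t(points)) +
    matrix(c(pose[["tx_mm"]], pose[["ty_mm"]], pose[["tz_mm"]]),
           nrow(points), 3, byrow = TRUE)
}

#' Project a face model into the image
#'
#' Forward pinhole projection `u = cx + f X/Z`, `v = cy + f Y/Z` of every
#' model landmark under a head pose. This is the forward model the pose
#' estimator inverts.
#'
#' @param model a `face_model`.
#' @param pose a `head_pose` (or coercible); `tz_mm` must be positive.
#' @param camera a `camera_model`.
#' @return tibble with columns `landmark_index` (0--67), `u_px`, `v_px`,
#'   `visible` (all `TRUE`).
#' @export
project <- function(model, pose, camera = default_camera()) {
  stopifnot(inherits(model, "face_model"), inherits(camera, "camera_model"))
  pose <- as_head_pose(pose)
  if (!(pose[["tz_mm"]] > 0)) stop("behind-camera: tz_mm must be positive")
  pc <- transform_points(model$points, pose)
  if (any(pc[, 3] <= 0)) {
    stop("behind-camera: a model point has non-positive camera-frame depth")
  }
  f <- camera$focal_px
  cx <- camera$principal_point_px[1]
  cy <- camera$principal_point_px[2]
  tibble::tibble(
    landmark_index = 0:(nrow(pc) - 1L),
    u_px = cx + f * pc[, 1] / pc[, 3],
    v_px = cy + f * pc[, 2] / pc[, 3],
    visible = TRUE
  )
}
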