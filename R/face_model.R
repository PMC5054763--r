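# Canonical 3D face model and camera description.
#
# Model frame: +x toward the subject's anatomical left, +y down (toward the
# chin), +z into the head (away from the camera when the subject faces it).
# Units are millimetres. The model origin is the midpoint of the two pupil
# centres, and the pupil separation is exactly 65 mm.

# standard 68-point left<->right index pairing (0-based), midline points
# map to themselves
.mirror_pairing <- function() {
  pair <- 0:67
  swap <- function(a, b) {
    pair[a + 1] <<- b
    pair[b + 1] <<- a
  }
  for (i in 0:7) swap(i, 16 - i)              # jawline
  for (i in 0:4) swap(17 + i, 26 - i)         # eyebrows
  swap(31, 35); swap(32, 34)                  # nostril row
  swap(36, 45); swap(37, 44); swap(38, 43)    # eyes
  swap(39, 42); swap(40, 47); swap(41, 46)
  swap(48, 54); swap(49, 53); swap(50, 52)    # outer lips
  swap(55, 59); swap(56, 58)
  swap(60, 64); swap(61, 63); swap(65, 67)    # inner lips
  pair
}

.region_counts <- c(
  jawline = 17, eyebrow_left = 5, eyebrow_right = 5, nose = 9,
  eye_left = 6, eye_right = 6, lips = 20
)

#' Construct a face model from a landmark coordinate table
#'
#' @param points data frame with columns `index` (0--67), `region`,
#'   `x_mm`, `y_mm`, `z_mm`.
#' @return A `face_model` object: a list carrying the 68 x 3 coordinate
#'   matrix (mm), per-point region labels, and the landmark index sets whose
#'   centroids define the two pupil centres.
#' @export
face_model <- function(points) {
  stopifnot(is.data.frame(points))
  req <- c("index", "region", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(points))) {
    stop("face model table must have columns ", paste(req, collapse = ", "))
  }
  points <- points[order(points$index), ]
  if (nrow(points) != 68 || !identical(as.integer(points$index), 0:67)) {
    stop("face model must contain exactly the 68 landmark indices 0-67")
  }
  counts <- table(points$region)
  for (reg in names(.region_counts)) {
    if (is.na(counts[reg]) || counts[reg] != .region_counts[reg]) {
      stop("region '", reg, "' must contain ", .region_counts[reg], " points")
    }
  }
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  dimnames(xyz) <- list(NULL, c("x_mm", "y_mm", "z_mm"))
  structure(
    list(
      points = xyz,
      region = as.character(points$region),
      pupil_left_index_set = which(points$region == "eye_left") - 1L,
      pupil_right_index_set = which(points$region == "eye_right") - 1L,
      mirror_pairing = .mirror_pairing()
    ),
    class = "face_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The canonical 68-point 3D face model
#'
#' Returns the fixed face-shape table the tracker fits: 68 landmarks in
#' millimetres following the standard region layout (17 jawline, 5+5
#' eyebrows, 9 nose, 6+6 lid margins, 20 lips), mirror-symmetric about the
#' midsagittal plane, with the origin at the midpoint of the pupil centres
#' and an interpupillary distance of exactly 65 mm. The table is stored as a
#' versioned CSV resource, so the model is identical on every call and
#' platform.
#'
#' @return A `face_model` object.
#' @export
#' @examples
#' model <- canonical_model()
#' interpupillary_distance(model)
canonical_model <- function() {
  path <- system.file("extdata", "canonical_face_model.csv",
                      package = "facepose", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  face_model(tab)
}

#' Pupil centres of a face model
#'
#' Centroids of the lid-margin landmark sets, in model coordinates (mm).
#'
#' @param model a `face_model`.
#' @return 2 x 3 matrix with rows `left`, `right`.
#' @export
pupil_centers <- function(model) {
  stopifnot(inherits(model, "face_model"))
  out <- rbind(
    left = colMeans(model$points[model$pupil_left_index_set + 1L, , drop = FALSE]),
    right = colMeans(model$points[model$pupil_right_index_set + 1L, , drop = FALSE])
  )
  out
}

#' Interpupillary distance of a face model in millimetres
#' @param model a `face_model`.
#' @export
interpupillary_distance <- function(model) {
  pc <- pupil_centers(model)
  sqrt(sum((pc["left", ] - pc["right", ])^2))
}

#' Serialize a face model to its CSV resource form
#'
#' Columns `index`, `region`, `x_mm`, `y_mm`, `z_mm`, matching the format of
#' the shipped canonical model.
#'
#' @param model a `face_model`.
#' @return tibble with one row per landmark.
#' @export
as_tibble.face_model <- function(model, ...) {
  tibble::tibble(
    index = 0:67,
    region = model$region,
    x_mm = model$points[, 1],
    y_mm = model$points[, 2],
    z_mm = model$points[, 3]
  )
}

#' @export
print.face_model <- function(x, ...) {
  cat("<face_model> 68 landmarks, IPD",
      format(interpupillary_distance(x), digits = 6), "mm\n")
  invisible(x)
}

#' Pinhole camera description
#'
#' @param focal_px focal length in pixels (> 0).
#' @param principal_point_px numeric length-2 `(cx, cy)` in pixels; defaults
#'   to the image centre.
#' @param image_size_px numeric length-2 `(width, height)` in pixels.
#' @return A `camera_model` object.
#' @export
camera_model <- function(focal_px = image_size_px[1],
                         principal_point_px = image_size_px / 2,
                         image_size_px = c(1920, 1080)) {
  stopifnot(length(image_size_px) == 2, all(image_size_px > 0))
  if (!is.numeric(focal_px) || length(focal_px) != 1 || focal_px <= 0) {
    stop("focal_px must be a positive number")
  }
  pp <- as.numeric(principal_point_px)
  if (length(pp) != 2 || any(pp < 0) || any(pp > image_size_px)) {
    stop("principal point must lie inside the image bounds")
  }
  structure(
    list(focal_px = as.numeric(focal_px), principal_point_px = pp,
         image_size_px = as.numeric(image_size_px)),
    class = "camera_model"
  )
}

#' Default webcam model
#'
#' Focal length equal to the image width (about a 53 degree horizontal field
#' of view, typical of consumer webcams) and principal point at the image
#' centre.
#'
#' @param width,height image size in pixels.
#' @export
default_camera <- function(width = 1920, height = 1080) {
  camera_model(focal_px = width, image_size_px = c(width, height))
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>", x$image_size_px[1], "x", x$image_size_px[2],
      "px, focal", x$focal_px, "px\n")
  invisible(x)
}

#' Construct a head pose
#'
#' Clinical Euler angles in degrees plus metric translation of the model
#' origin in the camera frame. Positive yaw = face turn to the subject's
#' left; positive pitch = chin up; positive roll = head tilt toward the
#' subject's right shoulder.
#'
#' @param yaw_deg,pitch_deg,roll_deg angles in degrees, each in (-180, 180].
#' @param tx_mm,ty_mm,tz_mm translation in millimetres, camera frame
#'   (x right, y down, z forward).
#' @return Named numeric vector of class `head_pose`.
#' @export
head_pose <- function(yaw_deg = 0, pitch_deg = 0, roll_deg = 0,
                      tx_mm = 0, ty_mm = 0, tz_mm = 1200) {
  p <- c(yaw_deg = wrap_angle(yaw_deg), pitch_deg = wrap_angle(pitch_deg),
         roll_deg = wrap_angle(roll_deg),
         tx_mm = as.numeric(tx_mm), ty_mm = as.numeric(ty_mm),
         tz_mm = as.numeric(tz_mm))
  structure(p, class = "head_pose")
}

pose_fields <- c("yaw_deg", "pitch_deg", "roll_deg", "tx_mm", "ty_mm", "tz_mm")

#' Coerce a one-row data frame, list, or named vector to a head pose
#' @param x object with fields `yaw_deg`, `pitch_deg`, `roll_deg`, `tx_mm`,
#'   `ty_mm`, `tz_mm`.
#' @export
as_head_pose <- function(x) {
  if (inherits(x, "head_pose")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- as.list(x)
  }
  x <- as.list(x)
  miss <- setdiff(pose_fields, names(x))
  if (length(miss)) stop("pose is missing fields: ", paste(miss, collapse = ", "))
  do.call(head_pose, x[pose_fields])
}

#' Wrap angles in degrees into (-180, 180]
#' @param a numeric vector of angles in degrees.
#' @export
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}
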