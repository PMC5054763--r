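# Readers and writers for the package's CSV schemas and the matrix-text
# pose-annotation dialect used by public head-pose video datasets
# (per-frame 3x3 rotation matrix plus translation vector).
#
# All CSV files: comma separator, '.' decimal, LF line endings, header row
# required. Angles in degrees everywhere; landmark indices are 0-based
# (0-67) in files.

landmark_cols <- c("frame_id", "landmark_index", "u_px", "v_px", "visible")
truth_cols <- c("frame_id", pose_fields, "dropped")
estimate_cols <- c("frame_id", pose_fields, "distance_mm", "confidence", "tracked")

#' Write a landmark table to CSV
#' @param landmarks tibble with the landmark schema columns.
#' @param path output file.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(all(landmark_cols %in% names(landmarks)))
  readr::write_csv(landmarks[, landmark_cols], path, eol = "\n")
  invisible(path)
}

#' Read a landmark CSV into per-frame observations
#'
#' Missing landmark rows are filled in as invisible; duplicate
#' (frame, landmark) rows and out-of-range indices are errors.
#'
#' @param path landmark CSV with columns `frame_id`, `landmark_index`,
#'   `u_px`, `v_px`, `visible`.
#' @return long tibble, 68 rows per frame, frames in first-appearance
#'   order.
#' @export
read_landmarks_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(landmark_cols %in% names(df))) {
    stop("landmark CSV must have columns ", paste(landmark_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(df[, landmark_cols])
  if (any(df$landmark_index < 0 | df$landmark_index > 67)) {
    stop("range error: landmark_index must lie in 0-67")
  }
  if (anyDuplicated(df[, c("frame_id", "landmark_index")])) {
    stop("duplicate (frame_id, landmark_index) rows")
  }
  df$visible <- as.logical(df$visible)
  frames <- unique(df$frame_id)
  full <- tidyr::expand_grid(frame_id = frames, landmark_index = 0:67)
  out <- dplyr::left_join(full, df, by = c("frame_id", "landmark_index"))
  out$visible[is.na(out$visible)] <- FALSE
  out$visible[!is.finite(out$u_px) | !is.finite(out$v_px)] <- FALSE
  out[, landmark_cols]
}

#' Write ground-truth poses to CSV
#' @param truth tibble with `frame_id`, the six pose columns, `dropped`.
#' @param path output file.
#' @export
write_truth_csv <- function(truth, path) {
  if (!"dropped" %in% names(truth)) truth$dropped <- FALSE
  stopifnot(all(truth_cols %in% names(truth)))
  readr::write_csv(truth[, truth_cols], path, eol = "\n")
  invisible(path)
}

#' Read a ground-truth pose CSV
#' @param path file written by [write_truth_csv()].
#' @export
read_truth_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("frame_id", pose_fields), names(df))
  if (length(miss)) stop("truth CSV missing columns ", paste(miss, collapse = ", "))
  if (!"dropped" %in% names(df)) df$dropped <- FALSE
  df$dropped <- as.logical(df$dropped)
  df[, truth_cols]
}

#' Write per-frame pose estimates to CSV
#' @param estimates tibble from [track_head_pose()].
#' @param path output file.
#' @export
write_estimates_csv <- function(estimates, path) {
  stopifnot(all(estimate_cols %in% names(estimates)))
  readr::write_csv(estimates[, estimate_cols], path, eol = "\n")
  invisible(path)
}

#' Read a per-frame estimate CSV
#' @param path file written by [write_estimates_csv()].
#' @export
read_estimates_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", "NaN"))
  miss <- setdiff(estimate_cols, names(df))
  if (length(miss)) stop("estimate CSV missing columns ", paste(miss, collapse = ", "))
  df$tracked <- as.logical(df$tracked)
  df[, estimate_cols]
}

#' Write poses in the matrix-text annotation dialect
#'
#' One block per frame: three lines with the rows of the rotation matrix,
#' then one line with the translation (mm), then a blank line.
#'
#' @param poses data frame of poses (six pose columns) or list of
#'   `head_pose`.
#' @param path output file.
#' @export
write_pose_annotation <- function(poses, path) {
  if (is.data.frame(poses)) {
    poses <- lapply(seq_len(nrow(poses)), function(i) as_head_pose(poses[i, ]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    R <- euler_to_rotation(p)
    for (i in 1:3) {
      writeLines(paste(sprintf("%.15g", R[i, ]), collapse = " "), con)
    }
    writeLines(paste(sprintf("%.15g", c(p[["tx_mm"]], p[["ty_mm"]], p[["tz_mm"]])),
                     collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read per-frame pose annotations
#'
#' Two dialects: `matrix_text` — per-frame blocks of a 3x3 row-major
#' rotation matrix (3 lines of 3 whitespace-separated floats) followed by
#' a translation line (3 floats, mm), blank lines between blocks tolerated;
#' `csv` — the ground-truth CSV dialect of [write_truth_csv()]. Rotation
#' matrices are converted to clinical Euler angles.
#'
#' @param path annotation file.
#' @param dialect `"matrix_text"` or `"csv"`.
#' @return tibble with `frame_id` and the six pose columns.
#' @export
read_pose_annotation <- function(path, dialect = c("matrix_text", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- read_truth_csv(path)
    return(df[, c("frame_id", pose_fields)])
  }
  lines <- readLines(path)
  nums <- vector("list", 0)
  line_no <- integer(0)
  for (i in seq_along(lines)) {
    s <- trimws(lines[i])
    if (s == "") next
    vals <- suppressWarnings(as.numeric(strsplit(s, "\\s+")[[1]]))
    if (length(vals) != 3 || anyNA(vals)) {
      stop("parse error at line ", i, ": expected 3 whitespace-separated numbers")
    }
    nums[[length(nums) + 1]] <- vals
    line_no[length(line_no) + 1] <- i
  }
  if (length(nums) %% 4 != 0) {
    bad <- line_no[length(nums)]
    stop("parse error at line ", bad,
         ": file truncated mid-block (each frame needs 4 data lines)")
  }
  n_frames <- length(nums) / 4
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    b <- nums[(4 * (f - 1) + 1):(4 * f)]
    R <- rbind(b[[1]], b[[2]], b[[3]])
    if (norm(crossprod(R) - diag(3), "F") > 1e-3) {
      stop("invalid rotation in frame ", f,
           " (line ", line_no[4 * (f - 1) + 1], "): matrix not orthonormal")
    }
    ang <- rotation_to_euler(R, tol = 1e-3)
    t <- b[[4]]
    rows[[f]] <- tibble::tibble(
      frame_id = f, yaw_deg = ang[["yaw_deg"]], pitch_deg = ang[["pitch_deg"]],
      roll_deg = ang[["roll_deg"]], tx_mm = t[1], ty_mm = t[2], tz_mm = t[3])
  }
  dplyr::bind_rows(rows)
}

#' Write a paired two-instrument measurement table to CSV
#' @param pairs tibble from [simulate_protocol_study()].
#' @param path output file.
#' @export
write_pairs_csv <- function(pairs, path) {
  cols <- c("subject", "axis", "target_deg", "instrument_a_deg", "instrument_b_deg")
  stopifnot(all(cols %in% names(pairs)))
  readr::write_csv(pairs[, cols], path, eol = "\n")
  invisible(path)
}

#' Read a paired two-instrument measurement table
#' @param path CSV written by [write_pairs_csv()].
#' @export
read_pairs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cols <- c("subject", "axis", "target_deg", "instrument_a_deg", "instrument_b_deg")
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("pairs CSV missing columns ", paste(miss, collapse = ", "))
  df[, cols]
}

# run-configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(
    image_width_px = 1920, image_height_px = 1080, focal_px = NULL,
    max_iterations = 50, convergence_tol_deg = 1e-6,
    convergence_tol_mm = 1e-4, min_visible_landmarks = 6,
    confidence_threshold = 0.75, residual_scale = 0.10,
    error_threshold_deg = 5, bin_width_deg = 5,
    dominance_threshold_deg = 10,
    loa_multiplier = 1.96, icc_mode = "agreement",
    n_subjects = 4, pose_execution_sd_deg = 3,
    instrument_noise_a_sd = 1, instrument_noise_b_sd = 1,
    subject_tz_mm = 1200, seed = 1
  )
}

#' Read a flat key-value run configuration
#'
#' YAML-subset config file (flat mapping). Unknown keys are rejected by
#' name so a typo in a threshold cannot silently corrupt an analysis.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @return named list of configuration values merged over the defaults.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}
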