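# Per-frame accuracy machinery: absolute angular errors against frame-level
# ground truth, confidence-filtered summaries, operational-range
# derivation, single-axis subsets, heat-map binning, and extraction of
# repeated-pose matrices for reliability (ICC) analysis.

axis_names <- c("yaw", "pitch", "roll")

#' Per-frame absolute angular errors
#'
#' Joins estimates to ground truth by `frame_id` and computes the per-axis
#' absolute error with angular wrap-around (differences taken in
#' (-180, 180]), plus the per-frame combined error, defined as the mean of
#' the three per-axis absolute errors. Untracked frames keep their row with
#' NA errors so downstream summaries can count them.
#'
#' @param estimates tibble from [track_head_pose()] (columns `frame_id`,
#'   pose angles, `confidence`, `tracked`).
#' @param truths tibble with `frame_id` and true `yaw_deg`, `pitch_deg`,
#'   `roll_deg`.
#' @return tibble with `frame_id`, true angles (`yaw_true_deg`, ...),
#'   `yaw_err_deg`, `pitch_err_deg`, `roll_err_deg`, `combined_err_deg`,
#'   `confidence`, `tracked`.
#' @export
absolute_errors <- function(estimates, truths) {
  stopifnot(is.data.frame(estimates), is.data.frame(truths))
  if (!setequal(estimates$frame_id, truths$frame_id) ||
      nrow(estimates) != nrow(truths)) {
    stop("alignment error: estimates and truths must cover the same frame_ids")
  }
  tr <- truths[match(estimates$frame_id, truths$frame_id), ]
  err <- function(est, tru) abs(wrap_angle(est - tru))
  out <- tibble::tibble(
    frame_id = estimates$frame_id,
    yaw_true_deg = tr$yaw_deg, pitch_true_deg = tr$pitch_deg,
    roll_true_deg = tr$roll_deg,
    yaw_err_deg = err(estimates$yaw_deg, tr$yaw_deg),
    pitch_err_deg = err(estimates$pitch_deg, tr$pitch_deg),
    roll_err_deg = err(estimates$roll_deg, tr$roll_deg),
    confidence = estimates$confidence %||% rep(1, nrow(estimates)),
    tracked = estimates$tracked %||% rep(TRUE, nrow(estimates))
  )
  out$yaw_err_deg[!out$tracked] <- NA_real_
  out$pitch_err_deg[!out$tracked] <- NA_real_
  out$roll_err_deg[!out$tracked] <- NA_real_
  out$combined_err_deg <-
    (out$yaw_err_deg + out$pitch_err_deg + out$roll_err_deg) / 3
  out
}

#' Summarize absolute errors with optional confidence filtering
#'
#' Mean and median absolute error per axis and combined, over tracked
#' frames passing the confidence filter. The combined statistics are taken
#' over the per-frame combined errors, so the combined mean equals the
#' grand mean of all per-axis errors. The fraction of frames retained is
#' reported alongside (the analogue of a confident-recognition rate).
#'
#' @param errors tibble from [absolute_errors()].
#' @param min_confidence drop frames with confidence below this fraction;
#'   `NULL` keeps every tracked frame.
#' @return one-row tibble: per-axis and combined mean/median errors
#'   (degrees), `n_frames_used`, `n_frames_total`, `retained_fraction`,
#'   `filter_description`.
#' @export
summarize_errors <- function(errors, min_confidence = NULL) {
  total <- nrow(errors)
  keep <- errors$tracked & !is.na(errors$combined_err_deg)
  desc <- "tracked frames"
  if (!is.null(min_confidence)) {
    keep <- keep & errors$confidence >= min_confidence
    desc <- sprintf("tracked frames with confidence >= %.2f", min_confidence)
  }
  used <- errors[keep, ]
  if (nrow(used) == 0) stop("empty summary: no frames pass the filter")
  tibble::tibble(
    yaw_mean_deg = mean(used$yaw_err_deg),
    yaw_median_deg = median(used$yaw_err_deg),
    pitch_mean_deg = mean(used$pitch_err_deg),
    pitch_median_deg = median(used$pitch_err_deg),
    roll_mean_deg = mean(used$roll_err_deg),
    roll_median_deg = median(used$roll_err_deg),
    combined_mean_deg = mean(used$combined_err_deg),
    combined_median_deg = median(used$combined_err_deg),
    n_frames_used = nrow(used),
    n_frames_total = total,
    retained_fraction = nrow(used) / total,
    filter_description = desc
  )
}

bin_center <- function(x, width) round(x / width) * width

#' Operational range: how far out does accuracy hold?
#'
#' For each axis, frames are binned by that axis's true value (bins of
#' `bin_width_deg` centred on multiples of the width) and the largest
#' symmetric range +/-L is found such that every populated bin inside it
#' keeps a mean combined absolute error below `threshold_deg`. This is the
#' range within which the tracker is accurate enough for clinical use.
#'
#' @param errors tibble from [absolute_errors()] (true angles included).
#' @param threshold_deg combined mean-absolute-error ceiling, degrees.
#' @param bin_width_deg bin width, degrees.
#' @return tibble with one row per axis: `axis`, `range_deg` (the L of
#'   +/-L), `warning` (TRUE when even the central bin fails, range 0).
#' @export
operational_range <- function(errors, threshold_deg = 5, bin_width_deg = 5) {
  stopifnot(threshold_deg > 0, bin_width_deg > 0)
  used <- errors[errors$tracked & !is.na(errors$combined_err_deg), ]
  res <- purrr::map(axis_names, function(ax) {
    truth <- used[[paste0(ax, "_true_deg")]]
    centers <- bin_center(truth, bin_width_deg)
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(center = centers,
                                     err = used$combined_err_deg), center),
      mean_err = mean(err), n = dplyr::n(), .groups = "drop")
    max_c <- max(abs(agg$center))
    L <- -1
    k <- 0
    while (k * bin_width_deg <= max_c) {
      inside <- agg[abs(agg$center) <= k * bin_width_deg, ]
      if (nrow(inside) > 0 && all(inside$mean_err < threshold_deg)) {
        L <- k * bin_width_deg
      } else if (nrow(inside) > 0) {
        break
      }
      k <- k + 1
    }
    tibble::tibble(axis = ax, range_deg = max(L, 0), warning = L < 0)
  })
  dplyr::bind_rows(res)
}

#' Per-bin mean combined error along one axis
#'
#' Helper behind [operational_range()], exposed for plotting the
#' error-versus-eccentricity profile.
#'
#' @inheritParams operational_range
#' @return tibble `axis`, `center_deg`, `mean_err_deg`, `n_frames`.
#' @export
error_by_eccentricity <- function(errors, bin_width_deg = 5) {
  used <- errors[errors$tracked & !is.na(errors$combined_err_deg), ]
  purrr::map_dfr(axis_names, function(ax) {
    centers <- bin_center(used[[paste0(ax, "_true_deg")]], bin_width_deg)
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(axis = ax, center_deg = centers,
                                     err = used$combined_err_deg),
                      axis, center_deg),
      mean_err_deg = mean(err), n_frames = dplyr::n(), .groups = "drop")
  })
}

#' Label frames that deviate on a single axis only
#'
#' A frame is assigned to axis A when |A| exceeds the dominance threshold
#' while both other axes stay within it; all other frames are left
#' unassigned (NA). Used for the single-axis subanalysis and for building
#' repeated-pose reliability subsets.
#'
#' @param frames tibble with true `yaw_deg`, `pitch_deg`, `roll_deg`
#'   columns (or the `*_true_deg` columns of an error table).
#' @param dominance_threshold_deg degrees; default 10.
#' @return the input with an added `dominant_axis` column.
#' @export
single_axis_subset <- function(frames, dominance_threshold_deg = 10) {
  get_axis <- function(ax) {
    frames[[paste0(ax, "_true_deg")]] %||% frames[[paste0(ax, "_deg")]]
  }
  v <- sapply(axis_names, function(ax) abs(get_axis(ax)))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1, dimnames = list(NULL, axis_names))
  thr <- dominance_threshold_deg
  lab <- apply(v, 1, function(r) {
    over <- r > thr
    if (sum(over) == 1 && all(r[!over] <= thr)) axis_names[over] else NA_character_
  })
  frames$dominant_axis <- lab
  frames
}

#' Joint actual-versus-predicted histogram (heat-map counts)
#'
#' Bins paired (actual, predicted) angle values into square bins; the
#' counts sum to the number of pairs.
#'
#' @param actual,predicted aligned numeric vectors, degrees.
#' @param bin_width_deg bin width, degrees.
#' @return tibble `actual_center_deg`, `predicted_center_deg`, `n`.
#' @export
heatmap_bins <- function(actual, predicted, bin_width_deg = 5) {
  stopifnot(length(actual) == length(predicted))
  keep <- is.finite(actual) & is.finite(predicted)
  tb <- tibble::tibble(
    actual_center_deg = bin_center(actual[keep], bin_width_deg),
    predicted_center_deg = bin_center(predicted[keep], bin_width_deg)
  )
  dplyr::summarise(dplyr::group_by(tb, actual_center_deg, predicted_center_deg),
                   n = dplyr::n(), .groups = "drop")
}

#' Build a poses x repeats matrix of repeated-pose measurements
#'
#' For reliability analysis: collects estimated values for frames whose
#' true pose deviates only on `axis` (other axes within `tolerance_deg`)
#' and whose true value on that axis lies within `tolerance_deg` of each
#' requested pose value; requires and keeps exactly `n_required` repeats
#' per pose. The result feeds [icc()].
#'
#' @param estimates tibble from [track_head_pose()].
#' @param truths matching ground-truth tibble.
#' @param axis `"yaw"`, `"pitch"` or `"roll"`.
#' @param pose_values requested true pose values, degrees.
#' @param tolerance_deg matching tolerance, degrees.
#' @param n_required repeats required per pose value.
#' @return numeric matrix, `length(pose_values)` x `n_required`, row names
#'   the pose values.
#' @export
repeated_pose_icc_prep <- function(estimates, truths, axis, pose_values,
                                   tolerance_deg = 2.5, n_required = 8) {
  stopifnot(axis %in% axis_names)
  tr <- truths[match(estimates$frame_id, truths$frame_id), ]
  others <- setdiff(axis_names, axis)
  pure <- abs(tr[[paste0(others[1], "_deg")]]) <= tolerance_deg &
    abs(tr[[paste0(others[2], "_deg")]]) <= tolerance_deg &
    estimates$tracked
  est_val <- estimates[[paste0(axis, "_deg")]]
  tru_val <- tr[[paste0(axis, "_deg")]]
  rows <- lapply(pose_values, function(v) {
    hit <- which(pure & abs(tru_val - v) <= tolerance_deg)
    if (length(hit) < n_required) {
      stop("insufficient repeats for ", axis, " = ", v, " deg: found ",
           length(hit), ", need ", n_required)
    }
    est_val[hit[seq_len(n_required)]]
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- pose_values
  mat
}
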