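# Synthetic fixture generation: subjects with perturbed face shape,
# landmark sequences under known pose with noise / occlusion / dropped
# frames, and the 43-pose fixation-target protocol with its paired
# two-instrument measurement simulation.

#' Generate a synthetic subject
#'
#' Perturbs the canonical face model with seeded isotropic Gaussian noise
#' per landmark (emulating inter-subject shape variation), recentres the
#' pupil midpoint at the origin, and rescales so the subject's true
#' interpupillary distance equals `ipd_mm` exactly.
#'
#' @param seed integer RNG seed; the subject is bitwise-reproducible per
#'   seed.
#' @param shape_sd_mm per-point isotropic perturbation SD in mm (>= 0).
#' @param ipd_mm the subject's true interpupillary distance (> 0). A value
#'   other than 65 makes the estimator's metric distance biased by
#'   `ipd_mm / 65`, which is the documented consequence of the fixed-IPD
#'   scale anchor.
#' @return a `face_model` for the subject.
#' @export
make_subject <- function(seed, shape_sd_mm = 2, ipd_mm = 65) {
  stopifnot(shape_sd_mm >= 0, ipd_mm > 0)
  base <- canonical_model()
  pts <- withr::with_seed(as.integer(seed), {
    base$points + matrix(rnorm(68 * 3, sd = shape_sd_mm), 68, 3)
  })
  tmp <- base
  tmp$points <- pts
  pc <- pupil_centers(tmp)
  mid <- (pc["left", ] + pc["right", ]) / 2
  pts <- sweep(pts, 2, mid)
  tmp$points <- pts
  cur_ipd <- interpupillary_distance(tmp)
  tmp$points <- pts * (ipd_mm / cur_ipd)
  tmp
}

#' Specification of a synthetic landmark sequence
#'
#' @param poses pose trajectory: a data frame with the six pose columns
#'   (one row per frame) or a single `head_pose` recycled `n_frames` times.
#' @param n_frames number of frames (defaults to `nrow(poses)`).
#' @param noise_sd_px i.i.d. Gaussian pixel noise SD added to each
#'   projected coordinate.
#' @param noise_gain_per_deg optional eccentricity-dependent noise: each
#'   frame's pixel-noise SD becomes
#'   `noise_sd_px + noise_gain_per_deg * max(|angles|)`, emulating landmark
#'   localization degrading toward extreme head postures.
#' @param occlusion_rate fraction of landmarks hidden per frame, in [0, 1].
#' @param drop_rate fraction of frames dropped entirely (no landmarks
#'   observed), in [0, 1].
#' @param camera a `camera_model`.
#' @param seed RNG seed for noise, occlusion and drops.
#' @export
sequence_spec <- function(poses, n_frames = NULL, noise_sd_px = 0,
                          noise_gain_per_deg = 0,
                          occlusion_rate = 0, drop_rate = 0,
                          camera = default_camera(), seed = 1) {
  if (inherits(poses, "head_pose")) {
    poses <- tibble::as_tibble(as.list(poses))
  }
  stopifnot(is.data.frame(poses))
  n_frames <- n_frames %||% nrow(poses)
  if (nrow(poses) == 1 && n_frames > 1) {
    poses <- poses[rep(1, n_frames), ]
  }
  stopifnot(n_frames >= 1, nrow(poses) == n_frames,
            occlusion_rate >= 0, occlusion_rate <= 1,
            drop_rate >= 0, drop_rate <= 1, noise_sd_px >= 0,
            noise_gain_per_deg >= 0)
  structure(list(poses = poses, n_frames = n_frames,
                 noise_sd_px = noise_sd_px,
                 noise_gain_per_deg = noise_gain_per_deg,
                 occlusion_rate = occlusion_rate,
                 drop_rate = drop_rate, camera = camera,
                 seed = as.integer(seed)),
            class = "sequence_spec")
}

#' Render an annotated synthetic landmark sequence
#'
#' Projects the subject at each trajectory pose, adds pixel noise, hides a
#' seeded random landmark subset, and drops a seeded random frame subset
#' (dropped frames have no visible landmarks). The ground-truth pose is
#' recorded for every frame, dropped or not.
#'
#' @param subject a `face_model` (see [make_subject()]).
#' @param spec a [sequence_spec()].
#' @return list of class `annotated_sequence` with elements `landmarks`
#'   (tibble `frame_id`, `landmark_index`, `u_px`, `v_px`, `visible`) and
#'   `truth` (tibble `frame_id`, pose columns, `dropped`).
#' @export
render_sequence <- function(subject, spec) {
  stopifnot(inherits(subject, "face_model"), inherits(spec, "sequence_spec"))
  n <- spec$n_frames
  withr::with_seed(spec$seed, {
    dropped <- runif(n) < spec$drop_rate
    lm_list <- vector("list", n)
    for (i in seq_len(n)) {
      pose <- as_head_pose(spec$poses[i, pose_fields])
      obs <- project(subject, pose, spec$camera)
      obs$frame_id <- i
      sd_i <- spec$noise_sd_px + spec$noise_gain_per_deg *
        max(abs(c(pose[["yaw_deg"]], pose[["pitch_deg"]], pose[["roll_deg"]])))
      if (sd_i > 0) {
        obs$u_px <- obs$u_px + rnorm(68, sd = sd_i)
        obs$v_px <- obs$v_px + rnorm(68, sd = sd_i)
      }
      if (spec$occlusion_rate > 0) {
        obs$visible <- runif(68) >= spec$occlusion_rate
      }
      if (dropped[i]) obs$visible <- FALSE
      obs$u_px[!obs$visible] <- NA_real_
      obs$v_px[!obs$visible] <- NA_real_
      lm_list[[i]] <- obs[, c("frame_id", "landmark_index", "u_px", "v_px", "visible")]
    }
    truth <- tibble::as_tibble(spec$poses[, pose_fields])
    truth <- dplyr::bind_cols(tibble::tibble(frame_id = seq_len(n)), truth)
    truth$dropped <- dropped
    structure(list(landmarks = dplyr::bind_rows(lm_list), truth = truth),
              class = "annotated_sequence")
  })
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat("<annotated_sequence>", nrow(x$truth), "frames,",
      sum(x$truth$dropped), "dropped\n")
  invisible(x)
}

#' The fixation-target head-posture protocol
#'
#' Enumerates the target postures of the clinical comparison protocol:
#' yaw and pitch targets at 5 degree increments from null out to +/-40
#' degrees in the pure horizontal and pure vertical meridians, and roll
#' targets from -40 to +40 degrees in 10 degree increments — one axis
#' varying per trial, the other two at zero. With defaults this yields
#' 17 + 17 + 9 = 43 distinct trials per subject.
#'
#' @param max_yaw_deg,yaw_step,max_pitch_deg,pitch_step,max_roll_deg,roll_step
#'   series extents and increments in degrees; each step must divide its
#'   extent.
#' @return tibble with columns `trial`, `axis` (`yaw`/`pitch`/`roll`),
#'   `target_deg`, and the full target pose columns `yaw_deg`, `pitch_deg`,
#'   `roll_deg`.
#' @export
#' @examples
#' nrow(crom_protocol_poses())   # 43
crom_protocol_poses <- function(max_yaw_deg = 40, yaw_step = 5,
                                max_pitch_deg = 40, pitch_step = 5,
                                max_roll_deg = 40, roll_step = 10) {
  chk <- function(extent, step, name) {
    if (step <= 0 || extent < 0 || (extent %% step) != 0) {
      stop(name, ": step must be positive and divide the extent")
    }
  }
  chk(max_yaw_deg, yaw_step, "yaw"); chk(max_pitch_deg, pitch_step, "pitch")
  chk(max_roll_deg, roll_step, "roll")
  series <- function(axis, extent, step) {
    vals <- seq(-extent, extent, by = step)
    out <- tibble::tibble(axis = axis, target_deg = vals,
                          yaw_deg = 0, pitch_deg = 0, roll_deg = 0)
    out[[paste0(axis, "_deg")]] <- vals
    out
  }
  out <- dplyr::bind_rows(
    series("yaw", max_yaw_deg, yaw_step),
    series("pitch", max_pitch_deg, pitch_step),
    series("roll", max_roll_deg, roll_step)
  )
  dplyr::bind_cols(tibble::tibble(trial = seq_len(nrow(out))), out)
}

#' Simulate the paired two-instrument protocol study
#'
#' For each subject x protocol trial, draws a true executed posture (the
#' target plus seeded Gaussian execution error on the trial's axis — the
#' protocol directs but does not force the posture) and then two
#' independent instrument readings of that executed posture, each with its
#' own Gaussian measurement noise.
#'
#' @param n_subjects number of subjects (4 reproduces the 172-row study
#'   layout).
#' @param pose_execution_sd_deg SD of the subject's execution error about
#'   the target, degrees.
#' @param instrument_noise_a_sd,instrument_noise_b_sd per-reading
#'   measurement noise SDs (degrees) for the two instruments (a =
#'   mechanical comparator, b = video tracker).
#' @param seed RNG seed.
#' @param protocol a protocol table from [crom_protocol_poses()].
#' @return tibble with columns `subject`, `axis`, `target_deg`,
#'   `instrument_a_deg`, `instrument_b_deg`.
#' @export
simulate_protocol_study <- function(n_subjects = 4, pose_execution_sd_deg = 3,
                                    instrument_noise_a_sd = 1,
                                    instrument_noise_b_sd = 1,
                                    seed = 1,
                                    protocol = crom_protocol_poses()) {
  stopifnot(n_subjects >= 1, pose_execution_sd_deg >= 0,
            instrument_noise_a_sd >= 0, instrument_noise_b_sd >= 0)
  n_trial <- nrow(protocol)
  withr::with_seed(as.integer(seed), {
    out <- tidyr::expand_grid(subject = seq_len(n_subjects),
                              protocol[, c("axis", "target_deg")])
    n <- nrow(out)
    executed <- out$target_deg + rnorm(n, sd = pose_execution_sd_deg)
    out$instrument_a_deg <- executed + rnorm(n, sd = instrument_noise_a_sd)
    out$instrument_b_deg <- executed + rnorm(n, sd = instrument_noise_b_sd)
    out
  })
}
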