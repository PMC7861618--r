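# End-to-end driver: calibrate, reconstruct every trial, segment reaches,
# compute kinematics, aggregate sessions, and fit the session-level mixed
# model. Operates on the directory layout written by write_experiment()
# (pose tables + manifest + calibration corners), which mirrors how real
# tracking exports are organized.

#' Run the full analysis pipeline on a data directory
#'
#' Reads the manifest, calibrates the camera pair from the correspondence
#' table (scale from the checkerboard square size), reconstructs every
#' trial's 3D trajectory, segments reaches, computes per-reach kinematics,
#' aggregates per-session measures, and (when at least two rats and two
#' sessions are present) fits a session-level mixed model of maximum reach
#' extent on laser x session. All outputs are written as CSV next to a run
#' log containing every threshold used.
#'
#' @param dir Data directory containing `manifest.yaml`.
#' @param out_dir Output directory (created; default `file.path(dir,
#'   "analysis")`).
#' @param config Named list of thresholds (see [default_config()]); partial
#'   lists are completed with defaults.
#' @return List with `kinematics` (per-reach table), `sessions`
#'   (per-session summary), `events`, `lmm` (an `lmm_fit` or NULL), `pair`,
#'   `log`.
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "analysis"),
                         config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  manifest_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    stop("[manifest] manifest.yaml not found in ", dir)
  }
  mf <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- calibration ----
  corr_path <- file.path(dir, mf$calibration)
  if (!file.exists(corr_path)) {
    stop("[calibration] correspondence file missing: ", corr_path)
  }
  corr <- read_correspondences(corr_path)
  # anchor scale on the first two corners of the first checkerboard row
  corr$adjacency <- matrix(c(1L, 2L), 1)
  K <- matrix(c(mf$intrinsics$focal_px, 0, mf$intrinsics$principal_point[1],
                0, mf$intrinsics$focal_px, mf$intrinsics$principal_point[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  pair <- calibrate_camera_pair(corr, K, square_size_mm = mf$square_size_mm)
  write_camera_pair(pair, file.path(out_dir, "campair.json"))

  # ---- per-trial reconstruction, segmentation, kinematics ----
  kin_rows <- list()
  ev_rows <- list()
  for (ses in mf$sessions) {
    for (f in ses$files) {
      fd <- file.path(dir, f$direct)
      fm <- file.path(dir, f$mirror)
      if (!file.exists(fd)) stop("[reconstruct] pose file missing: ", fd)
      if (!file.exists(fm)) stop("[reconstruct] pose file missing: ", fm)
      pose <- pose2d_series(read_pose_table(fd), read_pose_table(fm))
      traj <- reconstruct_trajectory(pose, pair, paw_side = ses$paw_side,
                                     conf_min = cfg$conf_min,
                                     threshold_px = cfg$reproj_threshold_px,
                                     max_gap = cfg$max_gap, tol_px = cfg$tol_px,
                                     trigger_frame = cfg$trigger_frame)
      ev <- detect_reaches(traj, slot_z = cfg$slot_z,
                           min_advance_mm = cfg$min_advance_mm,
                           min_duration_frames = cfg$min_duration_frames,
                           retract_eps_mm = cfg$retract_eps_mm,
                           end_smooth = cfg$end_smooth)
      meta <- data.frame(rat = ses$rat, group = ses$group, stage = ses$stage,
                         session = ses$session, trial = f$trial)
      if (nrow(ev)) {
        kin <- reach_kinematics(traj, ev)
        kin_rows[[length(kin_rows) + 1]] <- cbind(meta, kin)
        ev_rows[[length(ev_rows) + 1]] <- cbind(meta, ev)
      }
    }
  }
  kinematics <- if (length(kin_rows)) do.call(rbind, kin_rows) else NULL
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL

  # ---- session aggregation ----
  sessions <- NULL
  if (!is.null(kinematics)) {
    first <- kinematics[kinematics$is_first_reach, ]
    first$outcome <- NA_integer_
    first$paw_through_slot <- FALSE
    for (ses in mf$sessions) {
      sel <- first$rat == ses$rat & first$session == ses$session
      oc <- unlist(ses$outcomes)
      first$outcome[sel] <- oc[first$trial[sel]]
    }
    first$laser <- as.integer(first$stage == "laser_on")
    sessions <- summarize_sessions(first)
    utils::write.csv(sessions, file.path(out_dir, "sessions.csv"),
                     row.names = FALSE)
    utils::write.csv(kinematics, file.path(out_dir, "kinematics.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "reach_events.csv"),
                     row.names = FALSE)
  }

  # ---- session-level mixed model ----
  lmm <- NULL
  if (!is.null(sessions) &&
      length(unique(sessions$rat)) >= 2 &&
      length(unique(sessions$session)) >= 2 &&
      length(unique(sessions$laser)) >= 2) {
    lmm <- fit_lmm(sessions, lmm_spec("mean_extent_mm", ~ laser * session))
    utils::write.csv(lmm$coefficients,
                     file.path(out_dir, "lmm_extent.csv"), row.names = FALSE)
  }

  log <- c(sprintf("mirrorreach run %s", format(Sys.time(), "%Y-%m-%d")),
           sprintf("data dir: %s", dir),
           sprintf("manifest seed: %s", mf$seed %||% "NA"),
           sprintf("config: %s",
                   paste(sprintf("%s=%s", names(cfg), unlist(cfg)),
                         collapse = " ")),
           sprintf("calibration: %d pairs, median epipolar residual %.4g px, scale %.6g mm/unit",
                   pair$n_pairs, pair$median_residual_px, pair$s))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  list(kinematics = kinematics, sessions = sessions, events = events,
       lmm = lmm, pair = pair, log = log)
}
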