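# Multi-rat, multi-session synthetic experiments. A default experiment has
# five groups (channelrhodopsin or archaerhodopsin stimulation during or
# between reaches, plus an opsin-free control), six rats per group, and 22
# analyzed sessions per rat: the last two retraining sessions, ten
# laser-on sessions, and ten occlusion sessions. Outcome codes emerge
# mechanistically from the programmed kinematics via a grasp rule, so that
# drifting kinematic parameters produce declining success rates.

#' Experiment design
#'
#' @param groups Group labels, drawn from stim_during, stim_between,
#'   inhibit_during, inhibit_between, control.
#' @param rats_per_group Rats per group (default 6).
#' @param trials_per_session Trials per 30-min session (default 60).
#' @param n_retraining,n_laser,n_occlusion Sessions per stage entering the
#'   analysis (defaults 2 + 10 + 10 = 22).
#' @param schedules Optional named list (by group) of [effect_schedule()]s
#'   overriding the defaults.
#' @param grasp_window `c(lo, hi)`: max z_digit2 range (mm) within which a
#'   grasp can capture the pellet.
#' @param pellet_diameter_mm Minimum aperture at the pellet for a capture.
#' @param p_retry Probability a short first reach is followed by another
#'   attempt.
#' @param p_nontrial Probability of a non-reach administrative outcome
#'   (codes 0, 5, 6, 8, 9, 10).
#' @param p_paw_through_slot Probability a video begins with the paw
#'   already through the slot.
#' @param baseline_params A [reach_gen_params()] for unstimulated reaches.
#' @return An `experiment_design`.
#' @export
experiment_design <- function(groups = c("stim_during", "stim_between",
                                         "inhibit_during", "inhibit_between",
                                         "control"),
                              rats_per_group = 6,
                              trials_per_session = 60,
                              n_retraining = 2, n_laser = 10, n_occlusion = 10,
                              schedules = NULL,
                              grasp_window = c(0, 6),
                              pellet_diameter_mm = 3,
                              p_retry = 0.5,
                              p_nontrial = 0.03,
                              p_paw_through_slot = 0.01,
                              baseline_params = reach_gen_params()) {
  known <- c("stim_during", "stim_between", "inhibit_during",
             "inhibit_between", "control")
  bad <- setdiff(groups, known)
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  sched <- default_effect_schedules()
  for (g in names(schedules)) sched[[g]] <- schedules[[g]]
  structure(list(groups = groups, rats_per_group = rats_per_group,
                 trials_per_session = trials_per_session,
                 n_retraining = n_retraining, n_laser = n_laser,
                 n_occlusion = n_occlusion,
                 schedules = sched,
                 grasp_window = grasp_window,
                 pellet_diameter_mm = pellet_diameter_mm,
                 p_retry = p_retry, p_nontrial = p_nontrial,
                 p_paw_through_slot = p_paw_through_slot,
                 baseline_params = baseline_params),
            class = "experiment_design")
}

#' Default per-group effect schedules
#'
#' Stimulation during reaches progressively shortens reaches, opens the
#' aperture earlier (more negative logistic midpoint), and slows the paw;
#' inhibition during reaches progressively lengthens them. Between-reach
#' groups and controls have null schedules. Accumulated drifts return to
#' baseline at the first occlusion session.
#'
#' @return Named list of [effect_schedule()]s.
#' @export
default_effect_schedules <- function() {
  list(
    stim_during = effect_schedule(
      mode = "gradual",
      per_session_drift = c(extent_mean = -2, aperture_z_half = -0.5,
                            peak_speed = -25),
      revert_rate = 1),
    inhibit_during = effect_schedule(
      mode = "gradual",
      per_session_drift = c(extent_mean = 1, peak_speed = 10),
      revert_rate = 1),
    stim_between = effect_schedule(mode = "none"),
    inhibit_between = effect_schedule(mode = "none"),
    control = effect_schedule(mode = "none"))
}

# Stage label for session index i under a design.
session_stages <- function(design) {
  rep(c("retraining", "laser_on", "occlusion"),
      times = c(design$n_retraining, design$n_laser, design$n_occlusion))
}

# Accumulated drift vector for one session (gradual mode).
session_drift <- function(schedule, stage, laser_idx, occ_idx) {
  if (schedule$mode != "gradual" || !length(schedule$per_session_drift)) {
    return(numeric())
  }
  if (stage == "laser_on") {
    schedule$per_session_drift * laser_idx
  } else if (stage == "occlusion") {
    peak <- schedule$per_session_drift * 10   # drift reached by the last laser session
    peak * max(0, 1 - schedule$revert_rate)^occ_idx
  } else {
    numeric()
  }
}

# Outcome of one trial from its (first-reach) kinematics under the grasp
# rule. Returns list(outcome, n_attempts).
grasp_outcome <- function(maxz, ap0, window, diam, retry_maxz = NA,
                          retry_ap0 = NA) {
  if (!is.finite(maxz)) return(6L)
  if (maxz > window[2]) return(4L)                    # overshoot knocks it off
  if (maxz >= window[1]) {
    if (is.finite(ap0) && ap0 >= diam) return(1L)     # clean first-try grasp
    return(4L)                                        # contacted with closed paw
  }
  # short reach: pellet remains; a later attempt may capture it
  if (is.finite(retry_maxz)) {
    if (retry_maxz > window[2]) return(4L)
    if (retry_maxz >= window[1] && is.finite(retry_ap0) && retry_ap0 >= diam) {
      return(2L)
    }
  }
  7L
}

#' Generate a synthetic multi-rat experiment
#'
#' Draws per-trial reach kinematics for every rat, session, and trial under
#' the design's per-group effect schedules, assigns outcome codes by the
#' grasp rule, and (optionally) synthesizes full-frame ground-truth
#' trajectories and degraded two-view pose tables.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed; the experiment is fully reproducible from it.
#' @param detail "summary" draws per-trial kinematic endpoints directly
#'   from the programmed profiles (fast; for session/group statistics);
#'   "frames" additionally simulates full 1300-frame ground-truth
#'   trajectories; "pose" further projects and degrades them into 2D pose
#'   tables.
#' @param rig A `camera_rig` (needed for `detail = "pose"`).
#' @param noise_cfg Tracking-noise configuration for `detail = "pose"`.
#' @return A `synth_experiment`: list with `trials` (one row per trial:
#'   rat, group, paw_side, stage, session, trial, laser, outcome,
#'   paw_through_slot, max_extent_mm, end_aperture_mm, aperture_at_pellet,
#'   end_orientation_deg, max_velocity_mm_s), `sessions` (list of
#'   `synth_session` objects when detail != "summary"), `design`, `seed`,
#'   `detail`.
#' @export
generate_experiment <- function(design, seed = 1,
                                detail = c("summary", "frames", "pose"),
                                rig = NULL, noise_cfg = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  detail <- match.arg(detail)
  if (detail == "pose" && is.null(rig)) rig <- make_camera_rig()
  if (is.null(noise_cfg)) {
    noise_cfg <- list(px_sd = 0.5, p_missing = 0.02, p_mislabel = 0.002)
  }
  stages <- session_stages(design)
  trial_rows <- list()
  sessions <- list()
  rat_no <- 0
  for (g in design$groups) {
    schedule <- design$schedules[[g]]
    during <- grepl("_during$", g)
    for (r in seq_len(design$rats_per_group)) {
      rat_no <- rat_no + 1
      rat_id <- sprintf("%s_r%02d", g, r)
      paw_side <- if (r %% 4 == 0) "left" else "right"
      for (si in seq_along(stages)) {
        st <- stages[si]
        laser_idx <- if (st == "laser_on") si - design$n_retraining else 0
        occ_idx <- if (st == "occlusion") {
          si - design$n_retraining - design$n_laser
        } else 0
        drift <- session_drift(schedule, st, laser_idx, occ_idx)
        sseed <- child_seed(seed, rat_no, si)
        ses <- generate_session(design, schedule, st, drift, sseed,
                                laser_on_session = st == "laser_on",
                                during = during, detail = detail,
                                rig = rig, noise_cfg = noise_cfg)
        tt <- ses$trials
        tt <- data.frame(rat = rat_id, group = g, paw_side = paw_side,
                         stage = st, session = si, tt)
        trial_rows[[length(trial_rows) + 1]] <- tt
        if (detail != "summary") {
          ses$manifest <- list(rat = rat_id, group = g, paw_side = paw_side,
                               stage = st, session = si, seed = sseed)
          sessions[[length(sessions) + 1]] <- ses
        }
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 sessions = if (detail == "summary") NULL else sessions,
                 design = design, seed = seed, detail = detail),
            class = "synth_experiment")
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment: %d groups x %d rats, %d trials total (%s detail)\n",
              length(x$design$groups), x$design$rats_per_group,
              nrow(x$trials), x$detail))
  invisible(x)
}

# One session's trials. Gradual mode: `drift` is the accumulated additive
# drift for this session (applied when the group is stimulated during
# reaches, on stimulated sessions only -- drift is empty otherwise).
# Abrupt mode: the laser alternates off/on every block_length trials and
# `abrupt_effect` applies only while it is on.
generate_session <- function(design, schedule, stage, drift, seed,
                             laser_on_session, during, detail = "summary",
                             rig = NULL, noise_cfg = NULL) {
  nt <- design$trials_per_session
  base <- design$baseline_params
  abrupt <- schedule$mode == "abrupt_blocks" && stage == "alternating"
  with_seed(seed, {
    if (abrupt) {
      block <- schedule$block_length
      laser <- (((seq_len(nt) - 1) %/% block) %% 2) == 1
    } else {
      laser <- rep(laser_on_session, nt)
    }
    # per-trial effective parameters (drift applied where stimulated)
    param_for_trial <- function(tr) {
      p <- base
      if (!abrupt && length(drift) && during) {
        p <- apply_drift(p, drift)
        if (laser_on_session && length(schedule$per_trial_drift)) {
          p <- apply_drift(p, schedule$per_trial_drift * tr)
        }
      } else if (abrupt && during && laser[tr] &&
                 length(schedule$abrupt_effect)) {
        p <- apply_drift(p, schedule$abrupt_effect)
      }
      p
    }
    if (detail == "summary") {
      # vectorized draw of per-trial kinematic endpoints
      pl <- lapply(seq_len(nt), param_for_trial)
      emean <- vapply(pl, function(p) p$extent_mean, 0)
      esd <- vapply(pl, function(p) p$extent_sd, 0)
      apm <- t(vapply(pl, function(p) p$aperture_profile, numeric(4)))
      thm <- t(vapply(pl, function(p) p$orientation_profile, numeric(4)))
      spd <- vapply(pl, function(p) p$peak_speed, 0)
      apz <- function(z) logistic_profile(z, apm[, 1], apm[, 2], apm[, 3], apm[, 4])
      thz <- function(z) logistic_profile(z, thm[, 1], thm[, 2], thm[, 3], thm[, 4])
      maxz <- stats::rnorm(nt, emean, esd)
      ap0 <- ifelse(maxz >= 0, apz(0), NA_real_)
      retry <- maxz < design$grasp_window[1] & stats::runif(nt) < design$p_retry
      rz <- ifelse(retry, stats::rnorm(nt, emean + 1.5, esd), NA_real_)
      ra <- ifelse(retry & is.finite(rz) & rz >= 0, apz(0), NA_real_)
      out <- mapply(grasp_outcome, maxz, ap0, retry_maxz = rz, retry_ap0 = ra,
                    MoreArgs = list(window = design$grasp_window,
                                    diam = design$pellet_diameter_mm))
      nontrial <- stats::runif(nt) < design$p_nontrial
      if (any(nontrial)) {
        out[nontrial] <- sample(c(0L, 5L, 6L, 8L, 9L, 10L),
                                sum(nontrial), replace = TRUE)
      }
      trials <- data.frame(trial = seq_len(nt), laser = as.integer(laser),
                           outcome = as.integer(out),
                           paw_through_slot =
                             stats::runif(nt) < design$p_paw_through_slot,
                           max_extent_mm = maxz,
                           end_aperture_mm = apz(maxz),
                           aperture_at_pellet = ap0,
                           end_orientation_deg = thz(maxz),
                           max_velocity_mm_s = stats::rnorm(nt, spd, 12))
      laser_epochs <- session_laser_epochs(laser, during)
      return(structure(list(trials = trials, ground_truth = NULL,
                            poses = NULL, laser_epochs = laser_epochs,
                            stage = stage),
                       class = "synth_session"))
    }
    rows <- vector("list", nt)
    gts <- vector("list", nt)
    poses <- if (detail == "pose") vector("list", nt) else NULL
    for (tr in seq_len(nt)) {
      p <- param_for_trial(tr)
      nontrial <- stats::runif(1) < design$p_nontrial
      pts <- stats::runif(1) < design$p_paw_through_slot
      {
        retry <- stats::runif(1) < design$p_retry
        gt <- simulate_reach(p, seed = NULL,
                             extra_reaches = as.integer(retry))
        apf <- function(z) logistic_profile(z, p$aperture_profile[1],
                                            p$aperture_profile[2],
                                            p$aperture_profile[3],
                                            p$aperture_profile[4])
        thf <- function(z) logistic_profile(z, p$orientation_profile[1],
                                            p$orientation_profile[2],
                                            p$orientation_profile[3],
                                            p$orientation_profile[4])
        maxz <- gt$max_extent
        ap0 <- if (is.finite(maxz) && maxz >= 0) apf(0) else NA_real_
        w2 <- if (length(gt$reach_windows) > 1) gt$reach_windows[[2]] else NULL
        rz <- if (!is.null(w2)) gt$parts$digit2[w2["endpoint_frame"] + 1, 3] else NA
        ra <- if (is.finite(rz) && rz >= 0) apf(0) else NA
        out <- grasp_outcome(maxz, ap0, design$grasp_window,
                             design$pellet_diameter_mm, rz, ra)
        rows[[tr]] <- data.frame(trial = tr, laser = as.integer(laser[tr]),
                                 outcome = out, paw_through_slot = pts,
                                 max_extent_mm = maxz,
                                 end_aperture_mm = apf(maxz),
                                 aperture_at_pellet = ap0,
                                 end_orientation_deg = thf(maxz),
                                 max_velocity_mm_s = NA_real_)
        gts[[tr]] <- gt
        if (detail == "pose") {
          poses[[tr]] <- project_and_degrade(gt, rig, noise_cfg, seed = NULL)
        }
      }
      if (nontrial) {
        rows[[tr]]$outcome <- sample(c(0L, 5L, 6L, 8L, 9L, 10L), 1)
      }
    }
    trials <- do.call(rbind, rows)
    structure(list(trials = trials, ground_truth = gts, poses = poses,
                   laser_epochs = session_laser_epochs(laser, during),
                   stage = stage),
              class = "synth_session")
  })
}

# Per-trial laser epochs in absolute video frames (0-based; the video spans
# frames 0-1299 with the trigger at 300). During-reach light runs from the
# beam break to 3 s after the trigger; between-reach light starts 4 s after
# the trigger and lasts 5 s (outside the recorded video).
session_laser_epochs <- function(laser, during) {
  if (!any(laser)) return(list())
  if (during) {
    lapply(which(laser), function(tr) c(trial = tr, start = 0L, end = 1200L))
  } else {
    lapply(which(laser), function(tr) c(trial = tr, start = 1500L, end = 3000L))
  }
}

#' Generate one alternating-block (5-off/5-on) session set
#'
#' Emulates the final test in which the laser alternated every
#' `block_length` trials between off and on during reaches: one session per
#' rat, immediate additive kinematic effect while the laser is on, no
#' accumulation across trials.
#'
#' @param n_rats Number of rats.
#' @param trials_per_session Trials per session.
#' @param block_length Trials per laser block (default 5).
#' @param abrupt_effect Named additive effect while the laser is on
#'   (default extent_mean -4 mm).
#' @param baseline_params A [reach_gen_params()].
#' @param seed Integer seed.
#' @return Trial-level data frame with columns rat, trial, block,
#'   trial_in_block, laser, max_extent_mm, outcome.
#' @export
generate_alternating_sessions <- function(n_rats = 6, trials_per_session = 60,
                                          block_length = 5,
                                          abrupt_effect = c(extent_mean = -4),
                                          baseline_params = reach_gen_params(),
                                          seed = 1) {
  schedule <- effect_schedule(mode = "abrupt_blocks",
                              block_length = block_length,
                              abrupt_effect = abrupt_effect)
  design <- experiment_design(groups = "stim_during", rats_per_group = 1,
                              trials_per_session = trials_per_session)
  rows <- lapply(seq_len(n_rats), function(r) {
    ses <- generate_session(design, schedule, stage = "alternating",
                            drift = numeric(), seed = child_seed(seed, r),
                            laser_on_session = FALSE, during = TRUE)
    tt <- ses$trials
    # per-rat random intercept on reach extent
    tt$max_extent_mm <- tt$max_extent_mm +
      with_seed(child_seed(seed, r, 999), stats::rnorm(1, 0, 1))
    data.frame(rat = sprintf("r%02d", r),
               trial = tt$trial,
               block = (tt$trial - 1) %/% block_length + 1,
               trial_in_block = (tt$trial - 1) %% block_length + 1,
               laser = tt$laser,
               max_extent_mm = tt$max_extent_mm,
               outcome = tt$outcome)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
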