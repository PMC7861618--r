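# Forward model of a single reach-to-grasp movement and its degradation into
# markerless-tracking output. All ground truth is expressed in the pellet
# frame: origin at the pellet, +z paw advancement past the pellet (mm), +y
# downward, +x lateral. One trial's video is 1300 frames at 300 frames/s
# (300 pre-trigger, 1000 post-trigger).

#' Reach-generation parameters
#'
#' Parameterizes the sub-movement sequence of a rat reach: the paw advances
#' through the slot along a minimum-jerk path while the digits extend and
#' spread (aperture) and the paw pronates (orientation), both following
#' logistic profiles in the advancement coordinate z.
#'
#' @param extent_mean,extent_sd Mean and sd of the endpoint z of the second
#'   digit tip (mm; positive = past the pellet).
#' @param aperture_profile `c(a_min, a_max, z_half, slope)` of the logistic
#'   aperture-vs-z profile (mm, mm, mm, 1/mm).
#' @param orientation_profile `c(theta_start, theta_end, z_half, slope)` of
#'   the logistic orientation-vs-z profile (degrees; smaller = more
#'   pronated).
#' @param peak_speed Peak paw-dorsum speed during the advance (mm/s).
#' @param start_position 3D pellet-frame start of the digit-cluster centre
#'   (mm); z must be behind the slot.
#' @param n_frames Frames allotted to one reach (advance + retraction) at
#'   300 frames/s.
#' @return An object of class `reach_gen_params`.
#' @export
reach_gen_params <- function(extent_mean = 4,
                             extent_sd = 1.5,
                             aperture_profile = c(5, 14, -7, 2),
                             orientation_profile = c(90, 35, -8, 1.2),
                             peak_speed = 350,
                             start_position = c(2, 5, -28),
                             n_frames = 150) {
  stopifnot(length(aperture_profile) == 4, length(orientation_profile) == 4,
            length(start_position) == 3)
  if (aperture_profile[1] > aperture_profile[2]) {
    stop("aperture_profile: a_min must be <= a_max")
  }
  if (n_frames < 5) stop("n_frames must be >= 5")
  if (extent_sd < 0) stop("extent_sd must be >= 0")
  if (peak_speed <= 0) stop("peak_speed must be positive")
  structure(list(extent_mean = extent_mean, extent_sd = extent_sd,
                 aperture_profile = as.numeric(aperture_profile),
                 orientation_profile = as.numeric(orientation_profile),
                 peak_speed = peak_speed,
                 start_position = as.numeric(start_position),
                 n_frames = as.integer(n_frames)),
            class = "reach_gen_params")
}

#' Effect schedule for optogenetic manipulation
#'
#' Describes how programmed kinematic parameters drift under laser
#' stimulation. `gradual` mode accumulates additive drifts across stimulated
#' sessions (and optionally trials), emulating progressive kinematic change;
#' `abrupt_blocks` alternates the laser off/on every `block_length` trials
#' within a session with an immediate additive effect.
#'
#' @param mode One of "none", "gradual", "abrupt_blocks".
#' @param per_session_drift Named numeric: additive change per stimulated
#'   session for any of `extent_mean`, `aperture_z_half`,
#'   `orientation_z_half`, `peak_speed`.
#' @param per_trial_drift Same names, applied per stimulated trial.
#' @param block_length Trials per laser block (abrupt mode).
#' @param abrupt_effect Named numeric, additive while the laser is on
#'   (abrupt mode).
#' @param revert_rate Fraction of the accumulated gradual drift removed at
#'   each occlusion session (1 = full return to baseline at the first
#'   occlusion session).
#' @return An object of class `effect_schedule`.
#' @export
effect_schedule <- function(mode = c("none", "gradual", "abrupt_blocks"),
                            per_session_drift = numeric(),
                            per_trial_drift = numeric(),
                            block_length = 5L,
                            abrupt_effect = numeric(),
                            revert_rate = 1) {
  mode <- match.arg(mode)
  drift_names <- c("extent_mean", "aperture_z_half", "orientation_z_half",
                   "peak_speed")
  chk <- function(v, what) {
    if (length(v) && (is.null(names(v)) || !all(names(v) %in% drift_names))) {
      stop(what, " must be named with a subset of: ",
           paste(drift_names, collapse = ", "))
    }
    if (length(v) && any(!is.finite(v))) stop(what, " must be finite")
    v
  }
  structure(list(mode = mode,
                 per_session_drift = chk(per_session_drift, "per_session_drift"),
                 per_trial_drift = chk(per_trial_drift, "per_trial_drift"),
                 block_length = as.integer(block_length),
                 abrupt_effect = chk(abrupt_effect, "abrupt_effect"),
                 revert_rate = revert_rate),
            class = "effect_schedule")
}

# Apply an accumulated drift (named numeric) to reach parameters.
apply_drift <- function(params, drift) {
  if (!length(drift)) return(params)
  p <- params
  if ("extent_mean" %in% names(drift)) {
    p$extent_mean <- p$extent_mean + unname(drift["extent_mean"])
  }
  if ("aperture_z_half" %in% names(drift)) {
    p$aperture_profile[3] <- p$aperture_profile[3] + unname(drift["aperture_z_half"])
  }
  if ("orientation_z_half" %in% names(drift)) {
    p$orientation_profile[3] <- p$orientation_profile[3] + unname(drift["orientation_z_half"])
  }
  if ("peak_speed" %in% names(drift)) {
    p$peak_speed <- max(50, p$peak_speed + unname(drift["peak_speed"]))
  }
  p
}

# Fixed geometry of the synthetic paw: digit tips share the advancement z
# of the digit-cluster centre and sit on the digit1->digit4 line; the dorsum
# trails the digits.
.digit_offsets <- c(digit1 = -0.5, digit2 = -1/6, digit3 = 1/6, digit4 = 0.5)
.dorsum_offset <- c(0, 3, -8)    # pellet frame: 3 mm above (y is down), 8 mm behind
.nose_position <- c(0, -6, -17)

#' Simulate one ground-truth reach
#'
#' Generates pellet-frame 3D trajectories for the seven tracked body parts
#' over one trial video (default 1300 frames): the paw is held behind the
#' slot for the pre-trigger frames, advances along a minimum-jerk path to a
#' randomly drawn endpoint, then retracts. Digit tips are placed around the
#' cluster centre so that aperture(z) and orientation(z) follow the logistic
#' profiles in `params`.
#'
#' @param params A [reach_gen_params()] object (after any effect drift).
#' @param seed Optional integer seed; identical seeds give identical
#'   trajectories.
#' @param n_pre Pre-trigger frames (paw stationary behind the slot).
#' @param n_total Total frames in the trial video.
#' @param extra_reaches Number of additional reach attempts appended after
#'   full retraction (each with a freshly drawn endpoint).
#' @param fps Frame rate (frames/s).
#' @return An object of class `gt_reach`: list with `parts` (named list of
#'   n_total x 3 pellet-frame matrices), `endpoint_frame` (0-based frame of
#'   maximum digit2 advancement of the first reach), `max_extent` (mm),
#'   `reach_windows` (per-reach 0-based start/endpoint/stop frames),
#'   `params`, `fps`.
#' @export
simulate_reach <- function(params, seed = NULL, n_pre = 300, n_total = 1300,
                           extra_reaches = 0, fps = 300) {
  stopifnot(inherits(params, "reach_gen_params"))
  with_seed(seed, {
    n_reach <- params$n_frames
    start <- params$start_position
    centre <- matrix(rep(start, each = n_total), n_total, 3)
    windows <- list()
    cursor <- n_pre                     # 0-based frame at which motion begins
    n_attempts <- 1 + extra_reaches
    endpoint_frame <- NA_integer_
    max_extent <- NA_real_
    for (a in seq_len(n_attempts)) {
      if (cursor + 5 >= n_total) break
      z_end <- stats::rnorm(1, params$extent_mean, params$extent_sd)
      target <- c(0, 0, z_end)
      D <- vnorm(target - start)
      # advance duration set so the minimum-jerk peak speed matches peak_speed
      t_adv <- max(5, min(round(1.875 * D / params$peak_speed * fps),
                          n_reach - 3))
      t_ret <- max(4, min(n_reach - t_adv, t_adv + 10))
      n_seg <- t_adv + t_ret
      if (cursor + n_seg > n_total) n_seg <- n_total - cursor
      tau_a <- min_jerk(seq_len(min(t_adv, n_seg)) / t_adv)
      path_a <- outer(tau_a, target - start) +
        matrix(rep(start, each = length(tau_a)), ncol = 3)
      seg <- path_a
      if (n_seg > t_adv) {
        tau_r <- min_jerk(seq_len(n_seg - t_adv) / t_ret)
        path_r <- outer(tau_r, start - target) +
          matrix(rep(target, each = length(tau_r)), ncol = 3)
        seg <- rbind(path_a, path_r)
      }
      rows <- cursor + seq_len(nrow(seg))      # 1-based row indices
      centre[rows, ] <- seg
      if (max(rows) < n_total) {
        centre[(max(rows) + 1):n_total, ] <-
          matrix(rep(start, each = n_total - max(rows)), ncol = 3)
      }
      ep <- cursor + min(t_adv, nrow(seg)) - 1  # 0-based endpoint frame
      windows[[a]] <- c(start_frame = cursor, endpoint_frame = ep,
                        stop_frame = cursor + nrow(seg))
      if (a == 1) {
        endpoint_frame <- ep
        max_extent <- centre[ep + 1, 3]
      }
      # pause behind the slot before any further attempt
      cursor <- cursor + nrow(seg) + sample(15:40, 1)
    }
    z <- centre[, 3]
    ap <- logistic_profile(z, params$aperture_profile[1],
                           params$aperture_profile[2],
                           params$aperture_profile[3],
                           params$aperture_profile[4])
    th <- logistic_profile(z, params$orientation_profile[1],
                           params$orientation_profile[2],
                           params$orientation_profile[3],
                           params$orientation_profile[4]) * pi / 180
    dvec <- cbind(cos(th), -sin(th), 0)        # digit1 -> digit4 direction
    parts <- list()
    for (nm in names(.digit_offsets)) {
      parts[[nm]] <- centre + .digit_offsets[[nm]] * ap * dvec
    }
    parts$pawdorsum <- sweep(centre, 2, .dorsum_offset, "+")
    parts$nose <- matrix(rep(.nose_position, each = n_total), n_total, 3)
    parts$pellet <- matrix(0, n_total, 3)
    structure(list(parts = parts,
                   endpoint_frame = endpoint_frame,
                   max_extent = max_extent,
                   reach_windows = windows,
                   params = params, fps = fps, n_pre = n_pre),
              class = "gt_reach")
  })
}

#' Ground-truth reach as a trajectory table
#'
#' Converts a `gt_reach` into the pellet-frame trajectory table the
#' analysis stages consume, bypassing projection and reconstruction (all
#' points flagged as triangulated with zero reprojection error).
#'
#' @param reach A `gt_reach`.
#' @return A `trajectory3d` data frame.
#' @export
gt_as_trajectory <- function(reach) {
  stopifnot(inherits(reach, "gt_reach"))
  n <- nrow(reach$parts[[1]])
  out <- do.call(rbind, lapply(names(reach$parts), function(bp) {
    data.frame(frame = 0:(n - 1), bodypart = bp,
               x = reach$parts[[bp]][, 1],
               y = reach$parts[[bp]][, 2],
               z = reach$parts[[bp]][, 3],
               reproj_err_px = 0, provenance = "triangulated")
  }))
  rownames(out) <- NULL
  class(out) <- c("trajectory3d", "data.frame")
  attr(out, "paw_side") <- "right"
  attr(out, "frame_rate") <- reach$fps %||% 300
  out
}

#' @export
print.gt_reach <- function(x, ...) {
  cat(sprintf("Synthetic reach: %d frames, %d attempt(s), max extent %.2f mm (frame %d)\n",
              nrow(x$parts$digit2), length(x$reach_windows),
              x$max_extent, x$endpoint_frame))
  invisible(x)
}

#' Project a ground-truth reach into tracked 2D output and degrade it
#'
#' Projects every body part into the direct and mirror views, then applies
#' a tracking-noise model: isotropic pixel noise, missing labels (low
#' confidence), and occasional digit-identity swaps confined to one view and
#' one frame (so that downstream reprojection filtering is exercised).
#' Points falling outside the sensor are marked missing.
#'
#' @param reach A `gt_reach`.
#' @param rig A `camera_rig`.
#' @param noise_cfg List with `px_sd` (pixel noise sd), `p_missing`
#'   (per-label missing probability), `p_mislabel` (per-frame digit-swap
#'   probability).
#' @param seed Optional integer seed.
#' @return A `pose2d_series`: list of two data frames (`direct`, `mirror`)
#'   with columns frame (0-based), bodypart, u, v, confidence; plus
#'   `mislabel_log` recording injected swaps (frame, view, parts).
#' @export
project_and_degrade <- function(reach, rig,
                                noise_cfg = list(px_sd = 0.5, p_missing = 0.02,
                                                 p_mislabel = 0.002),
                                seed = NULL) {
  stopifnot(inherits(reach, "gt_reach"), inherits(rig, "camera_rig"))
  px_sd <- noise_cfg$px_sd %||% 0
  p_missing <- noise_cfg$p_missing %||% 0
  p_mislabel <- noise_cfg$p_mislabel %||% 0
  n <- nrow(reach$parts[[1]])
  parts <- names(reach$parts)
  with_seed(seed, {
    views <- list()
    for (vw in c("direct", "mirror")) views[[vw]] <- vector("list", length(parts))
    for (j in seq_along(parts)) {
      Xcam <- pellet_to_camera(reach$parts[[j]], rig)
      uv <- project_to_views(Xcam, rig)
      for (vw in c("direct", "mirror")) {
        m <- uv[[vw]]
        if (px_sd > 0) m <- m + matrix(stats::rnorm(2 * n, 0, px_sd), n, 2)
        views[[vw]][[j]] <- m
      }
    }
    mislabel_log <- list()
    digit_idx <- match(c("digit1", "digit2", "digit3", "digit4"), parts)
    if (p_mislabel > 0) {
      swap_frames <- which(stats::runif(n) < p_mislabel)
      for (f in swap_frames) {
        vw <- sample(c("direct", "mirror"), 1)
        pair <- sort(sample(digit_idx, 2))
        tmp <- views[[vw]][[pair[1]]][f, ]
        views[[vw]][[pair[1]]][f, ] <- views[[vw]][[pair[2]]][f, ]
        views[[vw]][[pair[2]]][f, ] <- tmp
        mislabel_log[[length(mislabel_log) + 1]] <-
          list(frame = f - 1L, view = vw, parts = parts[pair])
      }
    }
    out <- list()
    for (vw in c("direct", "mirror")) {
      dfs <- vector("list", length(parts))
      for (j in seq_along(parts)) {
        m <- views[[vw]][[j]]
        conf <- stats::runif(n, 0.95, 1)
        miss <- stats::runif(n) < p_missing
        oob <- !is.finite(m[, 1]) | m[, 1] < 0 | m[, 1] > rig$image_size[1] |
          m[, 2] < 0 | m[, 2] > rig$image_size[2]
        miss <- miss | oob
        conf[miss] <- stats::runif(sum(miss), 0, 0.2)
        dfs[[j]] <- data.frame(frame = 0:(n - 1), bodypart = parts[j],
                               u = m[, 1], v = m[, 2], confidence = conf)
      }
      out[[vw]] <- do.call(rbind, dfs)
      rownames(out[[vw]]) <- NULL
    }
    structure(list(direct = out$direct, mirror = out$mirror,
                   mislabel_log = mislabel_log, n_frames = n),
              class = "pose2d_series")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a checkerboard-cube calibration correspondence set
#'
#' Emulates calibration images of a cube carrying checkerboards (default
#' 4 x 4 mm squares) on its faces: 3D corner positions on three mutually
#' orthogonal faces, their projections into the direct and mirror views, and
#' the face-grid adjacency pairs whose true spacing equals the square size.
#'
#' @param rig A `camera_rig`.
#' @param square_size_mm Checkerboard square edge (mm).
#' @param n_squares Squares per face edge (corners per edge = n_squares + 1).
#' @param center 3D cube centre in camera coordinates (mm).
#' @param px_sd Optional pixel noise added to the projected corners.
#' @param seed Optional integer seed (used only when `px_sd > 0`).
#' @return A `correspondence_set`: data frame `points` (pair_id, u_direct,
#'   v_direct, u_mirror, v_mirror), matrix `X_true` (ground-truth 3D, mm),
#'   integer matrix `adjacency` (pairs of point indices with true spacing
#'   `square_size_mm`), and `square_size_mm`.
#' @export
generate_calibration_set <- function(rig, square_size_mm = 4, n_squares = 4,
                                     center = c(20, 10, 300), px_sd = 0,
                                     seed = NULL) {
  if (square_size_mm <= 0) stop("square_size_mm must be positive")
  g <- seq(0, n_squares) * square_size_mm
  half <- n_squares * square_size_mm / 2
  corners <- list()
  adj <- list()
  idx0 <- 0
  add_face <- function(origin, e1, e2) {
    pts <- matrix(NA_real_, (n_squares + 1)^2, 3)
    k <- 0
    for (i in seq_along(g)) for (j in seq_along(g)) {
      k <- k + 1
      pts[k, ] <- origin + g[i] * e1 + g[j] * e2
    }
    corners[[length(corners) + 1]] <<- pts
    nn <- n_squares + 1
    for (i in seq_len(nn)) for (j in seq_len(nn)) {
      k <- (i - 1) * nn + j
      if (j < nn) adj[[length(adj) + 1]] <<- idx0 + c(k, k + 1)
      if (i < nn) adj[[length(adj) + 1]] <<- idx0 + c(k, k + nn)
    }
    idx0 <<- idx0 + nn^2
  }
  c0 <- center
  # three faces of the cube meeting at corner (-half, -half, -half)
  add_face(c0 + c(-half, -half, -half), c(0, 1, 0), c(0, 0, 1))  # x = const
  add_face(c0 + c(-half, -half, -half), c(1, 0, 0), c(0, 0, 1))  # y = const
  add_face(c0 + c(-half, -half, -half), c(1, 0, 0), c(0, 1, 0))  # z = const
  X <- do.call(rbind, corners)
  uv <- project_to_views(X, rig)
  if (px_sd > 0) {
    uv <- with_seed(seed, {
      lapply(uv, function(m) m + matrix(stats::rnorm(length(m), 0, px_sd),
                                        nrow(m), 2))
    })
  }
  ok <- is.finite(uv$direct[, 1]) & is.finite(uv$mirror[, 1]) &
    uv$direct[, 1] >= 0 & uv$direct[, 1] <= rig$image_size[1] &
    uv$direct[, 2] >= 0 & uv$direct[, 2] <= rig$image_size[2] &
    uv$mirror[, 1] >= 0 & uv$mirror[, 1] <= rig$image_size[1] &
    uv$mirror[, 2] >= 0 & uv$mirror[, 2] <= rig$image_size[2]
  if (sum(ok) < 20) stop("fewer than 20 calibration corners visible in both views")
  keep <- which(ok)
  remap <- match(seq_len(nrow(X)), keep)
  adj <- do.call(rbind, adj)
  adj <- cbind(remap[adj[, 1]], remap[adj[, 2]])
  adj <- adj[stats::complete.cases(adj), , drop = FALSE]
  correspondence_set(
    points = data.frame(pair_id = seq_along(keep),
                        u_direct = uv$direct[keep, 1],
                        v_direct = uv$direct[keep, 2],
                        u_mirror = uv$mirror[keep, 1],
                        v_mirror = uv$mirror[keep, 2]),
    X_true = X[keep, , drop = FALSE],
    adjacency = adj,
    square_size_mm = square_size_mm)
}

#' Construct a correspondence set
#'
#' @param points Data frame with columns pair_id, u_direct, v_direct,
#'   u_mirror, v_mirror (pixels).
#' @param X_true Optional n x 3 ground-truth 3D positions (mm).
#' @param adjacency Optional m x 2 matrix of point-index pairs with known
#'   physical spacing (used to fix metric scale).
#' @param square_size_mm Physical spacing of adjacent pairs (mm).
#' @return A `correspondence_set`.
#' @export
correspondence_set <- function(points, X_true = NULL, adjacency = NULL,
                               square_size_mm = NA_real_) {
  req <- c("pair_id", "u_direct", "v_direct", "u_mirror", "v_mirror")
  if (!all(req %in% names(points))) {
    stop("points must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(points) < 8) stop("need at least 8 correspondences")
  if (any(!is.finite(as.matrix(points[, req[-1]])))) {
    stop("correspondences must be finite")
  }
  structure(list(points = points, X_true = X_true, adjacency = adjacency,
                 square_size_mm = square_size_mm),
            class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat(sprintf("Correspondence set: %d point pairs, %d adjacency pairs%s\n",
              nrow(x$points),
              if (is.null(x$adjacency)) 0 else nrow(x$adjacency),
              if (is.null(x$X_true)) "" else ", with 3D ground truth"))
  invisible(x)
}
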