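# Triangulation of matched 2D labels into 3D trajectories, reprojection
# quality control, temporal gap filling, and transformation into the
# pellet-centred analysis frame.

#' Triangulate a two-view pose series into 3D
#'
#' Body parts labelled with confidence >= `conf_min` in both views are
#' triangulated with the linear midpoint method under the calibrated camera
#' pair; the reprojection error of each point is the mean over the two views
#' of the pixel distance between the observed and reprojected labels. Parts
#' confident in at most one view are flagged missing.
#'
#' @param pose A `pose2d_series` (see [project_and_degrade()] or
#'   [read_pose_table()]).
#' @param pair A calibrated `camera_pair`.
#' @param conf_min Confidence threshold in \[0, 1\] (default 0.9).
#' @return A data frame (class `frames3d`) with columns `frame` (0-based),
#'   `bodypart`, `x`, `y`, `z` (mm, direct-camera frame),
#'   `reproj_err_px`, `provenance` (one of "triangulated", "estimated",
#'   "missing").
#' @export
triangulate_series <- function(pose, pair, conf_min = 0.9) {
  stopifnot(inherits(pair, "camera_pair"))
  if (conf_min < 0 || conf_min > 1) stop("conf_min must be in [0, 1]")
  d <- pose$direct
  m <- pose$mirror
  key_d <- paste(d$frame, d$bodypart)
  key_m <- paste(m$frame, m$bodypart)
  m <- m[match(key_d, key_m), ]
  ok <- is.finite(d$u) & is.finite(d$v) & is.finite(m$u) & is.finite(m$v) &
    d$confidence >= conf_min & m$confidence >= conf_min
  n <- nrow(d)
  out <- data.frame(frame = d$frame, bodypart = d$bodypart,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    reproj_err_px = NA_real_,
                    provenance = "missing",
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    x1 <- cbind(d$u[ok], d$v[ok])
    x2raw <- cbind(m$u[ok], m$v[ok])
    x2 <- if (pair$mirror_flip) flip_mirror_u(x2raw) else x2raw
    y1 <- to_normalized(x1, solve(pair$K))
    y2 <- to_normalized(x2, solve(pair$K_mirror))
    X <- triangulate_midpoint(y1, y2, pair$R, pair$t)
    err <- reprojection_error(X, x1, x2, pair)
    Xmm <- X * pair$s
    good <- is.finite(X[, 1])
    idx <- which(ok)
    out$x[idx] <- Xmm[, 1]
    out$y[idx] <- Xmm[, 2]
    out$z[idx] <- Xmm[, 3]
    out$reproj_err_px[idx] <- err
    out$provenance[idx][good] <- "triangulated"
  }
  class(out) <- c("frames3d", "data.frame")
  out
}

# Mean two-view reprojection error (px) for points X in reconstruction
# units (direct-camera frame, scale of unit baseline). x2 is in flipped
# mirror pixels when pair$mirror_flip.
reprojection_error <- function(X, x1, x2, pair) {
  p1 <- project_pinhole(X, pair$K)
  X2 <- X %*% t(pair$R)
  X2 <- sweep(X2, 2, pair$t, "+")
  p2 <- project_pinhole(X2, pair$K_mirror)
  e1 <- sqrt(rowSums((p1 - x1)^2))
  e2 <- sqrt(rowSums((p2 - x2)^2))
  (e1 + e2) / 2
}

#' Exclude 3D points with large reprojection errors
#'
#' Points whose reprojection error exceeds `threshold_px` (e.g. a body part
#' identified accurately in one view but misidentified in the other) are set
#' to missing.
#'
#' @param frames A `frames3d` data frame.
#' @param threshold_px Positive pixel threshold (default 3).
#' @return The filtered `frames3d`; attribute `n_removed` reports the count.
#' @export
filter_by_reprojection <- function(frames, threshold_px = 3) {
  if (threshold_px <= 0) stop("threshold_px must be positive")
  bad <- frames$provenance == "triangulated" &
    is.finite(frames$reproj_err_px) & frames$reproj_err_px > threshold_px
  frames$x[bad] <- NA_real_
  frames$y[bad] <- NA_real_
  frames$z[bad] <- NA_real_
  frames$provenance[bad] <- "missing"
  attr(frames, "n_removed") <- sum(bad)
  frames
}

#' Estimate short missing stretches from temporal context
#'
#' A body part missing in 3D for a gap of at most `max_gap` frames, but
#' labelled confidently in exactly one view there, is estimated by monotone
#' piecewise-cubic (pchip) interpolation of its 3D track over time. The
#' estimate is accepted only if its projection into the observed view lies
#' within `tol_px` of the observed label; accepted points get provenance
#' "estimated".
#'
#' @param frames A `frames3d` data frame (camera-frame mm).
#' @param pose The originating `pose2d_series` (for the single-view labels).
#' @param pair The calibrated `camera_pair`.
#' @param conf_min Confidence threshold for the observed single-view label.
#' @param max_gap Longest gap (frames) that may be bridged.
#' @param tol_px Acceptance tolerance on the single-view reprojection (px).
#' @return The augmented `frames3d`.
#' @export
estimate_missing_points <- function(frames, pose, pair, conf_min = 0.9,
                                    max_gap = 5, tol_px = 3) {
  d <- pose$direct
  m <- pose$mirror
  key <- paste(frames$frame, frames$bodypart)
  di <- match(key, paste(d$frame, d$bodypart))
  mi <- match(key, paste(m$frame, m$bodypart))
  for (bp in unique(frames$bodypart)) {
    rows <- which(frames$bodypart == bp)
    rows <- rows[order(frames$frame[rows])]
    valid <- frames$provenance[rows] != "missing"
    if (sum(valid) < 2) next
    miss <- which(!valid)
    if (!length(miss)) next
    runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
    vidx <- which(valid)
    for (run in runs) {
      if (length(run) > max_gap) next
      lo <- min(run) - 1; hi <- max(run) + 1
      if (lo < 1 || hi > length(rows)) next          # no flanking support
      if (!valid[lo] || !valid[hi]) next
      # local interpolation support: a few valid frames either side
      pre <- utils::tail(vidx[vidx <= lo], 4)
      post <- utils::head(vidx[vidx >= hi], 4)
      knots <- c(pre, post)
      vf <- frames$frame[rows[knots]]
      qf <- frames$frame[rows[run]]
      est <- cbind(
        pracma::pchip(vf, frames$x[rows[knots]], qf),
        pracma::pchip(vf, frames$y[rows[knots]], qf),
        pracma::pchip(vf, frames$z[rows[knots]], qf))
      for (k in seq_along(run)) {
        r <- rows[run[k]]
        cd <- d$confidence[di[r]]
        cm <- m$confidence[mi[r]]
        obs_d <- !is.na(cd) && cd >= conf_min && is.finite(d$u[di[r]])
        obs_m <- !is.na(cm) && cm >= conf_min && is.finite(m$u[mi[r]])
        if (obs_d == obs_m) next   # need exactly one observed view
        Xu <- matrix(est[k, ] / pair$s, 1)
        if (obs_d) {
          p <- project_pinhole(Xu, pair$K)
          dist <- vnorm(p - c(d$u[di[r]], d$v[di[r]]))
        } else {
          X2 <- Xu %*% t(pair$R) + matrix(pair$t, 1)
          p <- project_pinhole(X2, pair$K_mirror)
          if (pair$mirror_flip) p <- flip_mirror_u(p)
          dist <- vnorm(p - c(m$u[mi[r]], m$v[mi[r]]))
        }
        if (is.finite(dist) && dist <= tol_px) {
          frames$x[r] <- est[k, 1]
          frames$y[r] <- est[k, 2]
          frames$z[r] <- est[k, 3]
          frames$provenance[r] <- "estimated"
        }
      }
    }
  }
  frames
}

#' Express a 3D series in the pellet-centred analysis frame
#'
#' The origin is the robust (median) pellet position over the pre-reach
#' window; axes are built from the configured floor normal (+y, downward)
#' and chamber-to-camera axis (+z, paw advancement past the pellet),
#' orthonormalized; +x completes the right-handed triad. For left-pawed
#' sessions x is negated so left- and right-pawed reaches are directly
#' comparable.
#'
#' @param frames A `frames3d` data frame (camera-frame mm).
#' @param paw_side "right" or "left".
#' @param floor_normal Downward floor normal in camera coordinates.
#' @param camera_axis Chamber-to-camera direction in camera coordinates.
#' @param trigger_frame 0-based video trigger frame (default 300).
#' @param pellet_window Pre-trigger frames over which the pellet reference
#'   is taken (default 100).
#' @param min_pellet_frames Minimum valid pellet frames required.
#' @return A `trajectory3d` data frame (columns as `frames3d`, coordinates
#'   in pellet-frame mm) with attributes `paw_side`, `frame_rate`,
#'   `origin`, `rotation`.
#' @export
to_pellet_frame <- function(frames, paw_side = c("right", "left"),
                            floor_normal = c(0, 1, 0),
                            camera_axis = c(0, 0, -1),
                            trigger_frame = 300, pellet_window = 100,
                            min_pellet_frames = 10) {
  paw_side <- match.arg(paw_side)
  pre <- frames$bodypart == "pellet" &
    frames$frame >= trigger_frame - pellet_window &
    frames$frame < trigger_frame &
    frames$provenance != "missing"
  if (sum(pre) < min_pellet_frames) {
    stop("pellet not tracked in enough pre-reach frames (",
         sum(pre), " < ", min_pellet_frames, ")")
  }
  origin <- c(stats::median(frames$x[pre]), stats::median(frames$y[pre]),
              stats::median(frames$z[pre]))
  yax <- unit(floor_normal)
  zax <- unit(camera_axis - sum(camera_axis * yax) * yax)
  xax <- cross3(yax, zax)
  Rm <- rbind(xax, yax, zax)
  P <- cbind(frames$x, frames$y, frames$z)
  P <- sweep(P, 2, origin) %*% t(Rm)
  if (paw_side == "left") P[, 1] <- -P[, 1]
  frames$x <- P[, 1]
  frames$y <- P[, 2]
  frames$z <- P[, 3]
  class(frames) <- c("trajectory3d", class(frames)[!(class(frames) %in% "trajectory3d")])
  attr(frames, "paw_side") <- paw_side
  attr(frames, "frame_rate") <- 300
  attr(frames, "origin") <- origin
  attr(frames, "rotation") <- Rm
  frames
}

#' Full reconstruction path for one trial
#'
#' Triangulate, filter by reprojection error, bridge short gaps, and move
#' into the pellet frame.
#'
#' @inheritParams triangulate_series
#' @inheritParams to_pellet_frame
#' @param threshold_px Reprojection-error exclusion threshold (px).
#' @param max_gap,tol_px Gap-bridging parameters (see
#'   [estimate_missing_points()]).
#' @return A `trajectory3d`.
#' @export
reconstruct_trajectory <- function(pose, pair, paw_side = "right",
                                   conf_min = 0.9, threshold_px = 3,
                                   max_gap = 5, tol_px = 3,
                                   trigger_frame = 300) {
  fr <- triangulate_series(pose, pair, conf_min = conf_min)
  fr <- filter_by_reprojection(fr, threshold_px = threshold_px)
  fr <- estimate_missing_points(fr, pose, pair, conf_min = conf_min,
                                max_gap = max_gap, tol_px = tol_px)
  to_pellet_frame(fr, paw_side = paw_side, trigger_frame = trigger_frame)
}

#' Extract one body part's ordered track
#'
#' @param traj A `frames3d`/`trajectory3d` table.
#' @param bodypart Body-part name.
#' @return List with `frame` (0-based), `xyz` (n x 3 matrix, mm),
#'   `provenance`.
#' @export
part_track <- function(traj, bodypart) {
  rows <- traj$bodypart == bodypart
  o <- order(traj$frame[rows])
  list(frame = traj$frame[rows][o],
       xyz = cbind(traj$x[rows][o], traj$y[rows][o], traj$z[rows][o]),
       provenance = traj$provenance[rows][o])
}
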