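# Per-reach kinematic measures and coordination profiles: grasp aperture,
# paw orientation, paw velocity, and aperture/orientation re-parameterized
# on the paw-advancement (z_digit2) grid by monotone piecewise-cubic
# interpolation.

#' The advancement grid
#'
#' The fixed z_digit2 grid on which coordination profiles are evaluated:
#' -20.0, -19.9, ..., +14.9, +15.0 mm from the pellet (351 points).
#'
#' @return Numeric vector of length 351.
#' @export
extent_grid <- function() {
  seq.int(-200L, 150L) / 10
}

#' Grasp aperture per frame
#'
#' Euclidean distance (3D, mm) between the first and fourth digit tips in
#' each frame where both are valid (triangulated or estimated).
#'
#' @param traj A `trajectory3d` (or any frames table with digit1/digit4).
#' @return Data frame with columns `frame` and `aperture_mm` (NA where
#'   either tip is missing).
#' @export
aperture <- function(traj) {
  d1 <- part_track(traj, "digit1")
  d4 <- part_track(traj, "digit4")
  stopifnot(identical(d1$frame, d4$frame))
  a <- sqrt(rowSums((d1$xyz - d4$xyz)^2))
  a[d1$provenance == "missing" | d4$provenance == "missing"] <- NA_real_
  data.frame(frame = d1$frame, aperture_mm = a)
}

#' Paw orientation per frame
#'
#' Angle between the digit1-digit4 line and the floor, measured on the
#' frontal (x-y) projection, in \[0, 90\] degrees; smaller angles indicate a
#' more pronated paw. Left-paw x negation is assumed to have been applied
#' when the trajectory entered the pellet frame.
#'
#' @param traj A `trajectory3d`.
#' @return Data frame with columns `frame` and `orientation_deg` (NA where
#'   a tip is missing or the projection is degenerate).
#' @export
orientation <- function(traj) {
  d1 <- part_track(traj, "digit1")
  d4 <- part_track(traj, "digit4")
  stopifnot(identical(d1$frame, d4$frame))
  dx <- d4$xyz[, 1] - d1$xyz[, 1]
  dy <- d4$xyz[, 2] - d1$xyz[, 2]
  th <- atan2(abs(dy), abs(dx)) * 180 / pi
  th[(abs(dx) < 1e-12 & abs(dy) < 1e-12) |
       d1$provenance == "missing" | d4$provenance == "missing"] <- NA_real_
  data.frame(frame = d1$frame, orientation_deg = th)
}

#' Paw speed per frame
#'
#' Euclidean distance between the tracked part in consecutive frames
#' divided by the inter-frame interval (1/300 s by default). Speed is
#' reported at the later frame of each pair and is undefined across gaps
#' (no bridging).
#'
#' @param traj A `trajectory3d`.
#' @param part Body part (default "pawdorsum").
#' @param fps Frame rate (frames/s).
#' @return Data frame with columns `frame` and `speed_mm_s`.
#' @export
speed_series <- function(traj, part = "pawdorsum", fps = 300) {
  tr <- part_track(traj, part)
  n <- length(tr$frame)
  sp <- rep(NA_real_, n)
  if (n >= 2) {
    ok <- tr$provenance != "missing"
    step <- diff(tr$frame) == 1 & ok[-n] & ok[-1]
    d <- sqrt(rowSums((tr$xyz[-1, , drop = FALSE] -
                       tr$xyz[-n, , drop = FALSE])^2))
    sp[-1][step] <- d[step] * fps
  }
  data.frame(frame = tr$frame, speed_mm_s = sp)
}

#' Per-reach kinematic summary
#'
#' For each detected reach: maximum reach extent (z_digit2 at the end
#' frame), grasp aperture and paw orientation at the end frame (falling
#' back to the nearest valid frame within `end_tol_frames`), and the
#' maximum paw-dorsum speed between start and end frames.
#'
#' @param traj A `trajectory3d`.
#' @param events A `reach_events` table from [detect_reaches()].
#' @param end_tol_frames Search radius for a valid end-frame measure.
#' @param fps Frame rate (frames/s).
#' @return Data frame with one row per reach: `reach_idx`, `start_frame`,
#'   `end_frame`, `max_extent_mm`, `end_aperture_mm`,
#'   `end_orientation_deg`, `max_velocity_mm_s`, `is_first_reach`.
#' @export
reach_kinematics <- function(traj, events, end_tol_frames = 2, fps = 300) {
  ap <- aperture(traj)
  th <- orientation(traj)
  sp <- speed_series(traj, fps = fps)
  near <- function(df, col, frame) {
    i <- which(df$frame >= frame - end_tol_frames &
                 df$frame <= frame + end_tol_frames & is.finite(df[[col]]))
    if (!length(i)) return(NA_real_)
    df[[col]][i[which.min(abs(df$frame[i] - frame))]]
  }
  out <- events
  out$end_aperture_mm <- vapply(events$end_frame, function(f) near(ap, "aperture_mm", f), 0)
  out$end_orientation_deg <- vapply(events$end_frame, function(f) near(th, "orientation_deg", f), 0)
  out$max_velocity_mm_s <- mapply(function(s, e) {
    v <- sp$speed_mm_s[sp$frame > s & sp$frame <= e]
    if (all(!is.finite(v))) NA_real_ else max(v, na.rm = TRUE)
  }, events$start_frame, events$end_frame)
  out[, c("reach_idx", "start_frame", "end_frame", "max_extent_mm",
          "end_aperture_mm", "end_orientation_deg", "max_velocity_mm_s",
          "is_first_reach")]
}

#' Re-parameterize a reach on the advancement grid
#'
#' Restricts the reach to the maximal retained strictly-increasing
#' subsequence of z_digit2 (each retained frame exceeds every previously
#' retained value), interpolates each digit tip's 3D coordinates as
#' monotone piecewise-cubic (pchip) functions of z_digit2, and evaluates
#' them on the fixed grid. Aperture(z) and orientation(z) are derived from
#' the interpolated digit1/digit4 tracks; grid points outside the observed
#' z range are masked.
#'
#' @param traj A `trajectory3d`.
#' @param event One row of a `reach_events` table.
#' @param min_frames Minimum usable frames on the advancing path.
#' @return An `extent_profile`: list with `grid` (351 z values), `digits`
#'   (list of 351 x 3 matrices), `aperture_mm`, `orientation_deg`, `mask`
#'   (TRUE where aperture/orientation are defined), `z_range`.
#' @export
profile_by_extent <- function(traj, event, min_frames = 4) {
  grid <- extent_grid()
  d2 <- part_track(traj, "digit2")
  sel <- d2$frame >= event$start_frame & d2$frame <= event$end_frame &
    is.finite(d2$xyz[, 3]) & d2$provenance != "missing"
  z <- d2$xyz[sel, 3]
  fr <- d2$frame[sel]
  keep <- monotone_subsequence(z)
  empty <- structure(list(grid = grid,
                          digits = NULL,
                          aperture_mm = rep(NA_real_, length(grid)),
                          orientation_deg = rep(NA_real_, length(grid)),
                          mask = rep(FALSE, length(grid)),
                          z_range = c(NA_real_, NA_real_)),
                     class = "extent_profile")
  if (sum(keep) < min_frames) return(empty)
  zk <- z[keep]
  frk <- fr[keep]
  digits <- list()
  for (bp in c("digit1", "digit2", "digit3", "digit4")) {
    tr <- part_track(traj, bp)
    i <- match(frk, tr$frame)
    good <- !is.na(i) & tr$provenance[i] != "missing" &
      is.finite(tr$xyz[i, 1])
    M <- matrix(NA_real_, length(grid), 3)
    if (sum(good) >= min_frames) {
      zg <- zk[good]
      on <- grid >= min(zg) & grid <= max(zg)
      if (any(on)) {
        for (c3 in 1:3) {
          M[on, c3] <- pracma::pchip(zg, tr$xyz[i[good], c3], grid[on])
        }
      }
    }
    digits[[bp]] <- M
  }
  apz <- sqrt(rowSums((digits$digit1 - digits$digit4)^2))
  dx <- digits$digit4[, 1] - digits$digit1[, 1]
  dy <- digits$digit4[, 2] - digits$digit1[, 2]
  thz <- atan2(abs(dy), abs(dx)) * 180 / pi
  mask <- is.finite(apz)
  thz[!mask] <- NA_real_
  structure(list(grid = grid, digits = digits, aperture_mm = apz,
                 orientation_deg = thz, mask = mask,
                 z_range = range(zk)),
            class = "extent_profile")
}

#' @export
print.extent_profile <- function(x, ...) {
  cov <- sum(x$mask)
  cat(sprintf("Extent profile: %d/%d grid points covered (z in [%.1f, %.1f] mm)\n",
              cov, length(x$grid), x$z_range[1], x$z_range[2]))
  invisible(x)
}

# Maximal retained strictly-increasing subsequence: keep elements exceeding
# all previously retained values (greedy left-to-right running maximum).
monotone_subsequence <- function(z) {
  keep <- logical(length(z))
  cur <- -Inf
  for (k in seq_along(z)) {
    if (is.finite(z[k]) && z[k] > cur) {
      keep[k] <- TRUE
      cur <- z[k]
    }
  }
  keep
}

#' Sample coordination profiles at a grid z
#'
#' Evaluates a set of per-reach extent profiles at one grid value and
#' averages over the reaches that cover it; reaches whose z range misses
#' `z_query` are excluded from the average.
#'
#' @param profiles List of `extent_profile` objects.
#' @param z_query A value on the advancement grid (mm).
#' @param measure "aperture_mm" or "orientation_deg".
#' @return List with `values` (one per reach, NA where not covered),
#'   `mean` (over covering reaches; NA when none), `n` (covering count).
#' @export
sample_profile <- function(profiles, z_query,
                           measure = c("aperture_mm", "orientation_deg")) {
  measure <- match.arg(measure)
  grid <- extent_grid()
  i <- which(abs(grid - z_query) < 1e-9)
  if (!length(i)) stop("z_query must lie on the advancement grid")
  vals <- vapply(profiles, function(p) p[[measure]][i], 0)
  n <- sum(is.finite(vals))
  list(values = vals,
       mean = if (n) mean(vals[is.finite(vals)]) else NA_real_,
       n = n)
}
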