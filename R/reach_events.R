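# Segmentation of a trial's trajectory into discrete reaches.
#
# A reach is anchored at an outward crossing of the slot plane by the
# second digit tip; its start is found by walking backwards until the paw
# dorsum stopped moving forward, and its end is the frame of maximum digit2
# advancement before sustained retraction ("maximum reach extent").

#' Detect reaches in one trial's trajectory
#'
#' For each outward crossing of `slot_z` by the second digit tip: the start
#' frame is found by walking back from the crossing while the paw dorsum
#' advances (positive frame-to-frame change in z); the end frame is the
#' frame at which z_digit2 attains its maximum before retracting (assessed
#' on a short boxcar-smoothed copy of the series for noise robustness; ties
#' resolve to the last frame of a plateau). A subsequent reach requires the
#' digit to retract below `slot_z` first. Candidate reaches advancing less
#' than `min_advance_mm` beyond the slot or shorter than
#' `min_duration_frames` are rejected as jitter.
#'
#' @param traj A `trajectory3d` (pellet-frame mm).
#' @param slot_z Slot plane z (mm; default -15, the pellet-to-slot
#'   distance).
#' @param min_advance_mm Minimum advancement beyond `slot_z` (mm).
#' @param min_duration_frames Minimum reach duration (frames).
#' @param retract_eps_mm Retraction below the running maximum that ends the
#'   outward excursion (mm).
#' @param end_smooth Boxcar width (frames, odd) used when locating the
#'   extent maximum; 1 disables smoothing.
#' @return A data frame (class `reach_events`) with columns `reach_idx`,
#'   `start_frame`, `end_frame` (0-based), `max_extent_mm`,
#'   `is_first_reach`, `paw_through_slot`, `truncated`. Zero rows (with a
#'   warning if z_digit2 is never valid) when no reach is found.
#' @export
detect_reaches <- function(traj, slot_z = -15, min_advance_mm = 2,
                           min_duration_frames = 3, retract_eps_mm = 0.5,
                           end_smooth = 3) {
  d2 <- part_track(traj, "digit2")
  pd <- part_track(traj, "pawdorsum")
  z <- d2$xyz[, 3]
  frames <- d2$frame
  empty <- data.frame(reach_idx = integer(), start_frame = integer(),
                      end_frame = integer(), max_extent_mm = numeric(),
                      is_first_reach = logical(), paw_through_slot = logical(),
                      truncated = logical())
  class(empty) <- c("reach_events", "data.frame")
  if (!any(is.finite(z))) {
    warning("no valid z_digit2 in trajectory; no reaches detected")
    return(empty)
  }
  first_valid <- which(is.finite(z))[1]
  paw_through <- z[first_valid] > slot_z
  # walk-back reference: dorsum z where available, else digit2 z
  zd <- pd$xyz[, 3]
  if (!any(is.finite(zd))) zd <- z
  zs <- if (end_smooth > 1) smooth_boxcar(z, end_smooth) else z
  n <- length(z)
  events <- list()
  i <- 2
  below <- !paw_through      # must start (or return) below the slot plane
  while (i <= n) {
    crossing <- FALSE
    if (below) {
      # state-based crossing so unlabeled frames cannot hide a crossing
      crossing <- is.finite(z[i]) && z[i] >= slot_z
    } else if (i == first_valid + 1 && paw_through && !length(events)) {
      crossing <- TRUE       # trial began with the paw already through
    }
    if (!crossing) {
      if (is.finite(z[i]) && z[i] < slot_z) below <- TRUE
      i <- i + 1
      next
    }
    # ---- end: scan forward until sustained retraction ----
    run_max <- z[i]; run_max_i <- i
    j <- i
    truncated <- TRUE
    while (j < n) {
      j <- j + 1
      if (!is.finite(z[j])) next
      if (z[j] > run_max) { run_max <- z[j]; run_max_i <- j }
      if (z[j] < run_max - retract_eps_mm) { truncated <- FALSE; break }
    }
    # locate the extent maximum on the smoothed series; ties -> last frame
    win <- i:j
    win <- win[is.finite(zs[win])]
    if (length(win)) {
      mx <- max(zs[win])
      end_i <- max(win[zs[win] >= mx - 1e-12])
    } else end_i <- run_max_i
    # ---- start: walk back while the paw advanced; start is the frame
    # after the last non-positive dorsum step ----
    s <- i
    while (s > 1 && is.finite(zd[s]) && is.finite(zd[s - 1]) &&
           zd[s] - zd[s - 1] > 0) {
      s <- s - 1
    }
    if (s > 1 && is.finite(zd[s]) && is.finite(zd[s - 1]) &&
        zd[s] - zd[s - 1] <= 0 && s < end_i) {
      s <- s + 1
    }
    ok <- is.finite(z[end_i]) && (z[end_i] - slot_z) >= min_advance_mm &&
      (end_i - s + 1) >= min_duration_frames && end_i > s
    if (ok) {
      events[[length(events) + 1]] <- data.frame(
        start_frame = frames[s], end_frame = frames[end_i],
        max_extent_mm = z[end_i],
        paw_through_slot = paw_through && !length(events),
        truncated = truncated)
    }
    below <- FALSE
    i <- max(j, end_i) + 1
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out <- data.frame(reach_idx = seq_len(nrow(out)), out)
  out$is_first_reach <- out$reach_idx == 1
  out <- out[, c("reach_idx", "start_frame", "end_frame", "max_extent_mm",
                 "is_first_reach", "paw_through_slot", "truncated")]
  class(out) <- c("reach_events", "data.frame")
  out
}

# Centred boxcar smoothing, NA-aware, width w (odd).
smooth_boxcar <- function(x, w) {
  if (w <= 1) return(x)
  half <- floor(w / 2)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    lo <- max(1, k - half); hi <- min(n, k + half)
    v <- x[lo:hi]
    if (any(is.finite(v))) out[k] <- mean(v, na.rm = TRUE)
  }
  out
}
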