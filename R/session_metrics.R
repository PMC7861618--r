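# Session-, rat-, and group-level behavioural measures: outcome-code
# bookkeeping, success rates, baseline normalization, moving-block
# averages with carry-forward, extent-matched stratification, and
# abnormal-involuntary-movement (AIMs) composite arithmetic.

#' Reach outcome codes
#'
#' The visual-scoring outcome codes: 0 no pellet / mechanical failure;
#' 1 first-try success; 2 success on a later attempt; 3 grasped then
#' dropped in box; 4 pellet knocked off; 5 obtained with tongue; 6 trigger
#' error (no reach); 7 reached but pellet remained; 8 ipsilateral paw;
#' 9 laser error; 10 tongue then paw.
#'
#' @return Named integer vector (names are short labels).
#' @export
outcome_codes <- function() {
  c(no_pellet = 0L, first_success = 1L, multi_try_success = 2L,
    drop_in_box = 3L, pellet_knocked_off = 4L, used_tongue = 5L,
    trigger_error = 6L, pellet_remained = 7L, ipsilateral_paw = 8L,
    laser_error = 9L, tongue_and_paw = 10L)
}

# Codes that count as attempted reach trials in success-rate denominators.
.trial_codes <- c(1L, 2L, 3L, 4L, 7L)

check_outcomes <- function(outcomes) {
  if (!all(outcomes[!is.na(outcomes)] %in% 0:10)) {
    stop("outcome codes must be integers in 0..10")
  }
  outcomes
}

#' First-reach success rate
#'
#' Number of first-try successes (code 1) divided by the number of
#' attempted trials (codes 1, 2, 3, 4, 7). Trials flagged paw-through-slot
#' are excluded before counting.
#'
#' @param outcomes Integer outcome codes (0-10).
#' @param paw_through_slot Optional logical vector marking trials whose
#'   video began with the paw already through the slot.
#' @return Fraction in \[0, 1\]; NA when no attempted trials remain.
#' @export
first_success_rate <- function(outcomes, paw_through_slot = NULL) {
  outcomes <- drop_excluded(check_outcomes(outcomes), paw_through_slot)
  den <- sum(outcomes %in% .trial_codes)
  if (den == 0) return(NA_real_)
  sum(outcomes == 1L) / den
}

#' Any-reach success rate
#'
#' Successes on any attempt (codes 1 and 2) divided by attempted trials
#' (codes 1, 2, 3, 4, 7).
#'
#' @inheritParams first_success_rate
#' @return Fraction in \[0, 1\]; NA when no attempted trials remain.
#' @export
any_success_rate <- function(outcomes, paw_through_slot = NULL) {
  outcomes <- drop_excluded(check_outcomes(outcomes), paw_through_slot)
  den <- sum(outcomes %in% .trial_codes)
  if (den == 0) return(NA_real_)
  sum(outcomes %in% c(1L, 2L)) / den
}

drop_excluded <- function(outcomes, paw_through_slot) {
  if (!is.null(paw_through_slot)) {
    stopifnot(length(paw_through_slot) == length(outcomes))
    outcomes <- outcomes[!paw_through_slot]
  }
  outcomes[!is.na(outcomes)]
}

#' Normalize per-session values to the retraining baseline
#'
#' The baseline is the mean of the last two retraining-session values;
#' every session's value is divided by it.
#'
#' @param values Per-session values (one per session, in session order).
#' @param stages Character vector of session stages (same length); must
#'   contain at least two "retraining" entries.
#' @return List with `normalized` (values / baseline) and `baseline`.
#'   A zero baseline yields NA normalized values with a warning.
#' @export
normalize_to_baseline <- function(values, stages) {
  stopifnot(length(values) == length(stages))
  idx <- which(stages == "retraining")
  if (length(idx) < 2) stop("need at least two retraining sessions")
  base <- mean(values[utils::tail(idx, 2)])
  if (!is.finite(base) || base == 0) {
    warning("baseline is zero or undefined; normalized values set to NA")
    return(list(normalized = rep(NA_real_, length(values)), baseline = base))
  }
  list(normalized = values / base, baseline = base)
}

#' Moving-block average with carry-forward
#'
#' Trailing-window mean over a moving block of `window` trials, reported at
#' the window's last trial (positions before `window` are NA), ignoring
#' missing values within the window. When `carry_to` exceeds the series
#' length, the last value is repeated (carried forward) so that group
#' averages are not distorted by rats performing fewer trials.
#'
#' @param values Per-trial values (0/1 outcomes for success fractions, or
#'   kinematic measures).
#' @param window Block size in trials (default 10).
#' @param carry_to Optional length to extend the series to.
#' @return Numeric vector of length `max(length(values), carry_to)`.
#' @export
moving_block <- function(values, window = 10, carry_to = NULL) {
  if (window < 1) stop("window must be >= 1")
  n <- length(values)
  if (n == 0) return(numeric(0))
  out <- rep(NA_real_, n)
  if (n >= window) {
    for (k in window:n) {
      v <- values[(k - window + 1):k]
      if (any(is.finite(v))) out[k] <- mean(v, na.rm = TRUE)
    }
  }
  if (!is.null(carry_to) && carry_to > n) {
    out <- c(out, rep(out[n], carry_to - n))
  }
  out
}

#' Stratify trials by maximum reach extent
#'
#' Bins trials into 1-mm-wide strata of maximum z_digit2 beginning at 0
#' (bins \[k, k+1) mm, k = 0, 1, 2, ...), and summarizes success and grasp
#' kinematics within each stratum. Success is code 1; failures are codes 4
#' and 7; other codes do not enter the success fraction. Trials with
#' maximum extent below 0 are tallied separately and excluded from bins.
#'
#' @param trials Data frame with columns `max_extent_mm`, `outcome`, and
#'   optionally `end_aperture_mm`, `end_orientation_deg`.
#' @param bin_width Bin width (mm; default 1).
#' @return Data frame with one row per non-empty-range bin: `bin_lo`,
#'   `bin_hi`, `n`, `n_success`, `n_failure`, `success_rate`,
#'   `mean_aperture_mm`, `mean_orientation_deg`. Attribute
#'   `n_below_zero` counts the excluded short trials.
#' @export
stratify_by_extent <- function(trials, bin_width = 1) {
  stopifnot(is.data.frame(trials), "max_extent_mm" %in% names(trials))
  ext <- trials$max_extent_mm
  usable <- is.finite(ext)
  below <- usable & ext < 0
  inbin <- usable & ext >= 0
  if (!any(inbin)) {
    out <- data.frame(bin_lo = numeric(), bin_hi = numeric(), n = integer(),
                      n_success = integer(), n_failure = integer(),
                      success_rate = numeric(), mean_aperture_mm = numeric(),
                      mean_orientation_deg = numeric())
    attr(out, "n_below_zero") <- sum(below)
    return(out)
  }
  k <- floor(ext[inbin] / bin_width)
  kk <- seq.int(0L, max(k))
  colmean <- function(col, sel) {
    if (!col %in% names(trials)) return(NA_real_)
    v <- trials[[col]][inbin][sel]
    if (any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_
  }
  rows <- lapply(kk, function(b) {
    sel <- k == b
    oc <- trials$outcome[inbin][sel]
    ns <- sum(oc == 1L, na.rm = TRUE)
    nf <- sum(oc %in% c(4L, 7L), na.rm = TRUE)
    data.frame(bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
               n = sum(sel), n_success = ns, n_failure = nf,
               success_rate = if (ns + nf > 0) ns / (ns + nf) else NA_real_,
               mean_aperture_mm = colmean("end_aperture_mm", sel),
               mean_orientation_deg = colmean("end_orientation_deg", sel))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_below_zero") <- sum(below)
  out
}

#' AIMs composite scores
#'
#' Abnormal-involuntary-movement composites: amplitude and basic (duration)
#' scores are multiplied per body region; the global score is the sum of
#' the axial and limb composites; the rotational bias is contralateral
#' minus ipsilateral full turns.
#'
#' @param axial_amplitude,axial_basic,limb_amplitude,limb_basic Ordinal
#'   scores (non-negative); vectors are recycled elementwise.
#' @param contralateral_rotations,ipsilateral_rotations Full-turn counts.
#' @return Data frame with `axial_composite`, `limb_composite`, `global`,
#'   `rotation_bias`.
#' @export
aims_scores <- function(axial_amplitude, axial_basic,
                        limb_amplitude, limb_basic,
                        contralateral_rotations = 0,
                        ipsilateral_rotations = 0) {
  if (any(c(axial_amplitude, axial_basic, limb_amplitude, limb_basic,
            contralateral_rotations, ipsilateral_rotations) < 0,
          na.rm = TRUE)) {
    stop("AIMs scores and rotation counts must be non-negative")
  }
  axial <- axial_amplitude * axial_basic
  limb <- limb_amplitude * limb_basic
  data.frame(axial_composite = axial,
             limb_composite = limb,
             global = axial + limb,
             rotation_bias = contralateral_rotations - ipsilateral_rotations)
}

#' Summarize an experiment's trial table by session
#'
#' Aggregates a per-trial table (see [generate_experiment()] or the
#' pipeline's kinematics output) to one row per rat x session with success
#' rates and mean kinematics.
#'
#' @param trials Data frame with columns `rat`, `group`, `stage`, `session`,
#'   `laser`, `outcome`, `paw_through_slot`, `max_extent_mm`, and optional
#'   kinematic columns.
#' @return Data frame with per-session `first_success`, `any_success`,
#'   `n_trials`, `mean_extent_mm`, `mean_aperture_mm`,
#'   `mean_orientation_deg`, `mean_velocity_mm_s`, `laser`.
#' @export
summarize_sessions <- function(trials) {
  key <- interaction(trials$rat, trials$session, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(i) {
    tt <- trials[i, ]
    mean_of <- function(col) {
      if (!col %in% names(tt)) return(NA_real_)
      v <- tt[[col]]
      if (any(is.finite(v))) mean(v, na.rm = TRUE) else NA_real_
    }
    data.frame(rat = tt$rat[1], group = tt$group[1], stage = tt$stage[1],
               session = tt$session[1],
               laser = max(tt$laser),
               n_trials = sum(tt$outcome %in% .trial_codes & !tt$paw_through_slot),
               first_success = first_success_rate(tt$outcome, tt$paw_through_slot),
               any_success = any_success_rate(tt$outcome, tt$paw_through_slot),
               mean_extent_mm = mean_of("max_extent_mm"),
               mean_aperture_mm = mean_of("end_aperture_mm"),
               mean_orientation_deg = mean_of("end_orientation_deg"),
               mean_velocity_mm_s = mean_of("max_velocity_mm_s"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$rat, out$session), ]
  rownames(out) <- NULL
  out
}
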