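# Small shared helpers: smooth motion profiles, logistic kinematic profiles,
# seeded RNG scoping.

#' Minimum-jerk position profile
#'
#' Normalized minimum-jerk trajectory s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5,
#' the smooth point-to-point profile with a single-peaked, bell-shaped
#' velocity. Peak normalized velocity is 1.875 at tau = 0.5.
#'
#' @param tau Normalized time in \[0, 1\] (values outside are clamped).
#' @return Normalized displacement in \[0, 1\].
#' @keywords internal
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

#' Logistic profile in the advancement coordinate
#'
#' Evaluates `lo + (hi - lo) / (1 + exp(-slope * (z - z_half)))`, the
#' sigmoidal dependence used for grasp aperture and paw orientation as
#' functions of paw advancement z (mm).
#'
#' @param z Advancement coordinate (mm).
#' @param lo,hi Asymptotic values far before / far past `z_half`.
#' @param z_half Midpoint (mm): value there is `(lo + hi)/2`.
#' @param slope Steepness (1/mm), positive.
#' @return Numeric vector, same length as `z`.
#' @export
logistic_profile <- function(z, lo, hi, z_half, slope) {
  lo + (hi - lo) / (1 + exp(-slope * (z - z_half)))
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG. seed = NULL runs in the ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.finite(seed)) stop("seed must be a finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream indices, staying within
# 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in idx) s <- (s * 69069 + as.double(k) * 2654435761) %% 2147483647
  as.integer(s)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Canonical body-part names
#'
#' The tracked body parts, in table order: four digit tips, paw dorsum,
#' nose, and pellet.
#'
#' @return Character vector of length 7.
#' @export
bodypart_names <- function() {
  c("digit1", "digit2", "digit3", "digit4", "pawdorsum", "nose", "pellet")
}
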