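# Two-view geometry between the direct camera view and the mirror view.
#
# A planar mirror makes the virtual camera an improper (handedness-flipping)
# transform of the real one, so the standard essential-matrix machinery
# (which assumes det(R) = +1) cannot be applied to raw mirror pixels.
# Negating the mirror-view horizontal pixel coordinate composes a second
# reflection with the mirror reflection, turning the virtual camera into a
# proper right-handed camera whose intrinsics equal K with the principal
# point's x negated. All calibration and triangulation below operate in this
# flipped mirror pixel system (mirror_flip = TRUE, the default).

flip_mirror_u <- function(uv) {
  uv <- cbind(uv)
  uv[, 1] <- -uv[, 1]
  uv
}

mirror_intrinsics <- function(K) {
  Km <- K
  Km[1, 3] <- -K[1, 3]
  Km
}

corr_xy <- function(corr, mirror_flip = TRUE) {
  p <- corr$points
  x1 <- cbind(p$u_direct, p$v_direct)
  x2 <- cbind(p$u_mirror, p$v_mirror)
  if (mirror_flip) x2 <- flip_mirror_u(x2)
  list(x1 = x1, x2 = x2)
}

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2). Returns 3x3 similarity transform.
hartley_transform <- function(x) {
  mu <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, mu)^2))
  s <- sqrt(2) / mean(d)
  rbind(c(s, 0, -s * mu[1]),
        c(0, s, -s * mu[2]),
        c(0, 0, 1))
}

#' Estimate the fundamental matrix between direct and mirror views
#'
#' Hartley-normalized eight-point (least-squares over all pairs) estimate of
#' F satisfying x_mirror'^T F x_direct = 0, where x_mirror' is the mirror
#' label with its horizontal pixel coordinate negated (see `mirror_flip`).
#' Rank 2 is enforced by zeroing the smallest singular value and the result
#' is scaled to unit Frobenius norm.
#'
#' @param corr A `correspondence_set` (raw pixel coordinates in both views).
#' @param mirror_flip Negate the mirror-view u before estimation (default
#'   TRUE; required for a mirror rig).
#' @param cond_tol Degeneracy guard: error if the 8th singular value of the
#'   normalized design matrix falls below `cond_tol` times the largest.
#' @return A `fundamental_matrix`: list with `F` (3x3, unit norm, rank 2),
#'   `median_residual_px` (median symmetric point-to-epipolar-line
#'   distance), `n_pairs`, `mirror_flip`.
#' @export
estimate_fundamental <- function(corr, mirror_flip = TRUE, cond_tol = 1e-9) {
  stopifnot(inherits(corr, "correspondence_set"))
  xy <- corr_xy(corr, mirror_flip)
  n <- nrow(xy$x1)
  if (n < 8) stop("need at least 8 correspondences")
  T1 <- hartley_transform(xy$x1)
  T2 <- hartley_transform(xy$x2)
  h1 <- cbind(xy$x1, 1) %*% t(T1)
  h2 <- cbind(xy$x2, 1) %*% t(T2)
  A <- cbind(h2[, 1] * h1[, 1], h2[, 1] * h1[, 2], h2[, 1],
             h2[, 2] * h1[, 1], h2[, 2] * h1[, 2], h2[, 2],
             h1[, 1], h1[, 2], h1[, 3])
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < cond_tol * sv$d[1]) {
    stop("degenerate correspondence configuration (rank-deficient design)")
  }
  Fn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  # enforce rank 2
  sf <- svd(Fn)
  Fn <- sf$u %*% diag(c(sf$d[1:2], 0)) %*% t(sf$v)
  Fm <- t(T2) %*% Fn %*% T1
  Fm <- Fm / sqrt(sum(Fm^2))
  if (Fm[which.max(abs(Fm))] < 0) Fm <- -Fm   # fix overall sign
  res <- epipolar_residuals(Fm, xy$x1, xy$x2)
  structure(list(F = Fm, median_residual_px = stats::median(res),
                 n_pairs = n, mirror_flip = mirror_flip),
            class = "fundamental_matrix")
}

#' @export
print.fundamental_matrix <- function(x, ...) {
  cat(sprintf("Fundamental matrix (rank 2, unit norm), %d pairs, median epipolar residual %.3g px\n",
              x$n_pairs, x$median_residual_px))
  print(signif(x$F, 4))
  invisible(x)
}

#' Symmetric epipolar residuals
#'
#' Mean of the point-to-epipolar-line distances in the two views for each
#' correspondence.
#'
#' @param F 3x3 fundamental matrix (x2^T F x1 = 0 convention).
#' @param x1,x2 n x 2 pixel coordinates (x2 already mirror-flipped if
#'   applicable).
#' @return Numeric vector of length n (pixels).
#' @export
epipolar_residuals <- function(F, x1, x2) {
  h1 <- cbind(x1, 1)
  h2 <- cbind(x2, 1)
  l2 <- h1 %*% t(F)           # epipolar lines in view 2
  l1 <- h2 %*% F              # epipolar lines in view 1
  num <- abs(rowSums(h2 * l2))
  d2 <- num / sqrt(l2[, 1]^2 + l2[, 2]^2)
  d1 <- num / sqrt(l1[, 1]^2 + l1[, 2]^2)
  (d1 + d2) / 2
}

# Midpoint triangulation in normalized camera coordinates.
# y1, y2: n x 2 normalized image points; R, t: pose of camera 2 (y2-frame =
# R * y1-frame + t). Returns n x 3 points in camera-1 coordinates.
triangulate_midpoint <- function(y1, y2, R, t) {
  d1 <- cbind(y1, 1)
  d1 <- d1 / sqrt(rowSums(d1^2))
  d2c <- cbind(y2, 1)
  d2 <- d2c %*% R             # rotate camera-2 ray directions into frame 1
  d2 <- d2 / sqrt(rowSums(d2^2))
  C2 <- drop(-t %*% R)        # camera-2 centre in frame 1 (= -R^T t)
  a <- rowSums(d1 * d1)
  b <- rowSums(d1 * d2)
  cc <- rowSums(d2 * d2)
  w <- sweep(matrix(0, nrow(d1), 3), 2, C2, "+")
  d <- rowSums(w * d1)
  e <- rowSums(w * d2)
  den <- a * cc - b * b
  s1 <- (cc * d - b * e) / den
  s2 <- (b * d - a * e) / den
  P1 <- d1 * s1
  P2 <- sweep(d2 * s2, 2, C2, "+")
  X <- (P1 + P2) / 2
  X[abs(den) < 1e-12, ] <- NA_real_
  X
}

#' Derive metric camera matrices from the fundamental matrix
#'
#' Forms the essential matrix E = K_mirror^T F K, decomposes it into the
#' four (R, t) candidates, selects the one placing the calibration points in
#' front of both cameras (cheirality), and fixes the metric scale so that
#' the first listed adjacency pair of reconstructed corners spans
#' `square_size_mm`. The world frame is the direct camera frame: origin at
#' the lens, z along the optical axis.
#'
#' @param F A `fundamental_matrix` (or plain 3x3 matrix).
#' @param K 3x3 intrinsic matrix of the real camera.
#' @param corr The `correspondence_set` used for cheirality and scale.
#' @param square_size_mm Physical spacing of adjacent calibration corners
#'   (mm); defaults to the value stored in `corr`.
#' @param mirror_flip Negate mirror-view u (must match the F estimate).
#' @return A `camera_pair`: list with `K`, `K_mirror`, `R`, `t` (unit
#'   norm), `s` (mm per reconstruction unit), `P_direct`, `P_mirror` (in
#'   flipped mirror pixels), `mirror_flip`, plus diagnostics
#'   (`cheirality_fraction`, `scale_spread`, `n_pairs`).
#' @export
derive_camera_pair <- function(F, K, corr, square_size_mm = NULL,
                               mirror_flip = TRUE) {
  Fm <- if (inherits(F, "fundamental_matrix")) F$F else F
  if (inherits(F, "fundamental_matrix")) mirror_flip <- F$mirror_flip
  if (is.null(square_size_mm)) square_size_mm <- corr$square_size_mm
  if (!is.finite(square_size_mm) || square_size_mm <= 0) {
    stop("square_size_mm must be positive")
  }
  if (abs(det(K)) < .Machine$double.eps) stop("K must be invertible")
  Km <- mirror_intrinsics(K)
  E <- t(Km) %*% Fm %*% K
  se <- svd(E)
  # project to a valid essential matrix (two equal singular values, one 0)
  U <- se$u; V <- se$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  cands <- list()
  for (R in list(U %*% W %*% t(V), U %*% t(W) %*% t(V))) {
    for (sgn in c(1, -1)) {
      cands[[length(cands) + 1]] <- list(R = R, t = sgn * U[, 3])
    }
  }
  xy <- corr_xy(corr, mirror_flip)
  Kinv <- solve(K)
  Kminv <- solve(Km)
  y1 <- to_normalized(xy$x1, Kinv)
  y2 <- to_normalized(xy$x2, Kminv)
  best <- NULL
  best_frac <- -1
  for (cand in cands) {
    X <- triangulate_midpoint(y1, y2, cand$R, cand$t)
    z1 <- X[, 3]
    z2 <- (X %*% t(cand$R))[, 3] + cand$t[3]
    frac <- mean(z1 > 0 & z2 > 0, na.rm = TRUE)
    if (is.finite(frac) && frac > best_frac) {
      best_frac <- frac
      best <- c(cand, list(X = X))
    }
  }
  if (best_frac < 0.75) {
    stop("no (R, t) candidate passes the cheirality test; ",
         "check mirror_flip/handedness correction")
  }
  if (is.null(corr$adjacency) || nrow(corr$adjacency) < 1) {
    stop("correspondence set has no adjacency pairs to anchor the scale")
  }
  X <- best$X
  adj <- corr$adjacency
  d1 <- vnorm(X[adj[1, 1], ] - X[adj[1, 2], ])
  s <- square_size_mm / d1
  dists <- sqrt(rowSums((X[adj[, 1], , drop = FALSE] -
                         X[adj[, 2], , drop = FALSE])^2)) * s
  pair <- structure(list(
    K = K, K_mirror = Km, R = best$R, t = best$t, s = s,
    P_direct = K %*% cbind(diag(3), 0),
    P_mirror = Km %*% cbind(best$R, best$t),
    mirror_flip = mirror_flip,
    cheirality_fraction = best_frac,
    scale_spread = stats::sd(dists) / square_size_mm,
    n_pairs = nrow(xy$x1)),
    class = "camera_pair")
  pair
}

#' One-call calibration from correspondences
#'
#' Runs [estimate_fundamental()] then [derive_camera_pair()].
#'
#' @inheritParams derive_camera_pair
#' @param corr A `correspondence_set`.
#' @return A `camera_pair` (with the fundamental-matrix diagnostics attached
#'   as `median_residual_px`).
#' @export
calibrate_camera_pair <- function(corr, K, square_size_mm = NULL,
                                  mirror_flip = TRUE) {
  Fhat <- estimate_fundamental(corr, mirror_flip = mirror_flip)
  pair <- derive_camera_pair(Fhat, K, corr, square_size_mm = square_size_mm)
  pair$median_residual_px <- Fhat$median_residual_px
  pair$F <- Fhat$F
  pair
}

#' @export
print.camera_pair <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat("Calibrated direct/mirror camera pair\n")
  cat(sprintf("  relative rotation : %.2f deg (det R = %+.0f)\n", ang, det(x$R)))
  cat(sprintf("  baseline direction: (%.3f, %.3f, %.3f)\n",
              x$t[1], x$t[2], x$t[3]))
  cat(sprintf("  metric scale      : %.4f mm/unit\n", x$s))
  cat(sprintf("  cheirality        : %.1f%% of calibration points in front\n",
              100 * x$cheirality_fraction))
  if (!is.null(x$scale_spread)) {
    cat(sprintf("  edge-length spread: %.3g (relative sd across adjacency pairs)\n",
                x$scale_spread))
  }
  invisible(x)
}

to_normalized <- function(x, Kinv) {
  h <- cbind(x, 1) %*% t(Kinv)
  h[, 1:2] / h[, 3]
}
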