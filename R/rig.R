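# Synthetic camera rig: a single pinhole camera viewing the reaching chamber
# directly, plus a planar side mirror that yields a second, "virtual" camera
# view. World coordinates coincide with the direct camera frame (origin at
# the lens, z along the optical axis), matching the convention in which
# camera matrices are derived for the real and virtual cameras.

#' Construct a mirror-stereo camera rig
#'
#' Builds the geometry of one high-speed camera plus one planar side mirror.
#' The mirror view of a 3D point is obtained by reflecting the point across
#' the mirror plane and projecting it with the real camera; equivalently it
#' is the image seen by a "virtual" camera behind the mirror (the reflection
#' of the real camera, an improper/handedness-flipping transform).
#'
#' @param focal_px Focal length in pixels (square pixels assumed).
#' @param principal_point Length-2 pixel coordinates of the principal point.
#' @param image_size Length-2 `c(width, height)` in pixels.
#' @param mirror_normal Length-3 unit normal of the mirror plane, pointing
#'   toward the camera/scene side.
#' @param mirror_offset Plane offset d such that points x on the mirror
#'   satisfy `sum(mirror_normal * x) == d` (mm).
#' @param pellet_position 3D position of the pellet in camera coordinates
#'   (mm); anchors the synthetic scene.
#' @return An object of class `camera_rig`: list with `K` (3x3 intrinsics),
#'   `image_size`, `mirror_normal`, `mirror_offset`, `pellet_position`, and
#'   the derived virtual-camera matrix `P_virtual` (3x4, improper rotation
#'   block).
#' @examples
#' rig <- make_camera_rig()
#' p <- project_to_views(matrix(rig$pellet_position, 1), rig)
#' @export
make_camera_rig <- function(focal_px = 3600,
                            principal_point = c(1200, 512),
                            image_size = c(2400, 1024),
                            mirror_normal = -c(1, 0, 1) / sqrt(2),
                            mirror_offset = -260 / sqrt(2),
                            pellet_position = c(0, 0, 300)) {
  if (length(focal_px) != 1 || focal_px <= 0) stop("focal_px must be a positive scalar")
  if (abs(vnorm(mirror_normal) - 1) > 1e-8) {
    stop("mirror_normal must have unit length")
  }
  K <- matrix(c(focal_px, 0, principal_point[1],
                0, focal_px, principal_point[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  # camera centre is the world origin; it must lie strictly on the normal's
  # side of the mirror plane
  if (-mirror_offset <= 0) {
    stop("camera lies behind the mirror plane; flip mirror_normal/offset")
  }
  n <- mirror_normal
  H <- diag(3) - 2 * tcrossprod(n)          # reflection linear part, det = -1
  h <- 2 * mirror_offset * n                # reflection translation part
  rig <- list(
    K = K,
    image_size = as.numeric(image_size),
    mirror_normal = n,
    mirror_offset = mirror_offset,
    pellet_position = as.numeric(pellet_position),
    reflect_H = H,
    reflect_h = h,
    P_virtual = K %*% cbind(H, h)
  )
  class(rig) <- "camera_rig"
  # sanity: the scene anchor must be visible in both views
  uv <- project_to_views(matrix(rig$pellet_position, 1), rig)
  if (any(!is.finite(unlist(uv)))) stop("pellet_position projects at infinity")
  rig
}

#' @export
print.camera_rig <- function(x, ...) {
  cat("Mirror-stereo camera rig\n")
  cat(sprintf("  focal length : %.1f px\n", x$K[1, 1]))
  cat(sprintf("  image size   : %d x %d px\n", x$image_size[1], x$image_size[2]))
  cat(sprintf("  mirror plane : n = (%.3f, %.3f, %.3f), d = %.2f mm\n",
              x$mirror_normal[1], x$mirror_normal[2], x$mirror_normal[3],
              x$mirror_offset))
  cat(sprintf("  virtual cam  : centre (%.1f, %.1f, %.1f) mm\n",
              virtual_camera_center(x)[1], virtual_camera_center(x)[2],
              virtual_camera_center(x)[3]))
  invisible(x)
}

#' Reflect 3D points across the rig's mirror plane
#'
#' @param X n x 3 matrix of points (camera-frame mm).
#' @param rig A `camera_rig`.
#' @return n x 3 matrix of reflected points.
#' @export
reflect_points <- function(X, rig) {
  X <- as_points3(X)
  s <- X %*% rig$mirror_normal - rig$mirror_offset
  X - 2 * drop(s) %*% t(rig$mirror_normal)
}

#' Centre of the virtual (behind-mirror) camera
#'
#' The reflection of the real camera centre (the origin) across the mirror.
#'
#' @param rig A `camera_rig`.
#' @return Length-3 position (mm).
#' @export
virtual_camera_center <- function(rig) {
  drop(reflect_points(matrix(0, 1, 3), rig))
}

#' Pinhole projection with given intrinsics
#'
#' @param X n x 3 matrix of camera-frame points (mm); z must be positive.
#' @param K 3 x 3 intrinsic matrix.
#' @return n x 2 matrix of pixel coordinates; rows with non-positive depth
#'   are NA.
#' @export
project_pinhole <- function(X, K) {
  X <- as_points3(X)
  z <- X[, 3]
  uv <- cbind(K[1, 1] * X[, 1] / z + K[1, 3],
              K[2, 2] * X[, 2] / z + K[2, 3])
  uv[z <= 0, ] <- NA_real_
  uv
}

#' Project points into the direct and mirror views
#'
#' @param X n x 3 matrix of camera-frame points (mm).
#' @param rig A `camera_rig`.
#' @return List with `direct` and `mirror` n x 2 pixel matrices.
#' @export
project_to_views <- function(X, rig) {
  X <- as_points3(X)
  list(direct = project_pinhole(X, rig$K),
       mirror = project_pinhole(reflect_points(X, rig), rig$K))
}

# Pellet-frame <-> camera-frame conversion for the synthetic scene.
# Pellet frame: origin at the pellet; +z from the chamber toward the camera
# (paw advancement), +y downward, +x completing a right-handed triad.
pellet_frame_rotation <- function() {
  rbind(c(-1, 0, 0),
        c(0, 1, 0),
        c(0, 0, -1))
}

#' Map pellet-frame points to camera-frame points for a synthetic rig
#'
#' @param X n x 3 pellet-frame points (mm).
#' @param rig A `camera_rig`.
#' @return n x 3 camera-frame points (mm).
#' @export
pellet_to_camera <- function(X, rig) {
  X <- as_points3(X)
  R <- pellet_frame_rotation()
  sweep(X %*% R, 2, rig$pellet_position, "+")  # R^T = R here (symmetric)
}

as_points3 <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 3)
  if (ncol(X) != 3) stop("expected an n x 3 matrix of 3D points")
  X
}
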