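#' @useDynLib endogeo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median optimize quantile rnorm runif sd
#' @importFrom utils head tail
NULL

# Conventions (fixed once, used everywhere):
#  * right-handed camera frame, +z forward (optical axis), +x right, +y down;
#  * image origin top-left, x = column, y = row, pixel centres at integer
#    coordinates (0-based);
#  * world frame = first camera frame of a run;
#  * quaternions are scalar-first (w, x, y, z), camera-to-world:
#    X_world = R(q) %*% X_cam + r, composition q1 %x% q2 applies q2 first.

#' Stereo camera rig
#'
#' A rectified stereo rig: identical pinhole cameras separated by a pure
#' horizontal baseline, so corresponding points share an image row and
#' depth follows from disparity as \eqn{Z = f B / d}.
#'
#' @param focal_length_px focal length in pixels; length 1 (isotropic) or 2
#'   \code{c(fx, fy)}.
#' @param principal_point \code{c(cx, cy)} in pixels.
#' @param baseline_mm stereo baseline in mm (> 0).
#' @param image_size \code{c(width, height)} in pixels.
#' @return An object of class \code{camera_rig}.
#' @export
camera_rig <- function(focal_length_px, principal_point, baseline_mm,
                       image_size) {
  f <- as.numeric(focal_length_px)
  if (length(f) == 1) f <- c(f, f)
  stopifnot(length(f) == 2, all(f > 0), baseline_mm > 0,
            length(principal_point) == 2, length(image_size) == 2)
  structure(list(fx = f[1], fy = f[2],
                 cx = principal_point[1], cy = principal_point[2],
                 baseline_mm = as.numeric(baseline_mm),
                 width = as.integer(image_size[1]),
                 height = as.integer(image_size[2])),
            class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("Stereo rig: f = (%.1f, %.1f) px, c = (%.1f, %.1f) px, B = %.2f mm, %d x %d\n",
              x$fx, x$fy, x$cx, x$cy, x$baseline_mm, x$width, x$height))
  invisible(x)
}

#' Read a stereo calibration file
#'
#' YAML key/value calibration: either a single \code{f} or \code{fx}/\code{fy},
#' plus \code{cx}, \code{cy}, \code{baseline_mm}, \code{width}, \code{height}.
#'
#' @param path path to the YAML calibration file.
#' @return A [camera_rig()].
#' @export
read_calib <- function(path) {
  y <- yaml::read_yaml(path)
  f <- if (!is.null(y$f)) c(y$f, y$f) else c(y$fx, y$fy)
  camera_rig(f, c(y$cx, y$cy), y$baseline_mm, c(y$width, y$height))
}

#' Write a stereo calibration file
#' @param rig a [camera_rig()].
#' @param path output path.
#' @export
write_calib <- function(rig, path) {
  yaml::write_yaml(list(fx = rig$fx, fy = rig$fy, cx = rig$cx, cy = rig$cy,
                        baseline_mm = rig$baseline_mm,
                        width = rig$width, height = rig$height), path)
  invisible(path)
}

# ---- quaternion algebra (scalar-first) ----

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Quaternion from a rotation vector
#'
#' Converts an axis-angle rotation vector (angle = norm, radians) to a unit
#' quaternion; used by the constant-velocity prediction step.
#' @param v rotation vector (3).
#' @return unit quaternion (w, x, y, z).
#' @export
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(quat_normalize(c(1, v / 2)))
  c(cos(th / 2), sin(th / 2) * v / th)
}

quat_to_rotvec <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  s <- sqrt(sum(q[2:4]^2))
  if (s < 1e-12) return(2 * q[2:4])
  2 * atan2(s, q[1]) * q[2:4] / s
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion (w, x, y, z).
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_normalize(q)
}

#' Camera pose
#'
#' Position (mm, world frame) and camera-to-world unit quaternion.
#'
#' @param position 3-vector, mm.
#' @param orientation unit quaternion (w, x, y, z); normalised on entry.
#' @return An object of class \code{pose}.
#' @export
pose <- function(position = c(0, 0, 0), orientation = c(1, 0, 0, 0)) {
  stopifnot(length(position) == 3, length(orientation) == 4)
  structure(list(position = as.numeric(position),
                 orientation = quat_normalize(as.numeric(orientation))),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: r = (%.3f, %.3f, %.3f) mm, q = (%.4f, %.4f, %.4f, %.4f)\n",
              x$position[1], x$position[2], x$position[3],
              x$orientation[1], x$orientation[2], x$orientation[3],
              x$orientation[4]))
  invisible(x)
}

#' Compose two poses
#'
#' \code{pose_compose(a, b)} applies \code{b} in the frame of \code{a}:
#' the result maps b-frame coordinates to the world via \code{a}.
#' @param a,b poses.
#' @return a \code{pose}.
#' @export
pose_compose <- function(a, b) {
  Ra <- quat_to_rotmat(a$orientation)
  pose(a$position + as.numeric(Ra %*% b$position),
       quat_multiply(a$orientation, b$orientation))
}

#' Invert a pose
#' @param p a pose.
#' @return the inverse pose.
#' @export
pose_inverse <- function(p) {
  qi <- quat_conjugate(p$orientation)
  Ri <- quat_to_rotmat(qi)
  pose(-as.numeric(Ri %*% p$position), qi)
}

#' Transform points between camera and world frames
#'
#' @param points n x 3 matrix.
#' @param p a pose (camera-to-world).
#' @param inverse if \code{TRUE}, world-to-camera.
#' @return n x 3 matrix.
#' @export
transform_points <- function(points, p, inverse = FALSE) {
  points <- matrix(points, ncol = 3)
  R <- quat_to_rotmat(p$orientation)
  if (inverse) {
    sweep(points, 2, p$position) %*% R  # (X - r) %*% R == t(R^T (X - r))
  } else {
    points %*% t(R) + matrix(p$position, nrow(points), 3, byrow = TRUE)
  }
}

#' Stereo observation set
#'
#' Corresponding rectified keypoint pairs: left/right x coordinates on a
#' shared row; disparity \eqn{d = x_l - x_r} must be positive for a point at
#' finite depth.
#'
#' @param x_left,x_right x pixel coordinates (vectors).
#' @param y shared pixel row (vector).
#' @return data.frame with columns \code{x_left, x_right, y, disparity}.
#' @export
stereo_observation <- function(x_left, x_right, y) {
  data.frame(x_left = x_left, x_right = x_right, y = y,
             disparity = x_left - x_right)
}

#' Triangulate rectified stereo observations
#'
#' Depth from disparity on a rectified rig: \eqn{Z = f B / d}, with x and y
#' recovered by pinhole back-projection at that depth.  Observations with
#' disparity below \code{min_disparity} (near-infinity points, where the
#' depth error diverges) are rejected as \code{NA} rows.
#'
#' @param obs a [stereo_observation()] data.frame.
#' @param rig a [camera_rig()].
#' @param min_disparity minimum accepted disparity in px (default 0.5).
#' @return n x 3 matrix of camera-frame points (mm); rejected rows are NA.
#' @export
triangulate <- function(obs, rig, min_disparity = 0.5) {
  d <- obs$disparity
  ok <- is.finite(d) & d >= min_disparity
  Z <- ifelse(ok, rig$fx * rig$baseline_mm / d, NA_real_)
  X <- (obs$x_left - rig$cx) * Z / rig$fx
  Y <- (obs$y - rig$cy) * Z / rig$fy
  cbind(x = X, y = Y, z = Z)
}

#' Project world points into a camera
#'
#' Pinhole projection through the left or right camera of a rectified rig;
#' the right camera differs from the left by the baseline offset only.
#' Points at or behind the camera plane are flagged invisible.
#'
#' @param points_world n x 3 matrix of world points (mm).
#' @param p camera pose (camera-to-world).
#' @param rig a [camera_rig()].
#' @param camera \code{"left"} or \code{"right"}.
#' @param znear minimum camera-frame depth for visibility (mm).
#' @return data.frame with \code{x, y, depth, visible}.
#' @export
project_points <- function(points_world, p, rig, camera = c("left", "right"),
                           znear = 1e-6) {
  camera <- match.arg(camera)
  pc <- transform_points(points_world, p, inverse = TRUE)
  xs <- pc[, 1]
  if (camera == "right") xs <- xs - rig$baseline_mm
  z <- pc[, 3]
  visible <- is.finite(z) & z > znear
  px <- ifelse(visible, rig$fx * xs / z + rig$cx, NA_real_)
  py <- ifelse(visible, rig$fy * pc[, 2] / z + rig$cy, NA_real_)
  inside <- visible & px >= 0 & px <= rig$width - 1 & py >= 0 &
    py <= rig$height - 1
  data.frame(x = px, y = py, depth = ifelse(visible, z, NA_real_),
             visible = visible, in_image = inside)
}
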