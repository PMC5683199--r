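# Frame-to-frame camera pose estimation: constant-velocity prediction,
# guided re-projection search, and robust rigid alignment of corresponding
# 3D points (3-point RANSAC hypotheses + inlier refinement).

#' Camera motion state
#'
#' Pose plus linear/angular velocity (per frame) and optional accelerations
#' for the constant-velocity prediction model.  Accelerations default to
#' zero (the cited model's behaviour); they may be populated by
#' finite-differencing successive velocity estimates.
#'
#' @param pose a [pose()].
#' @param linear_velocity mm/frame (3-vector).
#' @param angular_velocity rad/frame rotation vector (3-vector).
#' @param linear_acceleration,angular_acceleration per-frame accelerations.
#' @param dt frame interval (frames; default 1).
#' @return object of class \code{motion_state}.
#' @export
motion_state <- function(pose = endogeo::pose(),
                         linear_velocity = c(0, 0, 0),
                         angular_velocity = c(0, 0, 0),
                         linear_acceleration = c(0, 0, 0),
                         angular_acceleration = c(0, 0, 0),
                         dt = 1) {
  structure(list(pose = pose,
                 linear_velocity = as.numeric(linear_velocity),
                 angular_velocity = as.numeric(angular_velocity),
                 linear_acceleration = as.numeric(linear_acceleration),
                 angular_acceleration = as.numeric(angular_acceleration),
                 dt = dt),
            class = "motion_state")
}

#' Predict the next camera pose
#'
#' Constant-velocity motion model: the position advances linearly,
#' \eqn{r_{t+1} = r_t + v_t \Delta t}; the orientation composes with the
#' quaternion of the rotation vector \eqn{\omega_t \Delta t},
#' \eqn{q_{t+1} = q_t \times q(\omega_t \Delta t)}; velocities advance by
#' the (by default zero) accelerations.
#'
#' @param state a [motion_state()].
#' @return list with the predicted \code{pose} and the updated
#'   \code{motion_state} (velocities advanced by the accelerations).
#' @export
predict_pose <- function(state) {
  dt <- state$dt
  v <- state$linear_velocity + state$linear_acceleration * dt
  w <- state$angular_velocity + state$angular_acceleration * dt
  p <- pose(state$pose$position + v * dt,
            quat_multiply(state$pose$orientation, quat_from_rotvec(w * dt)))
  st <- state
  st$linear_velocity <- v
  st$angular_velocity <- w
  list(pose = p, state = st)
}

#' Update a motion state from an estimated pose
#'
#' Re-estimates velocities by differencing the new and previous poses
#' (angular velocity in the body frame, matching the prediction's
#' right-composition); optionally estimates accelerations by differencing
#' the last two velocity estimates.
#'
#' @param state previous [motion_state()].
#' @param new_pose estimated pose at the new frame.
#' @param estimate_acceleration finite-difference accelerations (default
#'   \code{FALSE}: pure constant-velocity model).
#' @return updated \code{motion_state}.
#' @export
update_motion_state <- function(state, new_pose, estimate_acceleration = FALSE) {
  dt <- state$dt
  v_new <- (new_pose$position - state$pose$position) / dt
  dq <- quat_multiply(quat_conjugate(state$pose$orientation),
                      new_pose$orientation)
  w_new <- quat_to_rotvec(dq) / dt
  a <- c(0, 0, 0); al <- c(0, 0, 0)
  if (estimate_acceleration) {
    a <- (v_new - state$linear_velocity) / dt
    al <- (w_new - state$angular_velocity) / dt
  }
  motion_state(new_pose, v_new, w_new, a, al, dt)
}

#' Guided search windows from a predicted pose
#'
#' Re-projects map landmarks through the predicted pose; each visible
#' landmark yields a square search window of side \code{2 * radius_px}
#' centred on its predicted pixel, restricting descriptor matching and
#' cutting the search cost.  Landmarks behind the camera or out of view
#' yield no window.
#'
#' @param predicted predicted [pose()].
#' @param landmarks n x 3 matrix of landmark world positions.
#' @param rig a [camera_rig()].
#' @param radius_px half window side in px (default 15).
#' @return data.frame \code{landmark, cx, cy, radius} (one row per visible
#'   landmark).
#' @export
guided_search_regions <- function(predicted, landmarks, rig, radius_px = 15) {
  pr <- project_points(landmarks, predicted, rig, "left")
  vis <- which(pr$visible & pr$in_image)
  data.frame(landmark = vis, cx = pr$x[vis], cy = pr$y[vis],
             radius = rep(radius_px, length(vis)))
}

#' Minimal rigid alignment of paired 3D points
#'
#' Closed-form least-squares rigid transform (Kabsch/SVD) mapping \code{B}
#' onto \code{A}: minimises \eqn{\sum_i \| a_i - (R b_i + T) \|}.  With the
#' correspondence sets of two consecutive frames (\code{A} at time t,
#' \code{B} at time t+1) the returned (R, T) is the relative pose of camera
#' t+1 expressed in frame t.
#'
#' @param A,B n x 3 matrices of paired points (n >= 3, non-collinear).
#' @return list \code{rotation} (3x3, det +1), \code{translation} (3),
#'   or \code{NULL} for a degenerate (collinear) configuration.
#' @export
solve_rigid <- function(A, B) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 3)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  # collinearity: second singular value ~ 0 leaves the rotation undetermined
  if (s$d[2] < 1e-9 * max(s$d[1], 1e-300)) return(NULL)
  list(rotation = R, translation = as.numeric(ca - R %*% cb))
}

rigid_residuals <- function(tf, A, B) {
  pred <- B %*% t(tf$rotation) + matrix(tf$translation, nrow(B), 3, byrow = TRUE)
  sqrt(rowSums((A - pred)^2))
}

#' Robust rigid alignment by 3-point RANSAC
#'
#' Repeatedly samples three correspondences, solves the minimal rigid
#' alignment, and scores all pairs by their 3D residual against
#' \code{inlier_threshold}; the transform of the best hypothesis is refined
#' on its full inlier set (and the refinement never increases the residual
#' objective).  The iteration count adapts to the observed inlier ratio via
#' the standard RANSAC confidence formula.
#'
#' @param A,B n x 3 paired points (\code{B} is mapped onto \code{A}).
#' @param inlier_threshold 3D residual threshold in mm (default 1.0).
#' @param max_iterations cap on hypotheses (default 500).
#' @param confidence adaptive-termination confidence (default 0.99).
#' @param min_inliers below this the frame is declared tracking-lost.
#' @return list \code{transform}, \code{inliers} (logical), \code{ok};
#'   \code{ok = FALSE} signals tracking loss.  Uses the R RNG (seed with
#'   \code{set.seed} for reproducibility).
#' @export
estimate_rigid_ransac <- function(A, B, inlier_threshold = 1.0,
                                  max_iterations = 500, confidence = 0.99,
                                  min_inliers = 10) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  n <- nrow(A)
  if (n < 3) return(list(transform = NULL, inliers = logical(n), ok = FALSE))
  best <- NULL; best_n <- -1L; best_res <- Inf
  needed <- max_iterations
  it <- 0
  while (it < min(needed, max_iterations)) {
    it <- it + 1
    idx <- sample.int(n, 3)
    tf <- solve_rigid(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
    if (is.null(tf)) next
    r <- rigid_residuals(tf, A, B)
    inl <- r <= inlier_threshold
    ni <- sum(inl)
    score <- sum(pmin(r, inlier_threshold))
    if (ni > best_n || (ni == best_n && score < best_res)) {
      best <- list(tf = tf, inliers = inl)
      best_n <- ni
      best_res <- score
      p_good <- min(max((ni / n)^3, 0), 1 - 1e-12)
      needed <- if (p_good < 1e-9) max_iterations else
        min(max_iterations, ceiling(log(1 - confidence) / log1p(-p_good)))
    }
  }
  if (is.null(best) || best_n < max(min_inliers, 3)) {
    return(list(transform = NULL, inliers = logical(n), ok = FALSE))
  }
  refined <- solve_rigid(A[best$inliers, , drop = FALSE],
                         B[best$inliers, , drop = FALSE])
  if (is.null(refined)) refined <- best$tf
  # monotone refinement: keep whichever transform has the lower objective
  obj <- function(tf) sum(rigid_residuals(tf, A[best$inliers, , drop = FALSE],
                                          B[best$inliers, , drop = FALSE]))
  if (obj(refined) > obj(best$tf)) refined <- best$tf
  r <- rigid_residuals(refined, A, B)
  list(transform = refined, inliers = r <= inlier_threshold, ok = TRUE)
}

#' Write a camera trajectory in TUM format
#'
#' One line per pose: \code{timestamp tx ty tz qx qy qz qw} (position in mm,
#' quaternion scalar-last as in the TUM convention).
#'
#' @param poses list of [pose()] objects.
#' @param path output file.
#' @param timestamps numeric vector (defaults to 0, 1, 2, ...).
#' @export
write_trajectory_tum <- function(poses, path, timestamps = NULL) {
  if (is.null(timestamps)) timestamps <- seq_along(poses) - 1
  lines <- vapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    q <- p$orientation
    sprintf("%.6f %.9f %.9f %.9f %.9f %.9f %.9f %.9f", timestamps[i],
            p$position[1], p$position[2], p$position[3],
            q[2], q[3], q[4], q[1])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TUM-format trajectory
#' @param path file path.
#' @return list of [pose()] objects (timestamps as attribute).
#' @export
read_trajectory_tum <- function(path) {
  m <- as.matrix(utils::read.table(path))
  poses <- lapply(seq_len(nrow(m)), function(i) {
    pose(m[i, 2:4], c(m[i, 8], m[i, 5:7]))
  })
  attr(poses, "timestamps") <- m[, 1]
  poses
}
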