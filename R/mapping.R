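# Keyframe management and Huber-robust bundle adjustment.
#
# BA jointly refines keyframe poses and landmark positions by minimising
# the total Huber-robust reprojection cost
#   sum_{i,j} rho_h(|| p_ij - CamProj(KF_i, P_j) ||)
# with a Levenberg-Marquardt loop over sparse normal equations (Matrix).
# The gauge is fixed by anchoring the first keyframe pose.

#' Keyframe
#'
#' A stored snapshot: pose plus the (landmark id, left-image pixel)
#' observations that anchor map optimisation.
#'
#' @param id integer keyframe id.
#' @param pose camera [pose()].
#' @param observations data.frame \code{landmark, x, y} (0-based pixels).
#' @param frame source frame index.
#' @param descriptors optional observation-aligned descriptor matrix.
#' @return object of class \code{keyframe}.
#' @export
keyframe <- function(id, pose, observations, frame = NA_integer_,
                     descriptors = NULL) {
  stopifnot(all(c("landmark", "x", "y") %in% names(observations)))
  structure(list(id = id, pose = pose, observations = observations,
                 frame = frame, descriptors = descriptors),
            class = "keyframe")
}

#' Keyframe insertion criterion
#'
#' A new keyframe is inserted when the tracked frame shares fewer than
#' \code{overlap_threshold} (80 percent) of its keypoints with the last
#' keyframe AND its total keypoint count exceeds \code{min_count} (50).
#' The overlap fraction uses the smaller of the two keypoint counts as
#' denominator.
#'
#' @param current_ids landmark ids tracked in the current frame.
#' @param keyframe_ids landmark ids observed by the last keyframe.
#' @param overlap_threshold shared fraction below which a keyframe is due.
#' @param min_count required total keypoint count (exclusive bound).
#' @return logical.
#' @export
should_insert_keyframe <- function(current_ids, keyframe_ids,
                                   overlap_threshold = 0.80, min_count = 50) {
  n_cur <- length(current_ids)
  n_kf <- length(keyframe_ids)
  if (n_cur == 0 || n_kf == 0) return(n_cur > min_count)
  shared <- length(intersect(current_ids, keyframe_ids)) / min(n_cur, n_kf)
  shared < overlap_threshold && n_cur > min_count
}

#' Huber robust loss
#'
#' \eqn{\rho_h(e) = e^2/2} for \eqn{e \le \delta}, linear
#' \eqn{\delta(e - \delta/2)} beyond; the IRLS weight is
#' \eqn{\rho_h'(e)/e}.
#'
#' @param e non-negative residual norms.
#' @param delta transition point (px), > 0.
#' @return \code{huber_rho}: loss values; \code{huber_weight}: IRLS weights.
#' @export
huber_rho <- function(e, delta = 2.0) {
  stopifnot(delta > 0)
  ifelse(e <= delta, e^2 / 2, delta * (e - delta / 2))
}

#' @rdname huber_rho
#' @export
huber_weight <- function(e, delta = 2.0) {
  stopifnot(delta > 0)
  ifelse(e <= delta, 1, delta / pmax(e, 1e-12))
}

# stack all observations of a BA problem into flat vectors; x_right (the
# right-camera x of a stereo observation) is NA for monocular observations
ba_flatten <- function(keyframes) {
  kf_idx <- integer(0); lm_idx <- integer(0)
  u <- numeric(0); v <- numeric(0); ur <- numeric(0)
  for (i in seq_along(keyframes)) {
    ob <- keyframes[[i]]$observations
    kf_idx <- c(kf_idx, rep.int(i, nrow(ob)))
    lm_idx <- c(lm_idx, ob$landmark)
    u <- c(u, ob$x); v <- c(v, ob$y)
    ur <- c(ur, if ("x_right" %in% names(ob)) ob$x_right else
      rep(NA_real_, nrow(ob)))
  }
  list(kf = kf_idx, lm = lm_idx, u = u, v = v, ur = ur)
}

# residuals (observed - predicted) and camera-frame coords for all obs;
# stereo observations contribute a third, right-camera x component, which
# anchors landmark depth inside the window
ba_residuals <- function(obs, poses, landmarks, rig) {
  n <- length(obs$u)
  ru <- numeric(n); rv <- numeric(n); rr <- rep(NA_real_, n)
  Xc <- matrix(NA_real_, n, 3)
  for (i in unique(obs$kf)) {
    sel <- obs$kf == i
    P <- landmarks[obs$lm[sel], , drop = FALSE]
    pc <- transform_points(P, poses[[i]], inverse = TRUE)
    Xc[sel, ] <- pc
    ru[sel] <- obs$u[sel] - (rig$fx * pc[, 1] / pc[, 3] + rig$cx)
    rv[sel] <- obs$v[sel] - (rig$fy * pc[, 2] / pc[, 3] + rig$cy)
    rr[sel] <- obs$ur[sel] -
      (rig$fx * (pc[, 1] - rig$baseline_mm) / pc[, 3] + rig$cx)
  }
  rr[is.na(obs$ur)] <- NA_real_
  norm2 <- ru^2 + rv^2 + ifelse(is.na(rr), 0, rr^2)
  list(ru = ru, rv = rv, rr = rr, Xc = Xc, norm = sqrt(norm2))
}

#' Bundle adjustment
#'
#' Levenberg-Marquardt minimisation of the total Huber-robust reprojection
#' cost over keyframe poses and landmark positions.  Only landmarks observed
#' by at least two keyframes are optimised; the first keyframe pose is held
#' fixed to anchor the gauge.  The robust cost is non-increasing across
#' accepted iterations.
#'
#' @param keyframes list of [keyframe()] objects (>= 2).
#' @param landmarks n x 3 matrix of landmark world positions (mm), indexed
#'   by the observation \code{landmark} column.
#' @param rig a [camera_rig()].
#' @param huber_delta Huber transition point in px (default 2;
#'   \code{Inf} gives plain least squares).
#' @param max_iterations LM iteration cap.
#' @param tol relative cost-decrease convergence tolerance.
#' @return list \code{keyframes}, \code{landmarks}, \code{cost_trace}
#'   (robust cost after each accepted iterate, starting with the input
#'   configuration), \code{converged}.
#' @export
bundle_adjust <- function(keyframes, landmarks, rig, huber_delta = 2.0,
                          max_iterations = 25, tol = 1e-10) {
  stopifnot(length(keyframes) >= 2)
  obs <- ba_flatten(keyframes)
  n_obs <- length(obs$u)
  stopifnot(n_obs > 0)
  lm_tab <- table(obs$lm)
  free_lms <- as.integer(names(lm_tab)[lm_tab >= 2])
  lm_col <- match(obs$lm, free_lms)  # NA when the landmark is held fixed
  n_kf <- length(keyframes)
  n_free_kf <- n_kf - 1
  n_free_lm <- length(free_lms)
  n_par <- 6 * n_free_kf + 3 * n_free_lm

  poses <- lapply(keyframes, `[[`, "pose")
  lms <- landmarks
  hub <- function(e) {
    if (is.infinite(huber_delta)) sum(e^2 / 2) else sum(huber_rho(e, huber_delta))
  }
  res <- ba_residuals(obs, poses, lms, rig)
  cost <- hub(res$norm)
  trace <- cost
  lambda <- 1e-4
  converged <- FALSE

  if (n_par == 0) {
    return(list(keyframes = keyframes, landmarks = lms, cost_trace = trace,
                converged = TRUE))
  }

  stereo_obs <- which(!is.na(obs$ur))
  srow <- rep(NA_integer_, n_obs)
  srow[stereo_obs] <- 2 * n_obs + seq_along(stereo_obs)
  n_rows <- 2 * n_obs + length(stereo_obs)
  B <- rig$baseline_mm

  for (iter in seq_len(max_iterations)) {
    w <- if (is.infinite(huber_delta)) rep(1, n_obs) else
      huber_weight(res$norm, huber_delta)
    # Jacobian triplets of the *predicted* pixel wrt parameters
    x <- res$Xc[, 1]; y <- res$Xc[, 2]; z <- res$Xc[, 3]
    fx <- rig$fx; fy <- rig$fy
    du_dXc <- cbind(fx / z, 0, -fx * x / z^2)
    dv_dXc <- cbind(0, fy / z, -fy * y / z^2)
    dr_dXc <- cbind(fx / z, 0, -fx * (x - B) / z^2)  # right-camera x
    ti <- integer(0); tj <- integer(0); tv <- numeric(0)
    add <- function(rows, cols, vals) {
      ti <<- c(ti, rows); tj <<- c(tj, cols); tv <<- c(tv, vals)
    }
    for (i in seq_len(n_kf)) {
      sel <- which(obs$kf == i)
      if (length(sel) == 0) next
      R <- quat_to_rotmat(poses[[i]]$orientation)
      ssel <- sel[!is.na(srow[sel])]
      if (i > 1) {
        base <- 6 * (i - 2)
        xs <- x[sel]; ys <- y[sel]; zs <- z[sel]
        # rotation-increment block (local so(3) right-composition)
        du <- cbind(fx * xs * ys / zs^2, -fx * (1 + xs^2 / zs^2), fx * ys / zs)
        dv <- cbind(fy * (1 + ys^2 / zs^2), -fy * xs * ys / zs^2, -fy * xs / zs)
        for (k in 1:3) {
          add(2 * sel - 1, rep(base + k, length(sel)), du[, k])
          add(2 * sel, rep(base + k, length(sel)), dv[, k])
        }
        # translation block: dXc/dt = -R^T
        duT <- -du_dXc[sel, , drop = FALSE] %*% t(R)
        dvT <- -dv_dXc[sel, , drop = FALSE] %*% t(R)
        for (k in 1:3) {
          add(2 * sel - 1, rep(base + 3 + k, length(sel)), duT[, k])
          add(2 * sel, rep(base + 3 + k, length(sel)), dvT[, k])
        }
        if (length(ssel) > 0) {
          xs <- x[ssel]; ys <- y[ssel]; zs <- z[ssel]
          dr <- cbind(fx * (xs - B) * ys / zs^2,
                      -fx * (1 + (xs - B) * xs / zs^2),
                      fx * ys / zs)
          drT <- -dr_dXc[ssel, , drop = FALSE] %*% t(R)
          for (k in 1:3) {
            add(srow[ssel], rep(base + k, length(ssel)), dr[, k])
            add(srow[ssel], rep(base + 3 + k, length(ssel)), drT[, k])
          }
        }
      }
      # landmark block: dXc/dP = R^T
      fsel <- sel[!is.na(lm_col[sel])]
      if (length(fsel) > 0) {
        duP <- du_dXc[fsel, , drop = FALSE] %*% t(R)
        dvP <- dv_dXc[fsel, , drop = FALSE] %*% t(R)
        cols0 <- 6 * n_free_kf + 3 * (lm_col[fsel] - 1)
        for (k in 1:3) {
          add(2 * fsel - 1, cols0 + k, duP[, k])
          add(2 * fsel, cols0 + k, dvP[, k])
        }
        fs <- fsel[!is.na(srow[fsel])]
        if (length(fs) > 0) {
          drP <- dr_dXc[fs, , drop = FALSE] %*% t(R)
          cols0 <- 6 * n_free_kf + 3 * (lm_col[fs] - 1)
          for (k in 1:3) add(srow[fs], cols0 + k, drP[, k])
        }
      }
    }
    J <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                              dims = c(n_rows, n_par))
    sw <- sqrt(c(rep(w, each = 2), w[stereo_obs]))
    r <- c(as.numeric(rbind(res$ru, res$rv)), res$rr[stereo_obs])
    Jw <- J * sw
    rw <- r * sw
    H <- Matrix::crossprod(Jw)
    g <- Matrix::crossprod(Jw, rw)
    accepted <- FALSE
    for (try in 1:8) {
      Hd <- H + lambda * Matrix::Diagonal(n_par, pmax(Matrix::diag(H), 1e-8))
      delta <- tryCatch(as.numeric(Matrix::solve(Hd, g)),
                        error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        lambda <- lambda * 10
        next
      }
      new_poses <- poses
      for (i in 2:n_kf) {
        base <- 6 * (i - 2)
        dth <- delta[base + 1:3]
        dtr <- delta[base + 4:6]
        p <- new_poses[[i]]
        new_poses[[i]] <- pose(p$position + dtr,
                               quat_multiply(p$orientation,
                                             quat_from_rotvec(dth)))
      }
      new_lms <- lms
      if (n_free_lm > 0) {
        dP <- matrix(delta[6 * n_free_kf + seq_len(3 * n_free_lm)],
                     ncol = 3, byrow = TRUE)
        new_lms[free_lms, ] <- new_lms[free_lms, , drop = FALSE] + dP
      }
      new_res <- ba_residuals(obs, new_poses, new_lms, rig)
      new_cost <- hub(new_res$norm)
      if (is.finite(new_cost) && new_cost <= cost) {
        poses <- new_poses; lms <- new_lms
        accepted <- TRUE
        improved <- (cost - new_cost) <= tol * max(cost, 1e-300)
        cost <- new_cost
        res <- new_res
        trace <- c(trace, cost)
        lambda <- max(lambda / 3, 1e-9)
        if (improved) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) {
      if (!accepted) converged <- TRUE  # at a (robust) local minimum
      break
    }
  }
  for (i in seq_along(keyframes)) keyframes[[i]]$pose <- poses[[i]]
  list(keyframes = keyframes, landmarks = lms, cost_trace = trace,
       converged = converged)
}

#' Write a point cloud as ASCII PLY
#'
#' @param points n x 3 matrix (mm).
#' @param path output file.
#' @param normals optional n x 3 normal matrix.
#' @export
write_ply_points <- function(points, path, normals = NULL) {
  n <- nrow(points)
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  if (!is.null(normals)) {
    hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  }
  hdr <- c(hdr, "end_header")
  body <- if (is.null(normals)) {
    sprintf("%.6f %.6f %.6f", points[, 1], points[, 2], points[, 3])
  } else {
    sprintf("%.6f %.6f %.6f %.6f %.6f %.6f", points[, 1], points[, 2],
            points[, 3], normals[, 1], normals[, 2], normals[, 3])
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
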