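# Dense disparity estimation per keyframe: patch-based ZNCC cost volume,
# winner-takes-all selection, and Huber-L1 variational smoothing.
#
# Sign convention (asserted in tests): the ZNCC of Eq-style patch
# correlation is a similarity in [-1, 1]; the volume stores cost = -ZNCC so
# that lower = better everywhere downstream.

#' ZNCC patch correlation
#'
#' Zero-mean normalised cross-correlation of two equal-size patches:
#' invariant to affine intensity changes (gain > 0 and offset), which is why
#' it suits endoscopic illumination.  Returns \code{NA} for a zero-variance
#' patch (undefined correlation) rather than propagating NaN.
#'
#' @param left_patch,right_patch numeric matrices of equal size.
#' @return correlation in [-1, 1], or \code{NA}.
#' @export
zncc <- function(left_patch, right_patch) {
  stopifnot(all(dim(left_patch) == dim(right_patch)))
  a <- as.numeric(left_patch) - mean(left_patch)
  b <- as.numeric(right_patch) - mean(right_patch)
  na <- sum(a^2); nb <- sum(b^2)
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  max(-1, min(1, sum(a * b) / sqrt(na * nb)))
}

#' Build a ZNCC cost volume
#'
#' For every pixel p of the left image and disparity d in
#' \code{d_range}, the cost is the negated ZNCC between the patch centred on
#' p and the patch centred on p shifted left by d in the right image.
#' Border pixels and windows leaving either image are masked \code{NA}, as
#' are zero-variance patches.
#'
#' @param left,right rectified grayscale images (0-255 matrices).
#' @param d_range integer disparity range \code{c(d_min, d_max)}.
#' @param patch_radius half patch side (default 3, a 7x7 neighbourhood).
#' @return object of class \code{cost_volume}: array \code{cost}
#'   (h x w x n_d), \code{d_min}, \code{d_max}, \code{patch_radius}.
#' @export
build_cost_volume <- function(left, right, d_range = c(1, 64),
                              patch_radius = 3) {
  L <- as_gray(left); R <- as_gray(right)
  stopifnot(all(dim(L) == dim(R)), d_range[1] <= d_range[2])
  vol <- zncc_volume_cpp(L, R, as.integer(d_range[1]), as.integer(d_range[2]),
                         as.integer(patch_radius))
  structure(list(cost = vol, d_min = as.integer(d_range[1]),
                 d_max = as.integer(d_range[2]),
                 patch_radius = as.integer(patch_radius)),
            class = "cost_volume")
}

#' Winner-takes-all disparity selection
#'
#' Per-pixel argmin of the cost volume; ties break toward the smaller
#' disparity.  Optionally refines the winner by fitting a parabola through
#' the three costs around it (sub-pixel disparity).  Pixels with no finite
#' cost are invalid.
#'
#' @param volume a [build_cost_volume()] result.
#' @param subpixel logical (default \code{TRUE}).
#' @return object of class \code{disparity_map}: \code{disparity} matrix
#'   (px, \code{NA} where invalid) and logical \code{valid} mask.
#' @export
winner_takes_all <- function(volume, subpixel = TRUE) {
  dims <- dim(volume$cost)
  res <- wta_cpp(volume$cost, dims[1], dims[2], volume$d_min, subpixel)
  structure(list(disparity = res$disparity, valid = res$valid,
                 d_min = volume$d_min, d_max = volume$d_max),
            class = "disparity_map")
}

# cost volume flattened to (h*w) x nd with NA replaced by the worst ZNCC
# cost, so the data term never rewards invalid pixels
flatten_cost <- function(volume) {
  dims <- dim(volume$cost)
  M <- matrix(volume$cost, dims[1] * dims[2], dims[3])
  M[!is.finite(M)] <- 1
  M
}

# linear interpolation of the flattened volume at fractional disparity u
sample_cost_flat <- function(M, d_min, d_max, u) {
  nd <- ncol(M)
  uc <- pmin(pmax(as.numeric(u), d_min), d_max)
  k0 <- pmin(floor(uc - d_min) + 1, nd - 1)
  frac <- uc - (d_min + k0 - 1)
  npx <- nrow(M)
  c0 <- M[(k0 - 1) * npx + seq_len(npx)]
  c1 <- M[k0 * npx + seq_len(npx)]
  (1 - frac) * c0 + frac * c1
}

# sample the cost volume at fractional disparity u (linear interpolation
# along d, clamped to the valid range)
sample_cost <- function(volume, u) {
  M <- flatten_cost(volume)
  matrix(sample_cost_flat(M, volume$d_min, volume$d_max, u),
         dim(volume$cost)[1], dim(volume$cost)[2])
}

# Huber penalty of the forward-difference disparity gradient plus the
# data term lambda * C(p, u(p)); the energy smooth_disparity descends.
huber_l1_energy <- function(volume, u, valid, lambda, eps, gx, gy,
                            Mflat = NULL) {
  if (is.null(Mflat)) Mflat <- flatten_cost(volume)
  dux <- cbind(u[, -1] - u[, -ncol(u)], 0)
  duy <- rbind(u[-1, ] - u[-nrow(u), ], 0)
  hub <- function(t) {
    a <- abs(t)
    ifelse(a <= eps, t^2 / (2 * eps), a - eps / 2)
  }
  sm <- sum(gx * hub(dux)) + sum(gy * hub(duy))
  dat <- sample_cost_flat(Mflat, volume$d_min, volume$d_max, u)
  sm + lambda * sum(dat[as.vector(valid)])
}

#' Huber-L1 variational disparity smoothing
#'
#' Descends the energy
#' \deqn{E(u) = \sum_p g_p H_\epsilon(\nabla u(p)) + \lambda C(p, u(p))}
#' (Huber-regularised disparity gradient plus the interpolated matching
#' cost) from the winner-takes-all initialisation by projected gradient
#' descent with backtracking, so the energy is non-increasing by
#' construction.  The per-edge weights \eqn{g_p = \exp(-\beta |\nabla I|)}
#' preserve disparity edges where the image gradient is strong.
#'
#' @param volume a [build_cost_volume()] result.
#' @param wta a [winner_takes_all()] disparity map (the initialisation).
#' @param lambda data-term weight (default 1).
#' @param eps Huber transition of the gradient penalty, px (default 0.1).
#' @param beta edge-weight decay per unit image gradient (default 0.05).
#' @param iterations gradient steps (default 60).
#' @param image optional left image for the edge weights.
#' @return a \code{disparity_map} with the smoothed field and the achieved
#'   \code{energy} (attribute \code{energy_trace} holds initial and final).
#' @export
smooth_disparity <- function(volume, wta, lambda = 1.0, eps = 0.1,
                             beta = 0.05, iterations = 60, image = NULL) {
  u <- wta$disparity
  valid <- wta$valid & is.finite(u)
  if (!any(valid)) return(wta)
  u_work <- u
  u_work[!valid] <- mean(u[valid])  # inpaint invalids for smoothing only
  gx <- matrix(1, nrow(u), ncol(u)); gy <- gx
  if (!is.null(image)) {
    I <- as_gray(image)
    ix <- cbind(abs(I[, -1] - I[, -ncol(I)]), 0)
    iy <- rbind(abs(I[-1, ] - I[-nrow(I), ]), 0)
    gx <- exp(-beta * ix); gy <- exp(-beta * iy)
  }
  dims <- dim(volume$cost)
  res <- huber_l1_smooth_cpp(volume$cost, dims[1], dims[2],
                             volume$d_min, volume$d_max,
                             u_work, valid, gx, gy, lambda, eps,
                             as.integer(iterations))
  out <- wta
  out$disparity[valid] <- res$u[valid]
  attr(out, "energy_trace") <- c(initial = res$energy_initial,
                                 final = res$energy_final)
  out
}

#' Speckle-filter a disparity map
#'
#' Invalidates pixels whose disparity deviates from the local window median
#' by more than \code{tol} px.  Isolated false matches (repetitive texture,
#' saturated highlights) survive both winner-takes-all and variational
#' smoothing; this removes them before back-projection.
#'
#' @param disp a \code{disparity_map}.
#' @param radius window radius in px (default 2, a 5x5 window).
#' @param tol allowed deviation from the window median in px (default 2).
#' @return the filtered \code{disparity_map}.
#' @export
filter_disparity_speckles <- function(disp, radius = 2, tol = 2) {
  res <- median_filter_cpp(disp$disparity, disp$valid,
                           as.integer(radius), tol)
  disp$disparity <- res$disparity
  disp$valid <- res$valid
  disp
}

#' Gate a disparity map on matching quality
#'
#' Two standard validity gates applied before back-projection: (a) the full
#' disparity range must have been testable at the pixel — columns within
#' \code{d_max + patch_radius} of the left image border can only score low
#' disparities and produce confident-looking wrong winners in half-occluded
#' regions; (b) the correlation at the selected disparity must reach
#' \code{min_zncc}.
#'
#' @param volume the [build_cost_volume()] the map came from.
#' @param disp a \code{disparity_map}.
#' @param min_zncc minimum winner correlation in [-1, 1] (default 0.9).
#' @param full_range_only drop the truncated-range left margin (default
#'   \code{TRUE}).
#' @return the gated \code{disparity_map}.
#' @export
filter_disparity_quality <- function(volume, disp, min_zncc = 0.9,
                                     full_range_only = TRUE) {
  bad <- !disp$valid
  if (full_range_only) {
    margin <- volume$d_max + volume$patch_radius
    bad[, seq_len(min(ncol(bad), margin))] <- TRUE
  }
  if (min_zncc > -1) {
    wc <- sample_cost(volume, disp$disparity)  # cost = -zncc
    bad <- bad | !is.finite(wc) | (-wc < min_zncc)
  }
  disp$valid[bad] <- FALSE
  disp$disparity[bad] <- NA_real_
  disp
}

#' Back-project a disparity map to a camera-frame point cloud
#'
#' Applies the stereo depth relation \eqn{Z = f B / d} densely: every valid
#' pixel yields a camera-frame 3D point; invalid pixels are skipped.
#'
#' @param disp a \code{disparity_map}.
#' @param rig a [camera_rig()].
#' @param min_disparity disparities below this are skipped (default 0.5).
#' @param stride pixel subsampling stride (default 1 = every pixel).
#' @return list \code{points} (n x 3 mm), \code{pixel} (n x 2, 0-based x, y).
#' @export
disparity_to_points <- function(disp, rig, min_disparity = 0.5, stride = 1) {
  d <- disp$disparity
  h <- nrow(d); w <- ncol(d)
  rows <- seq(1, h, by = stride)
  cols <- seq(1, w, by = stride)
  ds <- d[rows, cols, drop = FALSE]
  vs <- disp$valid[rows, cols, drop = FALSE] & is.finite(ds) &
    ds >= min_disparity
  idx <- which(vs, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(points = matrix(numeric(0), 0, 3),
                pixel = matrix(numeric(0), 0, 2)))
  }
  px <- cols[idx[, 2]] - 1
  py <- rows[idx[, 1]] - 1
  dd <- ds[idx]
  Z <- rig$fx * rig$baseline_mm / dd
  X <- (px - rig$cx) * Z / rig$fx
  Y <- (py - rig$cy) * Z / rig$fy
  list(points = cbind(x = X, y = Y, z = Z), pixel = cbind(x = px, y = py))
}

#' Write a disparity map as a scaled 16-bit TIFF with a YAML sidecar
#'
#' Disparities are scaled by \code{scale} (default 256) and stored as
#' 16-bit unsigned samples; the sidecar records the scale factor and the
#' invalid value (0).
#'
#' @param disp a \code{disparity_map}.
#' @param path output \code{.tif} path; the sidecar is \code{path.yaml}.
#' @param scale disparity-to-integer scale factor.
#' @export
write_disparity <- function(disp, path, scale = 256) {
  d <- disp$disparity
  d[!disp$valid | !is.finite(d)] <- 0
  img <- pmin(d * scale, 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  yaml::write_yaml(list(scale = scale, invalid = 0), paste0(path, ".yaml"))
  invisible(path)
}

#' Read a disparity map written by [write_disparity()]
#' @param path the \code{.tif} path.
#' @return a \code{disparity_map}.
#' @export
read_disparity <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  img <- tiff::readTIFF(path)
  d <- img * 65535 / meta$scale
  valid <- d > 0
  d[!valid] <- NA_real_
  structure(list(disparity = d, valid = valid,
                 d_min = NA_integer_, d_max = NA_integer_),
            class = "disparity_map")
}
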