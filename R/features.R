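# Keypoint detection, stereo matching and specular filtering.
#
# Detection is a FAST-style segment test with an oriented, BRIEF-style
# 256-bit binary descriptor computed over an image pyramid (see src/).
# Stereo correspondence is mutual-best Hamming matching gated by the
# rectified epipolar geometry (same row within a tolerance) and a positive
# minimum disparity, with optional 1D ZNCC sub-pixel refinement.

#' Default feature-detection parameters
#'
#' @param n_features maximum keypoints kept per image.
#' @param threshold FAST intensity threshold (0-255 scale).
#' @param n_levels pyramid levels.
#' @param scale_factor pyramid scale step.
#' @param max_hamming maximum Hamming distance for an accepted match (of 256).
#' @param ratio best/second-best distance ratio gate.
#' @param row_tolerance epipolar row tolerance in px.
#' @param min_disparity minimum accepted disparity in px.
#' @param min_matches matches below this flag the frame untrackable.
#' @param subpixel refine disparity by 1D ZNCC parabola fit.
#' @return a named list of parameters.
#' @export
feature_params <- function(n_features = 1000, threshold = 10, n_levels = 3,
                           scale_factor = 1.2, max_hamming = 64, ratio = 0.9,
                           row_tolerance = 2, min_disparity = 0.5,
                           min_matches = 20, subpixel = TRUE) {
  list(n_features = n_features, threshold = threshold, n_levels = n_levels,
       scale_factor = scale_factor, max_hamming = max_hamming, ratio = ratio,
       row_tolerance = row_tolerance, min_disparity = min_disparity,
       min_matches = min_matches, subpixel = subpixel)
}

#' Convert an image to a grayscale intensity matrix
#'
#' Accepts a numeric matrix (returned unchanged, rescaled to 0-255 if in
#' [0,1]) or an RGB(A) array, converted with Rec. 601 luminance weights.
#'
#' @param img matrix or 3D array.
#' @return numeric matrix, intensities in 0-255, rows = image rows.
#' @export
as_gray <- function(img) {
  if (is.array(img) && length(dim(img)) == 3) {
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img <- as.matrix(img)
  if (max(img, na.rm = TRUE) <= 1) img <- img * 255
  img
}

#' Detect keypoints and binary descriptors in one image
#'
#' @param image grayscale matrix (0-255) or RGB array.
#' @param params a [feature_params()] list.
#' @return list with \code{keypoints} (data.frame x, y, score, angle, level,
#'   intensity; 0-based pixel coordinates) and \code{descriptors}
#'   (n x 32 integer matrix of bytes).
#' @export
detect_features <- function(image, params = feature_params()) {
  img <- as_gray(image)
  res <- detect_orb_cpp(img, params$n_features, params$threshold,
                        params$n_levels, params$scale_factor)
  list(keypoints = data.frame(x = res$x, y = res$y, score = res$score,
                              angle = res$angle, level = res$level,
                              intensity = res$intensity),
       descriptors = res$descriptor)
}

# 1D sub-pixel disparity refinement: ZNCC of a patch around the left
# keypoint against right patches at integer disparities d-1, d, d+1,
# then a parabola fit through the three correlations.
refine_disparity_subpixel <- function(left, right, xl, y, d, radius = 4) {
  h <- nrow(left); w <- ncol(left)
  n <- length(xl)
  out <- as.numeric(d)
  for (i in seq_len(n)) {
    xi <- round(xl[i]); yi <- round(y[i]); di <- round(d[i])
    if (xi - radius < 0 || xi + radius > w - 1 ||
        yi - radius < 0 || yi + radius > h - 1) next
    xr <- xi - di
    if (xr - radius - 1 < 0 || xr + radius + 1 > w - 1) next
    lp <- left[(yi - radius):(yi + radius) + 1, (xi - radius):(xi + radius) + 1]
    lv <- as.numeric(lp) - mean(lp)
    ln <- sqrt(sum(lv^2))
    if (ln < 1e-8) next
    sc <- numeric(3)
    for (k in -1:1) {
      rp <- right[(yi - radius):(yi + radius) + 1,
                  (xr - k - radius):(xr - k + radius) + 1]
      rv <- as.numeric(rp) - mean(rp)
      rn <- sqrt(sum(rv^2))
      sc[k + 2] <- if (rn < 1e-8) -1 else sum(lv * rv) / (ln * rn)
    }
    denom <- sc[1] - 2 * sc[2] + sc[3]
    if (is.finite(denom) && denom < -1e-12 && sc[2] >= sc[1] && sc[2] >= sc[3]) {
      delta <- 0.5 * (sc[1] - sc[3]) / denom
      if (abs(delta) <= 0.6) out[i] <- di + delta
    }
  }
  out
}

#' Detect and stereo-match keypoints in a rectified pair
#'
#' Runs the detector on both images, then forms mutual-best Hamming matches
#' filtered by (a) a distance threshold and best/second-best ratio, (b) the
#' rectified epipolar constraint (same row within \code{row_tolerance}), and
#' (c) a positive minimum disparity.
#'
#' @param left,right rectified images (matrices or RGB arrays, same size).
#' @param params a [feature_params()] list.
#' @param left_features,right_features optional precomputed
#'   [detect_features()] results (lets callers reuse detections).
#' @return An object of class \code{stereo_matches}: data.frame \code{matches}
#'   (x_left, y_left, x_right, y_right, disparity, intensity, score, and
#'   \code{feature_left}, the row of the left detection), descriptor matrix
#'   \code{descriptors} (left descriptors, row-aligned), and logical
#'   \code{untrackable} when fewer than \code{min_matches} survive.
#' @export
detect_and_match <- function(left, right, params = feature_params(),
                             left_features = NULL, right_features = NULL) {
  stopifnot(all(dim(as_gray(left)) == dim(as_gray(right))))
  L <- as_gray(left); R <- as_gray(right)
  fl <- if (is.null(left_features)) detect_features(L, params) else left_features
  fr <- if (is.null(right_features)) detect_features(R, params) else right_features
  empty <- data.frame(x_left = numeric(0), y_left = numeric(0),
                      x_right = numeric(0), y_right = numeric(0),
                      disparity = numeric(0), intensity = numeric(0),
                      score = numeric(0), feature_left = integer(0))
  if (nrow(fl$keypoints) == 0 || nrow(fr$keypoints) == 0) {
    return(structure(list(matches = empty,
                          descriptors = fl$descriptors[integer(0), , drop = FALSE],
                          untrackable = TRUE), class = "stereo_matches"))
  }
  m12 <- mutual_match_cpp(fl$descriptors, fr$descriptors)
  i <- seq_len(nrow(fl$keypoints))
  j <- m12$match
  mutual <- !is.na(j) & !is.na(m12$reverse[j]) & m12$reverse[j] == i
  good <- mutual & m12$dist <= params$max_hamming &
    (is.na(m12$second) | m12$dist <= params$ratio * m12$second)
  kl <- fl$keypoints[which(good), , drop = FALSE]
  kr <- fr$keypoints[j[which(good)], , drop = FALSE]
  drow <- abs(kl$y - kr$y) <= params$row_tolerance
  disp <- kl$x - kr$x
  keep <- drow & disp >= params$min_disparity
  kl <- kl[keep, , drop = FALSE]
  kr <- kr[keep, , drop = FALSE]
  disp <- disp[keep]
  if (params$subpixel && nrow(kl) > 0) {
    disp <- refine_disparity_subpixel(L, R, kl$x, kl$y, disp)
  }
  matches <- data.frame(x_left = kl$x, y_left = kl$y, x_right = kl$x - disp,
                        y_right = kr$y, disparity = disp,
                        intensity = kl$intensity, score = kl$score,
                        feature_left = which(good)[keep])
  structure(list(matches = matches,
                 descriptors = fl$descriptors[which(good)[keep], , drop = FALSE],
                 untrackable = nrow(matches) < params$min_matches),
            class = "stereo_matches")
}

#' @export
print.stereo_matches <- function(x, ...) {
  cat(sprintf("stereo_matches: %d matches%s\n", nrow(x$matches),
              if (x$untrackable) " (untrackable frame)" else ""))
  invisible(x)
}

#' Remove keypoints inside specular highlights
#'
#' Saturated specular reflections move with the light (co-located with the
#' endoscope) and violate the static-scene assumption; keypoints whose image
#' intensity exceeds the threshold are dropped.  Idempotent; preserves order.
#'
#' @param matches a \code{stereo_matches} object.
#' @param intensity_threshold intensity cutoff in (0, 255] (default 240).
#' @return the filtered \code{stereo_matches}.
#' @export
filter_specular <- function(matches, intensity_threshold = 240) {
  stopifnot(intensity_threshold > 0, intensity_threshold <= 255)
  keep <- matches$matches$intensity <= intensity_threshold
  matches$matches <- matches$matches[keep, , drop = FALSE]
  matches$descriptors <- matches$descriptors[keep, , drop = FALSE]
  rownames(matches$matches) <- NULL
  matches
}
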