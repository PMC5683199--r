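# Synthetic stereo-endoscopy scene generator and evaluation metrics.
#
# The generator emulates the quantitative ground-truth protocol used to
# assess the pipeline: a curved, textured, specular surface at organ scale
# (the principal structure spans ~140 mm, matching an average liver
# diameter of 14.0 cm), endoscope-style illumination from a spot light
# co-located with the camera, and a smooth hovering stereo camera
# trajectory with known per-frame pose and depth.  Rendering uses the
# package's software rasteriser with a Phong-style specular term.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# separable Gaussian smoothing of a matrix (reflected borders)
smooth_gauss <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  r <- max(1, ceiling(3 * sigma_cells))
  k <- exp(-((-r):r)^2 / (2 * sigma_cells^2))
  k <- k / sum(k)
  pad_filter <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(r)]), x, rev(x[n - seq_len(r) + 1]))
    as.numeric(stats::filter(xp, k, sides = 2))[r + seq_len(n)]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(t(m), 2, pad_filter))
}

#' Generate a synthetic endoscopic scene
#'
#' A single-valued height-field surface: a smooth dome whose principal
#' structure spans about \code{structure_span} mm (default 140, liver
#' scale), plus band-limited random undulation, with a multi-scale random
#' albedo texture and Phong specular material.  Deterministic for a fixed
#' seed.  The surface sits around depth \code{z0} along +z in the scene
#' frame; heights rise toward the camera side.
#'
#' @param seed RNG seed.
#' @param extent_mm square half-extent of the sheet in mm (default 80).
#' @param grid_mm height-field grid spacing (default 1.5).
#' @param tex_mm albedo texture grid spacing in mm (default 0.75; finer
#'   than the mesh so the rendered texture carries feature-scale detail).
#' @param structure_span diameter of the principal dome in mm (default 140).
#' @param dome_height_mm dome peak height (default 25).
#' @param bump_amplitude_mm RMS of the random undulation (default 3).
#' @param texture_contrast albedo contrast in (0, 1]; 0 is refused since the
#'   pipeline is feature-based (default 0.35).
#' @param specular_strength Phong specular coefficient (default 0.6).
#' @param shininess Phong exponent (default 40).
#' @param z0 depth of the surface base plane in mm (default 100).
#' @return object of class \code{synthetic_scene} with the ground-truth
#'   height field, a renderable mesh and a \code{height_at(x, y)} bilinear
#'   lookup.
#' @export
generate_scene <- function(seed = 1, extent_mm = 80, grid_mm = 1.5,
                           tex_mm = 0.75,
                           structure_span = 140, dome_height_mm = 25,
                           bump_amplitude_mm = 3, texture_contrast = 0.35,
                           specular_strength = 0.6, shininess = 40,
                           z0 = 100) {
  if (texture_contrast <= 0) {
    stop("texture_contrast must be positive: the pipeline is feature-based ",
         "and needs image texture")
  }
  xs <- seq(-extent_mm, extent_mm, by = grid_mm)
  ys <- xs
  nx <- length(xs); ny <- length(ys)
  rr <- sqrt(outer(xs^2, ys^2, `+`))
  sigma <- structure_span / 4
  dome <- dome_height_mm * exp(-rr^2 / (2 * sigma^2))
  txs <- seq(-extent_mm, extent_mm, by = tex_mm)
  ntx <- length(txs)
  scene <- with_seed(seed, {
    bumps <- smooth_gauss(matrix(rnorm(nx * ny), nx, ny), 8 / grid_mm)
    if (bump_amplitude_mm > 0 && sd(bumps) > 0) {
      bumps <- bumps / sd(bumps) * bump_amplitude_mm
    } else {
      bumps <- bumps * 0
    }
    oct <- function(sigma_mm) {
      m <- smooth_gauss(matrix(rnorm(ntx * ntx), ntx, ntx), sigma_mm / tex_mm)
      m / max(sd(m), 1e-9)
    }
    tex <- 0.45 * oct(0.9) + 0.35 * oct(2.5) + 0.2 * oct(6)
    tex <- tex / max(sd(tex), 1e-9)
    albedo <- pmin(pmax(0.55 + 0.55 * texture_contrast * tex, 0.12), 0.95)
    list(bumps = bumps, albedo = albedo)
  })
  height <- dome + scene$bumps
  # mesh: vertex (x, y, z0 - h); faces over the grid
  vx <- rep(xs, times = ny)
  vy <- rep(ys, each = nx)
  vz <- z0 - as.numeric(height)
  V <- cbind(vx, vy, vz)
  idx <- function(i, j) (j - 1) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  F1 <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
  F2 <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  faces <- rbind(F1, F2)
  # analytic-ish vertex normals from height-field gradient (toward -z)
  gx <- height; gy <- height
  gx[2:(nx - 1), ] <- (height[3:nx, ] - height[1:(nx - 2), ]) / (2 * grid_mm)
  gx[c(1, nx), ] <- gx[c(2, nx - 1), ]
  gy[, 2:(ny - 1)] <- (height[, 3:ny] - height[, 1:(ny - 2)]) / (2 * grid_mm)
  gy[, c(1, ny)] <- gy[, c(2, ny - 1)]
  # surface z(x, y) = z0 - h, so dz/dx = -gx; normal ~ (-dz/dx, -dz/dy, 1)
  # oriented toward the camera (-z): (-gx, -gy, -1)/norm
  nrm <- cbind(-as.numeric(gx), -as.numeric(gy), -1)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  height_at <- function(x, y) {
    xi <- pmin(pmax((x + extent_mm) / grid_mm, 0), nx - 1 - 1e-9)
    yi <- pmin(pmax((y + extent_mm) / grid_mm, 0), ny - 1 - 1e-9)
    i0 <- floor(xi); j0 <- floor(yi)
    fx <- xi - i0; fy <- yi - j0
    h00 <- height[cbind(i0 + 1, j0 + 1)]
    h10 <- height[cbind(i0 + 2, j0 + 1)]
    h01 <- height[cbind(i0 + 1, j0 + 2)]
    h11 <- height[cbind(i0 + 2, j0 + 2)]
    (1 - fx) * (1 - fy) * h00 + fx * (1 - fy) * h10 +
      (1 - fx) * fy * h01 + fx * fy * h11
  }
  structure(list(xs = xs, ys = ys, height = height, albedo = scene$albedo,
                 tex_x0 = -extent_mm, tex_dx = tex_mm,
                 vertices = V, faces = faces, normals = nrm,
                 z0 = z0, grid_mm = grid_mm, extent_mm = extent_mm,
                 structure_span = structure_span,
                 specular_strength = specular_strength,
                 shininess = shininess, seed = seed,
                 height_at = height_at),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scene: %.0f x %.0f mm sheet, %.0f mm dome, ",
                     "%d vertices (seed %d)\n"),
              2 * x$extent_mm, 2 * x$extent_mm, x$structure_span,
              nrow(x$vertices), x$seed))
  invisible(x)
}

#' Hovering camera trajectory
#'
#' A smooth orbit above the scene: the camera circles at
#' \code{orbit_radius} with a gentle vertical bob, always looking at a
#' fixed target on the structure, emulating an endoscope hovering over an
#' organ.
#'
#' @param n_frames number of frames (default 300).
#' @param orbit_radius lateral orbit radius in mm (default 22).
#' @param bob_mm vertical bob amplitude (default 4).
#' @param target look-at point in scene coordinates (default the dome top).
#' @param revolutions orbit fraction covered over the sequence (default 1).
#' @param scene optional scene (supplies the default target).
#' @return list of ground-truth [pose()] objects (camera-to-world in the
#'   scene frame).
#' @export
hover_trajectory <- function(n_frames = 300, orbit_radius = 22, bob_mm = 4,
                             target = NULL, revolutions = 1, scene = NULL) {
  if (is.null(target)) {
    z_top <- if (is.null(scene)) 80 else scene$z0 - max(scene$height)
    target <- c(0, 0, z_top + 10)
  }
  th <- seq(0, 2 * pi * revolutions, length.out = n_frames + 1)[seq_len(n_frames)]
  lapply(th, function(t) {
    pos <- c(orbit_radius * cos(t), orbit_radius * sin(t), bob_mm * sin(2 * t))
    zc <- target - pos
    zc <- zc / sqrt(sum(zc^2))
    up <- c(0, 1, 0)
    xc <- c(up[2] * zc[3] - up[3] * zc[2],
            up[3] * zc[1] - up[1] * zc[3],
            up[1] * zc[2] - up[2] * zc[1])
    xc <- xc / sqrt(sum(xc^2))
    yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
            zc[3] * xc[1] - zc[1] * xc[3],
            zc[1] * xc[2] - zc[2] * xc[1])
    pose(pos, rotmat_to_quat(cbind(xc, yc, zc)))
  })
}

#' Default synthetic stereo rig
#'
#' f = 500 px, B = 5 mm, 840 x 640 — chosen so working depths of
#' 50-200 mm give disparities in roughly the 5-50 px range.
#' @return a [camera_rig()].
#' @export
default_synth_rig <- function() {
  camera_rig(500, c(419.5, 319.5), 5, c(840, 640))
}

# shade one camera view of the scene; light co-located with the main
# (left) camera, Phong specular, quadratic distance falloff and a spot cone
shade_view <- function(scene, cam_pose, rig, light_pos, light_axis,
                       camera = "left") {
  bx <- if (camera == "right") rig$baseline_mm else 0
  res <- render_view_cpp(scene$vertices, scene$faces, scene$normals,
                         scene$albedo, scene$tex_x0, scene$tex_x0,
                         scene$tex_dx,
                         quat_to_rotmat(cam_pose$orientation),
                         cam_pose$position, bx,
                         rig$fx, rig$fy, rig$cx, rig$cy,
                         rig$width, rig$height,
                         light_pos, light_axis,
                         scene$specular_strength, scene$shininess,
                         ambient = 0.10, diffuse_gain = 1.75,
                         falloff_d0 = 90, spot_exp = 2)
  list(image = res$image, depth = res$depth,
       specular_mask = res$specular_mask)
}

#' Render one ground-truth stereo frame
#'
#' Rectified left/right pair with the true pose, true left-camera depth map
#' and the specular-highlight mask.  The spot light is co-located with the
#' main (left) camera.
#'
#' @param scene a [generate_scene()] result.
#' @param cam_pose ground-truth [pose()] in the scene frame.
#' @param rig a [camera_rig()].
#' @return list \code{left, right, depth, specular_mask, pose}.
#' @export
render_frame <- function(scene, cam_pose, rig) {
  Rw <- quat_to_rotmat(cam_pose$orientation)
  light_pos <- cam_pose$position
  light_axis <- as.numeric(Rw %*% c(0, 0, 1))
  lv <- shade_view(scene, cam_pose, rig, light_pos, light_axis, "left")
  rv <- shade_view(scene, cam_pose, rig, light_pos, light_axis, "right")
  list(left = lv$image, right = rv$image, depth = lv$depth,
       specular_mask = lv$specular_mask, pose = cam_pose)
}

#' Render a ground-truth stereo sequence
#'
#' @param scene a [generate_scene()] result.
#' @param trajectory list of ground-truth poses ([hover_trajectory()]).
#' @param rig a [camera_rig()].
#' @param min_coverage minimum fraction of the image the surface must cover
#'   in every frame (default 0.6); a frame below this aborts with its index.
#' @return list of [render_frame()] results.
#' @export
render_sequence <- function(scene, trajectory, rig, min_coverage = 0.6) {
  lapply(seq_along(trajectory), function(i) {
    fr <- render_frame(scene, trajectory[[i]], rig)
    cov <- mean(is.finite(fr$depth))
    if (cov < min_coverage) {
      stop(sprintf("surface out of view at frame %d (coverage %.2f)", i, cov))
    }
    fr
  })
}

#' Write a rendered sequence to disk
#'
#' Layout: \code{left/\%06d.png}, \code{right/\%06d.png},
#' \code{gt_poses.txt} (TUM format), \code{gt_depth/\%06d.tif} (32-bit
#' float TIFF), \code{calib.yaml}.
#'
#' @param frames a [render_sequence()] result.
#' @param rig the [camera_rig()].
#' @param dir output directory (created).
#' @export
write_dataset <- function(frames, rig, dir) {
  dir.create(file.path(dir, "left"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "right"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gt_depth"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]]$left / 255,
                  file.path(dir, "left", sprintf("%06d.png", i - 1)))
    png::writePNG(frames[[i]]$right / 255,
                  file.path(dir, "right", sprintf("%06d.png", i - 1)))
    tiff::writeTIFF(frames[[i]]$depth / 1000,
                    file.path(dir, "gt_depth", sprintf("%06d.tif", i - 1)),
                    bits.per.sample = 32L)
  }
  write_trajectory_tum(lapply(frames, `[[`, "pose"),
                       file.path(dir, "gt_poses.txt"))
  write_calib(rig, file.path(dir, "calib.yaml"))
  invisible(dir)
}

#' Sample a reconstructed cloud onto an evaluation height grid
#'
#' Grid-samples x, y positions at \code{spacing} over the evaluated extent
#' and takes the mean reconstructed z per cell alongside the ground-truth
#' surface z; cells with no reconstructed points are excluded and reported.
#'
#' @param scene the ground-truth [generate_scene()] scene.
#' @param cloud reconstructed world-frame points, n x 3, aligned to the
#'   scene frame.
#' @param spacing grid spacing in mm (default 2).
#' @param extent half-extent of the evaluated square in mm (default the
#'   structure radius).
#' @return object of class \code{evaluation_grid}: \code{Z} (truth),
#'   \code{z} (reconstruction), \code{covered}, \code{coverage}.
#' @export
evaluation_grid <- function(scene, cloud, spacing = 2, extent = NULL) {
  if (is.null(extent)) extent <- scene$structure_span / 2
  gx <- seq(-extent, extent, by = spacing)
  gy <- gx
  Zt <- outer(gx, gy, function(x, y) scene$z0 - scene$height_at(x, y))
  zr <- matrix(NA_real_, length(gx), length(gy))
  cnt <- matrix(0L, length(gx), length(gy))
  cloud <- matrix(cloud, ncol = 3)
  ix <- round((cloud[, 1] + extent) / spacing) + 1
  iy <- round((cloud[, 2] + extent) / spacing) + 1
  ok <- ix >= 1 & ix <= length(gx) & iy >= 1 & iy <= length(gy)
  if (any(ok)) {
    key <- (iy[ok] - 1) * length(gx) + ix[ok]
    # per-cell median: robust to stray points falling into the cell
    meds <- tapply(cloud[ok, 3], key, stats::median)
    ns <- tapply(rep(1, sum(ok)), key, sum)
    cells <- as.integer(names(meds))
    zr[cells] <- as.numeric(meds)
    cnt[cells] <- as.integer(ns)
  }
  covered <- !is.na(zr)
  structure(list(x = gx, y = gy, Z = Zt, z = zr, covered = covered,
                 coverage = mean(covered), spacing = spacing),
            class = "evaluation_grid")
}

#' Root-mean-square distance between two gridded surfaces
#'
#' \deqn{RMSD = \sqrt{\frac{1}{mn} \sum_x \sum_y (Z_{x,y} - z_{x,y})^2}}
#' over the covered grid cells; a coverage below 50 percent raises a
#' low-coverage warning.
#'
#' @param grid an [evaluation_grid()] (or any list with \code{Z}, \code{z},
#'   \code{covered}).
#' @return RMSD in mm, with attribute \code{coverage}.
#' @export
rmsd_surfaces <- function(grid) {
  d <- grid$Z[grid$covered] - grid$z[grid$covered]
  if (!is.null(grid$coverage) && grid$coverage < 0.5) {
    warning(sprintf("low evaluation coverage: %.1f%% of grid cells",
                    100 * grid$coverage))
  }
  structure(sqrt(mean(d^2)), coverage = grid$coverage)
}

#' Absolute trajectory error
#'
#' Rigidly aligns the estimated trajectory to the ground truth (no scale:
#' stereo is metric) by Kabsch on the positions, then reports the RMS
#' translation error (mm) and RMS rotation error (degrees).
#'
#' @param estimated,truth equal-length lists of [pose()] objects.
#' @param align apply the rigid alignment first (default \code{TRUE}).
#' @return list \code{rms_translation_mm}, \code{rms_rotation_deg}.
#' @export
trajectory_error <- function(estimated, truth, align = TRUE) {
  if (length(estimated) != length(truth)) {
    stop("trajectory length mismatch: ", length(estimated), " vs ",
         length(truth))
  }
  Pe <- t(vapply(estimated, `[[`, numeric(3), "position"))
  Pt <- t(vapply(truth, `[[`, numeric(3), "position"))
  Ra <- diag(3); Ta <- c(0, 0, 0)
  if (align && nrow(Pe) >= 3) {
    tf <- solve_rigid(Pt, Pe)
    if (!is.null(tf)) { Ra <- tf$rotation; Ta <- tf$translation }
  }
  Pa <- Pe %*% t(Ra) + matrix(Ta, nrow(Pe), 3, byrow = TRUE)
  rms_t <- sqrt(mean(rowSums((Pa - Pt)^2)))
  ang <- vapply(seq_along(estimated), function(i) {
    Re <- Ra %*% quat_to_rotmat(estimated[[i]]$orientation)
    Rt <- quat_to_rotmat(truth[[i]]$orientation)
    cang <- (sum(diag(t(Rt) %*% Re)) - 1) / 2
    acos(pmin(1, pmax(-1, cang))) * 180 / pi
  }, numeric(1))
  list(rms_translation_mm = rms_t, rms_rotation_deg = sqrt(mean(ang^2)))
}
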