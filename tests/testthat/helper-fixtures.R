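# Shared fixtures, built in code.  The heavier artefacts (rendered frames,
# pipeline runs) are memoised so several test files can share one build.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small rig + scene for fast rendered-image tests
small_rig <- function() camera_rig(250, c(159.5, 119.5), 5, c(320, 240))

small_scene <- function() {
  memo("small_scene", generate_scene(seed = 7, extent_mm = 45, grid_mm = 1.5,
                                     structure_span = 80,
                                     dome_height_mm = 14,
                                     bump_amplitude_mm = 2))
}

small_frames <- function(n = 10) {
  memo(paste0("small_frames_", n), {
    sc <- small_scene()
    tr <- hover_trajectory(n_frames = 120, orbit_radius = 14, bob_mm = 2,
                           scene = sc)[seq_len(n)]
    render_sequence(sc, tr, small_rig(), min_coverage = 0.5)
  })
}

small_trajectory <- function(n = 10) {
  sc <- small_scene()
  hover_trajectory(n_frames = 120, orbit_radius = 14, bob_mm = 2,
                   scene = sc)[seq_len(n)]
}

# ground-truth poses re-expressed in the pipeline's world frame
# (world = first camera frame)
gt_in_world <- function(trajectory) {
  inv1 <- pose_inverse(trajectory[[1]])
  lapply(trajectory, function(p) pose_compose(inv1, p))
}

# a small end-to-end pipeline run shared across test files
small_run <- function(n = 24) {
  memo(paste0("small_run_", n), {
    sc <- small_scene()
    tr <- small_trajectory(n)
    frames <- small_frames(n)
    cfg <- pipeline_config(feature = feature_params(n_features = 600),
                           smooth_iterations = 20, seed = 5)
    res <- run_pipeline(frames, small_rig(), cfg)
    list(scene = sc, trajectory = tr, result = res, rig = small_rig())
  })
}

# analytic meshes ------------------------------------------------------

# regular planar grid mesh on z = 0
plane_mesh <- function(nx = 21, ny = 21, spacing = 1) {
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  V <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  F <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  N <- matrix(rep(c(0, 0, 1), each = nrow(V)), ncol = 3)
  structure(list(vertices = V, faces = F, normals = N, n_unreferenced = 0L),
            class = "surface_mesh")
}

# hemisphere mesh (z >= 0 half of a sphere of radius R) from a
# latitude-longitude grid; n_lat controls fineness
hemisphere_mesh <- function(R = 10, n_lat = 40) {
  lats <- seq(0, pi / 2, length.out = n_lat)
  V <- matrix(c(0, 0, R), 1, 3)  # pole
  ring_start <- integer(n_lat)
  for (k in 2:n_lat) {
    th <- lats[k]
    n_lon <- max(8, round(2 * pi * sin(th) / (lats[2] - lats[1])))
    ph <- seq(0, 2 * pi, length.out = n_lon + 1)[seq_len(n_lon)]
    ring_start[k] <- nrow(V) + 1
    V <- rbind(V, cbind(R * sin(th) * cos(ph), R * sin(th) * sin(ph),
                        R * cos(th)))
  }
  ms <- triangulate_surface(V, radius = 3.5 * R * (lats[2] - lats[1]),
                            viewpoint = c(0, 0, 10 * R))
  ms
}

# Fibonacci-spiral point sampling of a hemisphere (well spaced)
hemisphere_cloud <- function(R = 10, n = 2000) {
  i <- seq_len(n) - 0.5
  z <- 1 - i / n        # cos(theta) in (0, 1): upper hemisphere
  th <- acos(z)
  ga <- pi * (3 - sqrt(5))
  ph <- ga * i
  cbind(R * sin(th) * cos(ph), R * sin(th) * sin(ph), R * z)
}

skew <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
         byrow = TRUE)
}

random_rotation <- function(angle_deg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  quat_to_rotmat(quat_from_rotvec(ax * angle_deg * pi / 180))
}

# synthetic bundle-adjustment problem: keyframes on an arc looking at a
# random landmark cloud, exact observations
make_ba_problem <- function(n_kf = 5, n_lm = 200, seed = 42, spread = 1,
                            stereo = FALSE) {
  set.seed(seed)
  rig <- camera_rig(400, c(199.5, 149.5), 5, c(400, 300))
  lms <- cbind(runif(n_lm, -40, 40), runif(n_lm, -30, 30),
               runif(n_lm, 80, 120))
  kfs <- list()
  for (i in seq_len(n_kf)) {
    ang <- (i - (n_kf + 1) / 2) * 0.05 * spread
    pos <- c(30 * sin(ang), 2 * (i - 1) * spread, 10 * (1 - cos(ang)))
    q <- quat_from_rotvec(c(0, -ang, 0))
    p <- pose(pos, q)
    pr <- project_points(lms, p, rig, "left")
    ok <- which(pr$in_image)
    ob <- data.frame(landmark = ok, x = pr$x[ok], y = pr$y[ok])
    if (stereo) {
      prr <- project_points(lms, p, rig, "right")
      ob$x_right <- ifelse(prr$in_image[ok], prr$x[ok], NA_real_)
    }
    kfs[[i]] <- keyframe(i, p, ob, frame = i)
  }
  list(keyframes = kfs, landmarks = lms, rig = rig)
}

ba_rms_reproj <- function(keyframes, landmarks, rig) {
  obs <- endogeo:::ba_flatten(keyframes)
  poses <- lapply(keyframes, `[[`, "pose")
  sqrt(mean(endogeo:::ba_residuals(obs, poses, landmarks, rig)$norm^2))
}

# anchor at the surface point of `mesh` nearest to a world point
anchor_near <- function(mesh, p) {
  vi <- which.min(colSums((t(mesh$vertices) - p)^2))
  f <- which(mesh$faces == vi, arr.ind = TRUE)[1, 1]
  tri <- mesh$faces[f, ]
  A <- mesh$vertices[tri[1], ]; B <- mesh$vertices[tri[2], ]
  C <- mesh$vertices[tri[3], ]
  # barycentric coordinates of p projected onto the face plane
  v0 <- B - A; v1 <- C - A; v2 <- p - A
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  b <- pmax(c(1 - v - w, v, w), 0)
  b <- b / sum(b)
  pos <- b[1] * A + b[2] * B + b[3] * C
  nrm <- b %*% mesh$normals[tri, , drop = FALSE]
  surface_anchor(f, b, pos, as.numeric(nrm))
}

# anchor on a (planar-ish) mesh at given x, y
pick_point_on <- function(mesh, xy) {
  anchor_near(mesh, c(xy[1], xy[2], mean(mesh$vertices[, 3])))
}
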