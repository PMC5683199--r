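# Synthetic scene generation, rendering and evaluation metrics.

test_that("scene generation is deterministic and validates its inputs", {
  a <- generate_scene(seed = 3, extent_mm = 30, grid_mm = 2)
  b <- generate_scene(seed = 3, extent_mm = 30, grid_mm = 2)
  expect_identical(a$height, b$height)
  expect_identical(a$albedo, b$albedo)
  c <- generate_scene(seed = 4, extent_mm = 30, grid_mm = 2)
  expect_false(identical(a$height, c$height))
  # a feature-based pipeline refuses an untextured scene
  expect_error(generate_scene(seed = 3, texture_contrast = 0), "texture")
  # flat-scene baseline
  flat <- generate_scene(seed = 3, extent_mm = 30, grid_mm = 2,
                         dome_height_mm = 0, bump_amplitude_mm = 0)
  expect_equal(max(abs(flat$height)), 0)
})

test_that("scene generation does not disturb the global RNG stream", {
  set.seed(555)
  x1 <- runif(3)
  set.seed(555)
  invisible(generate_scene(seed = 99, extent_mm = 20, grid_mm = 2))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("the default scene yields enough keypoints at 840 x 640", {
  sc <- generate_scene(seed = 1)
  rig <- default_synth_rig()
  tr <- hover_trajectory(n_frames = 4, scene = sc)
  fr <- render_frame(sc, tr[[1]], rig)
  f <- detect_features(fr$left, feature_params(n_features = 2000))
  expect_gte(nrow(f$keypoints), 500)
})

test_that("a static camera renders identical consecutive frames", {
  sc <- small_scene()
  p <- small_trajectory(1)[[1]]
  fr <- render_sequence(sc, list(p, p), small_rig())
  expect_identical(fr[[1]]$left, fr[[2]]$left)
  expect_identical(fr[[1]]$right, fr[[2]]$right)
  expect_identical(fr[[1]]$depth, fr[[2]]$depth)
})

test_that("rendered stereo pairs are photometrically consistent with Eq-1
          disparity", {
  fr <- small_frames(2)[[1]]
  rig <- small_rig()
  disp <- rig$fx * rig$baseline_mm / fr$depth
  h <- nrow(fr$left); w <- ncol(fr$left)
  # warp right image by the ground-truth disparity and compare to left
  diffs <- c()
  set.seed(131)
  for (k in 1:4000) {
    y <- sample(h, 1); x <- sample(30:(w - 5), 1)
    d <- disp[y, x]
    if (!is.finite(d)) next
    xr <- round(x - d)
    if (xr < 1) next
    if (!fr$specular_mask[y, x] && is.finite(fr$depth[y, x])) {
      diffs <- c(diffs, abs(fr$left[y, x] - fr$right[y, xr]))
    }
  }
  expect_lt(median(diffs), 10)
})

test_that("an out-of-view trajectory fails naming the offending frame", {
  sc <- small_scene()
  good <- small_trajectory(1)[[1]]
  bad <- pose(c(0, 0, -500), good$orientation)
  expect_error(render_sequence(sc, list(good, bad), small_rig()),
               "frame 2")
})

test_that("specular highlights are present, saturated and masked", {
  frames <- small_frames(6)
  tot <- sum(vapply(frames, function(f) sum(f$specular_mask), numeric(1)))
  expect_gt(tot, 100)
  for (f in frames) {
    if (sum(f$specular_mask) == 0) next
    expect_true(all(f$left[f$specular_mask] > 240))
  }
})

test_that("datasets round-trip through the on-disk layout", {
  frames <- small_frames(2)
  dir <- tempfile("dataset")
  write_dataset(frames, small_rig(), dir)
  expect_true(file.exists(file.path(dir, "calib.yaml")))
  prov <- frame_directory(dir)
  expect_equal(prov$n_frames, 2)
  f1 <- prov$get(1)
  expect_equal(f1$left, frames[[1]]$left, tolerance = 0.51,
               ignore_attr = TRUE)
  tr <- read_trajectory_tum(file.path(dir, "gt_poses.txt"))
  expect_equal(tr[[2]]$position, frames[[2]]$pose$position, tolerance = 1e-6)
})

test_that("RMSD reproduces its formula and a double-loop oracle", {
  sc <- small_scene()
  # identical surfaces: RMSD 0 via a perfect sample of the height field
  gx <- seq(-20, 20, by = 2)
  pts <- as.matrix(expand.grid(x = gx, y = gx))
  cloud <- cbind(pts, z = sc$z0 - sc$height_at(pts[, 1], pts[, 2]))
  eg <- evaluation_grid(sc, cloud, spacing = 2, extent = 20)
  expect_lt(rmsd_surfaces(eg), 0.05)  # only bilinear-vs-cell binning error
  # constant offset c: RMSD = c exactly
  eg2 <- eg
  eg2$z <- eg2$z + 1.37
  expect_equal(as.numeric(rmsd_surfaces(eg2)), 1.37, tolerance = 1e-9)
  # random fields vs the double-loop oracle
  set.seed(137)
  Z <- matrix(runif(100, 50, 100), 10, 10)
  z <- Z + matrix(rnorm(100), 10, 10)
  z[sample(100, 10)] <- NA
  grid <- list(Z = Z, z = z, covered = !is.na(z), coverage = 0.9)
  expect_equal(as.numeric(rmsd_surfaces(grid)), rmsd_oracle(Z, z),
               tolerance = 1e-12)
})

test_that("low evaluation coverage raises a warning", {
  Z <- matrix(1, 4, 4)
  z <- matrix(NA_real_, 4, 4)
  z[1:3] <- 1.5
  grid <- list(Z = Z, z = z, covered = !is.na(z), coverage = 3 / 16)
  expect_warning(rmsd_surfaces(grid), "coverage")
})

test_that("trajectory error is zero on identity and exact on offsets", {
  set.seed(139)
  poses <- lapply(1:20, function(i) {
    pose(rnorm(3, sd = 10), quat_normalize(rnorm(4)))
  })
  te <- trajectory_error(poses, poses)
  expect_lt(te$rms_translation_mm, 1e-9)
  expect_lt(te$rms_rotation_deg, 1e-5)  # acos conditioning near 0
  # constant 1 mm offset, alignment disabled
  off <- lapply(poses, function(p) pose(p$position + c(1, 0, 0),
                                        p$orientation))
  te2 <- trajectory_error(off, poses, align = FALSE)
  expect_equal(te2$rms_translation_mm, 1, tolerance = 1e-9)
  # alignment removes a rigid offset entirely
  te3 <- trajectory_error(off, poses, align = TRUE)
  expect_lt(te3$rms_translation_mm, 1e-6)
  # length mismatch is an error
  expect_error(trajectory_error(poses[1:3], poses), "mismatch")
})
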