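# World-space transforms, voxel fusion and surface triangulation.

test_that("to_world applies a rigid transform and preserves distances", {
  set.seed(101)
  pts <- matrix(rnorm(300, sd = 20), 100, 3)
  # identity
  expect_equal(to_world(pts, frame_to_world(pose())), pts,
               ignore_attr = TRUE)
  # pure translation shifts the centroid exactly
  tf <- frame_to_world(rotation = diag(3), translation = c(5, -3, 2))
  moved <- to_world(pts, tf)
  expect_equal(colMeans(moved) - colMeans(pts), c(5, -3, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # general rigid transform preserves pairwise distances, inverse round-trips
  p <- pose(c(3, 1, -2), quat_normalize(c(0.9, 0.2, -0.3, 0.1)))
  tf2 <- frame_to_world(p)
  w <- to_world(pts, tf2)
  i <- sample(100, 30); j <- sample(100, 30)
  d0 <- sqrt(rowSums((pts[i, ] - pts[j, ])^2))
  d1 <- sqrt(rowSums((w[i, ] - w[j, ])^2))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_lt(max(abs(to_world(w, tf2, inverse = TRUE) - pts)), 1e-9)
})

test_that("frame_to_world rejects non-rotations", {
  expect_error(frame_to_world(rotation = diag(c(1, 1, 2)),
                              translation = c(0, 0, 0)))
})

test_that("voxel fusion deduplicates and never exceeds the union count", {
  set.seed(103)
  X <- matrix(runif(300, 0, 20), 100, 3)
  fx <- fuse(X, X, voxel_size = 1)
  f1 <- fuse(NULL, X, voxel_size = 1)
  # fusing a cloud with itself gives exactly its own voxel representatives
  expect_equal(fx, f1)
  expect_lte(nrow(fx), 200)
  # disjoint clouds concatenate (up to voxelisation)
  Y <- X + 100
  fxy <- fuse(X, Y, voxel_size = 1)
  expect_equal(nrow(fxy), nrow(f1) * 2)
  # representatives stay within half a voxel diagonal of an input point
  nn <- apply(fx, 1, function(p) min(sqrt(colSums((t(X) - p)^2))))
  expect_lt(max(nn), sqrt(3) * 1)
})

test_that("a planar grid triangulates to its analytic area", {
  xs <- seq(0, 20, by = 1)
  grid <- as.matrix(expand.grid(x = xs, y = xs))
  cloud <- cbind(grid, z = 0)
  mesh <- triangulate_surface(cloud, radius = 2.2, viewpoint = c(0, 0, 100))
  expect_equal(mesh_area(mesh), 400, tolerance = 0.01)
  expect_equal(mesh$n_unreferenced, 0)
  # normals are consistent and unit length
  expect_equal(rowSums(mesh$normals^2), rep(1, nrow(cloud)), tolerance = 1e-9)
  expect_true(all(abs(mesh$normals[, 3]) > 0.999))
})

test_that("a hemisphere cloud meshes to within 5% of 2 pi R^2", {
  R <- 10
  cloud <- hemisphere_cloud(R, 3000)
  mesh <- triangulate_surface(cloud, viewpoint = c(0, 0, 100))
  expect_lt(abs(mesh_area(mesh) - 2 * pi * R^2) / (2 * pi * R^2), 0.05)
  # no zero-area faces
  expect_true(all(endogeo:::face_areas(mesh) > 1e-12))
})

test_that("meshing is insensitive to fusion order at voxel resolution", {
  set.seed(107)
  sc <- small_scene()
  # three overlapping patches of the ground-truth surface
  pick_patch <- function(x0) {
    xs <- seq(x0, x0 + 24, by = 0.7)
    g <- as.matrix(expand.grid(x = xs, y = seq(-12, 12, by = 0.7)))
    cbind(g, z = sc$z0 - sc$height_at(g[, 1], g[, 2]))
  }
  a <- pick_patch(-20); b <- pick_patch(-10); c <- pick_patch(0)
  vox <- 1
  incr <- fuse(fuse(a, b, vox), c, vox)       # keyframe-by-keyframe
  batch <- fuse(rbind(a, b), c, vox)          # one shot
  m1 <- triangulate_surface(incr, radius = 2.5 * vox, viewpoint = c(0, 0, -100))
  m2 <- triangulate_surface(batch, radius = 2.5 * vox, viewpoint = c(0, 0, -100))
  # mutual vertex RMSD at most the voxel size
  nn_rms <- function(A, B) {
    d <- vapply(seq_len(nrow(A)), function(i) {
      min(sqrt(colSums((t(B) - A[i, ])^2)))
    }, numeric(1))
    sqrt(mean(d^2))
  }
  expect_lte(nn_rms(m1$vertices, m2$vertices), vox)
  expect_lte(nn_rms(m2$vertices, m1$vertices), vox)
})

test_that("meshes round-trip through PLY and export to OBJ", {
  cloud <- hemisphere_cloud(5, 400)
  mesh <- triangulate_surface(cloud, viewpoint = c(0, 0, 50))
  ply <- tempfile(fileext = ".ply")
  write_ply_mesh(mesh, ply)
  back <- read_ply_mesh(ply)
  expect_equal(back$vertices, unname(mesh$vertices), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$faces, unname(mesh$faces), ignore_attr = TRUE)
  obj <- tempfile(fileext = ".obj")
  write_obj_mesh(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
})

test_that("overlapping keyframe clouds land on the same world surface", {
  # two views of the same patch, reconstructed independently and placed in
  # the world through their poses, must coincide
  sc <- small_scene()
  rig <- small_rig()
  tr <- small_trajectory(10)
  dense_world <- function(fr, p) {
    vol <- build_cost_volume(fr$left, fr$right, c(1, 32), 3)
    sm <- filter_disparity_quality(
      vol, filter_disparity_speckles(
        smooth_disparity(vol, winner_takes_all(vol), iterations = 15,
                         image = fr$left)))
    pts <- disparity_to_points(sm, rig, stride = 4)$points
    to_world(pts, frame_to_world(p))
  }
  f1 <- render_frame(sc, tr[[1]], rig)
  f2 <- render_frame(sc, tr[[10]], rig)
  w1 <- dense_world(f1, tr[[1]])
  w2 <- dense_world(f2, tr[[10]])
  set.seed(11)
  sub <- w1[sample(nrow(w1), 300), ]
  nn <- vapply(seq_len(nrow(sub)), function(i) {
    min(sqrt(colSums((t(w2) - sub[i, ])^2)))
  }, numeric(1))
  expect_lte(median(nn), 1.5)
})
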