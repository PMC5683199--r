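# Geometry-aware AR: picking, re-projection, measurement, highlighting,
# labels.

fronto_triangle <- function(z = 50) {
  V <- matrix(c(-10, -10, z, 10, -10, z, 0, 12, z), 3, byrow = TRUE)
  structure(list(vertices = V, faces = matrix(1:3, 1),
                 normals = matrix(rep(c(0, 0, -1), 3), 3, byrow = TRUE),
                 n_unreferenced = 0L),
            class = "surface_mesh")
}

test_that("picking the centroid of a triangle returns centered barycentrics", {
  rig <- small_rig()
  mesh <- fronto_triangle(50)
  cen <- colMeans(mesh$vertices)
  pr <- project_points(matrix(cen, 1), pose(), rig)
  a <- pick(c(pr$x, pr$y), pose(), rig, mesh)
  expect_equal(a$face, 1L)
  expect_equal(a$bary, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(a$position, cen, tolerance = 0.1)
  # a ray that misses returns NULL
  expect_null(pick(c(0, 0), pose(), rig, mesh))
})

test_that("picking returns the nearer of two stacked triangles", {
  rig <- small_rig()
  near <- fronto_triangle(40)
  far <- fronto_triangle(90)
  mesh <- structure(list(vertices = rbind(near$vertices, far$vertices),
                         faces = rbind(c(1, 2, 3), c(4, 5, 6)),
                         normals = rbind(near$normals, far$normals),
                         n_unreferenced = 0L),
                    class = "surface_mesh")
  a <- pick(c(rig$cx, rig$cy), pose(), rig, mesh)
  expect_equal(a$face, 1L)
  expect_equal(a$position[3], 40, tolerance = 1e-6)
})

test_that("picking agrees with a brute-force all-triangles oracle", {
  set.seed(109)
  rig <- small_rig()
  cloud <- hemisphere_cloud(30, 800)
  cloud[, 3] <- 80 - cloud[, 3]  # dome facing the camera
  mesh <- triangulate_surface(cloud, viewpoint = c(0, 0, -100))
  hits <- 0
  for (k in 1:1000) {
    px <- c(runif(1, 0, rig$width - 1), runif(1, 0, rig$height - 1))
    dir_cam <- c((px[1] - rig$cx) / rig$fx, (px[2] - rig$cy) / rig$fy, 1)
    a <- pick(px, pose(), rig, mesh)
    o <- ray_mesh_oracle(c(0, 0, 0), dir_cam, mesh$vertices, mesh$faces)
    expect_equal(if (is.null(a)) 0L else a$face, o$face)
    if (o$face > 0) hits <- hits + 1
  }
  expect_gt(hits, 100)  # the scene is actually in view
})

test_that("mesh re-projection gives a correct z-buffered depth layer", {
  rig <- small_rig()
  # mesh fully behind the camera: empty buffer
  behind <- fronto_triangle(-50)
  buf <- reproject_mesh(behind, pose(), rig)
  expect_true(all(is.na(buf$depth)))
  expect_true(all(buf$face == 0))
  # single fronto-parallel triangle at known depth
  mesh <- fronto_triangle(60)
  buf <- reproject_mesh(mesh, pose(), rig)
  covered <- which(buf$face == 1)
  expect_gt(length(covered), 100)
  expect_lt(max(abs(buf$depth[covered] - 60)), 1e-6)
  # consistency with picking on 100 random covered pixels
  set.seed(113)
  idx <- sample(covered, 100)
  for (i in idx) {
    py <- (i - 1) %% rig$height
    px <- (i - 1) %/% rig$height
    a <- pick(c(px, py), pose(), rig, mesh)
    expect_equal(a$face, buf$face[i])
  }
})

test_that("re-projected depth matches rendered ground truth", {
  run <- small_run()
  res <- run$result
  fr1 <- small_frames(2)[[1]]
  buf <- reproject_mesh(res$mesh, res$trajectory[[1]], run$rig)
  both <- is.finite(buf$depth) & is.finite(fr1$depth)
  expect_gt(mean(both), 0.3)
  expect_lte(median(abs(buf$depth[both] - fr1$depth[both])), 2)
})

test_that("measurement on a flat sheet equals the straight distance", {
  mesh <- plane_mesh(31, 31, 1)
  a <- pick_point_on(mesh, c(5.2, 5.2))
  b <- pick_point_on(mesh, c(25.3, 20.1))
  path <- measure_on_surface(a, b, mesh)
  d <- sqrt(sum((a$position - b$position)^2))
  expect_lt(abs(path$length_mm - d) / d, 0.01)
  expect_gte(path$length_mm, path$chord_mm - 1e-12)
})

test_that("hemisphere measurement approaches the analytic geodesic", {
  R <- 10
  fine <- hemisphere_mesh(R, n_lat = 48)
  # two points a quarter great-circle apart on the equator-to-pole arc
  a <- anchor_near(fine, c(R, 0, 0))
  b <- anchor_near(fine, c(0, 0, R))
  p_fine <- measure_on_surface(a, b, fine)
  geo <- pi * R / 2
  expect_lt(abs(p_fine$length_mm - geo) / geo, 0.03)
  expect_gt(p_fine$length_mm, sqrt(2) * R)  # strictly above the chord
  # a coarser meshing is no closer than the fine one
  coarse <- hemisphere_mesh(R, n_lat = 14)
  p_coarse <- measure_on_surface(anchor_near(coarse, c(R, 0, 0)),
                                 anchor_near(coarse, c(0, 0, R)), coarse)
  expect_lte(abs(p_fine$length_mm - geo), abs(p_coarse$length_mm - geo) + 1e-9)
})

test_that("anchors in disconnected components are reported unreachable", {
  m1 <- plane_mesh(5, 5, 1)
  m2 <- plane_mesh(5, 5, 1)
  m2$vertices[, 1] <- m2$vertices[, 1] + 100
  mesh <- structure(list(vertices = rbind(m1$vertices, m2$vertices),
                         faces = rbind(m1$faces, m2$faces + nrow(m1$vertices)),
                         normals = rbind(m1$normals, m2$normals),
                         n_unreferenced = 0L),
                    class = "surface_mesh")
  a <- pick_point_on(mesh, c(2, 2))
  b <- anchor_near(mesh, c(102, 2, 0))
  expect_error(measure_on_surface(a, b, mesh), "unreachable|disconnected")
})

test_that("area highlighting matches analytic disc and cap areas", {
  # whole mesh
  mesh <- plane_mesh(41, 41, 1)
  a <- pick_point_on(mesh, c(20, 20))
  all_faces <- highlight_area(a, Inf, mesh)
  expect_equal(all_faces$area_mm2, mesh_area(mesh), tolerance = 1e-9)
  # planar disc of radius r: area within 5% of pi r^2
  r <- 12
  disc <- highlight_area(a, r, mesh)
  expect_lt(abs(disc$area_mm2 - pi * r^2) / (pi * r^2), 0.05)
  # hemisphere cap of angular radius theta: 2 pi R^2 (1 - cos theta)
  R <- 10; theta <- pi / 4
  hm <- hemisphere_mesh(R, n_lat = 48)
  top <- anchor_near(hm, c(0, 0, R))
  cap <- highlight_area(top, R * theta, hm)
  a_true <- 2 * pi * R^2 * (1 - cos(theta))
  expect_lt(abs(cap$area_mm2 - a_true) / a_true, 0.05)
})

test_that("labels orient along the local surface normal", {
  # fronto-parallel plane: label normal is the (+-) viewing direction
  mesh <- plane_mesh(11, 11, 1)
  mesh$vertices[, 3] <- 50
  a <- pick_point_on(mesh, c(5, 5))
  lab <- place_label(a, pose())
  expect_gt(abs(sum(lab$normal * c(0, 0, 1))), 0.999)
  # in-plane axes are orthonormal and orthogonal to the normal
  expect_equal(sum(lab$up * lab$right), 0, tolerance = 1e-9)
  expect_equal(sum(lab$up * lab$normal), 0, tolerance = 1e-9)
  expect_equal(sqrt(sum(lab$right^2)), 1, tolerance = 1e-9)
  # sphere: label normals radial within 5 degrees
  R <- 10
  hm <- hemisphere_mesh(R, n_lat = 40)
  set.seed(127)
  for (k in 1:20) {
    v <- hm$vertices[sample(nrow(hm$vertices), 1), ]
    if (v[3] < 0.3 * R) next  # stay clear of the open equator rim
    a <- anchor_near(hm, v)
    radial <- a$position / sqrt(sum(a$position^2))
    ang <- acos(min(1, abs(sum(place_label(a)$normal * radial))))
    expect_lt(ang * 180 / pi, 5)
  }
})

test_that("anchors and paths serialise to a JSON sidecar", {
  mesh <- plane_mesh(11, 11, 1)
  a <- pick_point_on(mesh, c(2, 2))
  b <- pick_point_on(mesh, c(8, 7))
  p <- measure_on_surface(a, b, mesh)
  path <- tempfile(fileext = ".json")
  write_overlay_json(list(a, b), list(p), path)
  back <- jsonlite::read_json(path)
  expect_length(back$anchors, 2)
  expect_equal(back$paths[[1]]$length_mm, p$length_mm, tolerance = 1e-9)
})
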