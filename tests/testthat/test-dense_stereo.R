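# ZNCC cost volume, winner-takes-all and Huber-L1 smoothing.

test_that("ZNCC equals 1 for identical and affinely related patches", {
  set.seed(61)
  p <- matrix(runif(49, 0, 255), 7, 7)
  expect_equal(zncc(p, p), 1)
  # affine illumination change: gain > 0 plus offset
  expect_equal(zncc(p, 1.7 * p + 31), 1, tolerance = 1e-12)
  # anti-correlated patch
  expect_equal(zncc(p, -p), -1, tolerance = 1e-12)
  # zero-variance patch: undefined, masked as NA (never NaN)
  flat <- matrix(5, 7, 7)
  expect_true(is.na(zncc(p, flat)))
  expect_true(is.na(zncc(flat, flat)))
})

test_that("the cost volume equals a brute-force double-loop oracle", {
  set.seed(67)
  L <- matrix(runif(16 * 16, 0, 255), 16, 16)
  R <- matrix(runif(16 * 16, 0, 255), 16, 16)
  vol <- build_cost_volume(L, R, d_range = c(1, 6), patch_radius = 2)
  oracle <- zncc_volume_oracle(L, R, 1, 6, 2)
  same_na <- is.na(vol$cost) == is.na(oracle)
  expect_true(all(same_na))
  expect_lt(max(abs(vol$cost - oracle), na.rm = TRUE), 1e-10)
  # every finite cost lies in the (negated) ZNCC range
  expect_true(all(abs(vol$cost[!is.na(vol$cost)]) <= 1 + 1e-12))
})

test_that("the cost volume is invariant to affine illumination changes", {
  set.seed(71)
  L <- matrix(runif(400, 0, 200), 20, 20)
  R <- matrix(runif(400, 0, 200), 20, 20)
  v1 <- build_cost_volume(L, R, c(1, 5), 2)
  v2 <- build_cost_volume(1.5 * L + 20, 0.7 * R + 40, c(1, 5), 2)
  expect_lt(max(abs(v1$cost - v2$cost), na.rm = TRUE), 1e-9)
})

test_that("a pure shift is recovered exactly by winner-takes-all", {
  set.seed(73)
  k <- 4
  base <- matrix(runif(40 * 60, 0, 255), 40, 60)
  L <- base
  R <- cbind(base[, (k + 1):ncol(base)], base[, seq_len(k)])
  # L(x) == R(x - k) for x > k
  vol <- build_cost_volume(L, R, c(1, 8), 2)
  wta <- winner_takes_all(vol, subpixel = FALSE)
  interior <- wta$disparity[, (k + 8):(ncol(L) - 8)]
  expect_true(mean(interior == k, na.rm = TRUE) > 0.99)
})

test_that("WTA breaks ties toward the smaller disparity", {
  vol <- structure(list(cost = array(0.5, c(3, 8, 4)), d_min = 2L,
                        d_max = 5L, patch_radius = 1L),
                   class = "cost_volume")
  vol$cost[2, 4, ] <- c(0.3, 0.1, 0.1, 0.4)  # tie at d = 3 and 4
  wta <- winner_takes_all(vol, subpixel = FALSE)
  expect_equal(wta$disparity[2, 4], 3)
  # all-equal column: smallest disparity wins
  expect_equal(wta$disparity[1, 1], 2)
})

test_that("sub-pixel refinement recovers a quadratic minimum to 0.05 px", {
  h <- 4; w <- 5; nd <- 9
  d_true <- 4.3
  cost <- array(NA_real_, c(h, w, nd))
  for (d in 1:nd) cost[, , d] <- 0.05 * (d - d_true)^2 - 0.8
  vol <- structure(list(cost = cost, d_min = 1L, d_max = 9L,
                        patch_radius = 1L), class = "cost_volume")
  wta <- winner_takes_all(vol, subpixel = TRUE)
  expect_lt(max(abs(wta$disparity - d_true)), 0.05)
})

test_that("all-masked pixels come out invalid", {
  cost <- array(NA_real_, c(3, 3, 4))
  cost[1, 1, ] <- c(0.5, 0.2, 0.9, 1)
  vol <- structure(list(cost = cost, d_min = 1L, d_max = 4L,
                        patch_radius = 1L), class = "cost_volume")
  wta <- winner_takes_all(vol)
  expect_true(wta$valid[1, 1])
  expect_false(any(wta$valid[-1]))
  expect_true(all(is.na(wta$disparity[!wta$valid])))
})

test_that("smoothing lowers both energy and RMSE on a noisy staircase", {
  set.seed(79)
  h <- 30; w <- 40; nd <- 10
  d_true <- matrix(3, h, w)
  d_true[, 21:40] <- 7
  # cost volume with minima at the true disparity
  cost <- array(0, c(h, w, nd))
  for (d in 1:nd) cost[, , d] <- 0.02 * (d - d_true)^2 - 0.9
  vol <- structure(list(cost = cost, d_min = 1L, d_max = 10L,
                        patch_radius = 1L), class = "cost_volume")
  wta <- winner_takes_all(vol, subpixel = FALSE)
  wta$disparity <- wta$disparity + matrix(rnorm(h * w, sd = 0.8), h, w)
  sm <- smooth_disparity(vol, wta, lambda = 1, iterations = 80)
  tr <- attr(sm, "energy_trace")
  expect_lt(tr["final"], tr["initial"])
  rmse <- function(u) sqrt(mean((u - d_true)^2))
  expect_lt(rmse(sm$disparity), rmse(wta$disparity))
})

test_that("an overwhelming data term reproduces the WTA input", {
  set.seed(83)
  L <- matrix(runif(600, 0, 255), 20, 30)
  R <- cbind(L[, 3:30], L[, 1:2])
  vol <- build_cost_volume(L, R, c(1, 6), 2)
  wta <- winner_takes_all(vol)
  sm <- smooth_disparity(vol, wta, lambda = 1e8, iterations = 20)
  ok <- wta$valid & is.finite(wta$disparity)
  expect_lt(max(abs(sm$disparity[ok] - wta$disparity[ok])), 0.2)
})

test_that("a flat cost volume smooths a noisy field toward constancy", {
  set.seed(89)
  h <- 20; w <- 20
  cost <- array(0, c(h, w, 8))
  vol <- structure(list(cost = cost, d_min = 1L, d_max = 8L,
                        patch_radius = 1L), class = "cost_volume")
  init <- structure(list(disparity = matrix(4 + rnorm(h * w, sd = 0.5), h, w),
                         valid = matrix(TRUE, h, w), d_min = 1L, d_max = 8L),
                    class = "disparity_map")
  sm <- smooth_disparity(vol, init, lambda = 1, iterations = 400)
  expect_lt(sd(sm$disparity), 0.25 * sd(init$disparity))
})

test_that("disparity maps back-project through Z = f B / d", {
  rig <- small_rig()
  h <- rig$height; w <- rig$width
  disp <- structure(list(disparity = matrix(10, h, w),
                         valid = matrix(TRUE, h, w), d_min = 1L, d_max = 64L),
                    class = "disparity_map")
  dp <- disparity_to_points(disp, rig)
  expect_true(all(abs(dp$points[, "z"] - rig$fx * rig$baseline_mm / 10) < 1e-12))
  # re-projection lands on the source pixels
  pr <- project_points(dp$points, pose(), rig, "left")
  expect_lt(max(abs(pr$x - dp$pixel[, "x"])), 0.5)
  expect_lt(max(abs(pr$y - dp$pixel[, "y"])), 0.5)
})

test_that("dense disparity from a rendered keyframe matches ground truth", {
  fr <- small_frames(2)[[1]]
  rig <- small_rig()
  vol <- build_cost_volume(fr$left, fr$right, c(1, 32), 3)
  wta <- winner_takes_all(vol)
  dtrue <- rig$fx * rig$baseline_mm / fr$depth
  ok <- wta$valid & is.finite(dtrue)
  frac <- mean(abs(wta$disparity - dtrue)[ok] <= 1, na.rm = TRUE)
  expect_gte(frac, 0.85)
  # smoothed cloud depth RMSE within 1 mm of truth
  sm <- smooth_disparity(vol, wta, iterations = 40, image = fr$left)
  dp <- disparity_to_points(sm, rig)
  zt <- fr$depth[cbind(dp$pixel[, "y"] + 1, dp$pixel[, "x"] + 1)]
  good <- is.finite(zt)
  expect_lt(sqrt(mean((dp$points[good, "z"] - zt[good])^2)), 1)
})

test_that("disparity maps round-trip through scaled 16-bit TIFF", {
  set.seed(97)
  d <- matrix(runif(200, 1, 60), 10, 20)
  d[1, 1:5] <- NA
  dm <- structure(list(disparity = d, valid = !is.na(d), d_min = 1L,
                       d_max = 64L), class = "disparity_map")
  path <- tempfile(fileext = ".tif")
  write_disparity(dm, path)
  back <- read_disparity(path)
  expect_equal(back$valid, dm$valid, ignore_attr = TRUE)
  expect_lt(max(abs(back$disparity - d), na.rm = TRUE), 1 / 256 + 1e-6)
})
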