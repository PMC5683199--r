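# Constant-velocity prediction, guided search, rigid alignment, RANSAC.

test_that("constant-velocity prediction handles rest, translation, rotation", {
  # rest state: pose unchanged
  st <- motion_state(pose(c(1, 2, 3), c(1, 0, 0, 0)))
  pr <- predict_pose(st)
  expect_equal(pr$pose$position, c(1, 2, 3))
  expect_equal(pr$pose$orientation, c(1, 0, 0, 0))
  # pure translation, four steps
  st <- motion_state(pose(), linear_velocity = c(1, 0, 0))
  for (k in 1:4) {
    pr <- predict_pose(st)
    st <- pr$state
    st$pose <- pr$pose
  }
  expect_equal(st$pose$position, c(4, 0, 0), tolerance = 1e-12)
  # quarter-turn per frame about z: four steps return to start
  st <- motion_state(pose(), angular_velocity = c(0, 0, pi / 2))
  for (k in 1:4) {
    pr <- predict_pose(st)
    st <- pr$state
    st$pose <- pr$pose
  }
  expect_lt(max(abs(quat_to_rotmat(st$pose$orientation) - diag(3))), 1e-9)
  expect_equal(sum(st$pose$orientation^2), 1, tolerance = 1e-12)
})

test_that("motion-state update recovers velocities from pose deltas", {
  st <- motion_state(pose())
  new <- pose(c(2, 0, 0), quat_from_rotvec(c(0, 0.1, 0)))
  st2 <- update_motion_state(st, new)
  expect_equal(st2$linear_velocity, c(2, 0, 0))
  expect_equal(st2$angular_velocity, c(0, 0.1, 0), tolerance = 1e-9)
  # prediction from the updated state continues the motion
  pr <- predict_pose(st2)
  expect_equal(pr$pose$position, c(4, 0, 0))
})

test_that("guided search windows contain the true projections", {
  rig <- small_rig()
  set.seed(31)
  lms <- cbind(runif(200, -20, 20), runif(200, -15, 15), runif(200, 60, 120))
  p <- pose()
  reg <- guided_search_regions(p, lms, rig, radius_px = 15)
  pr <- project_points(lms[reg$landmark, , drop = FALSE], p, rig)
  expect_true(all(abs(pr$x - reg$cx) <= 15 & abs(pr$y - reg$cy) <= 15))
  # landmark behind the camera yields no window
  behind <- matrix(c(0, 0, -50), 1)
  expect_equal(nrow(guided_search_regions(p, behind, rig)), 0)
  # slightly wrong prediction still captures >= 95% of true pixels
  p_err <- pose(c(1.5, -1, 0.5), quat_from_rotvec(c(0.5, 0.5, 0) * pi / 180))
  reg2 <- guided_search_regions(p_err, lms, rig, radius_px = 15)
  tru <- project_points(lms[reg2$landmark, , drop = FALSE], p, rig)
  inside <- abs(tru$x - reg2$cx) <= 15 & abs(tru$y - reg2$cy) <= 15
  expect_gte(mean(inside, na.rm = TRUE), 0.95)
})

test_that("minimal rigid solver matches a quaternion-method oracle", {
  # aligned triple: identity
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  tf <- solve_rigid(A, A)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(tf$translation)), 1e-12)
  # pure translation
  tf <- solve_rigid(A + 2.5, A)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-12)
  expect_equal(tf$translation, rep(2.5, 3), tolerance = 1e-12)
  # random triples vs the Horn quaternion oracle
  set.seed(17)
  for (k in 1:25) {
    B <- matrix(rnorm(9, sd = 10), 3)
    R0 <- random_rotation(runif(1, 0, 180))
    T0 <- rnorm(3, sd = 5)
    A <- B %*% t(R0) + matrix(T0, 3, 3, byrow = TRUE)
    tf <- solve_rigid(A, B)
    or <- horn_rigid_oracle(A, B)
    expect_lt(max(abs(tf$rotation - or$rotation)), 1e-9)
    expect_lt(max(abs(tf$translation - or$translation)), 1e-9)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(t(tf$rotation) %*% tf$rotation - diag(3))), 1e-9)
  }
  # collinear triple is rejected
  C <- cbind(1:3, 0, 0)
  expect_null(solve_rigid(C, C + 1))
})

test_that("RANSAC recovers an exact transform and the identity", {
  set.seed(41)
  B <- cbind(runif(100, -30, 30), runif(100, -30, 30), runif(100, 60, 120))
  # identity case
  est <- estimate_rigid_ransac(B, B)
  expect_true(est$ok)
  expect_lt(max(abs(est$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(est$transform$translation)), 1e-9)
  expect_true(all(est$inliers))
  # noise-free known transform
  R0 <- random_rotation(12)
  T0 <- c(3, -2, 1)
  A <- B %*% t(R0) + matrix(T0, 100, 3, byrow = TRUE)
  est <- estimate_rigid_ransac(A, B)
  expect_lt(max(abs(est$transform$rotation - R0)), 1e-9)
  expect_lt(max(abs(est$transform$translation - T0)), 1e-9)
})

test_that("RANSAC is robust to 30% outliers at sigma = 0.1 mm", {
  set.seed(43)
  n_in <- 70; n_out <- 30
  B <- cbind(runif(n_in + n_out, -30, 30), runif(n_in + n_out, -30, 30),
             runif(n_in + n_out, 60, 120))
  R0 <- random_rotation(8)
  T0 <- c(2, 1, -3)
  A <- B %*% t(R0) + matrix(T0, n_in + n_out, 3, byrow = TRUE)
  A[1:n_in, ] <- A[1:n_in, ] + matrix(rnorm(3 * n_in, sd = 0.1), n_in, 3)
  out_idx <- (n_in + 1):(n_in + n_out)
  A[out_idx, ] <- cbind(runif(n_out, -30, 30), runif(n_out, -30, 30),
                        runif(n_out, 60, 120))
  est <- estimate_rigid_ransac(A, B)
  expect_true(est$ok)
  ang <- acos(min(1, (sum(diag(t(R0) %*% est$transform$rotation)) - 1) / 2))
  expect_lte(ang * 180 / pi, 0.2)
  expect_lte(sqrt(sum((est$transform$translation - T0)^2)), 0.5)
  expect_gte(mean(est$inliers[1:n_in]), 0.95)
})

test_that("true inliers are recovered across seeds (50% outliers)", {
  recovered <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n_in <- 50; n_out <- 50
    B <- cbind(runif(n_in + n_out, -30, 30), runif(n_in + n_out, -30, 30),
               runif(n_in + n_out, 60, 120))
    R0 <- random_rotation(10)
    T0 <- rnorm(3, sd = 3)
    A <- B %*% t(R0) + matrix(T0, n_in + n_out, 3, byrow = TRUE)
    A[1:n_in, ] <- A[1:n_in, ] + matrix(rnorm(3 * n_in, sd = 0.05), n_in, 3)
    A[(n_in + 1):(n_in + n_out), ] <-
      cbind(runif(n_out, -30, 30), runif(n_out, -30, 30),
            runif(n_out, 60, 120))
    est <- estimate_rigid_ransac(A, B)
    est$ok && mean(est$inliers[1:n_in]) >= 0.95
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("non-rigid motion of 20% of points does not bias the estimate", {
  set.seed(47)
  n <- 200
  B <- cbind(runif(n, -30, 30), runif(n, -30, 30), runif(n, 60, 120))
  R0 <- random_rotation(6)
  T0 <- c(1, -1, 2)
  A <- B %*% t(R0) + matrix(T0, n, 3, byrow = TRUE)
  A <- A + matrix(rnorm(3 * n, sd = 0.05), n, 3)
  # 20% of the scene deforms (smooth drift up to ~4 mm)
  deform <- seq_len(0.2 * n)
  A[deform, ] <- A[deform, ] + matrix(runif(3 * length(deform), 2, 4),
                                      length(deform), 3)
  est <- estimate_rigid_ransac(A, B)
  ang <- acos(min(1, (sum(diag(t(R0) %*% est$transform$rotation)) - 1) / 2))
  expect_lte(ang * 180 / pi, 0.2)
  expect_lte(sqrt(sum((est$transform$translation - T0)^2)), 0.5)
})

test_that("refinement never worsens the inlier objective", {
  set.seed(53)
  for (k in 1:10) {
    n <- 60
    B <- cbind(runif(n, -30, 30), runif(n, -30, 30), runif(n, 60, 120))
    R0 <- random_rotation(15)
    A <- B %*% t(R0) + matrix(rnorm(3, 2), n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, sd = 0.2), n, 3)
    est <- estimate_rigid_ransac(A, B)
    expect_true(est$ok)
    # refit on the reported inliers cannot beat the returned transform
    refit <- solve_rigid(A[est$inliers, ], B[est$inliers, ])
    obj <- function(tf) sum(endogeo:::rigid_residuals(tf, A[est$inliers, ],
                                                      B[est$inliers, ]))
    expect_lte(obj(est$transform), obj(refit) + 1e-9)
  }
})

test_that("trajectories round-trip through the TUM format", {
  set.seed(59)
  poses <- lapply(1:5, function(i) pose(rnorm(3), quat_normalize(rnorm(4))))
  path <- tempfile(fileext = ".txt")
  write_trajectory_tum(poses, path)
  back <- read_trajectory_tum(path)
  for (i in 1:5) {
    expect_equal(back[[i]]$position, poses[[i]]$position, tolerance = 1e-6)
    expect_lt(min(sum((back[[i]]$orientation - poses[[i]]$orientation)^2),
                  sum((back[[i]]$orientation + poses[[i]]$orientation)^2)),
              1e-10)
  }
})
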