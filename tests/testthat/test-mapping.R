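# Keyframe selection and Huber-robust bundle adjustment.

test_that("keyframe criterion requires low overlap AND sufficient count", {
  mk <- function(n) seq_len(n)
  # overlap 90%, count 100 -> no keyframe
  expect_false(should_insert_keyframe(c(mk(90), 1000 + mk(10)), mk(100)))
  # overlap 70%, count 60 -> keyframe
  expect_true(should_insert_keyframe(c(mk(42), 1000 + mk(18)), mk(60)))
  # overlap 70%, count 40 -> no keyframe (count clause fails)
  expect_false(should_insert_keyframe(c(mk(28), 1000 + mk(12)), mk(40)))
  # boundary: overlap exactly 0.80 is not "< 80%"
  expect_false(should_insert_keyframe(c(mk(80), 1000 + mk(20)), mk(100)))
  # boundary: count exactly 50 does not "exceed 50"
  expect_false(should_insert_keyframe(c(mk(30), 1000 + mk(20)), mk(50)))
})

test_that("the Huber loss is quadratic below delta and linear above", {
  d <- 2
  expect_equal(huber_rho(0, d), 0)
  e <- seq(0, d, by = 0.1)
  expect_equal(huber_rho(e, d), e^2 / 2)
  e2 <- seq(d, 10, by = 0.5)
  expect_equal(diff(huber_rho(e2, d)) / diff(e2), rep(d, length(e2) - 1))
  # continuity at the transition
  expect_equal(huber_rho(d - 1e-9, d), huber_rho(d + 1e-9, d),
               tolerance = 1e-6)
  expect_equal(huber_weight(1, d), 1)
  expect_equal(huber_weight(8, d), d / 8)
})

test_that("the true configuration is a fixed point of bundle adjustment", {
  prob <- make_ba_problem(n_kf = 3, n_lm = 60)
  res <- bundle_adjust(prob$keyframes, prob$landmarks, prob$rig)
  expect_lt(tail(res$cost_trace, 1), 1e-10)
  expect_lt(max(abs(res$landmarks - prob$landmarks)), 1e-8)
  for (i in seq_along(prob$keyframes)) {
    expect_lt(max(abs(res$keyframes[[i]]$pose$position -
                        prob$keyframes[[i]]$pose$position)), 1e-8)
  }
})

test_that("BA reduces the reprojection RMS of a perturbed problem by 90%", {
  prob <- make_ba_problem(n_kf = 5, n_lm = 200, seed = 42)
  set.seed(1)
  lms <- prob$landmarks + matrix(rnorm(length(prob$landmarks), sd = 1),
                                 ncol = 3)
  pre <- ba_rms_reproj(prob$keyframes, lms, prob$rig)
  res <- bundle_adjust(prob$keyframes, lms, prob$rig, max_iterations = 50)
  post <- ba_rms_reproj(res$keyframes, res$landmarks, prob$rig)
  expect_lte(post, 0.1 * pre)
  # cost trace is monotone non-increasing
  expect_true(all(diff(res$cost_trace) <= 1e-9))
})

test_that("the first keyframe pose anchors the gauge bit-exactly", {
  prob <- make_ba_problem(n_kf = 4, n_lm = 80, seed = 9)
  set.seed(2)
  lms <- prob$landmarks + matrix(rnorm(length(prob$landmarks), sd = 0.5),
                                 ncol = 3)
  res <- bundle_adjust(prob$keyframes, lms, prob$rig)
  expect_identical(res$keyframes[[1]]$pose, prob$keyframes[[1]]$pose)
})

test_that("Huber BA shields inliers from a gross outlier landmark", {
  prob <- make_ba_problem(n_kf = 4, n_lm = 120, seed = 5)
  set.seed(3)
  lms0 <- prob$landmarks + matrix(rnorm(length(prob$landmarks), sd = 0.3),
                                  ncol = 3)
  # baseline: no outlier
  base <- bundle_adjust(prob$keyframes, lms0, prob$rig, huber_delta = 2)
  err_base <- sqrt(rowSums((base$landmarks - prob$landmarks)^2))
  # gross 50 mm outlier on one landmark
  lms1 <- lms0
  lms1[7, ] <- lms1[7, ] + c(50, 0, 0)
  rob <- bundle_adjust(prob$keyframes, lms1, prob$rig, huber_delta = 2)
  err_rob <- sqrt(rowSums((rob$landmarks - prob$landmarks)^2))
  inl <- setdiff(seq_len(nrow(lms0)), 7)
  expect_lte(mean(err_rob[inl]), 2 * max(mean(err_base[inl]), 1e-6))
  # quadratic loss drags the solution further than the Huber loss does
  quad <- bundle_adjust(prob$keyframes, lms1, prob$rig, huber_delta = Inf)
  err_quad <- sqrt(rowSums((quad$landmarks - prob$landmarks)^2))
  expect_lte(mean(err_rob[inl]), mean(err_quad[inl]) + 1e-9)
})

test_that("with delta -> Inf BA matches an unrobust least-squares oracle", {
  # a wide-baseline stereo pair: stereo observations fix the translation
  # scale, so the least-squares optimum is the exact configuration
  prob <- make_ba_problem(n_kf = 2, n_lm = 20, seed = 13, spread = 5,
                          stereo = TRUE)
  obs <- endogeo:::ba_flatten(prob$keyframes)
  free <- as.integer(names(which(table(obs$lm) >= 2)))
  # perturb only the landmarks BA may move, so the global optimum is the
  # exact configuration at zero cost
  set.seed(4)
  lms <- prob$landmarks
  lms[free, ] <- lms[free, ] + matrix(rnorm(3 * length(free), sd = 0.5),
                                      ncol = 3)
  res <- bundle_adjust(prob$keyframes, lms, prob$rig, huber_delta = Inf,
                       max_iterations = 60)
  # independent oracle: BFGS on the same least-squares objective over the
  # free parameters (second pose + all landmarks observed twice)
  par0 <- c(rep(0, 6), as.numeric(t(lms[free, ])))
  p2 <- prob$keyframes[[2]]$pose
  objective <- function(par) {
    poses <- list(prob$keyframes[[1]]$pose,
                  pose(p2$position + par[4:6],
                       quat_multiply(p2$orientation,
                                     quat_from_rotvec(par[1:3]))))
    lm2 <- lms
    lm2[free, ] <- matrix(par[-(1:6)], ncol = 3, byrow = TRUE)
    r <- endogeo:::ba_residuals(obs, poses, lm2, prob$rig)
    sum(r$norm^2) / 2
  }
  oracle <- optim(par0, objective, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-15))
  # observations are exact, so the global least-squares optimum is the true
  # configuration at cost ~0: both routes must land there
  expect_lt(tail(res$cost_trace, 1), 1e-8)
  expect_lte(tail(res$cost_trace, 1), oracle$value + 1e-8)
  expect_lt(max(abs(res$landmarks[free, ] - prob$landmarks[free, ])), 1e-6)
  lm_oracle <- matrix(oracle$par[-(1:6)], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(res$landmarks[free, ] - lm_oracle)), 1e-2)
})

test_that("point clouds are written as valid PLY", {
  pts <- matrix(rnorm(30), 10, 3)
  path <- tempfile(fileext = ".ply")
  write_ply_points(pts, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  expect_true("element vertex 10" %in% lines)
  body <- read.table(text = lines[(which(lines == "end_header") + 1):length(lines)])
  expect_equal(as.matrix(body), unname(pts), tolerance = 1e-5,
               ignore_attr = TRUE)
})
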