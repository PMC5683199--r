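# Independent oracle implementations used to cross-check the package's
# fast paths.  These deliberately use different algorithms from the
# implementation they verify.

# Two-view homogeneous linear (DLT) triangulation for a rectified stereo
# rig: builds both 3x4 projection matrices and takes the SVD null vector.
dlt_triangulate_oracle <- function(x_left, x_right, y, rig) {
  K <- matrix(c(rig$fx, 0, rig$cx,
                0, rig$fy, rig$cy,
                0, 0, 1), 3, 3, byrow = TRUE)
  P1 <- K %*% cbind(diag(3), c(0, 0, 0))
  P2 <- K %*% cbind(diag(3), c(-rig$baseline_mm, 0, 0))
  t(vapply(seq_along(x_left), function(i) {
    A <- rbind(x_left[i] * P1[3, ] - P1[1, ],
               y[i] * P1[3, ] - P1[2, ],
               x_right[i] * P2[3, ] - P2[1, ],
               y[i] * P2[3, ] - P2[2, ])
    v <- svd(A)$v[, 4]
    v[1:3] / v[4]
  }, numeric(3)))
}

# Horn's closed-form absolute orientation via the quaternion eigenvalue
# method (distinct from the SVD/Kabsch route used by solve_rigid).
horn_rigid_oracle <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- t(Bc) %*% Ac
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- quat_to_rotmat(q)
  list(rotation = R, translation = as.numeric(ca - R %*% cb))
}

# Brute-force ZNCC cost volume: per-pixel, per-disparity double loop over
# explicit patches through the public zncc() definition.
zncc_volume_oracle <- function(L, R, dmin, dmax, radius) {
  h <- nrow(L); w <- ncol(L)
  nd <- dmax - dmin + 1
  vol <- array(NA_real_, c(h, w, nd))
  for (di in seq_len(nd)) {
    d <- dmin + di - 1
    for (x in seq_len(w)) {
      for (y in seq_len(h)) {
        if (x - radius < 1 || x + radius > w) next
        if (y - radius < 1 || y + radius > h) next
        xr <- x - d
        if (xr - radius < 1 || xr + radius > w) next
        lp <- L[(y - radius):(y + radius), (x - radius):(x + radius)]
        rp <- R[(y - radius):(y + radius), (xr - radius):(xr + radius)]
        z <- zncc(lp, rp)
        if (!is.na(z)) vol[y, x, di] <- -z
      }
    }
  }
  vol
}

# Double-loop RMSD straight from the printed formula.
rmsd_oracle <- function(Z, z) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(Z))) {
    for (j in seq_len(ncol(Z))) {
      if (is.na(z[i, j])) next
      s <- s + (Z[i, j] - z[i, j])^2
      n <- n + 1
    }
  }
  sqrt(s / n)
}

# All-triangles ray intersection oracle (vectorised Moller-Trumbore in R).
ray_mesh_oracle <- function(orig, dir, V, F) {
  best_t <- Inf; best_f <- 0L
  for (f in seq_len(nrow(F))) {
    v0 <- V[F[f, 1], ]; v1 <- V[F[f, 2], ]; v2 <- V[F[f, 3], ]
    e1 <- v1 - v0; e2 <- v2 - v0
    p <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-12) next
    tv <- orig - v0
    u <- sum(tv * p) / det
    if (u < -1e-9 || u > 1 + 1e-9) next
    q <- c(tv[2] * e1[3] - tv[3] * e1[2],
           tv[3] * e1[1] - tv[1] * e1[3],
           tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(dir * q) / det
    if (v < -1e-9 || u + v > 1 + 1e-9) next
    tt <- sum(e2 * q) / det
    if (tt > 1e-9 && tt < best_t) { best_t <- tt; best_f <- f }
  }
  list(face = best_f, t = best_t)
}
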