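# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (endpoint reduction, closed-form moments) so that
# agreement is evidence, not tautology.

# Brute-force collision check: sample points uniformly on the capsule surface
# (cylindrical side + the two cap spheres, area-weighted) and test whether any
# sampled point lies outside the channel wall. The supremum of the radial
# distance over the capsule solid is attained on this surface.
oracle_collides <- function(p, x, u, ch, n = 1e5) {
  r <- p$r
  l <- p$l
  a_side <- 2 * pi * r * l
  a_caps <- 4 * pi * r^2
  n_side <- round(n * a_side / (a_side + a_caps))
  n_caps <- n - n_side
  pts <- NULL
  if (n_caps > 0) {
    dirs <- matrix(rnorm(3 * n_caps), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    side <- sign(dirs %*% u)
    side[side == 0] <- 1
    centers <- matrix(x, n_caps, 3, byrow = TRUE) +
      (side * (l / 2)) %*% t(u / sqrt(sum(u^2)))
    pts <- centers + r * dirs
  }
  if (n_side > 0) {
    # orthonormal basis perpendicular to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- w - sum(w * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    s <- runif(n_side, -l / 2, l / 2)
    psi <- runif(n_side, 0, 2 * pi)
    side_pts <- matrix(x, n_side, 3, byrow = TRUE) + s %*% t(u) +
      r * (cos(psi) %*% t(e1) + sin(psi) %*% t(e2))
    pts <- rbind(pts, side_pts)
  }
  any(pts[, 1]^2 + pts[, 2]^2 > ch$radius^2)
}

# Quadrature oracle for the uniform-density capsule inertia tensor (total
# mass 1): integrate over circular cross-sections perpendicular to the
# symmetry axis. For a slice of radius R(z) at height z:
#   dMzz = rho * pi R^4 / 2 dz
#   dMxx = rho * (pi R^4 / 4 + pi R^2 z^2) dz
oracle_inertia <- function(l, d) {
  r <- d / 2
  Rz <- function(z) {
    out <- numeric(length(z))
    core <- abs(z) <= l / 2
    out[core] <- r
    out[!core] <- sqrt(pmax(r^2 - (abs(z[!core]) - l / 2)^2, 0))
    out
  }
  vol <- pi * r^2 * l + 4 / 3 * pi * r^3
  rho <- 1 / vol
  zmax <- l / 2 + r
  Mzz <- integrate(function(z) rho * pi * Rz(z)^4 / 2, -zmax, zmax,
                   rel.tol = 1e-12, subdivisions = 1000L)$value
  Mxx <- integrate(function(z) rho * (pi * Rz(z)^4 / 4 + pi * Rz(z)^2 * z^2),
                   -zmax, zmax, rel.tol = 1e-12, subdivisions = 1000L)$value
  diag(c(Mxx, Mxx, Mzz))
}

# Explicit lab-frame conjugation R M R^T for the axial moment, with R any
# rotation mapping the body z-axis onto u.
oracle_axial_moment <- function(p, u, A) {
  u <- u / sqrt(sum(u^2))
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- w - sum(w * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  R <- cbind(e1, e2, u)    # columns: images of body x, y, z
  M_lab <- R %*% p$M_body %*% t(R)
  drop(t(A) %*% M_lab %*% A)
}

# Bootstrap standard deviation of the sample median.
boot_median_sd <- function(x, B = 200L) {
  meds <- vapply(seq_len(B), function(i) {
    median(sample(x, length(x), replace = TRUE))
  }, numeric(1))
  sd(meds)
}

# Minimal hand-built ensemble for the analysis pipeline: `pos_list` holds
# per-trajectory position matrices on a common stride grid.
fake_ensemble <- function(pos_list, stride = 1L, fpt = NULL, theta = NULL,
                          censored = NULL, L = 14.3, sigma_x = 0.05) {
  n <- length(pos_list)
  if (is.null(fpt)) fpt <- rep(NA_real_, n)
  if (is.null(theta)) theta <- rep(NA_real_, n)
  if (is.null(censored)) censored <- is.na(fpt)
  cfg <- sim_config(spherocylinder(l = 0, d = 0.1), channel(L),
                    sigma_x = sigma_x, n_traj = n, seed = 1L,
                    record_stride = stride)
  trajectories <- lapply(seq_len(n), function(i) {
    pos <- pos_list[[i]]
    if (ncol(pos) == 4L)
      pos <- cbind(pos, ux = 0, uy = 0, uz = 1)
    colnames(pos) <- c("t", "x", "y", "z", "ux", "uy", "uz")
    structure(list(fpt = fpt[i], censored = censored[i],
                   exit_theta = theta[i],
                   steps = if (is.na(fpt[i])) cfg$max_steps else fpt[i],
                   accepted_translations = 0, accepted_rotations = 0,
                   positions = pos, seed = i),
              class = "pore_trajectory")
  })
  structure(list(config = cfg, trajectories = trajectories,
                 subseeds = seq_len(n)),
            class = "pore_ensemble")
}
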