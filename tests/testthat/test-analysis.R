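test_that("MSD of hand-built trajectories equals the exact average", {
  # two 3-step trajectories on a stride-1 grid
  p1 <- cbind(t = 0:3, x = c(0, 1, 1, 2), y = c(0, 0, 1, 1), z = c(0, 0, 0, 1))
  p2 <- cbind(t = 0:3, x = c(0, 0, 0, 0), y = c(0, 2, 0, 2), z = c(0, 0, 1, 1))
  ens <- fake_ensemble(list(p1, p2), stride = 1L)
  curve <- compute_msd(ens)
  expect_equal(curve$t, 0:3)
  expect_equal(curve$n_alive, rep(2L, 4))
  expect_equal(curve$msd, c(0, (1 + 4) / 2, (2 + 1) / 2, (6 + 5) / 2))
})

test_that("a stationary trajectory has identically zero MSD", {
  pos <- cbind(t = 0:10, x = 0, y = 0, z = 0)
  curve <- compute_msd(fake_ensemble(list(pos), stride = 1L))
  expect_true(all(curve$msd == 0))
})

test_that("attrition reduces n_alive but never corrupts the grid", {
  pA <- cbind(t = c(0, 1, 2, 3, 4), x = 0, y = 0, z = c(0, 1, 2, 3, 4))
  pB <- cbind(t = c(0, 1), x = 0, y = 0, z = c(0, 2))   # absorbed early
  curve <- compute_msd(fake_ensemble(list(pA, pB), stride = 1L))
  expect_equal(curve$n_alive, c(2L, 2L, 1L, 1L, 1L))
  expect_equal(curve$msd[1:2], c(0, (1 + 4) / 2))
  expect_equal(curve$msd[3:5], c(4, 9, 16))
})

test_that("free 3D Gaussian walk recovers msd = 3 sigma_x^2 t and alpha = 1", {
  set.seed(41)
  sigma_x <- 0.05
  n <- 400
  steps <- 300
  pos_list <- lapply(seq_len(n), function(i) {
    xyz <- apply(matrix(rnorm(3 * steps, 0, sigma_x), ncol = 3), 2, cumsum)
    cbind(t = 0:steps, x = c(0, xyz[, 1]), y = c(0, xyz[, 2]),
          z = c(0, xyz[, 3]))
  })
  curve <- compute_msd(fake_ensemble(pos_list, stride = 1L))
  expect_equal(curve$msd[curve$t == 100], 3 * sigma_x^2 * 100,
               tolerance = 0.1)
  fit <- fit_diffusion(curve, tmin = steps, window = c(3, steps))
  expect_equal(fit$alpha, 1, tolerance = 0.05)
  expect_equal(2 * fit$D, 3 * sigma_x^2, tolerance = 0.1)
})

test_that("diffusion fit is exact on noiseless power laws", {
  t <- seq(0, 5000, by = 100)
  mk <- function(D, a) {
    structure(data.frame(t = t, msd = 2 * D * t^a,
                         n_alive = 100L),
              class = c("msd_curve", "data.frame"))
  }
  f1 <- fit_diffusion(mk(0.002, 1.0), tmin = 5000)
  expect_equal(f1$D, 0.002, tolerance = 1e-10)
  expect_equal(f1$alpha, 1.0, tolerance = 1e-10)
  f2 <- fit_diffusion(mk(0.001, 0.8), tmin = 5000)
  expect_equal(f2$D, 0.001, tolerance = 1e-10)
  expect_equal(f2$alpha, 0.8, tolerance = 1e-10)
  expect_equal(unname(coef(f2)), c(0.001, 0.8), tolerance = 1e-10)
  expect_error(fit_diffusion(mk(0.002, 1), tmin = 300), "5 grid points")
})

test_that("diffusion fit tolerates multiplicative noise with small bias", {
  set.seed(43)
  t <- seq(100, 10000, by = 100)
  for (rep in 1:5) {
    msd <- 2 * 0.0015 * t^0.95 * exp(rnorm(length(t), 0, 0.1))
    curve <- structure(data.frame(t = t, msd = msd, n_alive = 100L),
                       class = c("msd_curve", "data.frame"))
    fit <- fit_diffusion(curve, tmin = 10000, window = range(t))
    expect_equal(fit$alpha, 0.95, tolerance = 0.02)
  }
})

test_that("empirical survival is a valid step estimate", {
  S <- survival_curve(c(10, 20, 30))
  expect_equal(S$time, c(10, 20, 30))
  expect_equal(S$surv, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(S$surv) <= 0))
  expect_true(all(S$surv >= 0 & S$surv <= 1))
  expect_error(survival_curve(c(100, 200), censored = c(TRUE, TRUE)),
               "censored")
})

test_that("right-censored samples prolong the risk set", {
  S <- survival_curve(c(10, 20, 50, 50), censored = c(FALSE, FALSE, TRUE, TRUE))
  # Kaplan-Meier: S(10+) = 3/4, S(20+) = 3/4 * 2/3 = 1/2, then flat
  expect_equal(S$surv[S$time == 10], 3 / 4)
  expect_equal(S$surv[S$time == 20], 1 / 2)
})

test_that("exponential tails are recovered by the survival fit", {
  # exact exponential on a grid: lambda recovered to numerical precision
  tt <- seq(100, 5e5, by = 100)
  Sx <- structure(data.frame(time = tt, surv = exp(-2e-5 * tt)),
                  class = c("survival_curve", "data.frame"))
  attr(Sx, "fpt") <- tt
  attr(Sx, "censored") <- rep(FALSE, length(tt))
  fit <- fit_lambda(Sx, tail_start = 0, trim = 0)
  expect_equal(fit$lambda, 2e-5, tolerance = 1e-8)
  expect_equal(fit$A, 1, tolerance = 1e-6)
  # sampled exponentials: slope within 5%
  set.seed(47)
  smp <- rexp(1e4, rate = 1e-4)
  fit2 <- fit_lambda(survival_curve(smp))
  expect_equal(fit2$lambda, 1e-4, tolerance = 0.05)
  expect_equal(fit2$median_fpt, median(smp))
  expect_equal(fit_lambda(survival_curve(as.numeric(1:101)),
                          tail_start = 0)$median_fpt, 51)
  expect_error(fit_lambda(survival_curve(c(1, 2, 3))), "10 points")
})

test_that("isotropic orientations give a flat reweighted angle density", {
  set.seed(53)
  th <- acos(1 - 2 * runif(1e5))   # density sin(theta)/2 on [0, pi]
  ang <- angle_distribution(th)
  expect_equal(sum(ang$p_theta * diff(ang$bin_edges)), 1, tolerance = 1e-9)
  # per-bin deviation scaled by its sampling error (edge bins carry very
  # little sphere measure, so a flat relative band would be noise-dominated)
  w <- cos(ang$bin_edges[-37]) - cos(ang$bin_edges[-1])
  se <- (1 / pi) / sqrt(1e5 * w / 2)
  expect_lt(max(abs(ang$p_theta - 1 / pi) / se), 5)
  # wide central bins are flat to within 5% relative
  mid_bins <- 10:27
  expect_lt(max(abs(ang$p_theta[mid_bins] - 1 / pi)) / (1 / pi), 0.05)
  expect_equal(angle_sigma(ang), pi / sqrt(3), tolerance = 0.01)
})

test_that("angle histogram localizes a spike and stays normalized", {
  th <- pi / 2 + 0.04 + runif(500, -0.01, 0.01)   # interior of one bin
  ang <- angle_distribution(th)
  expect_equal(sum(ang$p_theta > 0), 1L)
  expect_equal(sum(ang$p_theta * diff(ang$bin_edges)), 1, tolerance = 1e-9)
  expect_error(angle_distribution(numeric(0)), "no exit angles")
  expect_error(angle_distribution(c(1, 4)), "0, pi")
})

test_that("second moment: uniform density and symmetric two-point mass", {
  expect_equal(angle_sigma(uniform_angle_summary(360)), pi / sqrt(3),
               tolerance = 1e-4)
  expect_equal(angle_sigma(uniform_angle_summary(36)), pi / sqrt(3),
               tolerance = 1e-3)
  # half the mass at each end: sigma^2 -> (0 + pi^2)/2 up to bin-centre offset
  ang <- angle_distribution(c(rep(1e-3, 500), rep(pi - 1e-3, 500)))
  w <- diff(ang$bin_edges)
  direct <- sqrt(sum(ang$mid^2 * ang$p_theta * w))   # direct sum cross-check
  expect_equal(angle_sigma(ang), direct)
  expected <- sqrt((ang$mid[1]^2 + ang$mid[36]^2) / 2)
  expect_equal(angle_sigma(ang), expected, tolerance = 1e-9)
  expect_equal(expected, sqrt(pi^2 / 2), tolerance = 0.02)
})

test_that("full analysis runs end to end on a small simulated ensemble", {
  p <- spherocylinder(l = 0, d = 0.3)
  cfg <- sim_config(p, channel(2), n_traj = 60, seed = 61, record_stride = 5)
  ens <- run_ensemble(cfg)
  an <- analyze_ensemble(ens)
  expect_s3_class(an, "pore_analysis")
  expect_gt(an$diffusion$D, 0)
  expect_gt(an$survival_fit$lambda, 0)
  expect_true(an$sigma_theta > 0 && an$sigma_theta < pi / sqrt(3) * 1.1)
  expect_error(analyze_ensemble(fake_ensemble(list(cbind(t = 0, x = 0, y = 0,
                                                         z = 0)))),
               "insufficient ensemble")
})
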