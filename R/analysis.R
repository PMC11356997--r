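#' Ensemble mean squared displacement
#'
#' Computes the mean squared displacement (MSD) of the particle centre from
#' its starting point (the origin) on the recording grid, averaging at each
#' time over the trajectories that are still inside the channel. The number
#' of contributing trajectories `n_alive` is reported alongside, so fits can
#' be restricted to times where the full ensemble contributes (attrition by
#' absorption would otherwise bias the tail).
#'
#' @param ensemble A `"pore_ensemble"` with recorded positions.
#' @param t_max Optional cap on the time grid (steps).
#' @return An object of class `"msd_curve"`: a data frame with columns `t`,
#'   `msd`, `n_alive`.
#' @export
compute_msd <- function(ensemble, t_max = NULL) {
  stopifnot(inherits(ensemble, "pore_ensemble"))
  trajs <- ensemble$trajectories
  if (length(trajs) == 0L) stop("empty ensemble")
  if (nrow(trajs[[1]]$positions) == 0L)
    stop("ensemble has no recorded positions (record_positions = FALSE?)")
  stride <- ensemble$config$record_stride
  horizon <- max(vapply(trajs, function(tr) max(tr$positions[, "t"]),
                        numeric(1)))
  if (!is.null(t_max)) horizon <- min(horizon, t_max)
  grid <- seq(0, horizon, by = stride)
  sumsq <- numeric(length(grid))
  n_alive <- integer(length(grid))
  for (tr in trajs) {
    pos <- tr$positions
    k <- min(nrow(pos), length(grid))
    sq <- pos[seq_len(k), "x"]^2 + pos[seq_len(k), "y"]^2 +
      pos[seq_len(k), "z"]^2
    sumsq[seq_len(k)] <- sumsq[seq_len(k)] + sq
    n_alive[seq_len(k)] <- n_alive[seq_len(k)] + 1L
  }
  keep <- n_alive > 0L
  out <- data.frame(t = grid[keep], msd = sumsq[keep] / n_alive[keep],
                    n_alive = n_alive[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the diffusion law to an MSD curve
#'
#' Ordinary least squares on `log(msd) = log(2 D) + alpha * log(t)` over the
#' grid points inside the fitting window. The default window is
#' `[0.01 * tmin, tmin]`, where `tmin` is the minimal observed first-passage
#' time in the ensemble: below `tmin` every trajectory is still inside, so
#' neither the reflecting entrance transient nor absorption attrition
#' distorts the averaged curve. `alpha = 1` is normal diffusion; smaller or
#' larger values indicate sub- or superdiffusion.
#'
#' @param curve An `"msd_curve"`.
#' @param tmin Minimal observed first-passage time (steps); see [min_fpt()].
#' @param window Fitting window `c(t_lo, t_hi)` in steps; defaults to
#'   `c(0.01 * tmin, tmin)`.
#' @return An object of class `"diffusion_fit"` with elements `D`, `alpha`,
#'   `window`, `n_points` and the residual standard error.
#' @export
fit_diffusion <- function(curve, tmin, window = c(0.01 * tmin, tmin)) {
  stopifnot(inherits(curve, "msd_curve"))
  sel <- curve$t >= window[1] & curve$t <= window[2] &
    curve$t > 0 & curve$msd > 0
  if (sum(sel) < 5L)
    stop("fitting window contains fewer than 5 grid points")
  fit <- stats::lm(log(msd) ~ log(t), data = curve[sel, ])
  cf <- stats::coef(fit)
  structure(
    list(D = unname(exp(cf[1]) / 2), alpha = unname(cf[2]),
         window = window, n_points = sum(sel),
         sigma_resid = sqrt(sum(stats::resid(fit)^2) /
                              stats::df.residual(fit))),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Diffusion fit over t in [%g, %g] (%d points):\n",
              x$window[1], x$window[2], x$n_points))
  cat(sprintf("  D = %.4g length^2/step^alpha, alpha = %.4g (resid SE %.3g)\n",
              x$D, x$alpha, x$sigma_resid))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D = object$D, alpha = object$alpha)
}

#' Minimal observed first-passage time
#'
#' @param ensemble A `"pore_ensemble"`.
#' @return The smallest uncensored first-passage time, in steps.
#' @export
min_fpt <- function(ensemble) {
  fp <- first_passage(ensemble)
  if (all(fp$censored)) stop("all trajectories censored")
  min(fp$fpt_steps[!fp$censored])
}

#' Empirical survival function of the first-passage time
#'
#' Kaplan-Meier estimate of `S(t)`, the fraction of particles still inside
#' the channel after `t` steps. Censored trajectories enter as right-censored
#' (they contribute to the risk set up to `max_steps`); with no censoring the
#' estimate reduces to one minus the empirical CDF.
#'
#' @param fpt_samples Either a `"pore_ensemble"` or a numeric vector of
#'   first-passage times.
#' @param censored Logical vector (recycled `FALSE`) when `fpt_samples` is
#'   numeric; censored entries hold the censoring time (`max_steps`).
#' @return An object of class `"survival_curve"`: a data frame with columns
#'   `time` and `surv` (the value of S just after `time`), plus the raw
#'   samples as attributes.
#' @export
survival_curve <- function(fpt_samples, censored = NULL) {
  if (inherits(fpt_samples, "pore_ensemble")) {
    fp <- first_passage(fpt_samples)
    times <- ifelse(fp$censored, fpt_samples$config$max_steps, fp$fpt_steps)
    censored <- fp$censored
  } else {
    times <- as.numeric(fpt_samples)
    if (is.null(censored)) censored <- rep(FALSE, length(times))
  }
  if (all(censored)) stop("all samples censored: no survival estimate")
  sf <- survival::survfit(survival::Surv(times, !censored) ~ 1)
  out <- data.frame(time = sf$time, surv = sf$surv)
  attr(out, "fpt") <- times
  attr(out, "censored") <- censored
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Fit the exponential tail of the survival function
#'
#' At long times the survival probability decays exponentially,
#' `S(t) ~ A * exp(-lambda t)`; `lambda` is obtained by least squares on
#' `log S(t)` over the tail window. By default the window starts at the
#' median uncensored first-passage time (short times, where a particle cannot
#' yet have crossed the channel, are excluded) and drops the last 1% of event
#' times, where the step estimate of S is noisiest. The median first-passage
#' time `Mt` is reported alongside as the bulk transport summary.
#'
#' @param S A `"survival_curve"`.
#' @param tail_start Beginning of the tail window (steps); default the median
#'   uncensored first-passage time.
#' @param trim Fraction of the largest event times to drop (default 0.01).
#' @return An object of class `"survival_fit"` with elements `lambda`, `A`,
#'   `median_fpt`, `tail_window`, `n_points`.
#' @export
fit_lambda <- function(S, tail_start = NULL, trim = 0.01) {
  stopifnot(inherits(S, "survival_curve"))
  fpt <- attr(S, "fpt")
  cens <- attr(S, "censored")
  med <- stats::median(fpt[!cens])
  if (is.null(tail_start)) tail_start <- med
  t_hi <- stats::quantile(S$time, 1 - trim, names = FALSE)
  sel <- S$time > tail_start & S$time <= t_hi & S$surv > 0
  if (sum(sel) < 10L)
    stop("fewer than 10 points in the survival tail window")
  fit <- stats::lm(log(surv) ~ time, data = S[sel, ])
  cf <- stats::coef(fit)
  structure(
    list(lambda = unname(-cf[2]), A = unname(exp(cf[1])),
         median_fpt = med, tail_window = c(tail_start, t_hi),
         n_points = sum(sel)),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Survival tail fit over t in [%g, %g] (%d points):\n",
              x$tail_window[1], x$tail_window[2], x$n_points))
  cat(sprintf("  lambda = %.4g per step, A = %.4g, median FPT Mt = %g steps\n",
              x$lambda, x$A, x$median_fpt))
  invisible(x)
}

#' @export
coef.survival_fit <- function(object, ...) {
  c(lambda = object$lambda, A = object$A, median_fpt = object$median_fpt)
}

#' Exit-orientation distribution with sphere-measure reweighting
#'
#' Histograms the exit angles theta (between the particle axis and the pore
#' axis, in `[0, pi]`) and divides each bin count by the exact sphere-measure
#' weight of the bin, `integral of sin(theta) over the bin`, before
#' normalising to unit integral. Under this reweighting an isotropically
#' oriented particle yields a flat density `p(theta) = 1/pi`; alignment with
#' the channel axis shows up as excess weight near 0 and pi. Using the exact
#' bin integral of sin (rather than sin at the bin centre) keeps the edge
#' bins at theta near 0 and pi finite.
#'
#' @param exit_thetas Either a `"pore_ensemble"` or a numeric vector of
#'   angles in radians, `[0, pi]`.
#' @param n_bins Number of equal-width bins on `[0, pi]` (default 36).
#' @return An object of class `"angle_summary"` with elements `bin_edges`,
#'   `mid`, `p_theta` (reweighted, normalised density), `p_raw` (plain
#'   histogram density, for comparison), and `n`.
#' @export
angle_distribution <- function(exit_thetas, n_bins = 36) {
  if (inherits(exit_thetas, "pore_ensemble")) {
    fp <- first_passage(exit_thetas)
    exit_thetas <- fp$exit_theta_rad[!fp$censored]
  }
  th <- as.numeric(exit_thetas)
  th <- th[!is.na(th)]
  if (length(th) == 0L) stop("no exit angles supplied")
  if (any(th < -1e-9 | th > pi + 1e-9))
    stop("exit angles must lie in [0, pi]")
  th <- pmin(pmax(th, 0), pi)
  edges <- seq(0, pi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(th, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  width <- diff(edges)
  w_sphere <- cos(edges[-length(edges)]) - cos(edges[-1])  # exact sin integral
  p <- counts / w_sphere
  p <- p / sum(p * width)
  structure(
    list(bin_edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
         p_theta = p, p_raw = counts / (length(th) * width), n = length(th)),
    class = "angle_summary"
  )
}

#' Second moment of the exit-angle distribution
#'
#' Computes `sigma = sqrt(integral of theta^2 p(theta) dtheta)` by midpoint
#' quadrature on the reweighted histogram. For the uniform density
#' `p = 1/pi` this gives `pi/sqrt(3) ~ 1.814` (free rotation); strong
#' alignment with the channel axis drives sigma down.
#'
#' @param summary An `"angle_summary"`.
#' @return sigma in radians.
#' @export
angle_sigma <- function(summary) {
  stopifnot(inherits(summary, "angle_summary"))
  width <- diff(summary$bin_edges)
  sqrt(sum(summary$mid^2 * summary$p_theta * width))
}

#' Uniform (free-rotation) exit-angle reference
#'
#' Builds the exact uniform orientation-angle density `p(theta) = 1/pi` on a
#' histogram grid, the reference an isotropically oriented (freely rotating)
#' particle attains after sphere-measure reweighting. Its second moment
#' [angle_sigma()] is `pi/sqrt(3) ~ 1.814`.
#'
#' @param n_bins Number of bins on `[0, pi]`.
#' @return An `"angle_summary"` with flat `p_theta`.
#' @export
uniform_angle_summary <- function(n_bins = 360) {
  edges <- seq(0, pi, length.out = n_bins + 1L)
  structure(
    list(bin_edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
         p_theta = rep(1 / pi, n_bins),
         p_raw = (cos(edges[-length(edges)]) - cos(edges[-1])) /
           diff(edges) / 2,
         n = 0L),
    class = "angle_summary"
  )
}

#' @export
print.angle_summary <- function(x, ...) {
  cat(sprintf("Exit-angle distribution: %d samples in %d bins on [0, pi]\n",
              x$n, length(x$mid)))
  cat(sprintf("  sigma = %.4g rad (uniform reference pi/sqrt(3) = %.4g)\n",
              angle_sigma(x), pi / sqrt(3)))
  invisible(x)
}

#' Full analysis of a simulated ensemble
#'
#' Runs the three observable pipelines on one ensemble: MSD with diffusion
#' fit over `[0.01 tmin, tmin]`, survival curve with exponential-tail rate
#' and median first-passage time, and the sphere-reweighted exit-angle
#' distribution with its second moment.
#'
#' @param ensemble A `"pore_ensemble"`.
#' @param n_bins Bins for the angle histogram.
#' @return An object of class `"pore_analysis"` holding `msd`, `diffusion`,
#'   `survival`, `survival_fit`, `angles`, `sigma_theta` and the censoring
#'   count.
#' @export
analyze_ensemble <- function(ensemble, n_bins = 36) {
  stopifnot(inherits(ensemble, "pore_ensemble"))
  if (length(ensemble$trajectories) < 2L)
    stop("insufficient ensemble: need at least 2 trajectories for fits")
  fp <- first_passage(ensemble)
  tmin <- min_fpt(ensemble)
  msd <- compute_msd(ensemble)
  dfit <- fit_diffusion(msd, tmin)
  S <- survival_curve(ensemble)
  sfit <- fit_lambda(S)
  ang <- angle_distribution(ensemble, n_bins = n_bins)
  structure(
    list(msd = msd, diffusion = dfit, survival = S, survival_fit = sfit,
         angles = ang, sigma_theta = angle_sigma(ang),
         n_censored = sum(fp$censored), tmin = tmin),
    class = "pore_analysis"
  )
}

#' @export
print.pore_analysis <- function(x, ...) {
  cat(sprintf(
    "D = %.4g, alpha = %.3f, lambda = %.4g, Mt = %g, sigma_theta = %.3f (censored %d)\n",
    x$diffusion$D, x$diffusion$alpha, x$survival_fit$lambda,
    x$survival_fit$median_fpt, x$sigma_theta, x$n_censored))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, fit = NULL, ...) {
  sel <- x$t > 0 & x$msd > 0
  graphics::plot(x$t[sel], x$msd[sel], log = "xy", type = "p", pch = 16,
                 cex = 0.5, xlab = "t (steps)", ylab = "MSD", ...)
  if (!is.null(fit)) {
    tt <- x$t[sel]
    graphics::lines(tt, 2 * fit$D * tt^fit$alpha, col = 2, lwd = 2)
  }
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$time, x$surv, log = "y", type = "s",
                 xlab = "t (steps)", ylab = "S(t)", ...)
  if (!is.null(fit))
    graphics::lines(x$time, fit$A * exp(-fit$lambda * x$time), col = 2)
  invisible(x)
}

#' @export
plot.angle_summary <- function(x, ...) {
  graphics::plot(x$mid, x$p_theta, type = "h", lwd = 3,
                 xlab = expression(theta), ylab = expression(p(theta)), ...)
  graphics::abline(h = 1 / pi, lty = 2)
  invisible(x)
}
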