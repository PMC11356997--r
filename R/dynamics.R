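#' Simulation configuration
#'
#' Bundles a particle, a channel, and the stochastic-update parameters into a
#' validated configuration. Defaults follow the reference study conditions:
#' translational step scale `sigma_x = 0.05`, channel length `L = 14.3` (in
#' channel-width units) and 5000 trajectories per ensemble.
#'
#' @param particle A [spherocylinder()].
#' @param channel A [channel()].
#' @param sigma_x Translational step scale (length units per step), `> 0`.
#' @param n_traj Ensemble size, `>= 1`.
#' @param seed Integer master seed; per-trajectory sub-seeds are derived from
#'   it, making ensembles reproducible and trajectories replayable.
#' @param max_steps Safety cap per trajectory. Default `100 * L^2 / sigma_x^2`,
#'   far out on the exponential tail of the first-passage distribution, so
#'   censoring is essentially impossible at the defaults.
#' @param record_stride Interval (in steps) between recorded positions;
#'   first-passage times and exit angles are always exact, never subsampled.
#' @param record_positions Set `FALSE` to skip the position record entirely
#'   (first-passage statistics only).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(particle, channel = porewalk::channel(),
                       sigma_x = 0.05, n_traj = 5000, seed,
                       max_steps = NULL, record_stride = 100,
                       record_positions = TRUE) {
  stopifnot(inherits(particle, "spherocylinder"), inherits(channel, "pore_channel"))
  if (!is.numeric(sigma_x) || length(sigma_x) != 1L || sigma_x <= 0)
    stop("`sigma_x` must be a single number > 0")
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: reproducibility is mandatory")
  seed <- as.integer(seed)
  n_traj <- as.integer(n_traj)
  if (n_traj < 1L) stop("`n_traj` must be >= 1")
  record_stride <- as.integer(record_stride)
  if (record_stride < 1L) stop("`record_stride` must be >= 1")
  if (is.null(max_steps))
    max_steps <- ceiling(100 * channel$L^2 / sigma_x^2)
  structure(
    list(particle = particle, channel = channel, sigma_x = sigma_x,
         n_traj = n_traj, seed = seed, max_steps = as.numeric(max_steps),
         record_stride = record_stride,
         record_positions = isTRUE(record_positions)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Confined random-walk configuration\n")
  print(x$particle)
  print(x$channel)
  cat(sprintf("  sigma_x = %g, n_traj = %d, seed = %d\n",
              x$sigma_x, x$n_traj, x$seed))
  cat(sprintf("  max_steps = %g, record_stride = %d\n",
              x$max_steps, x$record_stride))
  invisible(x)
}

#' Particle state
#'
#' @param x 3-vector centre position (z along the pore axis).
#' @param u Unit 3-vector axis direction.
#' @param t Elapsed step count.
#' @return An object of class `"particle_state"`.
#' @export
particle_state <- function(x = c(0, 0, 0), u = c(0, 0, 1), t = 0L) {
  u <- u / sqrt(sum(u^2))
  structure(list(x = x, u = u, t = t, absorbed = FALSE),
            class = "particle_state")
}

#' Draw a random translation vector
#'
#' Each component is independent Normal(0, `sigma_x`): the translational noise
#' is isotropic (the same diffusion coefficient along and across the particle
#' axis).
#'
#' @param sigma_x Step scale, `> 0`.
#' @param n Number of vectors.
#' @return For `n = 1` a 3-vector; otherwise an `n x 3` matrix.
#' @export
propose_translation <- function(sigma_x, n = 1) {
  if (n == 1L) return(sigma_x * stats::rnorm(3))
  matrix(sigma_x * stats::rnorm(3 * n), ncol = 3, byrow = TRUE)
}

#' Advance one step of the confined random walk (reference stepper)
#'
#' Performs, in order: (1) one translation attempt, accepted iff the moved
#' capsule stays clear of the wall and the centre keeps `z >= 0`; if the
#' accepted move carries the centre to `z >= L` the particle is absorbed and
#' the step ends there; (2) otherwise one rotation attempt about a uniformly
#' random axis with an equipartition-scaled normal angle, accepted iff the
#' rotated capsule stays clear of the wall. Time advances by exactly 1 whether
#' or not the attempts are accepted.
#'
#' This pure-R stepper consumes R's global RNG stream in the same fixed order
#' as the compiled trajectory loop, so the two produce bit-identical paths
#' from the same seed. It is the readable reference; [run_trajectory()] is the
#' production path.
#'
#' @param state A [particle_state()].
#' @param cfg A [sim_config()].
#' @return The updated `"particle_state"`; `$absorbed` is `TRUE` once the
#'   centre has reached `z >= L`.
#' @export
step_state <- function(state, cfg) {
  if (state$absorbed) stop("particle already absorbed")
  p <- cfg$particle
  ch <- cfg$channel
  nx <- state$x + propose_translation(cfg$sigma_x)
  if (nx[3] >= 0 && !collides(p, nx, state$u, ch)) {
    state$x <- nx
    if (nx[3] >= ch$L) {       # absorbed: skip the rotation sub-step
      state$t <- state$t + 1L
      state$absorbed <- TRUE
      return(state)
    }
  }
  A <- random_unit_axis()
  dphi <- sigma_phi(p, state$u, A, cfg$sigma_x) * stats::rnorm(1)
  nu <- rotate_axis(state$u, A, dphi)
  if (!collides(p, state$x, nu, ch)) state$u <- nu
  state$t <- state$t + 1L
  state
}

#' Run a single trajectory
#'
#' Starts the particle aligned along the pore axis with its centre at the
#' origin and iterates the stochastic update until the centre reaches
#' `z >= L` (absorbed; the first-passage time in steps and the exit angle
#' between the particle axis and the pore axis are recorded) or `max_steps`
#' is hit (censored; flagged, never dropped). Positions and orientations are
#' recorded every `record_stride` steps while the particle is inside.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this trajectory (defaults to `cfg$seed`).
#' @return An object of class `"pore_trajectory"`: `fpt` (steps, `NA` if
#'   censored), `censored`, `exit_theta` (radians), `positions` (matrix with
#'   columns t, x, y, z, ux, uy, uz), acceptance counters, and the seed used.
#' @export
run_trajectory <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$particle
  if (collides(p, c(0, 0, 0), c(0, 0, 1), cfg$channel))
    stop("initial state collides with the wall: particle does not fit (d >= 1)")
  set.seed(as.integer(seed))
  res <- run_trajectory_cpp(p$l, p$r, cfg$channel$L, cfg$sigma_x,
                            p$M_body[1, 1], p$M_body[3, 3],
                            cfg$max_steps, cfg$record_stride,
                            cfg$record_positions)
  res$seed <- as.integer(seed)
  class(res) <- "pore_trajectory"
  res
}

#' @export
print.pore_trajectory <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Censored trajectory: %g steps without exit\n", x$steps))
  } else {
    cat(sprintf("Trajectory absorbed at t = %g steps, exit angle %.3f rad\n",
                x$fpt, x$exit_theta))
  }
  cat(sprintf("  acceptance: translations %.3f, rotations %.3f\n",
              x$accepted_translations / x$steps, x$accepted_rotations / x$steps))
  invisible(x)
}

#' Run an ensemble of independent trajectories
#'
#' Draws `cfg$n_traj` sub-seeds deterministically from the master seed and
#' runs one trajectory per sub-seed. Trajectories are statistically
#' independent and individually replayable via their recorded sub-seed;
#' aggregate statistics do not depend on execution order.
#'
#' @param cfg A [sim_config()].
#' @param progress Print a progress line every `progress` trajectories
#'   (0 = silent).
#' @return An object of class `"pore_ensemble"`: the configuration, the list
#'   of [run_trajectory()] results, and the per-trajectory sub-seeds.
#' @export
run_ensemble <- function(cfg, progress = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  subseeds <- sample.int(2147483647L, cfg$n_traj)
  trajectories <- vector("list", cfg$n_traj)
  for (i in seq_len(cfg$n_traj)) {
    trajectories[[i]] <- run_trajectory(cfg, seed = subseeds[i])
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  trajectory %d / %d", i, cfg$n_traj))
  }
  structure(list(config = cfg, trajectories = trajectories,
                 subseeds = subseeds),
            class = "pore_ensemble")
}

#' Extract first-passage times from an ensemble
#'
#' @param ensemble A `"pore_ensemble"`.
#' @return A data frame with columns `traj_id`, `seed`, `fpt_steps`,
#'   `exit_theta_rad`, `censored`.
#' @export
first_passage <- function(ensemble) {
  stopifnot(inherits(ensemble, "pore_ensemble"))
  data.frame(
    traj_id = seq_along(ensemble$trajectories),
    seed = ensemble$subseeds,
    fpt_steps = vapply(ensemble$trajectories, function(tr) tr$fpt, numeric(1)),
    exit_theta_rad = vapply(ensemble$trajectories,
                            function(tr) tr$exit_theta, numeric(1)),
    censored = vapply(ensemble$trajectories,
                      function(tr) tr$censored, logical(1))
  )
}

#' @export
print.pore_ensemble <- function(x, ...) {
  fp <- first_passage(x)
  cat(sprintf("Ensemble of %d trajectories (seed %d)\n",
              length(x$trajectories), x$config$seed))
  cat(sprintf("  particle: d = %.3g, f = %.3g; channel L = %.3g; sigma_x = %g\n",
              x$config$particle$d, x$config$particle$f,
              x$config$channel$L, x$config$sigma_x))
  cat(sprintf("  censored: %d\n", sum(fp$censored)))
  if (any(!fp$censored))
    cat(sprintf("  median FPT: %g steps (min %g, max %g)\n",
                stats::median(fp$fpt_steps[!fp$censored]),
                min(fp$fpt_steps[!fp$censored]),
                max(fp$fpt_steps[!fp$censored])))
  invisible(x)
}

#' @export
summary.pore_ensemble <- function(object, ...) {
  fp <- first_passage(object)
  ok <- !fp$censored
  acc_t <- vapply(object$trajectories,
                  function(tr) tr$accepted_translations / tr$steps, numeric(1))
  acc_r <- vapply(object$trajectories,
                  function(tr) tr$accepted_rotations / tr$steps, numeric(1))
  out <- list(
    n_traj = nrow(fp),
    n_censored = sum(fp$censored),
    median_fpt = if (any(ok)) stats::median(fp$fpt_steps[ok]) else NA_real_,
    mean_fpt = if (any(ok)) mean(fp$fpt_steps[ok]) else NA_real_,
    min_fpt = if (any(ok)) min(fp$fpt_steps[ok]) else NA_real_,
    translation_acceptance = mean(acc_t),
    rotation_acceptance = mean(acc_r)
  )
  class(out) <- "summary.pore_ensemble"
  out
}

#' @export
print.summary.pore_ensemble <- function(x, ...) {
  cat(sprintf("n = %d (censored %d)\n", x$n_traj, x$n_censored))
  cat(sprintf("FPT steps: min %g, median %g, mean %g\n",
              x$min_fpt, x$median_fpt, x$mean_fpt))
  cat(sprintf("acceptance rates: translation %.3f, rotation %.3f\n",
              x$translation_acceptance, x$rotation_acceptance))
  invisible(x)
}
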