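#' Write a simulated ensemble to a run directory
#'
#' Persists the ensemble as plain text: `fpt.csv` (one row per trajectory:
#' `traj_id, seed, fpt_steps, exit_theta_rad, censored`), `run_meta.json`
#' (full configuration echo, package version, censoring count) and optionally
#' one `traj_<id>.csv` per trajectory with the stride-sampled positions and
#' orientations. Any run can be regenerated bit-identically from
#' `run_meta.json` alone.
#'
#' @param ensemble A `"pore_ensemble"`.
#' @param dir Output directory (created if missing).
#' @param trajectories Also write per-trajectory position files.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir, trajectories = FALSE) {
  stopifnot(inherits(ensemble, "pore_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- first_passage(ensemble)
  utils::write.csv(fp, file.path(dir, "fpt.csv"), row.names = FALSE)
  cfg <- ensemble$config
  meta <- list(
    package = "porewalk",
    version = as.character(utils::packageVersion("porewalk")),
    config = list(
      l = cfg$particle$l, d = cfg$particle$d, f = cfg$particle$f,
      L = cfg$channel$L, sigma_x = cfg$sigma_x, n_traj = cfg$n_traj,
      seed = cfg$seed, max_steps = cfg$max_steps,
      record_stride = cfg$record_stride,
      record_positions = cfg$record_positions
    ),
    n_censored = sum(fp$censored)
  )
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (trajectories) {
    for (i in seq_along(ensemble$trajectories)) {
      pos <- ensemble$trajectories[[i]]$positions
      utils::write.csv(as.data.frame(pos),
                       file.path(dir, sprintf("traj_%d.csv", i)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Rebuild the configuration stored in a run directory
#'
#' @param dir A directory written by [write_ensemble()].
#' @return The `"sim_config"` reconstructed from `run_meta.json`; running
#'   [run_ensemble()] on it reproduces the stored run exactly.
#' @export
read_run_config <- function(dir) {
  path <- file.path(dir, "run_meta.json")
  if (!file.exists(path)) stop("no run_meta.json in ", dir)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- meta$config
  sim_config(
    particle = spherocylinder(l = cf$l, d = cf$d),
    channel = channel(L = cf$L),
    sigma_x = cf$sigma_x, n_traj = cf$n_traj, seed = cf$seed,
    max_steps = cf$max_steps, record_stride = cf$record_stride,
    record_positions = cf$record_positions
  )
}

#' Read the first-passage table of a stored run
#'
#' @param dir A run directory.
#' @return The `fpt.csv` contents as a data frame.
#' @export
read_fpt <- function(dir) {
  path <- file.path(dir, "fpt.csv")
  if (!file.exists(path)) stop("no fpt.csv in ", dir)
  utils::read.csv(path)
}

#' Write the analysis outputs of a run
#'
#' Produces `msd.csv` (`t, msd, n_alive`), `angles.csv`
#' (`bin_center, p_theta, p_raw`) and `fits.json` (`D`, `alpha`, `lambda`,
#' `median_fpt`, `sigma_theta` plus the fitting windows) in the run
#' directory.
#'
#' @param analysis A `"pore_analysis"` from [analyze_ensemble()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "pore_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(unclass(analysis$msd))[
    c("t", "msd", "n_alive")],
    file.path(dir, "msd.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(bin_center = analysis$angles$mid,
               p_theta = analysis$angles$p_theta,
               p_raw = analysis$angles$p_raw),
    file.path(dir, "angles.csv"), row.names = FALSE)
  fits <- list(
    D = analysis$diffusion$D,
    alpha = analysis$diffusion$alpha,
    lambda = analysis$survival_fit$lambda,
    median_fpt = analysis$survival_fit$median_fpt,
    sigma_theta = analysis$sigma_theta,
    msd_window = analysis$diffusion$window,
    tail_window = analysis$survival_fit$tail_window,
    n_censored = analysis$n_censored
  )
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a simulation or sweep configuration from a YAML file
#'
#' Recognised keys for a single run: `l` or `f`, `d`, `L`, `sigma_x`,
#' `n_traj`, `seed`, `max_steps`, `record_stride`, `record_positions`.
#' A sweep configuration additionally carries `grid`, a list of `(f, d)` or
#' `(l, d)` pairs (duplicates are removed), plus an optional `output_dir`.
#' Unknown keys are errors; missing values fall back to the defaults
#' (`sigma_x = 0.05`, `L = 14.3`, `n_traj = 5000`) except `seed` and the
#' particle dimensions, which must be explicit.
#'
#' @param path Path to a YAML file.
#' @return A `"sim_config"`, or a `"sweep_spec"` when a `grid` key is
#'   present.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("l", "f", "d", "L", "sigma_x", "n_traj", "seed", "max_steps",
             "record_stride", "record_positions", "grid", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("`seed` must be set explicitly in the config")
  shared <- list(
    L = if (is.null(cfg$L)) 14.3 else cfg$L,
    sigma_x = if (is.null(cfg$sigma_x)) 0.05 else cfg$sigma_x,
    n_traj = if (is.null(cfg$n_traj)) 5000 else cfg$n_traj,
    seed = cfg$seed, max_steps = cfg$max_steps,
    record_stride = if (is.null(cfg$record_stride)) 100 else cfg$record_stride,
    record_positions = if (is.null(cfg$record_positions)) TRUE
                       else cfg$record_positions
  )
  if (shared$sigma_x <= 0) stop("invalid `sigma_x`: must be > 0")
  if (!is.null(cfg$grid)) {
    grid <- do.call(rbind, lapply(cfg$grid, function(g) {
      data.frame(f = if (is.null(g$f)) 1 + g$l / g$d else g$f, d = g$d)
    }))
    grid <- unique(grid)
    if (any(grid$d <= 0 | grid$d >= 1)) stop("invalid `d` in grid: need 0 < d < 1")
    if (any(grid$f < 1)) stop("invalid `f` in grid: need f >= 1")
    return(structure(c(list(grid = grid, output_dir = cfg$output_dir), shared),
                     class = "sweep_spec"))
  }
  if (is.null(cfg$d)) stop("`d` must be set (particle diameter)")
  if (cfg$d <= 0 || cfg$d >= 1) stop("invalid `d`: need 0 < d < 1")
  particle <- if (!is.null(cfg$f)) spherocylinder(d = cfg$d, f = cfg$f)
              else spherocylinder(l = if (is.null(cfg$l)) 0 else cfg$l,
                                  d = cfg$d)
  sim_config(particle = particle, channel = channel(L = shared$L),
             sigma_x = shared$sigma_x, n_traj = shared$n_traj,
             seed = shared$seed, max_steps = shared$max_steps,
             record_stride = shared$record_stride,
             record_positions = shared$record_positions)
}
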