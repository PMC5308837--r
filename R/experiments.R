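#' Named experiment configurations
#'
#' Bundles population, simulation, optics and tracking parameters for the
#' package's end-to-end in-silico experiments. The morphology-named
#' experiments use the measured rotation rates of the three cell types
#' (longitudinal rotation `omega_tau` = 11.0 +/- 3.0 rad/s for the
#' trypomastigote, 2.5 +/- 0.7 rad/s for the epimastigote-like mutant and
#' 0.15 rad/s for the promastigote), path-curvature rotation
#' `omega_kappa` = 0.6 +/- 0.2 rad/s and swimming speed 5 +/- 2 um/s, and
#' run the full simulate - render - track - summarise chain in a periodic
#' volume. The grid experiments sweep `omega_kappa` and `omega_tau` (0-5
#' rad/s) and measure directionality directly from the 3-D paths, under
#' three noise models: fixed rates with Brownian motion
#' (`grid_brownian`), per-cell random curvature (`grid_percell`) and
#' curvature re-randomised every 200 ms (`grid_rerandomized`).
#'
#' @param name one of `"trypomastigote"`, `"epimastigote"`,
#'   `"promastigote"`, `"grid_brownian"`, `"grid_percell"`,
#'   `"grid_rerandomized"`, `"custom"`.
#' @param n_cells cells per condition/grid point. Defaults are scaled down
#'   (100 for populations, 25 per grid point) from the 10,000-cell
#'   full-scale runs; pass larger values to reproduce at full scale.
#' @param seed integer seed.
#' @param duration simulated seconds (default 102.4 = 512 frames at 5 Hz).
#' @param ... overrides merged into the config (e.g. `population`,
#'   `optics`, `volume`, `eval_dt`).
#' @return object of class `experiment_config` (fully serialisable with
#'   [write_config()]).
#' @export
experiment_config <- function(name = c("trypomastigote", "epimastigote",
                                       "promastigote", "grid_brownian",
                                       "grid_percell", "grid_rerandomized",
                                       "custom"),
                              n_cells = NULL, seed = 1L, duration = 102.4,
                              ...) {
  name <- match.arg(name)
  pop_for <- function(wt_mean, wt_sd)
    population_spec(speed_mean = 5, speed_sd = 2,
                    omega_kappa_mean = 0.6, omega_kappa_sd = 0.2,
                    omega_tau_mean = wt_mean, omega_tau_sd = wt_sd)
  base <- list(
    name = name, seed = as.integer(seed), duration = duration,
    volume = c(333, 281, 100),
    optics = optics_model(image_size = c(512L, 432L), focal_plane_z = 50),
    blur_px = 2, link_px = 15, min_track_s = 5, eval_dt = 2,
    render = FALSE, population = NULL,
    grid = NULL)
  cfg <- switch(name,
    trypomastigote = modifyList(base, list(
      population = pop_for(11.0, 3.0), render = TRUE,
      n_cells = if (is.null(n_cells)) 100L else n_cells)),
    epimastigote = modifyList(base, list(
      population = pop_for(2.5, 0.7), render = TRUE,
      n_cells = if (is.null(n_cells)) 100L else n_cells)),
    promastigote = modifyList(base, list(
      population = pop_for(0.15, 0), render = TRUE,
      n_cells = if (is.null(n_cells)) 100L else n_cells)),
    grid_brownian = modifyList(base, list(
      grid = list(omega_kappa = c(0, 1, 2.5, 5), omega_tau = c(0, 1, 2.5, 5),
                  mode = "fixed"),
      n_cells = if (is.null(n_cells)) 25L else n_cells)),
    grid_percell = modifyList(base, list(
      grid = list(omega_kappa_sd = c(0, 1, 2.5, 5),
                  omega_tau = c(0, 1, 2.5, 5), mode = "per_cell"),
      n_cells = if (is.null(n_cells)) 25L else n_cells)),
    grid_rerandomized = modifyList(base, list(
      grid = list(omega_kappa_sd = c(0, 1, 2), omega_tau = c(0, 1, 2.5, 5),
                  mode = "rerandomized"),
      n_cells = if (is.null(n_cells)) 25L else n_cells)),
    custom = modifyList(base, list(
      n_cells = if (is.null(n_cells)) 100L else n_cells)))
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "experiment_config"
  cfg
}

#' Run a named experiment end to end
#'
#' Population experiments: simulate the population in a periodic volume,
#' render synthetic dark-field videomicrographs, subtract background,
#' detect, link and summarise - the same pipeline applied to real
#' videomicrographs. Grid experiments: directionality sweeps via
#' [reproduce_grid()]. Identical config and seed give identical outputs.
#' When `output_dir` is given, the tracks, per-track statistics, summary
#' and a copy of the config are written there (plus the TIFF stack if
#' `write_tiff`).
#'
#' @param cfg an [experiment_config()].
#' @param output_dir optional output directory (created if needed).
#' @param write_tiff logical, write the rendered stack as multi-page TIFF.
#' @return For population experiments: list with `tracks`, `summary`
#'   (from [population_summary()]) and `simulated` (per-cell table).
#'   For grid experiments: the grid data.frame.
#' @export
run_experiment <- function(cfg, output_dir = NULL, write_tiff = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  if (!is.null(cfg$grid)) {
    grid <- cfg$grid
    res <- reproduce_grid(
      mode = "simulated",
      omega_kappa = if (!is.null(grid$omega_kappa)) grid$omega_kappa else 0,
      omega_tau = grid$omega_tau,
      omega_kappa_sd = if (!is.null(grid$omega_kappa_sd)) grid$omega_kappa_sd
                       else 0,
      noise_mode = grid$mode, n_cells = cfg$n_cells, seed = cfg$seed,
      duration = cfg$duration)
    if (!is.null(output_dir)) {
      write.csv(res, file.path(output_dir, "grid_directionality.csv"),
                row.names = FALSE)
      write_config(cfg, file.path(output_dir, "config.yaml"))
    }
    return(res)
  }
  sim_cfg <- simulation_config(duration = cfg$duration, brownian = TRUE,
                               volume = cfg$volume, cyclic = TRUE,
                               seed = cfg$seed)
  sim <- simulate_population(cfg$population, sim_cfg, n_cells = cfg$n_cells,
                             random_start = TRUE, keep_trajectories = TRUE)
  out <- list(simulated = sim$summary)
  if (cfg$render) {
    stack <- render_stack(sim$trajectories, cfg$optics)
    stack <- subtract_background(stack)
    det <- detect_stack(stack, blur_px = cfg$blur_px)
    tracks <- link_tracks(det, max_link = cfg$link_px, optics = cfg$optics)
    summ <- population_summary(tracks, eval_dt = cfg$eval_dt,
                               min_duration = cfg$min_track_s)
    out$tracks <- tracks
    out$summary <- summ
    if (!is.null(output_dir)) {
      write_tracks(tracks, file.path(output_dir, "tracks.csv"))
      write.csv(summ$per_track,
                file.path(output_dir, "track_statistics.csv"),
                row.names = FALSE)
      if (write_tiff)
        write_image_stack(stack, file.path(output_dir, "stack.tif"))
    }
  }
  if (!is.null(output_dir)) {
    write_config(cfg, file.path(output_dir, "config.yaml"))
    write.csv(sim$summary, file.path(output_dir, "simulated_cells.csv"),
              row.names = FALSE)
  }
  out
}

#' Directionality over a grid of rotation rates
#'
#' Analytic mode evaluates the closed-form large-turn directionality
#' `omega_tau / sqrt(omega_kappa^2 + omega_tau^2)`
#' ([directionality_limit()]). Simulated mode runs populations of swimming
#' cells for each grid point and reports mean simulated directionality; the
#' three noise modes mirror [population_spec()]. Analytic and noise-free
#' simulated grids agree to within the chord-term corrections; Brownian
#' motion lowers the maximum attainable directionality.
#'
#' @param mode `"analytic"` or `"simulated"`.
#' @param omega_kappa,omega_tau grid values, rad/s.
#' @param omega_kappa_sd noise levels for the `per_cell` / `rerandomized`
#'   modes (replaces `omega_kappa` as the swept axis when non-zero).
#' @param noise_mode `"fixed"`, `"per_cell"` or `"rerandomized"`.
#' @param n_cells cells per grid point (simulated mode).
#' @param seed integer seed.
#' @param duration simulated seconds.
#' @param brownian include Brownian motion (simulated mode).
#' @param speed_mean,speed_sd swimming speed distribution, um/s.
#' @return data.frame with the grid coordinates, `directionality` (mean)
#'   and, for simulated mode, `sd` and `n`.
#' @export
reproduce_grid <- function(mode = c("analytic", "simulated"),
                           omega_kappa = c(0, 1, 2.5, 5),
                           omega_tau = c(0, 1, 2.5, 5),
                           omega_kappa_sd = 0,
                           noise_mode = c("fixed", "per_cell",
                                          "rerandomized"),
                           n_cells = 25L, seed = 1L, duration = 102.4,
                           brownian = TRUE, speed_mean = 5, speed_sd = 2) {
  mode <- match.arg(mode)
  noise_mode <- match.arg(noise_mode)
  sweep_sd <- noise_mode != "fixed" && any(omega_kappa_sd > 0)
  kappa_axis <- if (sweep_sd) omega_kappa_sd else omega_kappa
  grid <- expand.grid(kappa_axis = kappa_axis, omega_tau = omega_tau)
  names(grid)[1L] <- if (sweep_sd) "omega_kappa_sd" else "omega_kappa"
  if (mode == "analytic") {
    if (sweep_sd)
      stop("analytic mode applies to fixed rotation rates only")
    grid$directionality <- mapply(function(wk, wt) {
      s <- speed_mean
      abs(directionality_limit(wk / s, wt / s))
    }, grid$omega_kappa, grid$omega_tau)
    return(grid)
  }
  grid$directionality <- NA_real_
  grid$sd <- NA_real_
  grid$n <- n_cells
  for (i in seq_len(nrow(grid))) {
    pop <- population_spec(
      speed_mean = speed_mean, speed_sd = speed_sd,
      omega_kappa_mean = if (sweep_sd) 0 else grid[[1L]][i],
      omega_kappa_sd = if (sweep_sd) grid$omega_kappa_sd[i] else 0,
      omega_tau_mean = grid$omega_tau[i], omega_tau_sd = 0,
      kappa_noise_mode = noise_mode)
    cfg <- simulation_config(duration = duration, brownian = brownian,
                             seed = seed + 131L * i)
    sim <- simulate_population(pop, cfg, n_cells = n_cells,
                               keep_trajectories = FALSE)
    grid$directionality[i] <- mean(sim$summary$directionality)
    grid$sd[i] <- sd(sim$summary$directionality)
  }
  grid
}

#' Write / read an experiment config as YAML
#'
#' Round-trips through [yaml::write_yaml()]; `read_config()` rebuilds the
#' classed objects, so serialise - parse - serialise is the identity.
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @return the path invisibly (`write_config`); an `experiment_config`
#'   (`read_config`).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  plain <- unclass(cfg)
  plain$optics <- unclass(plain$optics)
  plain$population <- if (!is.null(plain$population))
    unclass(plain$population)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- unclass(experiment_config("custom"))
  plain <- obj[setdiff(names(obj), c("optics", "population"))]
  # modifyList would delete fields serialised as null; keep the template's
  plain <- plain[!vapply(plain, is.null, logical(1L))]
  cfg <- modifyList(cfg, plain)
  if (!is.null(obj$optics)) cfg$optics <- do.call(optics_model, obj$optics)
  if (!is.null(obj$population))
    cfg$population <- do.call(population_spec, obj$population)
  cfg$name <- obj$name
  class(cfg) <- "experiment_config"
  cfg
}
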