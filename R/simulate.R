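#' Cell state: position and orthonormal body frame
#'
#' @param position 3-vector, um.
#' @param t,n unit vectors: travel direction / long axis and normal. The
#'   binormal is completed as `b = t x n` after Gram-Schmidt
#'   orthonormalisation.
#' @return object of class `cell_state` with `position`, `t`, `n`, `b`.
#' @export
cell_state <- function(position = c(0, 0, 0), t = c(1, 0, 0),
                       n = c(0, 1, 0)) {
  stopifnot(length(position) == 3L, length(t) == 3L, length(n) == 3L,
            all(is.finite(c(position, t, n))))
  fr <- .renormalise_frame(t, n)
  structure(list(position = as.numeric(position),
                 t = fr$t, n = fr$n, b = fr$b),
            class = "cell_state")
}

#' Simulation configuration
#'
#' @param dt time step, s. Default 0.2 s.
#' @param duration simulated time, s; must be an integer multiple of `dt`.
#' @param brownian logical: include translational and rotational Brownian
#'   motion.
#' @param volume optional 3 extents (x, y, z), um, for volume simulations.
#' @param cyclic logical: wrap positions into `volume` (cyclic boundaries).
#' @param seed integer seed for reproducible populations.
#' @param environment a [swim_environment()].
#' @param spheroid a [spheroid_geometry()].
#' @param rotation_mode how the two deterministic per-step rotations are
#'   composed. `"combined"` (default) applies the single rotation by the
#'   per-step rotation vector `omega_kappa * b + omega_tau * t` (the exact
#'   rotation for a constant body-frame rate, so the noise-free discrete
#'   path samples the continuous helix); `"sequential"` rotates `t`,`n`
#'   about `b` by `omega_kappa * dt` and then `b`,`n` about the new `t` by
#'   `omega_tau * dt`, which incurs an O(dt^2) axis-splitting bias at large
#'   rotation rates.
#' @param perrin_mode passed to [rotational_diffusion()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.2, duration = 102.4, brownian = TRUE,
                              volume = NULL, cyclic = FALSE, seed = 1L,
                              environment = swim_environment(),
                              spheroid = spheroid_geometry(),
                              rotation_mode = c("combined", "sequential"),
                              perrin_mode = c("divide", "multiply")) {
  .check_scalar(dt, "dt"); .check_scalar(duration, "duration")
  if (dt <= 0) stop("'dt' must be > 0")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("'duration' must be an integer multiple of 'dt'")
  if (cyclic && is.null(volume))
    stop("cyclic boundaries require a 'volume'")
  structure(list(dt = dt, duration = duration, n_steps = as.integer(round(n_steps)),
                 brownian = brownian, volume = volume, cyclic = cyclic,
                 seed = as.integer(seed), environment = environment,
                 spheroid = spheroid,
                 rotation_mode = match.arg(rotation_mode),
                 perrin_mode = match.arg(perrin_mode)),
            class = "simulation_config")
}

# One deterministic + Brownian update. `noise` is a length-6 vector of
# standard normal draws (3 translation, 3 rotation) or NULL when brownian
# motion is off; `diff` the diffusion_set.
.step <- function(pos, t, n, b, s, wk, wt, cfg, diff = NULL, noise = NULL) {
  dt <- cfg$dt
  # (1) translate along t
  pos <- pos + s * dt * t
  # (2,3) deterministic frame rotation
  if (cfg$rotation_mode == "combined") {
    ax <- wt * t + wk * b
    w <- .norm3(ax)
    if (w > 0) {
      ax <- ax / w
      ang <- w * dt
      t <- .rotate(t, ax, ang)
      n <- .rotate(n, ax, ang)
      b <- .rotate(b, ax, ang)
    }
  } else {
    if (wk != 0) {
      t <- .rotate(t, b, wk * dt)
      n <- .rotate(n, b, wk * dt)
    }
    if (wt != 0) {
      n <- .rotate(n, t, wt * dt)
      b <- .rotate(b, t, wt * dt)
    }
  }
  # (4) Brownian translation and rotation in the instantaneous body frame
  if (!is.null(noise)) {
    sd_d <- sqrt(2 * diff$D_d * dt)
    sd_np <- sqrt(2 * diff$D_np * dt)
    pos <- pos + (noise[1L] * sd_d) * t + (noise[2L] * sd_np) * n +
      (noise[3L] * sd_np) * b
    a_t <- noise[4L] * sqrt(2 * diff$E_d * dt)
    a_n <- noise[5L] * sqrt(2 * diff$E_np * dt)
    a_b <- noise[6L] * sqrt(2 * diff$E_np * dt)
    n <- .rotate(n, t, a_t); b <- .rotate(b, t, a_t)
    t <- .rotate(t, n, a_n); b <- .rotate(b, n, a_n)
    t <- .rotate(t, b, a_b); n <- .rotate(n, b, a_b)
  }
  fr <- .renormalise_frame(t, n)
  if (cfg$cyclic) pos <- pos %% cfg$volume
  list(pos = pos, t = fr$t, n = fr$n, b = fr$b)
}

#' Advance a swimming cell by one time step
#'
#' Applies, in order: translation by `speed * dt` along `t`; the
#' deterministic frame rotation generated by `omega_kappa` (about the
#' binormal) and `omega_tau` (about the travel direction); optionally
#' Brownian translation along `t`, `n`, `b` (sds `sqrt(2 D_i dt)`) and
#' rotation about `t`, `n`, `b` (sds `sqrt(2 E_i dt)`); frame
#' re-orthonormalisation; and cyclic wrapping if configured. Brownian draws
#' come from the R session RNG.
#'
#' @param state a [cell_state()].
#' @param kin a [path_kinematics()].
#' @param cfg a [simulation_config()].
#' @param diff optional precomputed [rotational_diffusion()] set (computed
#'   from `cfg` if needed).
#' @return updated `cell_state`.
#' @export
step_cell <- function(state, kin, cfg, diff = NULL) {
  stopifnot(inherits(state, "cell_state"), inherits(kin, "path_kinematics"),
            inherits(cfg, "simulation_config"))
  if (!all(is.finite(c(state$position, state$t, state$n, state$b))))
    stop("non-finite cell state")
  noise <- NULL
  if (cfg$brownian) {
    if (is.null(diff))
      diff <- rotational_diffusion(cfg$spheroid, cfg$environment,
                                   cfg$perrin_mode)
    noise <- rnorm(6L)
  }
  st <- .step(state$position, state$t, state$n, state$b,
              kin$speed, kin$omega_kappa, kin$omega_tau, cfg, diff, noise)
  structure(list(position = st$pos, t = st$t, n = st$n, b = st$b),
            class = "cell_state")
}

# Core trajectory loop. wk may be a scalar or a per-step vector
# (rerandomised curvature noise). Returns an (n_steps+1) x 12 matrix.
.simulate_path <- function(s, wk, wt, cfg, initial, diff = NULL) {
  n_steps <- cfg$n_steps
  out <- matrix(NA_real_, n_steps + 1L, 12L)
  pos <- initial$position; t <- initial$t; n <- initial$n; b <- initial$b
  out[1L, ] <- c(pos, t, n, b)
  noise_mat <- if (cfg$brownian) matrix(rnorm(6L * n_steps), n_steps, 6L)
  wk_vec <- if (length(wk) == 1L) rep.int(wk, n_steps) else wk
  stopifnot(length(wk_vec) == n_steps)
  for (i in seq_len(n_steps)) {
    st <- .step(pos, t, n, b, s, wk_vec[i], wt, cfg, diff,
                if (cfg$brownian) noise_mat[i, ])
    pos <- st$pos; t <- st$t; n <- st$n; b <- st$b
    out[i + 1L, ] <- c(pos, t, n, b)
  }
  out
}

#' Simulate a single swimming cell
#'
#' Time-stepped (Euler) simulation of one cell for `cfg$duration` seconds.
#' Deterministic given the R session RNG state (seed the session, or use
#' [simulate_population()] for per-cell streams).
#'
#' @inheritParams step_cell
#' @param initial initial [cell_state()]; default: origin, `t` along +x.
#' @return a `swim_trajectory`: data.frame with columns `time`, `x`, `y`,
#'   `z` (um) and the frame components `tx..bz`, with the generating
#'   kinematics attached as attribute `kinematics`.
#' @examples
#' cfg <- simulation_config(duration = 10, brownian = FALSE)
#' tr <- simulate_cell(path_kinematics(5, 0, 0), cfg)
#' max(tr$x)  # 50 um along +x
#' @export
simulate_cell <- function(kin, cfg, initial = cell_state(), diff = NULL) {
  stopifnot(inherits(kin, "path_kinematics"),
            inherits(cfg, "simulation_config"),
            inherits(initial, "cell_state"))
  if (cfg$brownian && is.null(diff))
    diff <- rotational_diffusion(cfg$spheroid, cfg$environment,
                                 cfg$perrin_mode)
  m <- .simulate_path(kin$speed, kin$omega_kappa, kin$omega_tau, cfg,
                      initial, diff)
  tr <- data.frame(time = seq(0, by = cfg$dt, length.out = nrow(m)),
                   x = m[, 1L], y = m[, 2L], z = m[, 3L],
                   tx = m[, 4L], ty = m[, 5L], tz = m[, 6L],
                   nx = m[, 7L], ny = m[, 8L], nz = m[, 9L],
                   bx = m[, 10L], by = m[, 11L], bz = m[, 12L])
  attr(tr, "kinematics") <- kin
  class(tr) <- c("swim_trajectory", "data.frame")
  tr
}

#' Directionality of a simulated trajectory
#'
#' Net displacement divided by the distance the cell swam,
#' `|l(T) - l(0)| / (speed * T)`: 1 for straight-line swimming, ~0 for a
#' closed (futile circular) path. With cyclic boundaries this is
#' meaningless; compute it on unwrapped trajectories.
#'
#' @param traj a `swim_trajectory` from [simulate_cell()].
#' @param speed the cell's swimming speed, um/s; taken from the attached
#'   kinematics if omitted.
#' @return dimensionless directionality.
#' @export
path_directionality <- function(traj, speed = NULL) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (is.null(speed)) speed <- attr(traj, "kinematics")$speed
  T_total <- traj$time[nrow(traj)] - traj$time[1L]
  if (T_total <= 0) stop("trajectory has zero duration")
  d <- c(traj$x[nrow(traj)] - traj$x[1L],
         traj$y[nrow(traj)] - traj$y[1L],
         traj$z[nrow(traj)] - traj$z[1L])
  .norm3(d) / (speed * T_total)
}

#' Population specification for directionality experiments
#'
#' Each cell draws its speed and rotation rates once from normal
#' distributions (draws giving `speed <= 0` are redrawn). Curvature noise
#' can additionally be re-randomised during a run:
#' * `"fixed"`: `omega_kappa` held at its mean for every cell (sd ignored),
#' * `"per_cell"` (default): drawn once per cell - models random variation
#'   in morphogenesis,
#' * `"rerandomized"`: redrawn every `rerandomize_interval` seconds -
#'   models random variation in flagellar propulsion.
#'
#' @param speed_mean,speed_sd swimming speed distribution, um/s
#'   (defaults 5 +/- 2).
#' @param omega_kappa_mean,omega_kappa_sd curvature rotation rate, rad/s.
#' @param omega_tau_mean,omega_tau_sd longitudinal rotation rate, rad/s.
#' @param kappa_noise_mode see above.
#' @param rerandomize_interval s, default 0.2.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(speed_mean = 5, speed_sd = 2,
                            omega_kappa_mean = 0, omega_kappa_sd = 0,
                            omega_tau_mean = 0, omega_tau_sd = 0,
                            kappa_noise_mode = c("per_cell", "fixed",
                                                 "rerandomized"),
                            rerandomize_interval = 0.2) {
  if (speed_sd < 0 || omega_kappa_sd < 0 || omega_tau_sd < 0)
    stop("standard deviations must be >= 0")
  structure(list(speed_mean = speed_mean, speed_sd = speed_sd,
                 omega_kappa_mean = omega_kappa_mean,
                 omega_kappa_sd = omega_kappa_sd,
                 omega_tau_mean = omega_tau_mean,
                 omega_tau_sd = omega_tau_sd,
                 kappa_noise_mode = match.arg(kappa_noise_mode),
                 rerandomize_interval = rerandomize_interval),
            class = "population_spec")
}

# Per-cell RNG stream: a distinct, order-independent seed for each cell.
.cell_seed <- function(seed, i) {
  s <- (as.double(seed) + 1000003 * as.double(i)) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

.draw_positive <- function(mean, sd) {
  x <- rnorm(1L, mean, sd)
  k <- 0L
  while (x <= 0 && k < 1000L) { x <- rnorm(1L, mean, sd); k <- k + 1L }
  if (x <= 0) stop("could not draw a positive speed")
  x
}

#' Simulate a population of swimming cells
#'
#' Draws per-cell kinematics from `pop`, simulates each cell with its own
#' RNG stream derived from `(cfg$seed, cell index)` (so results are
#' independent of execution order), and computes per-cell directionality.
#' For directionality experiments every cell starts at the origin with `t`
#' along +x; with `random_start = TRUE` (volume simulations) initial
#' positions are uniform in `cfg$volume` and orientations uniform on the
#' sphere.
#'
#' @param pop a [population_spec()].
#' @param cfg a [simulation_config()].
#' @param n_cells number of cells.
#' @param random_start logical, see above.
#' @param keep_trajectories logical; set `FALSE` for large sweeps to return
#'   only the summary table.
#' @return list with `summary` (data.frame: cell, speed, omega_kappa,
#'   omega_tau, directionality) and `trajectories` (list of
#'   `swim_trajectory` or NULL).
#' @export
simulate_population <- function(pop, cfg, n_cells = 100L,
                                random_start = FALSE,
                                keep_trajectories = TRUE) {
  stopifnot(inherits(pop, "population_spec"),
            inherits(cfg, "simulation_config"))
  if (random_start && is.null(cfg$volume))
    stop("random_start requires cfg$volume")
  diff <- if (cfg$brownian)
    rotational_diffusion(cfg$spheroid, cfg$environment, cfg$perrin_mode)
  trajs <- if (keep_trajectories) vector("list", n_cells)
  summ <- data.frame(cell = seq_len(n_cells), speed = NA_real_,
                     omega_kappa = NA_real_, omega_tau = NA_real_,
                     directionality = NA_real_)
  for (i in seq_len(n_cells)) {
    set.seed(.cell_seed(cfg$seed, i))
    s <- .draw_positive(pop$speed_mean, pop$speed_sd)
    wt <- rnorm(1L, pop$omega_tau_mean, pop$omega_tau_sd)
    wk <- switch(pop$kappa_noise_mode,
      fixed = pop$omega_kappa_mean,
      per_cell = rnorm(1L, pop$omega_kappa_mean, pop$omega_kappa_sd),
      rerandomized = {
        every <- max(1L, as.integer(round(pop$rerandomize_interval / cfg$dt)))
        draws <- rnorm(ceiling(cfg$n_steps / every),
                       pop$omega_kappa_mean, pop$omega_kappa_sd)
        rep(draws, each = every)[seq_len(cfg$n_steps)]
      })
    init <- if (random_start) {
      p0 <- runif(3L) * cfg$volume
      t0 <- .unit(rnorm(3L))
      n0 <- .unit(.cross(t0, if (abs(t0[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
      cell_state(p0, t0, n0)
    } else cell_state()
    m <- .simulate_path(s, wk, wt, cfg, init, diff)
    disp <- sqrt(sum((m[nrow(m), 1:3] - m[1L, 1:3])^2))
    summ$speed[i] <- s
    summ$omega_kappa[i] <- if (length(wk) == 1L) wk else mean(wk)
    summ$omega_tau[i] <- wt
    summ$directionality[i] <- disp / (s * cfg$duration)
    if (keep_trajectories) {
      tr <- data.frame(time = seq(0, by = cfg$dt, length.out = nrow(m)),
                       x = m[, 1L], y = m[, 2L], z = m[, 3L],
                       tx = m[, 4L], ty = m[, 5L], tz = m[, 6L],
                       nx = m[, 7L], ny = m[, 8L], nz = m[, 9L],
                       bx = m[, 10L], by = m[, 11L], bz = m[, 12L])
      attr(tr, "kinematics") <- path_kinematics(s, abs(mean(wk)), wt)
      class(tr) <- c("swim_trajectory", "data.frame")
      trajs[[i]] <- tr
    }
  }
  list(summary = summ, trajectories = trajs)
}

#' Write trajectories to CSV
#'
#' One row per (cell, step): `cell_id, step, time_s, x_um, y_um, z_um,
#' tx..bz`.
#'
#' @param trajectories list of `swim_trajectory`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(cell_id = i, step = seq_len(nrow(tr)) - 1L,
               time_s = tr$time, x_um = tr$x, y_um = tr$y, z_um = tr$z,
               tx = tr$tx, ty = tr$ty, tz = tr$tz,
               nx = tr$nx, ny = tr$ny, nz = tr$nz,
               bx = tr$bx, by = tr$by, bz = tr$bz)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
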