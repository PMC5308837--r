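test_that("single deterministic steps translate and rotate as specified", {
  cfg <- simulation_config(dt = 0.2, duration = 0.2, brownian = FALSE)
  st <- step_cell(cell_state(), path_kinematics(5, 0, 0), cfg)
  expect_equal(st$position, c(1, 0, 0))
  expect_equal(st$t, c(1, 0, 0))
  expect_equal(st$n, c(0, 1, 0))

  # rotation about t cannot change t: straight path with precessing n, b
  cfg2 <- simulation_config(dt = 0.2, duration = 4, brownian = FALSE)
  tr <- simulate_cell(path_kinematics(5, 0, 2), cfg2)
  expect_equal(tr$y, rep(0, nrow(tr)))
  expect_equal(tr$z, rep(0, nrow(tr)))
  expect_equal(tr$x[nrow(tr)], 20)
  ang <- 2 * 0.2  # per-step precession of n about t
  expect_equal(tr$ny[2], cos(ang))
  expect_equal(tr$nz[2], sin(ang), tolerance = 1e-9)
})

test_that("20 steps at a 0.1 pi per-step turn close into a regular 20-gon", {
  for (mode in c("combined", "sequential")) {
    cfg <- simulation_config(dt = 0.2, duration = 4, brownian = FALSE,
                             rotation_mode = mode)
    tr <- simulate_cell(path_kinematics(5, pi / 2, 0), cfg)
    endpt <- c(tr$x[21], tr$y[21], tr$z[21])
    expect_lt(sqrt(sum(endpt^2)), 1e-9)
  }
})

test_that("simulate_cell agrees with repeated step_cell", {
  cfg <- simulation_config(dt = 0.2, duration = 2, brownian = FALSE)
  kin <- path_kinematics(4, 0.8, 1.7)
  tr <- simulate_cell(kin, cfg)
  st <- cell_state()
  for (i in 1:10) st <- step_cell(st, kin, cfg)
  expect_equal(c(tr$x[11], tr$y[11], tr$z[11]), st$position, tolerance = 1e-12)
  expect_equal(c(tr$tx[11], tr$ty[11], tr$tz[11]), st$t, tolerance = 1e-12)
})

test_that("noise-free trajectories: straight distance and helix directionality", {
  cfg <- simulation_config(duration = 102.4, brownian = FALSE)
  tr <- simulate_cell(path_kinematics(5, 0, 0), cfg)
  expect_equal(tr$x[nrow(tr)], 512)
  expect_equal(path_directionality(tr), 1)

  for (wk in c(1, 2.5)) for (wt in c(0.5, 2.5)) {
    trh <- simulate_cell(path_kinematics(5, wk, wt), cfg)
    expect_equal(path_directionality(trh),
                 analytic_directionality(wk, wt),
                 tolerance = 0.01)
  }
})

test_that("frame stays orthonormal over long runs", {
  cfg <- simulation_config(dt = 0.2, duration = 1000, brownian = TRUE,
                           seed = 2)
  set.seed(2)
  tr <- simulate_cell(path_kinematics(5, 2, 5), cfg)
  last <- nrow(tr)
  t <- c(tr$tx[last], tr$ty[last], tr$tz[last])
  n <- c(tr$nx[last], tr$ny[last], tr$nz[last])
  b <- c(tr$bx[last], tr$by[last], tr$bz[last])
  expect_lt(abs(sum(t * t) - 1), 1e-9)
  expect_lt(abs(sum(n * n) - 1), 1e-9)
  expect_lt(abs(sum(t * n)), 1e-9)
  expect_lt(max(abs(b - c(t[2] * n[3] - t[3] * n[2],
                          t[3] * n[1] - t[1] * n[3],
                          t[1] * n[2] - t[2] * n[1]))), 1e-9)
})

test_that("Brownian-only runs diffuse without net drift", {
  cfg <- simulation_config(duration = 2, brownian = TRUE, seed = 9)
  diff <- rotational_diffusion()
  n <- 400
  disp <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    set.seed(chiroswim:::.cell_seed(9, i))
    tr <- simulate_cell(path_kinematics(0, 0, 0), cfg, diff = diff)
    disp[i, ] <- c(tr$x[11] - tr$x[1], tr$y[11] - tr$y[1], tr$z[11] - tr$z[1])
  }
  se <- apply(disp, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(disp)) < 3 * se))
})

test_that("populations are reproducible and order-independent", {
  pop <- population_spec(omega_kappa_mean = 0.6, omega_kappa_sd = 0.2,
                         omega_tau_mean = 2.5, omega_tau_sd = 0.7)
  cfg <- simulation_config(duration = 10, seed = 42)
  a <- simulate_population(pop, cfg, n_cells = 5, keep_trajectories = FALSE)
  b <- simulate_population(pop, cfg, n_cells = 5, keep_trajectories = FALSE)
  expect_identical(a$summary, b$summary)
  # cell i does not depend on how many cells were simulated
  c3 <- simulate_population(pop, cfg, n_cells = 3, keep_trajectories = FALSE)
  expect_identical(a$summary[1:3, ], c3$summary)
})

test_that("population draws respect the spec: truncation, zero-sd, noise modes", {
  # speeds are redrawn until positive
  pop <- population_spec(speed_mean = 1, speed_sd = 2)
  cfg <- simulation_config(duration = 1, brownian = FALSE, seed = 3)
  s <- simulate_population(pop, cfg, n_cells = 50,
                           keep_trajectories = FALSE)$summary
  expect_true(all(s$speed > 0))

  # all-zero sds: every cell identical directionality
  pop0 <- population_spec(speed_sd = 0, omega_kappa_mean = 1,
                          omega_tau_mean = 2)
  d <- simulate_population(pop0, simulation_config(duration = 10,
                                                   brownian = FALSE, seed = 4),
                           n_cells = 8, keep_trajectories = FALSE)$summary
  expect_equal(max(d$directionality) - min(d$directionality), 0)

  # rerandomized mode runs and redraws curvature within a cell
  popr <- population_spec(omega_kappa_mean = 0, omega_kappa_sd = 2,
                          omega_tau_mean = 1,
                          kappa_noise_mode = "rerandomized")
  r <- simulate_population(popr, simulation_config(duration = 10, seed = 5,
                                                   brownian = FALSE),
                           n_cells = 3)
  expect_equal(nrow(r$summary), 3)
  expect_true(all(is.finite(r$summary$directionality)))
})

test_that("noise-free discrete path converges to the continuous helix", {
  err <- function(dt) {
    cfg <- simulation_config(dt = dt, duration = 102.4, brownian = FALSE)
    tr <- simulate_cell(path_kinematics(5, 5, 0), cfg)
    abs(path_directionality(tr) - analytic_directionality(5, 0))
  }
  e_coarse <- err(0.2)
  e_fine <- err(0.1)
  expect_lt(e_fine, e_coarse / 2 + 1e-9)
})
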