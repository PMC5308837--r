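make_params <- function(omega_r = 11, f_b = 19, A_b = NULL, A_r = NULL,
                        p_r = NULL, p_o = NULL) {
  z <- seq(0, 21, by = 3)
  pts <- data.frame(z = z,
                    A_r = if (is.null(A_r)) rep(1, 8) else A_r,
                    p_r = if (is.null(p_r)) seq(0, 2.1, by = 0.3) else p_r,
                    A_b = if (is.null(A_b)) rep(0.5, 8) else A_b,
                    p_b = seq(0, -2.8, by = -0.4),
                    p_o = if (is.null(p_o)) rep(0, 8) else p_o,
                    w = rep(1.2, 8))
  shape_model_params(pts, omega_r, f_b)
}

test_that("model evaluation reduces correctly in its limit cases", {
  tt <- seq(0, 1, by = 1 / 200)

  # no beat: a circle of radius A_r traced at omega_r
  m0 <- make_params(A_b = rep(0, 8))
  ev <- eval_model(m0, z = 4.5, t = tt)
  expect_equal(sqrt(ev$x_c^2 + ev$y_c^2), rep(1, length(tt)))
  ph <- atan2(ev$x_c, ev$y_c)
  expect_equal(sort(unique(round(diff(ph[1:10]), 10))),
               round(11 / 200, 10))

  # pure planar beat with p_r = 0: motion confined to y
  mp <- make_params(omega_r = 0, A_r = rep(0, 8), p_r = rep(0, 8))
  evp <- eval_model(mp, z = 6, t = tt)
  expect_equal(evp$x_c, rep(0, length(tt)))
  expect_equal(evp$y_c, 0.5 * sin(approx(mp$points$z, mp$points$p_b,
                                         6)$y + 2 * pi * 19 * tt))
  # with p_r = pi/2 the same beat lies along x
  mx <- make_params(omega_r = 0, A_r = rep(0, 8), p_r = rep(pi / 2, 8))
  evx <- eval_model(mx, z = 6, t = tt)
  expect_equal(evx$y_c, rep(0, length(tt)), tolerance = 1e-12)

  # triangle inequality: |(x_c, y_c)| between A_r - A_b and A_r + A_b
  m <- make_params()
  sweep <- eval_model(m, z = 9, t = seq(0, 5, by = 0.001))
  r <- sqrt(sweep$x_c^2 + sweep$y_c^2)
  expect_gte(min(r), 0.5 - 1e-9)
  expect_lte(max(r), 1.5 + 1e-9)

  expect_error(eval_model(m, z = 30, t = 0), "outside")
})

test_that("model is periodic in the rotation and beat periods", {
  m <- make_params(omega_r = 3, f_b = 12, A_b = rep(0, 8))
  t0 <- seq(0, 0.3, by = 0.01)
  a <- eval_model(m, 9, t0)
  b <- eval_model(m, 9, t0 + 2 * pi / 3)
  expect_equal(a$x_c, b$x_c, tolerance = 1e-12)

  # beat-only model is periodic in 1 / f_b
  mb <- make_params(omega_r = 0, A_r = rep(0, 8), f_b = 12)
  a2 <- eval_model(mb, 9, t0)
  b2 <- eval_model(mb, 9, t0 + 1 / 12)
  expect_equal(a2$y_c, b2$y_c, tolerance = 1e-12)
})

test_that("kymograph traces sample x_c on the fast camera clock", {
  m <- make_params()
  ky <- model_kymograph(m, z = 9)
  expect_s3_class(ky, "kymograph")
  expect_equal(diff(ky$time)[1], 1 / 200)
  expect_equal(ky$x, eval_model(m, 9, ky$time)$x_c)
})

test_that("goodness of fit is R squared", {
  x <- sin(seq(0, 10, by = 0.01))
  expect_equal(goodness_of_fit(x, x), 1)
  expect_equal(goodness_of_fit(rep(mean(x), length(x)), x), 0)
  set.seed(7)
  noisy <- x + rnorm(length(x), 0, 0.1)
  expect_equal(goodness_of_fit(x, noisy), 1 - 0.01 / var(noisy),
               tolerance = 0.05)
  expect_warning(r2 <- goodness_of_fit(x, rep(1, length(x))), "constant")
  expect_true(is.na(r2))
})

test_that("fitting recovers known parameters", {
  truth <- shape_fixture("trypomastigote")
  times <- seq(0, 1.5, by = 1 / 200)
  z <- truth$points$z
  traces0 <- lapply(z, function(zi)
    data.frame(time = times, x = eval_model(truth, zi, times)$x_c))

  # exact initial guess: identical recovery, R^2 = 1
  fit0 <- fit_model(traces0, truth, estimate_frequencies = FALSE)
  expect_equal(min(attr(fit0, "r_squared")), 1, tolerance = 1e-9)
  expect_equal(fit0$omega_r, truth$omega_r, tolerance = 1e-9)

  # +-20% perturbed guess and 1% noise: within 5%
  set.seed(11)
  traces <- lapply(traces0, function(tr) {
    tr$x <- tr$x + rnorm(length(tr$x), 0, 0.01 * sd(tr$x))
    tr
  })
  ip <- truth$points
  ip$A_r <- ip$A_r * runif(8, 0.8, 1.2)
  ip$A_b <- ip$A_b * runif(8, 0.8, 1.2)
  ip$p_r <- ip$p_r + runif(8, -0.3, 0.3)
  ip$p_b <- ip$p_b + runif(8, -0.3, 0.3)
  init <- shape_model_params(ip, truth$omega_r * 1.2, truth$f_b * 0.8)
  fit <- fit_model(traces, init)
  expect_true(attr(fit, "converged"))
  expect_lt(abs(fit$omega_r - truth$omega_r) / truth$omega_r, 0.05)
  expect_lt(abs(fit$f_b - truth$f_b) / truth$f_b, 0.05)
  expect_lt(max(abs(fit$points$A_r - truth$points$A_r) /
                  pmax(truth$points$A_r, 0.1)), 0.05)
  expect_lt(max(abs(fit$points$A_b - truth$points$A_b) /
                  pmax(truth$points$A_b, 0.1)), 0.05)
  # phases on a continuous branch after unwrapping
  expect_true(all(abs(diff(fit$points$p_r)) < pi))

  # non-rotating cell: rotation parameters flagged unidentifiable
  still <- make_params(omega_r = 0, A_r = rep(0, 8))
  tr_still <- lapply(still$points$z, function(zi)
    data.frame(time = times, x = eval_model(still, zi, times)$x_c))
  f2 <- suppressWarnings(fit_model(tr_still, still,
                                   estimate_frequencies = FALSE))
  expect_false(attr(f2, "rotation_identifiable"))
})

test_that("effective shape: zeroed beat, rigid phase rotation, handedness", {
  # constant A_r with p_r linear in z: an ideal helix centreline
  m <- make_params(A_b = rep(0, 8))
  es <- effective_shape(m)
  expect_equal(sqrt(es$x^2 + es$y^2), rep(1, 8))
  ph <- atan2(es$x, es$y)
  expect_equal(diff(ph), rep(0.3, 7), tolerance = 1e-12)

  # p_r constant in z: planar (achiral) centreline
  flat <- effective_shape(make_params(p_r = rep(0.4, 8)))
  expect_equal(flat$x / flat$y, rep(tan(0.4), 8))

  # time translation only rotates the shape rigidly about z
  es2 <- effective_shape(m, t = 0.123)
  expect_equal(sqrt(es2$x^2 + es2$y^2), sqrt(es$x^2 + es$y^2))
  expect_equal(es2$z, es$z)
  d1 <- dist(cbind(es$x, es$y, es$z))
  d2 <- dist(cbind(es2$x, es2$y, es2$z))
  expect_equal(as.numeric(d2), as.numeric(d1), tolerance = 1e-12)

  # negating the p_r slope mirrors the helix
  mneg <- make_params(p_r = -seq(0, 2.1, by = 0.3), A_b = rep(0, 8))
  esn <- effective_shape(mneg)
  expect_equal(esn$x, -es$x, tolerance = 1e-12)
  expect_equal(esn$y, es$y, tolerance = 1e-12)
})

test_that("shape parameters round trip through JSON", {
  m <- shape_fixture("epimastigote")
  path <- tempfile(fileext = ".json")
  write_shape_model(m, path)
  m2 <- read_shape_model(path)
  expect_equal(m2$points, m$points)
  expect_equal(m2$omega_r, m$omega_r)
  expect_equal(m2$f_b, m$f_b)
  unlink(path)
})
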