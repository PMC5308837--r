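# helper: analytic frame with Gaussian spots at (x, y) pixel centres
gauss_frame <- function(centres, amp = 1000, sigma = 1.5,
                        dims = c(48, 64)) {
  img <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(centres))) {
    gx <- exp(-((seq_len(dims[2]) - centres[i, 1])^2) / (2 * sigma^2))
    gy <- exp(-((seq_len(dims[1]) - centres[i, 2])^2) / (2 * sigma^2))
    img <- img + amp * outer(gy, gx)
  }
  img
}

as_stack <- function(frames, frame_rate = 5, pixel_size = 1) {
  opt <- optics_model(pixel_size = pixel_size, frame_rate = frame_rate,
                      image_size = c(ncol(frames[[1]]), nrow(frames[[1]])))
  structure(list(frames = frames, optics = opt), class = "image_stack")
}

test_that("minimum-projection background subtraction", {
  # static scene vanishes entirely
  f <- gauss_frame(rbind(c(10, 10)))
  st <- subtract_background(as_stack(list(f, f, f)))
  expect_true(all(vapply(st$frames, max, numeric(1)) == 0))

  # moving spot on constant background: spot on zero background
  b <- 50
  fr <- lapply(c(10, 20, 30), function(x) gauss_frame(rbind(c(x, 10))) + b)
  st2 <- subtract_background(as_stack(fr))
  expect_lt(min(vapply(st2$frames, min, numeric(1))), 1e-9)
  expect_gt(max(st2$frames[[2]]), 900)

  # brute-force per-pixel min on a 3-frame toy stack
  toy <- list(matrix(c(5, 1, 2, 8), 2), matrix(c(3, 4, 2, 9), 2),
              matrix(c(7, 1, 6, 8), 2))
  mn <- pmin(toy[[1]], pmin(toy[[2]], toy[[3]]))
  st3 <- subtract_background(as_stack(toy))
  for (i in 1:3) expect_equal(st3$frames[[i]], toy[[i]] - mn)

  expect_error(subtract_background(as_stack(list(f))), "2 frames")
})

test_that("detection finds blurred local maxima and merges close spots", {
  expect_equal(nrow(detect_cells(matrix(0, 48, 64))), 0)

  two <- gauss_frame(rbind(c(20, 24), c(40, 24)))
  d <- detect_cells(two)
  expect_equal(nrow(d), 2)
  d <- d[order(d$x_px), ]
  expect_lt(max(abs(d$x_px - c(20, 40))), 1.5)
  expect_lt(max(abs(d$y_px - 24)), 1.5)

  # two spots 1 px apart merge into one after a 2 px blur
  close_pair <- gauss_frame(rbind(c(30, 24), c(31, 24)))
  expect_equal(nrow(detect_cells(close_pair)), 1)
})

test_that("linking follows moving cells and respects the link radius", {
  # single cell at 2 px/frame: one track spanning all frames
  frames <- lapply(0:9, function(k) cbind(frame = k + 1, x_px = 10 + 2 * k,
                                          y_px = 20))
  det <- as.data.frame(do.call(rbind, frames))
  tk <- link_tracks(det, max_link = 15)
  expect_length(tk, 1)
  expect_equal(nrow(tk[[1]]), 10)

  # a 20 px jump (> 15) terminates the track and seeds a new one
  det2 <- data.frame(frame = 1:6, x_px = c(10, 12, 14, 34, 36, 38), y_px = 20)
  tk2 <- link_tracks(det2, max_link = 15)
  expect_length(tk2, 2)
  expect_equal(vapply(tk2, nrow, integer(1)), c(3L, 3L))
})

test_that("motion prediction keeps identities of crossing cells", {
  # cell A moves +4 px/frame in x; cell B -4 px/frame; they cross at frame 3
  fx_a <- c(10, 14, 18, 22, 26)
  fx_b <- c(26, 22, 18, 14, 10)
  det <- rbind(data.frame(frame = 1:5, x_px = fx_a, y_px = 20),
               data.frame(frame = 1:5, x_px = fx_b, y_px = 20))
  tk <- link_tracks(det, max_link = 15)
  expect_length(tk, 2)
  xs <- lapply(tk, function(t) t$x)
  expect_true(any(vapply(xs, function(x) all(x == fx_a - 1), logical(1))))
  expect_true(any(vapply(xs, function(x) all(x == fx_b - 1), logical(1))))

  # deterministic under detection order shuffling within frames
  set.seed(1)
  det_shuffled <- det[sample(nrow(det)), ]
  tk_s <- link_tracks(det_shuffled, max_link = 15)
  expect_equal(lapply(tk_s, as.data.frame), lapply(tk, as.data.frame))
})

test_that("track statistics: straight, reversing and circular motion", {
  tt <- seq(0, 30, by = 0.2)
  straight <- cell_track(tt, 5 * tt, 2 + 0 * tt)
  st <- track_statistics(straight, eval_dt = 2)
  expect_equal(st$mean_speed, 5)
  expect_equal(st$persistence, 1)
  expect_equal(st$duration, 30)

  # perfect period-2*eval_dt reversal: persistence -1
  saw <- cell_track(0:20, c(0, 1, 2, 1)[1 + (0:20) %% 4], 0 * (0:20))
  expect_equal(track_statistics(saw, eval_dt = 2)$persistence, -1)

  # uniform circular motion: persistence = cos(omega * eval_dt)
  circ <- circle_track(rho = 10, w = 0.5, frame_dt = 0.2, n_frames = 151)
  expect_equal(track_statistics(circ, eval_dt = 2)$persistence, cos(1.0),
               tolerance = 1e-9)

  expect_error(track_statistics(cell_track(0:3, 0:3, 0:3), eval_dt = 2),
               "too short")
})

test_that("persistence is invariant under rigid motions of the track set", {
  circ <- circle_track(rho = 8, w = 0.3)
  th <- 0.77
  rot <- cell_track(circ$time,
                    cos(th) * circ$x - sin(th) * circ$y + 12,
                    sin(th) * circ$x + cos(th) * circ$y - 40)
  a <- track_statistics(circ, 2)
  b <- track_statistics(rot, 2)
  expect_equal(a$persistence, b$persistence, tolerance = 1e-12)
  expect_equal(a$mean_speed, b$mean_speed, tolerance = 1e-12)
})

test_that("population summary weights by track duration", {
  # durations 10 s and 30 s, persistences ~0 and ~1 -> weighted mean 0.75
  t1 <- circle_track(rho = 4, w = pi / 4, frame_dt = 0.5, n_frames = 21)
  stopifnot(abs(track_statistics(t1, 2)$persistence) < 1e-9)  # cos(pi/2)
  tt2 <- seq(0, 30, by = 0.5)
  t2 <- cell_track(tt2, 6 * tt2, 0 * tt2)
  ps <- population_summary(list(t1, t2), eval_dt = 2)
  expect_equal(ps$n_tracks, 2)
  expect_equal(ps$mean_persistence, 0.75, tolerance = 1e-9)
  # persistence thresholds: only the straight 30 s track exceeds 0.8
  expect_equal(unname(ps$persistence_fraction), rep(0.75, 3))
  # conditional on speed > 5: only the straight track (6 um/s) qualifies
  expect_equal(unname(ps$speed_conditional_persistence[1]), 1)

  # single track: its own statistics
  one <- population_summary(list(t2), eval_dt = 2)
  expect_equal(one$mean_persistence, 1)
  expect_equal(one$mean_speed, 6)

  # all below 0.8: zero threshold fractions
  low <- population_summary(list(t1), eval_dt = 2)
  expect_equal(unname(low$persistence_fraction), c(0, 0, 0))

  # empty input: explicit empty result
  none <- population_summary(list(), eval_dt = 2)
  expect_equal(none$n_tracks, 0)
  expect_true(is.na(none$mean_persistence))
})

test_that("autocorrelation curve: straight tracks flat at 1, circles at cos(w lag)", {
  tt <- seq(0, 40, by = 0.1)
  straight <- cell_track(tt, 3 * tt, 1 + 0 * tt)
  ac <- persistence_autocorrelation(list(straight), base_dt = 0.5,
                                    lags = seq(0, 10, by = 2))
  expect_equal(ac$autocorrelation, rep(1, nrow(ac)))

  w <- 0.4
  circ <- cell_track(tt, 10 * cos(w * tt), 10 * sin(w * tt))
  ac2 <- persistence_autocorrelation(list(circ), base_dt = 0.5,
                                     lags = c(0, 1, 2, 5))
  expect_equal(ac2$autocorrelation, cos(w * c(0, 1, 2, 5)),
               tolerance = 1e-9)
})

test_that("rendered straight swimmers are recovered by the full pipeline", {
  opt <- optics_model(image_size = c(200, 64), focal_plane_z = 50)
  cfg <- simulation_config(duration = 20, dt = 0.2, brownian = FALSE)
  trajs <- lapply(c(10, 30), function(y0)
    simulate_cell(path_kinematics(5, 0, 0), cfg,
                  cell_state(c(5, y0, 50))))
  st <- subtract_background(render_stack(trajs, opt))
  tracks <- link_tracks(detect_stack(st), max_link = 15, optics = opt)
  expect_length(tracks, 2)
  for (tk in tracks) {
    s <- track_statistics(tk, eval_dt = 2)
    expect_equal(s$mean_speed, 5, tolerance = 0.02)
    expect_gt(s$persistence, 0.99)
  }
})
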