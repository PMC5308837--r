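#' Analytical cell-movement model parameters
#'
#' The movement of a swimming trypanosomatid, viewed at a position `z`
#' along its long axis, is described as the sum of (i) lateral displacement
#' of an underlying (possibly helical) cell shape rotating longitudinally
#' at angular velocity `omega_r`, and (ii) displacement due to a planar
#' sinusoid-like flagellar beat of frequency `f_b` whose apparent magnitude
#' depends on the instantaneous orientation of the beat plane:
#' \deqn{x_r = A_r(z) \sin(p_r(z) + \omega_r t),\quad
#'       y_r = A_r(z) \cos(p_r(z) + \omega_r t)}
#' \deqn{b = A_b(z) \sin(p_b(z) + \omega_b t),\quad \omega_b = 2\pi f_b}
#' \deqn{x_c = x_r + b \sin(p_r + p_o + \omega_r t),\quad
#'       y_c = y_r + b \cos(p_r + p_o + \omega_r t)}
#' Parameter functions are defined at control points along `z` (8 in the
#' standard layout; `z` increasing from the flagellum-tip end) and linearly
#' interpolated between them. This is a numerical description of shape
#' change, not a physically consistent kinematic model (it does not, for
#' instance, preserve cell length over a beat cycle).
#'
#' @param points data.frame with one row per control point and columns
#'   `z` (um, strictly increasing), `A_r` (um, >= 0), `p_r` (rad),
#'   `A_b` (um, >= 0), `p_b` (rad), `p_o` (rad) and `w` (cell width, um,
#'   > 0).
#' @param omega_r cell rotation angular velocity, rad/s.
#' @param f_b flagellar beat frequency, Hz.
#' @return object of class `shape_model`.
#' @export
shape_model_params <- function(points, omega_r, f_b) {
  req <- c("z", "A_r", "p_r", "A_b", "p_b", "p_o", "w")
  stopifnot(is.data.frame(points), all(req %in% names(points)),
            nrow(points) >= 2L)
  if (any(diff(points$z) <= 0)) stop("'z' must be strictly increasing")
  if (any(points$A_r < 0) || any(points$A_b < 0))
    stop("amplitudes must be >= 0")
  if (any(points$w <= 0)) stop("widths must be > 0")
  .check_scalar(omega_r, "omega_r"); .check_scalar(f_b, "f_b")
  structure(list(points = points[req], omega_r = omega_r, f_b = f_b),
            class = "shape_model")
}

.interp_params <- function(params, z) {
  p <- params$points
  if (any(z < min(p$z) - 1e-9) || any(z > max(p$z) + 1e-9))
    stop("'z' outside the control-point range")
  lapply(c(A_r = "A_r", p_r = "p_r", A_b = "A_b", p_b = "p_b", p_o = "p_o",
           w = "w"),
         function(f) approx(p$z, p[[f]], xout = z, rule = 2)$y)
}

#' Evaluate the cell-movement model
#'
#' @param params a [shape_model_params()].
#' @param z position along the cell, um (scalar, within the control-point
#'   range).
#' @param t time(s), s (vectorised).
#' @return data.frame with `t`, `x_c`, `y_c` (um).
#' @export
eval_model <- function(params, z, t) {
  stopifnot(inherits(params, "shape_model"))
  .check_scalar(z, "z")
  pz <- .interp_params(params, z)
  omega_b <- 2 * pi * params$f_b
  phase_r <- pz$p_r + params$omega_r * t
  x_r <- pz$A_r * sin(phase_r)
  y_r <- pz$A_r * cos(phase_r)
  b <- pz$A_b * sin(pz$p_b + omega_b * t)
  x_c <- x_r + b * sin(phase_r + pz$p_o)
  y_c <- y_r + b * cos(phase_r + pz$p_o)
  data.frame(t = t, x_c = x_c, y_c = y_c)
}

#' Model kymograph trace at a fixed position on the cell
#'
#' The lateral in-focal-plane displacement `x_c(z, t)` sampled at the high
#' frame rate (200 Hz by default), directly overlayable on an
#' image-derived kymograph taken through the same transverse section.
#'
#' @inheritParams eval_model
#' @param times sampling times, s; default one second at 200 Hz.
#' @return object of class `kymograph`: data.frame with `time` and `x`.
#' @export
model_kymograph <- function(params, z, times = seq(0, 1, by = 1 / 200)) {
  ev <- eval_model(params, z, times)
  out <- data.frame(time = times, x = ev$x_c)
  attr(out, "z") <- z
  class(out) <- c("kymograph", "data.frame")
  out
}

#' Goodness of fit between a model trace and an observed trace
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot`. A constant
#' observed trace has no variance to explain; `NA` is returned with a
#' warning.
#'
#' @param model numeric vector of model values.
#' @param observed numeric vector of the same length.
#' @return `R^2` (1 for a perfect fit, 0 for a fit no better than the
#'   observed mean).
#' @export
goodness_of_fit <- function(model, observed) {
  stopifnot(length(model) == length(observed))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("constant observed trace: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - model)^2) / ss_tot
}

# summed DFT power of the traces at an arbitrary frequency (Hz)
.dft_power <- function(traces, f) {
  vapply(f, function(fi) {
    sum(vapply(traces, function(tr) {
      x <- tr$x - mean(tr$x)
      Mod(sum(x * exp(-2i * pi * fi * tr$time)))^2
    }, numeric(1L)))
  }, numeric(1L))
}

# Refine the rotation and beat frequencies before least squares. The model
# is a sum of sinusoids at f_r and (because the beat term is a product of
# two sinusoids) at f_b - f_r and f_b + f_r; each is located by maximising
# the summed periodogram of the traces on a fine grid around the initial
# guess, which tolerates initial frequency errors far beyond the basin of a
# local least-squares fit.
.refine_frequencies <- function(traces, omega_r0, f_b0, span = 0.35) {
  f_r0 <- abs(omega_r0) / (2 * pi)
  grid_about <- function(f0) seq((1 - span) * f0, (1 + span) * f0,
                                 length.out = 241L)
  if (f_r0 > 1e-6) {
    g <- grid_about(f_r0)
    f_r <- g[which.max(.dft_power(traces, g))]
    g <- grid_about(f_b0)
    p <- .dft_power(traces, g - f_r) + .dft_power(traces, g + f_r)
    f_b <- g[which.max(p)]
    list(omega_r = sign(omega_r0) * 2 * pi * f_r, f_b = f_b)
  } else {
    g <- grid_about(f_b0)
    f_b <- g[which.max(.dft_power(traces, g))]
    list(omega_r = omega_r0, f_b = f_b)
  }
}

# unwrap a phase sequence onto a continuous branch (< pi jumps)
.unwrap <- function(p) {
  if (length(p) < 2L) return(p)
  out <- p
  for (i in 2:length(p)) {
    d <- out[i] - out[i - 1L]
    out[i] <- out[i] - 2 * pi * round(d / (2 * pi))
  }
  out
}

#' Fit the cell-movement model to kymograph traces
#'
#' Bounded Levenberg-Marquardt least squares over all per-control-point
#' parameters plus the global rotation rate and beat frequency, minimising
#' the summed squared residual (equivalently maximising summed `R^2`)
#' across traces observed at each control-point `z`. This automates the
#' manual fit-by-eye workflow; [eval_model()] plus [goodness_of_fit()]
#' remain available for manual iteration. Because phases are only defined
#' modulo 2 pi, fitted phases are afterwards unwrapped onto a continuous
#' branch (adjacent control points differing by < pi), working outward from
#' the first control point, so that linear interpolation between control
#' points is meaningful.
#'
#' If the rotation rate is (near) zero the rotation amplitude and phase are
#' structurally unidentifiable - rotation cannot be inferred without
#' rotation - and the result is flagged with attribute
#' `rotation_identifiable = FALSE`.
#'
#' @param traces list of data.frames (`time`, `x`), one per control point,
#'   in control-point order.
#' @param init a [shape_model_params()] initial guess; its `z` and `w` are
#'   kept fixed.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param estimate_frequencies refine the rotation rate and beat frequency
#'   from the traces' periodogram before least squares (default `TRUE`);
#'   local optimisation alone needs frequency guesses good enough that the
#'   accumulated phase drift over a trace stays below half a cycle.
#' @return fitted `shape_model` with attributes `r_squared` (per trace),
#'   `converged` and `rotation_identifiable`. Non-convergence warns and
#'   returns the best parameters found.
#' @export
fit_model <- function(traces, init, max_iter = 200L,
                      estimate_frequencies = TRUE) {
  stopifnot(inherits(init, "shape_model"), is.list(traces),
            length(traces) == nrow(init$points))
  if (estimate_frequencies) {
    fr <- .refine_frequencies(traces, init$omega_r, init$f_b)
    init <- shape_model_params(init$points, fr$omega_r, fr$f_b)
  }
  npt <- nrow(init$points)
  z <- init$points$z
  pack <- function(pts, omega_r, f_b)
    c(pts$A_r, pts$p_r, pts$A_b, pts$p_b, pts$p_o, omega_r, f_b)
  unpack <- function(par) {
    pts <- init$points
    pts$A_r <- par[1:npt]
    pts$p_r <- par[npt + (1:npt)]
    pts$A_b <- par[2 * npt + (1:npt)]
    pts$p_b <- par[3 * npt + (1:npt)]
    pts$p_o <- par[4 * npt + (1:npt)]
    list(points = pts, omega_r = par[5 * npt + 1L], f_b = par[5 * npt + 2L])
  }
  resid_fn <- function(par) {
    u <- unpack(par)
    m <- shape_model_params(u$points, u$omega_r, u$f_b)
    unlist(lapply(seq_len(npt), function(i) {
      tr <- traces[[i]]
      eval_model(m, z[i], tr$time)$x_c - tr$x
    }))
  }
  lower <- c(rep(0, npt), rep(-Inf, npt), rep(0, npt), rep(-Inf, 2 * npt),
             -Inf, 1e-6)
  fit <- minpack.lm::nls.lm(
    par = pack(init$points, init$omega_r, init$f_b), lower = lower,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("model fit did not converge; returning best parameters found")
  u <- unpack(fit$par)
  pts <- u$points
  pts$p_r <- .unwrap(pts$p_r)
  pts$p_b <- .unwrap(pts$p_b)
  pts$p_o <- .unwrap(pts$p_o)
  out <- shape_model_params(pts, u$omega_r, u$f_b)
  r2 <- vapply(seq_len(npt), function(i) {
    tr <- traces[[i]]
    goodness_of_fit(eval_model(out, z[i], tr$time)$x_c, tr$x)
  }, numeric(1L))
  identifiable <- abs(out$omega_r) > 1e-6
  if (!identifiable)
    warning("rotation rate ~ 0: rotation amplitude/phase unidentifiable")
  attr(out, "r_squared") <- r2
  attr(out, "converged") <- converged
  attr(out, "rotation_identifiable") <- identifiable
  out
}

#' Effective hydrodynamic shape of the cell
#'
#' Setting the flagellar beat amplitude to zero removes the cyclic,
#' beat-driven displacement and leaves the shape the fluid effectively
#' sees: the 3-D centreline
#' `(A_r(z) sin(p_r(z) + omega_r t), A_r(z) cos(p_r(z) + omega_r t), z)`
#' at the control points, with segment radii `w(z) / 2`. Changing `t` only
#' rotates the shape rigidly about the long axis; it does not change the
#' geometry.
#'
#' @param params a [shape_model_params()].
#' @param t rotation phase time, s (default 0).
#' @return object of class `effective_shape`: data.frame with `x`, `y`,
#'   `z` (um) and `radius` (um).
#' @export
effective_shape <- function(params, t = 0) {
  stopifnot(inherits(params, "shape_model"))
  p <- params$points
  phase <- p$p_r + params$omega_r * t
  out <- data.frame(x = p$A_r * sin(phase), y = p$A_r * cos(phase),
                    z = p$z, radius = p$w / 2)
  class(out) <- c("effective_shape", "data.frame")
  out
}

#' Read / write shape-model parameters (JSON)
#'
#' One record per control point plus a globals record (`omega_r`, `f_b`),
#' mirroring the hand-fitted parameter-table layout.
#'
#' @param path file path.
#' @return [shape_model_params()] object (`read_shape_model`) or the path,
#'   invisibly (`write_shape_model`).
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  shape_model_params(as.data.frame(obj$points), obj$omega_r, obj$f_b)
}

#' @rdname read_shape_model
#' @param params a `shape_model`.
#' @export
write_shape_model <- function(params, path) {
  stopifnot(inherits(params, "shape_model"))
  jsonlite::write_json(list(omega_r = params$omega_r, f_b = params$f_b,
                            points = params$points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
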