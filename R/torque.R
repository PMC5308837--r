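#' Uniform axial flow specification
#'
#' @param U flow speed along the shape's long (z) axis, um/s (default 1).
#' @param viscosity dynamic viscosity, Pa s (default 8.7e-4).
#' @return object of class `flow_spec`.
#' @export
flow_spec <- function(U = 1, viscosity = 8.7e-4) {
  .check_scalar(U, "U"); .check_scalar(viscosity, "viscosity")
  if (U < 0) stop("'U' must be >= 0")
  if (viscosity <= 0) stop("'viscosity' must be > 0")
  structure(list(U = U, viscosity = viscosity), class = "flow_spec")
}

#' Resistive-force (slender-body) drag coefficients
#'
#' Drag per unit length per unit speed for a slender cylindrical segment in
#' Stokes flow, for motion parallel and perpendicular to the segment axis.
#' The default Gray-Hancock form is
#' \deqn{C_\parallel = \frac{2\pi\mu}{\ln(2q/r) - 1/2},\qquad
#'       C_\perp = \frac{4\pi\mu}{\ln(2q/r) + 1/2}}
#' with `q` the slenderness length scale (the segment length by default)
#' and `r` the segment radius; the Lighthill variant replaces the
#' additive constants with -0.807 and +0.193. The anisotropy
#' `C_perp > C_par` (ratio tending to 2 as `q/r` grows) is what generates
#' lateral force on tilted segments.
#'
#' @param q slenderness length scale, um (must exceed `2 r`).
#' @param r segment radius, um (> 0).
#' @param viscosity dynamic viscosity, Pa s.
#' @param method `"gray-hancock"` (default) or `"lighthill"`.
#' @return named vector `c(C_par = , C_perp = )` in Pa s (force per length
#'   per speed).
#' @export
resistive_coefficients <- function(q, r, viscosity = 8.7e-4,
                                   method = c("gray-hancock", "lighthill")) {
  .check_scalar(q, "q"); .check_scalar(r, "r")
  method <- match.arg(method)
  if (r <= 0) stop("'r' must be > 0")
  if (q <= 2 * r) stop("slenderness violated: need q > 2 r")
  L <- log(2 * q / r)
  if (method == "gray-hancock") {
    C_par <- 2 * pi * viscosity / (L - 0.5)
    C_perp <- 4 * pi * viscosity / (L + 0.5)
  } else {
    C_par <- 2 * pi * viscosity / (L - 0.807)
    C_perp <- 4 * pi * viscosity / (L + 0.193)
  }
  c(C_par = C_par, C_perp = C_perp)
}

#' Lateral force on a tilted slender segment under axial flow
#'
#' The incoming flow `U` along z is decomposed into components parallel and
#' perpendicular to the segment tangent; anisotropic drag
#' (`C_perp > C_par`) makes the total drag force non-parallel to the flow,
#' leaving a component perpendicular to the flow of magnitude per unit
#' length \eqn{(C_\perp - C_\parallel) U \sin\theta\cos\theta} for tilt
#' angle theta. Segments parallel or perpendicular to the flow generate no
#' lateral force.
#'
#' @param tangent unit 3-vector, segment direction.
#' @param length segment length, um (> 0).
#' @param coefficients from [resistive_coefficients()].
#' @param flow a [flow_spec()].
#' @return list with `force` (3-vector, pN, the component perpendicular to
#'   the flow) and `magnitude` (pN).
#' @export
segment_lateral_force <- function(tangent, length, coefficients, flow) {
  stopifnot(inherits(flow, "flow_spec"), length(tangent) == 3L)
  if (length <= 0) stop("zero-length segment")
  u <- .unit(tangent)
  zhat <- c(0, 0, 1)
  C_par <- coefficients[["C_par"]]; C_perp <- coefficients[["C_perp"]]
  U_m <- flow$U * 1e-6       # m/s
  len_m <- length * 1e-6     # m
  # F/L = C_par U_par + C_perp U_perp = C_perp U zhat + (C_par - C_perp)(U.u) u
  # lateral (perpendicular-to-flow) part:
  lat <- (C_par - C_perp) * (U_m * u[3L]) * (u - u[3L] * zhat)  # N/m
  force_pN <- lat * len_m * 1e12
  list(force = force_pN, magnitude = .norm3(force_pN))
}

#' Axial torque on a segmented effective shape under axial flow
#'
#' For each segment between consecutive centreline points, the lateral
#' (perpendicular-to-flow) drag force is computed from slender-body theory
#' and crossed with the segment midpoint's radial offset from the z-axis
#' (the rotation axis of the shape-model frame); the z-components are
#' summed. A chiral (helical) shape yields a net axial torque whose sign
#' follows the handedness; planar or on-axis shapes yield exactly zero.
#' Torque is linear in both flow speed and viscosity.
#'
#' @param shape an [effective_shape()] (or data.frame with `x`, `y`, `z`,
#'   `radius` in um), at least 2 points.
#' @param flow a [flow_spec()].
#' @param method coefficient variant, see [resistive_coefficients()].
#' @param slenderness_length optional fixed slenderness length scale `q`
#'   (um) used for every segment; default `NULL` uses each segment's own
#'   length. Fixing it makes torque comparable across discretisations of
#'   the same curve.
#' @return list with `per_segment` (data.frame: segment, z_mid, torque in
#'   pN um) and `total` (pN um).
#' @export
axial_torque <- function(shape, flow = flow_spec(),
                         method = c("gray-hancock", "lighthill"),
                         slenderness_length = NULL) {
  stopifnot(inherits(flow, "flow_spec"),
            all(c("x", "y", "z", "radius") %in% names(shape)),
            nrow(shape) >= 2L)
  method <- match.arg(method)
  ns <- nrow(shape) - 1L
  torque <- numeric(ns)
  z_mid <- numeric(ns)
  for (i in seq_len(ns)) {
    p1 <- c(shape$x[i], shape$y[i], shape$z[i])
    p2 <- c(shape$x[i + 1L], shape$y[i + 1L], shape$z[i + 1L])
    seg <- p2 - p1
    len <- .norm3(seg)
    if (len == 0) stop("zero-length segment")
    r_seg <- (shape$radius[i] + shape$radius[i + 1L]) / 2
    q <- if (is.null(slenderness_length)) len else slenderness_length
    coef <- resistive_coefficients(q, r_seg, flow$viscosity, method)
    lf <- segment_lateral_force(seg / len, len, coef, flow)
    mid <- (p1 + p2) / 2
    lever_m <- c(mid[1L], mid[2L], 0) * 1e-6            # m
    f_N <- lf$force * 1e-12                             # N
    tz <- lever_m[1L] * f_N[2L] - lever_m[2L] * f_N[1L] # N m, z-component
    torque[i] <- tz * 1e18                              # pN um
    z_mid[i] <- mid[3L]
  }
  list(per_segment = data.frame(segment = seq_len(ns), z_mid = z_mid,
                                torque = torque),
       total = sum(torque))
}

#' Ideal helical test centreline
#'
#' A single-turn (by default) helix centreline discretised at `n_points`,
#' used for torque validation: radius sets the chirality lever arm, the
#' sign of `pitch` the handedness.
#'
#' @param radius helix radius, um.
#' @param pitch helix pitch, um (signed).
#' @param n_points number of centreline points (default 8).
#' @param turns number of turns (default 1).
#' @param segment_radius cylinder radius of the body, um (default 0.15).
#' @return an `effective_shape` data.frame.
#' @export
helical_shape <- function(radius, pitch, n_points = 8L, turns = 1,
                          segment_radius = 0.15) {
  p <- seq(0, 2 * pi * turns, length.out = n_points)
  out <- data.frame(x = radius * cos(p), y = radius * sin(p),
                    z = pitch * p / (2 * pi), radius = segment_radius)
  class(out) <- c("effective_shape", "data.frame")
  out
}
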