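#' Prolate-spheroid cell geometry for Brownian motion
#'
#' The swimming cell is modelled, for the purpose of its Brownian motion,
#' as a prolate spheroid with effective radius `r_d` for displacement along
#' the long axis (travel direction t) and `r_np` for displacement along the
#' normal and binormal. Defaults are the trypanosomatid values r_d = 1.5 um
#' and r_np = 8.0 um.
#'
#' @param r_d effective radius along the long axis, um (> 0).
#' @param r_np effective radius along the two short axes, um (> 0).
#' @return object of class `spheroid_geometry` with fields `r_d`, `r_np`,
#'   `aspect` (`e = r_np / r_d`) and `equal_volume_radius`
#'   (`a = (r_d^2 r_np)^(1/3)`, um).
#' @examples
#' spheroid_geometry()$equal_volume_radius  # 18^(1/3) ~ 2.62 um
#' @export
spheroid_geometry <- function(r_d = 1.5, r_np = 8.0) {
  .check_scalar(r_d, "r_d"); .check_scalar(r_np, "r_np")
  if (r_d <= 0 || r_np <= 0) stop("spheroid radii must be > 0")
  structure(list(r_d = r_d, r_np = r_np, aspect = r_np / r_d,
                 equal_volume_radius = (r_d^2 * r_np)^(1 / 3)),
            class = "spheroid_geometry")
}

#' Thermodynamic environment for diffusion calculations
#'
#' @param temperature thermodynamic temperature, kelvin. The default
#'   299.15 K corresponds to the 26 degree C ambient temperature of the
#'   imaging experiments.
#' @param celsius alternative way to give the temperature, degrees Celsius;
#'   converted by adding 273.15. If supplied, overrides `temperature`.
#' @param viscosity dynamic viscosity, Pa s. Default 8.7e-4 (water at
#'   26 degrees C).
#' @return object of class `swim_environment`.
#' @examples
#' swim_environment(celsius = 26)$temperature  # 299.15
#' @export
swim_environment <- function(temperature = 299.15, celsius = NULL,
                             viscosity = 8.7e-4) {
  if (!is.null(celsius)) {
    .check_scalar(celsius, "celsius")
    temperature <- celsius + 273.15
  }
  .check_scalar(temperature, "temperature")
  .check_scalar(viscosity, "viscosity")
  if (temperature <= 0) stop("'temperature' must be > 0 K")
  if (viscosity <= 0) stop("'viscosity' must be > 0")
  structure(list(temperature = temperature, viscosity = viscosity,
                 boltzmann = .kB),
            class = "swim_environment")
}

#' Perrin rotational friction factors of a prolate spheroid
#'
#' Friction factors for rotation about the major axis (`f_d`) and the minor
#' axes (`f_np`) relative to the sphere of equal volume, as functions of the
#' axial ratio `e = r_np / r_d`. With \eqn{\xi = \sqrt{|e^2-1|}/e} and
#' \eqn{S = 2\,\mathrm{artanh}(\xi)/\xi}:
#' \deqn{f_d = \frac{4}{3}\frac{\xi^2}{2 - S/e^2},\qquad
#'       f_{np} = \frac{4}{3}\frac{1/e^2 - e^2}{2 - S(2 - 1/e^2)}}
#' For a prolate spheroid (`e > 1` with the convention used here)
#' `f_d < 1 < f_np`: spinning about the long axis is easier than for the
#' equal-volume sphere, tumbling about a short axis is harder. The sphere
#' limit `e = 1` returns `c(1, 1)`.
#'
#' @param e axial ratio `r_np / r_d` (> 0).
#' @return named numeric vector `c(f_d = , f_np = )`.
#' @examples
#' perrin_factors(8.0 / 1.5)
#' @export
perrin_factors <- function(e) {
  .check_scalar(e, "e")
  if (e <= 0) stop("'e' must be > 0")
  if (abs(e - 1) < 1e-9) return(c(f_d = 1, f_np = 1))
  xi <- sqrt(abs(e^2 - 1)) / e
  if (e > 1) {
    # prolate: S = 2 artanh(xi) / xi
    S <- 2 * atanh(xi) / xi
    f_d <- (4 / 3) * xi^2 / (2 - S / e^2)
  } else {
    # oblate continuation: artanh of an imaginary argument becomes arctan
    # and the spin denominator changes sign
    S <- 2 * atan(xi) / xi
    f_d <- (4 / 3) * xi^2 / (S / e^2 - 2)
  }
  f_np <- (4 / 3) * (1 / e^2 - e^2) / (2 - S * (2 - 1 / e^2))
  c(f_d = f_d, f_np = f_np)
}

#' Translational diffusion coefficients (Stokes-Einstein)
#'
#' \eqn{D_i = kT / (6\pi r_i \mu)} for the two effective radii of the
#' spheroid, returned in um^2/s.
#'
#' @param geom a [spheroid_geometry()].
#' @param env a [swim_environment()].
#' @return named numeric vector `c(D_d = , D_np = )`, um^2/s.
#' @examples
#' translational_diffusion(spheroid_geometry(), swim_environment())
#' @export
translational_diffusion <- function(geom = spheroid_geometry(),
                                    env = swim_environment()) {
  stopifnot(inherits(geom, "spheroid_geometry"),
            inherits(env, "swim_environment"))
  kT <- env$boltzmann * env$temperature
  d_one <- function(r_um) kT / (6 * pi * (r_um * 1e-6) * env$viscosity) * 1e12
  c(D_d = d_one(geom$r_d), D_np = d_one(geom$r_np))
}

#' Rotational diffusion coefficients with Perrin adjustment
#'
#' The equal-volume-sphere rotational diffusion coefficient follows the
#' Stokes-Einstein-Debye relation \eqn{E = kT / (8\pi\mu a^3)} with
#' \eqn{a = (r_d^2 r_{np})^{1/3}}. Rotation about each body axis is then
#' adjusted by the Perrin friction factors: with the default
#' `perrin_mode = "divide"` the effective coefficients are
#' `E_d = E / f_d` (about the long axis) and `E_np = E / f_np` (about the
#' short axes) - larger friction means slower diffusion. The alternative
#' `"multiply"` convention is provided for comparison only.
#'
#' @inheritParams translational_diffusion
#' @param perrin_mode `"divide"` (default, physically standard) or
#'   `"multiply"`.
#' @return object of class `diffusion_set`: list with translational
#'   `D_d`, `D_np` (um^2/s), sphere `E` (rad^2/s), factors `f_d`, `f_np`
#'   and effective `E_d`, `E_np` (rad^2/s).
#' @examples
#' rotational_diffusion()
#' @export
rotational_diffusion <- function(geom = spheroid_geometry(),
                                 env = swim_environment(),
                                 perrin_mode = c("divide", "multiply")) {
  stopifnot(inherits(geom, "spheroid_geometry"),
            inherits(env, "swim_environment"))
  perrin_mode <- match.arg(perrin_mode)
  kT <- env$boltzmann * env$temperature
  a_m <- geom$equal_volume_radius * 1e-6
  E <- kT / (8 * pi * env$viscosity * a_m^3)  # rad^2/s
  f <- perrin_factors(geom$aspect)
  if (perrin_mode == "divide") {
    E_d <- E / f[["f_d"]]; E_np <- E / f[["f_np"]]
  } else {
    E_d <- E * f[["f_d"]]; E_np <- E * f[["f_np"]]
  }
  D <- translational_diffusion(geom, env)
  structure(list(D_d = D[["D_d"]], D_np = D[["D_np"]], E = E,
                 f_d = f[["f_d"]], f_np = f[["f_np"]],
                 E_d = E_d, E_np = E_np, perrin_mode = perrin_mode),
            class = "diffusion_set")
}
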