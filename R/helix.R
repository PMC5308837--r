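#' Helix descriptor from path curvature and torsion
#'
#' A cell swimming with unchanging behaviour (no Brownian motion, no noise)
#' follows a path of constant curvature `kappa` and torsion `tau`, i.e. a
#' helix of radius \eqn{r = \kappa/(\kappa^2+\tau^2)} and pitch
#' \eqn{h = 2\pi\tau/(\kappa^2+\tau^2)}. `tau > 0` is taken as a
#' right-handed helix. The straight-line case `kappa = tau = 0` is returned
#' as an explicit degenerate descriptor (radius and pitch are `NA`), never
#' silently as zeros, so downstream code cannot divide by zero.
#'
#' @param kappa path curvature, 1/um (must be >= 0).
#' @param tau path torsion, 1/um; sign sets handedness.
#' @return An object of class `helix_descriptor`: a list with elements
#'   `kappa`, `tau`, `radius` (um), `pitch` (um), `axial_rate` (um per
#'   radian of helix parameter, `pitch / 2 pi`) and logical `degenerate`.
#' @examples
#' h <- helix_from_curvature_torsion(1, 1)
#' h$radius          # 0.5
#' h$pitch           # pi
#' @seealso [helix_metrics()], [directionality_limit()]
#' @export
helix_from_curvature_torsion <- function(kappa, tau) {
  .check_scalar(kappa, "kappa")
  .check_scalar(tau, "tau")
  if (kappa < 0) stop("'kappa' must be >= 0")
  q <- kappa^2 + tau^2
  if (q == 0) {
    out <- list(kappa = 0, tau = 0, radius = NA_real_, pitch = NA_real_,
                axial_rate = NA_real_, degenerate = TRUE)
  } else {
    r <- kappa / q
    h <- 2 * pi * tau / q
    out <- list(kappa = kappa, tau = tau, radius = r, pitch = h,
                axial_rate = h / (2 * pi), degenerate = FALSE)
  }
  class(out) <- "helix_descriptor"
  out
}

#' @export
print.helix_descriptor <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate helix (straight line): kappa = tau = 0\n")
  } else {
    cat(sprintf(
      "Helix: kappa = %g /um, tau = %g /um, radius = %g um, pitch = %g um\n",
      x$kappa, x$tau, x$radius, x$pitch))
  }
  invisible(x)
}

#' Arc length, displacement and directionality along a helix
#'
#' For the parametric helix \eqn{(r\cos p, r\sin p, cp)} the arc length from
#' `p = 0` to `p = P` is \eqn{l = P\sqrt{r^2+c^2}} and the displacement is
#' the chord \eqn{s = \sqrt{(r\cos P - r)^2 + (r \sin P)^2 + c^2P^2}}.
#' Directionality is the ratio `s / l`, the displacement achieved per unit
#' distance swum. A degenerate (straight-line) helix has directionality 1
#' for any `P`.
#'
#' @param helix a [helix_from_curvature_torsion()] descriptor.
#' @param P helix parameter interval traversed, radians (> 0). At speed `s`
#'   a cell traverses `P = T * sqrt(omega_kappa^2 + omega_tau^2)` in time `T`.
#' @return list with `arc_length` (um), `displacement` (um) and
#'   `directionality` (dimensionless, in (0, 1]).
#' @examples
#' h <- helix_from_curvature_torsion(1, 1)
#' helix_metrics(h, 2 * pi)$directionality  # 1/sqrt(2)
#' @export
helix_metrics <- function(helix, P) {
  stopifnot(inherits(helix, "helix_descriptor"))
  .check_scalar(P, "P")
  if (P <= 0) stop("'P' must be > 0")
  if (helix$degenerate)
    return(list(arc_length = NA_real_, displacement = NA_real_,
                directionality = 1))
  r <- helix$radius
  cc <- helix$axial_rate
  l <- P * sqrt(r^2 + cc^2)
  s_disp <- sqrt((r * cos(P) - r)^2 + (r * sin(P))^2 + (cc * P)^2)
  list(arc_length = l, displacement = s_disp, directionality = s_disp / l)
}

#' Large-turn limit of helical path directionality
#'
#' In the limit of many helix turns (`h P >> r`) the lateral chord terms
#' vanish and directionality tends to \eqn{\tau/\sqrt{\kappa^2+\tau^2}}.
#' Directionality therefore decreases with path curvature and increases
#' with path torsion. By convention the straight line `kappa = tau = 0`
#' returns 1.
#'
#' @inheritParams helix_from_curvature_torsion
#' @return dimensionless directionality in \[0, 1\] (sign of `tau` ignored
#'   would flip handedness only; negative `tau` gives negative values,
#'   callers comparing magnitudes should pass `abs(tau)`).
#' @examples
#' directionality_limit(0.12, 2.2)  # ~0.99852
#' @export
directionality_limit <- function(kappa, tau) {
  .check_scalar(kappa, "kappa")
  .check_scalar(tau, "tau")
  if (kappa < 0) stop("'kappa' must be >= 0")
  q <- kappa^2 + tau^2
  if (q == 0) return(1)
  tau / sqrt(q)
}

#' Path kinematics of a swimmer with constant rotation rates
#'
#' Describes a swimmer moving at constant speed `speed` whose body frame
#' rotates at `omega_kappa` about the binormal (bending the path) and
#' `omega_tau` about the travel direction (longitudinal rotation, twisting
#' the path). By the Darboux relation at constant speed these generate a
#' path with curvature `omega_kappa / speed` and torsion
#' `omega_tau / speed`.
#'
#' @param speed swimming speed, um/s (>= 0; zero describes a passive,
#'   non-swimming particle, useful for pure-diffusion checks).
#' @param omega_kappa rotation rate about the binormal, rad/s (>= 0).
#' @param omega_tau rotation rate about the travel direction, rad/s;
#'   sign sets helix handedness.
#' @return object of class `path_kinematics`.
#' @examples
#' k <- path_kinematics(5, 0.6, 11)
#' kinematics_to_path(k)  # kappa = 0.12, tau = 2.2
#' @export
path_kinematics <- function(speed, omega_kappa = 0, omega_tau = 0) {
  .check_scalar(speed, "speed")
  .check_scalar(omega_kappa, "omega_kappa")
  .check_scalar(omega_tau, "omega_tau")
  if (speed < 0) stop("'speed' must be >= 0")
  if (omega_kappa < 0) stop("'omega_kappa' must be >= 0")
  structure(list(speed = speed, omega_kappa = omega_kappa,
                 omega_tau = omega_tau),
            class = "path_kinematics")
}

#' Convert rotation rates to path curvature and torsion
#'
#' @param kin a [path_kinematics()] object with `speed > 0`.
#' @return list with `kappa` and `tau` (1/um).
#' @export
kinematics_to_path <- function(kin) {
  stopifnot(inherits(kin, "path_kinematics"))
  if (kin$speed <= 0) stop("path curvature/torsion need 'speed' > 0")
  list(kappa = kin$omega_kappa / kin$speed, tau = kin$omega_tau / kin$speed)
}
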