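# Independent oracles used across the test suite.

# Rotational friction factors of a prolate spheroid (semi-axes p > q = q)
# relative to the equal-volume sphere, by numerical quadrature of the
# classical ellipsoid drag integrals - independent of the closed forms in
# perrin_factors().
perrin_quadrature <- function(e) {
  p <- e; q <- 1
  alpha <- function(ai2) integrate(function(s)
    1 / ((ai2 + s) * sqrt((p^2 + s) * (q^2 + s)^2)),
    0, Inf, rel.tol = 1e-13)$value
  a_p <- alpha(p^2); a_q <- alpha(q^2)
  zeta_spin <- 16 * pi * (2 * q^2) / (3 * (2 * q^2 * a_q))
  zeta_tumble <- 16 * pi * (p^2 + q^2) / (3 * (p^2 * a_p + q^2 * a_q))
  R3 <- p * q * q
  c(f_d = zeta_spin / (8 * pi * R3), f_np = zeta_tumble / (8 * pi * R3))
}

# Numerical arc length of the parametric helix (r cos p, r sin p, c p)
# from 0 to P, by quadrature of |dx/dp|.
helix_arclength_quadrature <- function(r, cc, P) {
  integrate(function(p) sqrt(r^2 * sin(p)^2 + r^2 * cos(p)^2 + cc^2),
            0, P, rel.tol = 1e-12)$value
}

# Numerical curvature and torsion of a parametric curve via finite
# differences of the Frenet formulas.
curve_curvature_torsion <- function(fx, fy, fz, p0, h = 1e-3) {
  d1 <- function(f) (f(p0 + h) - f(p0 - h)) / (2 * h)
  d2 <- function(f) (f(p0 + h) - 2 * f(p0) + f(p0 - h)) / h^2
  d3 <- function(f) (f(p0 + 2 * h) - 2 * f(p0 + h) + 2 * f(p0 - h) -
                       f(p0 - 2 * h)) / (2 * h^3)
  r1 <- c(d1(fx), d1(fy), d1(fz))
  r2 <- c(d2(fx), d2(fy), d2(fz))
  r3 <- c(d3(fx), d3(fy), d3(fz))
  cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  kappa <- sqrt(sum(cr^2)) / sum(r1^2)^1.5
  tau <- sum(cr * r3) / sum(cr^2)
  c(kappa = kappa, tau = tau)
}

# Analytic finite-turn helix directionality for a swimmer with rotation
# rates (wk, wt) at speed s over duration Tt.
analytic_directionality <- function(wk, wt, s = 5, Tt = 102.4) {
  if (wk == 0 && wt == 0) return(1)
  h <- helix_from_curvature_torsion(wk / s, wt / s)
  helix_metrics(h, Tt * sqrt(wk^2 + wt^2))$directionality
}

# Synthetic circular-motion track: radius rho, angular rate w, sampled at
# frame_dt for n_frames.
circle_track <- function(rho = 10, w = 0.5, frame_dt = 0.2, n_frames = 151) {
  tt <- (seq_len(n_frames) - 1) * frame_dt
  cell_track(tt, rho * cos(w * tt), rho * sin(w * tt))
}

shape_fixture <- function(which = c("trypomastigote", "epimastigote",
                                    "promastigote")) {
  which <- match.arg(which)
  read_shape_model(system.file(
    "extdata", paste0("synthetic_shape_", which, ".json"),
    package = "chiroswim"))
}
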