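# chiroswim

Chiral swimming-path simulation and motility analysis for
trypanosomatids.

Swimming microorganisms usually follow helical paths: chiral asymmetry
in cell shape or propulsion bends the path and makes the cell rotate
about its long axis. chiroswim is an R toolkit for analysing how that
chirality confers highly directional, noise-tolerant swimming at low
Reynolds number, built around the trypanosomatid parasites
*Trypanosoma brucei* (strongly chiral trypomastigote) and *Leishmania
mexicana* (near-symmetric promastigote). It is aimed at people studying
microswimmer motility who want a tested, fully synthetic-data-driven
reimplementation of this analysis chain:

* **Helical path geometry** — a constant-behaviour swimmer follows a
  helix of radius `r = kappa / (kappa^2 + tau^2)` and pitch
  `h = 2 pi tau / (kappa^2 + tau^2)`; its directionality (displacement
  per distance swum) tends to `tau / sqrt(kappa^2 + tau^2)`. Body-frame
  rotation rates map to path shape by `kappa = omega_kappa / s`,
  `tau = omega_tau / s`.
* **Brownian dynamics** — anisotropic Stokes–Einstein /
  Stokes–Einstein–Debye diffusion of a prolate spheroid (r_d = 1.5 um,
  r_np = 8 um) with Perrin friction factors.
* **Swimmer simulation** — 0.2 s time steps; deterministic
  chirality-driven frame rotation plus Brownian translation/rotation;
  population sweeps under three biological-noise models.
* **Synthetic dark-field videomicrographs** — 5 Hz, 512-frame 16-bit
  TIFF stacks of point-like swimmers with plateau-then-exponential
  depth detectability.
* **Tracking** — minimum-projection background subtraction, blur +
  local-maximum detection, motion-predicted nearest-neighbour linking,
  duration-weighted speed/persistence statistics and persistence
  autocorrelation.
* **Cell-shape model** — rotation + planar flagellar beat evaluated at
  8 control points, kymograph fitting (spectral frequency
  pre-estimation + Levenberg–Marquardt), and reconstruction of the
  effective hydrodynamic shape by zeroing beat amplitude.
* **Slender-body torque** — Gray–Hancock resistive-force calculation of
  the axial torque a chiral shape extracts from axial flow.

## Worked example

Simulate the three morphologies at their measured longitudinal rotation
rates (trypomastigote 11.0 ± 3.0 rad/s, epimastigote-like 2.5 ± 0.7
rad/s, promastigote 0.15 rad/s; all at 5 ± 2 um/s with path-curvature
rotation 0.6 ± 0.2 rad/s), render them into synthetic dark-field
movies, and run the same tracking pipeline used for real
videomicrographs:

```r
library(chiroswim)

for (nm in c("trypomastigote", "epimastigote", "promastigote")) {
  res <- run_experiment(experiment_config(nm, n_cells = 100, seed = 1))
  cat(sprintf("%-15s tracks %4d  persistence %.3f  frac>0.9 %.3f\n",
              nm, res$summary$n_tracks, res$summary$mean_persistence,
              res$summary$persistence_fraction[["gt_0.9"]]))
}
#> trypomastigote  tracks  423  persistence 0.944  frac>0.9 0.880
#> epimastigote    tracks  412  persistence 0.909  frac>0.9 0.794
#> promastigote    tracks  332  persistence 0.279  frac>0.9 0.013
```

Directional persistence (mean cosine of the direction change over a 2 s
evaluation step, duration-weighted) rank-orders exactly with
longitudinal rotation rate: the rapidly rotating trypomastigote swims
near-straight, the non-rotating promastigote follows wide curved paths.
The geometry alone predicts the same ordering:

```r
ct <- kinematics_to_path(path_kinematics(5, 0.6, 11))   # trypomastigote
directionality_limit(ct$kappa, ct$tau)
#> [1] 0.9985157
```

And the torque that drives the rotation follows the chirality of the
effective hydrodynamic shape (synthetic shape tables shipped in
`inst/extdata/`):

```r
sh <- read_shape_model(system.file("extdata",
  "synthetic_shape_trypomastigote.json", package = "chiroswim"))
axial_torque(effective_shape(sh), flow_spec(U = 1))$total  # pN um
#> [1] 0.003644585
```

A planar (achiral) shape gives exactly zero axial torque, and a mirror
image exactly negates it.

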