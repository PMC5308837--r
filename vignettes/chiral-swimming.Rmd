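---
title: "Chiral cell shape and directional swimming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral cell shape and directional swimming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiroswim)
```

## The scientific problem

Swimming cells at low Reynolds number typically follow helical paths:
chiral asymmetry in shape or propulsion bends what would otherwise be a
straight trajectory. Trypanosomatid parasites make a natural model system
for the question this package addresses — *why* asymmetric, chiral shapes
are so common when a perfectly symmetric shape would also swim straight.
The trypomastigote form (long lateral flagellum attachment) is strongly
chiral and rotates rapidly about its long axis while swimming; the
promastigote form is nearly axially symmetric and does not rotate; an
engineered epimastigote-like morphology (shortened flagellum attachment
zone) sits in between. chiroswim implements the complete computational
chain relating shape chirality to swimming directionality, exercisable
entirely on synthetic data.

## Helical path geometry

A cell with unchanging swimming behaviour follows a path of constant
curvature $\kappa$ and torsion $\tau$: a helix of radius
$r = \kappa/(\kappa^2+\tau^2)$ and pitch $h = 2\pi\tau/(\kappa^2+\tau^2)$.
At constant speed $s$ the body frame rotates at $\omega_\kappa = s\kappa$
about the binormal and $\omega_\tau = s\tau$ about the travel direction
(the Darboux description); $\omega_\tau$ is the longitudinal rotation one
sees in swimming trypomastigotes. Directionality — displacement per
distance swum — tends to $\tau/\sqrt{\kappa^2+\tau^2}$ over many turns:
it falls with curvature and rises with torsion, which is the geometric
heart of "spin stabilisation". The degenerate straight line
($\kappa=\tau=0$) is carried as an explicit flagged descriptor rather than
infinite radius, so nothing downstream divides by zero. Handedness
convention: $\tau > 0$ is a right-handed helix; directionality is
insensitive to the sign.

```{r helix}
kinematics_to_path(path_kinematics(speed = 5, omega_kappa = 0.6,
                                   omega_tau = 11))
directionality_limit(0.12, 2.2)
```

## The swimmer simulator

Each time step (default $\delta t$ = 0.2 s, matching the 5 Hz camera
clock) translates the cell by $s\,\delta t$ along its long axis, applies
the deterministic chirality-driven frame rotation, adds Brownian
translation and rotation, and re-orthonormalises the frame.

**Rotation composition.** The two deterministic rotations
($\omega_\kappa$ about the binormal, $\omega_\tau$ about the travel
direction) are applied by default as a *single* rotation about the
combined per-step rotation vector $\omega_\kappa \mathbf{b} +
\omega_\tau \mathbf{t}$ — the exact solution for a constant body-frame
rotation rate, so a noise-free discrete path samples the continuous helix
at the step times. Composing the two rotations sequentially instead
(available as `rotation_mode = "sequential"`) introduces an
$O(\delta t^2)$ axis-splitting bias per step that accumulates to several
percent of directionality at $\omega \sim 5$ rad/s and $\delta t = 0.2$ s;
we made the combined rotation the default so that discrete and analytic
geometry agree to better than $10^{-3}$ at the production step size.
Brownian rotations are small ($\ll$ 1 rad per step) and are applied
sequentially about the instantaneous body axes in the fixed order t, n, b.

**Brownian coefficients.** The cell is a prolate spheroid with effective
radii $r_d$ = 1.5 um (along the long axis) and $r_{np}$ = 8.0 um
(perpendicular). Translational coefficients follow Stokes–Einstein,
$D_i = kT/6\pi r_i \mu$; rotational diffusion starts from the
equal-volume sphere ($E = kT/8\pi\mu a^3$, $a = (r_d^2 r_{np})^{1/3}$)
and is adjusted per axis by the Perrin friction factors. We divide by the
friction factor ($E_i = E/f_i$): friction factors are ratios of friction
relative to the equal-volume sphere, and more friction means slower
diffusion. Multiplying instead is physically non-standard but switchable
(`perrin_mode = "multiply"`) because the convention affects rotational
noise by up to ~7x about specific axes. Per-step standard deviations are
$\sqrt{2D_i\delta t}$ and $\sqrt{2E_i\delta t}$. The closed-form Perrin
factors are continued analytically to oblate ratios ($e < 1$,
artanh $\to$ arctan) so the sphere limit is continuous; both branches are
verified against numerical quadrature of the classical ellipsoid drag
integrals. Temperature defaults to 299.15 K (26 degC ambient imaging
temperature); viscosity is not a measured quantity here and defaults to
8.7e-4 Pa s (water at 26 degC), configurable everywhere it enters.

**Populations and reproducibility.** Each cell draws speed and rotation
rates once from normal distributions (speeds are redrawn until positive,
since a normal 5 +/- 2 um/s otherwise produces occasional negative
speeds); curvature noise can be fixed, drawn per cell (morphogenetic
noise), or re-randomised every 200 ms (propulsion noise). Every cell gets
its own RNG stream derived from (seed, cell index), so populations are
reproducible and independent of execution order.

One caveat worth stating: when the re-randomisation interval equals the
integration step, per-step curvature noise is white, and torsion can give
only a small directional benefit — there is no persistent bend for the
longitudinal rotation to wind around the path axis. The benefit of
torsion against propulsion noise grows with the noise correlation time,
which is why `rerandomize_interval` is exposed as a parameter.

## Synthetic videomicrographs and tracking

The renderer emulates 5 Hz, 512-frame low-magnification dark-field
acquisitions (0.65 um/px): cells are point-like Gaussian spots whose
amplitude is constant within 10 um of the focal plane and decays
exponentially beyond it (decay length 5 um by default), emulating the
empirically observed plateau-then-exponential detectability of defocused
cells; spot width grows linearly with defocus. This is a detectability
model, not a physical dark-field scattering computation, and the cells
are rendered without body shape — appropriate at 10x magnification.
Stacks round-trip through multi-page 16-bit TIFF with pixel size and
frame rate in the description tag.

Tracking mirrors a classical ImageJ-macro pipeline: minimum-projection
background subtraction, a 2 px Gaussian blur (ImageJ sigma convention),
local-maximum detection, and motion-predicted nearest-neighbour linking
within 15 px with no gap closing. The detection threshold (not a measured
quantity) defaults to five robust standard deviations of the blurred
image, floored at a tiny fraction of the image maximum so float-level
blur ripples never register on noise-free synthetic frames. Plateaus of
tied maxima (two merged spots) count once, ties resolved toward the
earliest pixel in scan order; assignment conflicts in linking are
resolved greedily by ascending predicted distance with coordinate
tie-breaks, so results do not depend on detection order.

Statistics treat tracks as a biased random walk: velocities over a 2 s
evaluation window (overlapping, one per frame), mean speed
$\bar{|v_t|}$, and directional persistence — the mean cosine of the
direction change between windows ($1$ straight, $0$ uncorrelated, $-1$
oscillating). The 2 s window is motivated by the persistence
autocorrelation curve (computed with a 0.5 s base window over lags
0–10 s), which decays sharply over beat/rotation time scales before
settling. All population summaries are weighted by track duration to
avoid bias toward behaviours that fragment tracks.

## The analytical cell-movement model

Viewed at position $z$ along the cell, lateral displacement is the sum of
a rotating underlying shape and a planar flagellar beat:

$$x_r = A_r(z)\sin(p_r(z)+\omega_r t),\qquad
  b = A_b(z)\sin(p_b(z)+\omega_b t)$$
$$x_c = x_r + b\,\sin(p_r(z)+p_o(z)+\omega_r t)$$

with $y_c$ the cosine counterpart. Parameters live at 8 control points
along $z$ (increasing from the flagellum-tip end) and are linearly
interpolated. The model is a numerical description of shape change, not
physically consistent kinematics (cell length is not conserved over a
beat cycle). Because phases are defined modulo $2\pi$, fitted phases are
unwrapped to a continuous branch (adjacent control points within $\pi$)
so interpolation is meaningful.

Fitting automates the original fit-by-eye workflow. Frequencies are
pre-estimated from the traces' periodogram (the beat term is a product of
sinusoids, so its energy sits at $f_b \pm f_r$; both peaks are located on
a fine grid around the initial guess), then all parameters are refined by
bounded Levenberg–Marquardt least squares. This tolerates initial
frequency errors of tens of percent, where a purely local fit would
stall once phase drift across a trace exceeds half a cycle. A
non-rotating cell leaves $A_r$ and $p_r$ structurally unidentifiable;
the fit flags this instead of guessing.

Setting $A_b(z) \equiv 0$ leaves the *effective hydrodynamic shape*: the
3-D centreline the fluid effectively sees, with radii from the width
profile $w(z)/2$. The width profile is piecewise linear; the shipped
shape tables are synthetic (their filenames say so) because the original
hand-fitted tables derive from undeposited videos — they use the
measured rotation rates (11.0, 2.5 and ~0 rad/s) and realistic
amplitude/phase profiles: a helical trypomastigote-like shape ($p_r$
linear in $z$), an epimastigote-like shape twisted only near the
anterior, and a planar promastigote-like shape ($p_r$ constant).

## Slender-body torque

Hydrodynamic drag on a thin cylinder is anisotropic
($C_\perp > C_\parallel$), so a segment tilted at angle $\theta$ to an
axial flow $U$ feels a lateral force per unit length
$(C_\perp - C_\parallel)U\sin\theta\cos\theta$. Crossed with each
segment's radial offset from the rotation axis and summed over the 7
segments of the effective shape, this gives the axial torque a chiral
shape extracts from forward motion. Gray–Hancock coefficients
($C_\parallel = 2\pi\mu/(\ln(2q/r)-\tfrac12)$,
$C_\perp = 4\pi\mu/(\ln(2q/r)+\tfrac12)$) are the default, with the
Lighthill constants switchable; the choice scales absolute torque but
not sign or rank order, so conclusions rest on exact antisymmetries
(planar shapes give zero; mirror images negate) and rank ordering across
morphologies. The slenderness scale $q$ defaults to each segment's
length; it can be fixed so torque is comparable across discretisations
of the same curve (an 8-point helix agrees with a 1000-point
discretisation within 15% under a fixed scale). Torque is exactly linear
in $U$ and $\mu$; results are reported in pN um for a 1 um/s flow.

## Problem sizes and numerical choices

The package's experiments default to scaled-down sizes chosen to keep a
complete run interactive while leaving all statistical conclusions
clear: 25 cells per grid point for directionality sweeps and 100 cells
per morphology for the rendered populations (versus 10,000-cell
full-scale runs, reachable via `n_cells`). A 6x6 noise-free sweep
agrees with the analytic helix to ~2e-4 absolute, so grid resolution,
not integrator error, limits these maps. Populations in rendered
experiments use a 333 x 281 x 100 um periodic volume imaged at
512 x 432 px — a 1/100-area crop of the full-scale acquisition volume
with identical depth, pixel size and frame rate, preserving densities
per field.

Other numerical choices: frames are Gram–Schmidt re-orthonormalised
every step (drift stays at rounding level over 10^5+ steps); Brownian
draws are pre-generated per cell; intensities clip to the 16-bit range;
and tracks shorter than 5 s are excluded from statistics, as in the
original pipeline.

## What the synthetic data do and do not show

The generator reproduces the features the tracking pipeline is sensitive
to — point-like cells, depth-limited detectability, frame-rate
subsampling, crossing tracks — and the simulator reproduces the
geometry- and noise-driven behaviour of swimming paths. It does not
emulate flagellar waveform imagery, cell-cell interactions, surface
entrainment, beat reversals (tumbling), or real dark-field
backgrounds. Passing tests therefore demonstrate the internal
consistency of the geometry, simulation, rendering and analysis chain
under the stated model, not performance on real videomicrographs with
debris, intensity drift, or dense fields.
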