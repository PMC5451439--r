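---
title: "Modelling murine glioma growth: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling murine glioma growth: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `gliomafit`, the numerical
schemes behind them, and the design decisions taken where more than one
defensible choice existed. It states no empirical result that the package's
tests and `scripts/acceptance.R` do not themselves compute.

## The growth model

Tumor cell density `u(t, x)`, expressed as a fraction of a carrying capacity
normalised to 1, follows the Fisher–KPP reaction–diffusion equation

    du/dt = div(D grad u) + rho * u * (1 - u)

on the brain domain `Omega` (imaged brain tissue with the ventricles segmented
out), with no-flux conditions on all domain boundaries: tumor cells penetrate
neither the skull nor the ventricular space. `D` (um^2/h) controls invasion,
`rho` (1/h) logistic proliferation. Two consequences of the model organise the
whole analysis:

* localized initial data develop a traveling front whose asymptotic speed is
  `c = 2 * sqrt(D * rho)`;
* binary "visible tumor" masks — voxels where `u` is at or above the detection
  threshold 0.16 — depend on the dynamics almost entirely through the position
  of that front, which is why `D` and `rho` are individually poorly
  identified while `c` is well identified.

Imaging sessions happen at days 11, 15, 18, 22, 25 post-implantation; day `d`
maps to `t = 24 d` hours everywhere. Simulations start from the first scan:
visible-tumor voxels are painted with density `u0 = 0.5` and everything else
with zero. All lengths are millimetres internally; `D` is accepted in um^2/h at
every public interface and converted once (`um2h_to_mm2h`, 1e-6).

## 3D forward solver

Space is discretised on the imaging grid (0.1 x 0.1 x 0.5 mm voxels) with
flux-form centred differences: the Laplacian is assembled from face fluxes
`D (u_j - u_i) / h^2`, and faces adjoining non-domain voxels carry zero flux.
This form implements the no-flux condition exactly (equivalent to ghost-voxel
reflection) and makes the discrete divergence conservative to round-off, which
gives the sharp mass-conservation test used in the suite (`rho = 0`, drift
below 1e-6 relative over 336 h).

Time integration uses an adaptive embedded Dormand–Prince 4(5) pair with PI
step control, implemented in compiled code for throughput on ~5e4-voxel
domains (a full day-11-to-25 run takes well under a second). Defaults:
relative tolerance 1e-6, absolute tolerance 1e-9. Two deliberate choices:

* **Output times are hit by clipping the adaptive step** rather than by dense
  output interpolation; for an adaptive method the two are equivalent in
  accuracy and clipping is simpler to reason about.
* **The solution is never clamped.** Densities outside `[0, 1]` beyond the
  `clamp_check` tolerance (1e-6) abort the run: bound violations signal
  instability and are detected, not silently repaired. The package's own
  tests surfaced the one regime where this matters — multi-thousand-hour
  front-speed channels, where integration noise near the `u = 1` equilibrium
  decays only at rate `rho` — and `measure_front_speed` therefore defaults to
  tighter tolerances (1e-8/1e-11) than the 14-day volumetric runs.

An independent cross-check integrates the same right-hand side with
`deSolve::ode` (`rk45dp7`); the two solutions agree to integrator tolerance on
a randomly masked domain.

Thresholding to visible tumor uses an inclusive comparison (`u >= 0.16`): the
source description uses both "greater than" and "at and above", and the
package standardises on inclusive, fixed by a unit test.

### Front-speed measurement

`measure_front_speed` builds a quasi-1D channel (n x 1 x 1, no-flux ends),
seeds one end, and regresses the interpolated threshold-crossing position on
time over the second half of a 3000-hour record. The long window matters: the
front approaches its asymptotic speed with a relative deficit of roughly
`3/(4 rho t)`, so short records bias the slope low. Because that deficit is
independent of `D`, the `D -> 4D` doubling check uses the same window for both
runs. The pure-diffusion control (`rho = 0`) instead seeds a mass whose
channel-average sits below the detection threshold and measures across the
late window where the contour position has flattened; the measured slope is an
order of magnitude below any fitted wave speed.

## Jaccard fitting and the three hypotheses

Fit quality is the Jaccard distance `d_J(A, B) = 1 - |A n B| / |A u B|`
between simulated and observed visible-tumor masks. Two empty masks are
defined to match perfectly (`d_J = 0`; the formula is 0/0 there); one empty
mask against a nonempty one gives 1. Aggregation conventions follow the
printed usage: the constant-parameter fit reports the time average over the
`n` follow-up scans, per-interval fits report per-interval values and their
sum, and both modes are always stored. The hypothesis-comparison percentages
divide per-interval sums by the constant-fit (mean-mode) error — the only
convention that reproduces the published comparison arithmetic; the package
keeps that convention and records it here rather than "fixing" it.

* **Hypothesis 1** – one `(D, rho)` for the whole series.
* **Hypothesis 2** – one pair per inter-scan interval; the *continuous*
  simulated density at each interval end is carried into the next interval.
  (Whether the original analysis carried the continuous or the thresholded
  state is not stated; continuous is the choice here, since thresholding
  would discard interior structure the model itself produced.)
* **Hypothesis 3** – as Hypothesis 2, but the state is rebuilt from each
  *observed* mask (density `u0` inside, the same convention as day 11) before
  fitting the next interval; per-interval errors are those of the predictions
  made *before* each reset. A "carry" variant that keeps simulated densities
  inside the observed mask is available behind `h3_reset_mode`.

Minimisation is Nelder–Mead over `(log D, log rho)` — the log transform
guarantees every evaluated point is positive — via `stats::optim`, matching
the derivative-free simplex family used originally. `optim` does not expose
simplex initialisation, so the ±20% perturbation initialisation that a
hand-rolled simplex would use is not replicated; convergence tolerances
(relative 1e-3, max 300 iterations) are config fields. Failed forward solves
return a large finite penalty (10 n) so the simplex can retreat rather than
abort. The optimizer result is compared against the initial guess and the
better of the two returned (best-so-far contract).

On a noiseless phantom the objective is *exactly* zero at the true
parameters, because the phantom's masks and the fit's forward runs share one
code path; this end-to-end oracle anchors the fitting tests. One caveat
discovered during development and kept visible in the tests: single-interval
Jaccard objectives are piecewise constant in the parameters (masks are
discrete), so per-interval fits can stall on small plateaus; properties that
compare hypotheses are therefore asserted on noisy phantoms, where all
baselines are well away from zero.

## Identifiability analysis

`compute_error_surface` evaluates the Hypothesis-1 objective on a log-spaced
`(D, rho)` grid; `valley_flatness` samples the surface along the constant-speed
arc `rho(D) = c^2 / (4 D)` and compares the spread of `E` along the arc with
the spread over the whole grid, flagging practical nonidentifiability when the
ratio falls below 0.25 (a package convention, config-exposed; the source makes
only a qualitative claim).

Two surface-grid layouts are used, and the choice deserves explanation. On a
*noiseless* phantom the error at the truth is exactly zero, so relative
variation along the arc cannot be small unless the grid provides across-valley
dynamic range: the display grid therefore spans a moderate `D` interval
(x/1.3) against a wide `rho` interval (x/4). On a symmetric narrow grid
(both x/1.3) the `E <= 0.05` sublevel set is the object of interest: it forms
a connected band elongated along a negative log–log slope. That slope is
slightly shallower than the asymptotic constant-`c` slope of -1 because over a
finite 14-day window the front-formation transient also shifts with `D`: at
fixed `c`, larger `D` means a wider front that takes longer to form, so the
14-day displacement is not exactly constant along the arc. The grid exact
ranges of the original surface plots are not printed anywhere; the defaults
(50–2000 um^2/h, 0.005–0.06 1/h) bracket the fitted range.

## 2D moving-boundary (Stefan) solver

The 2D reformulation treats the visible tumor as a region `Omega1` with a
sharp interface: inside, the same reaction–diffusion law holds with Dirichlet
`u = ubar = 0.16` on the boundary; the interface moves with the Darcy/Stefan
normal velocity `v . n = -(D/ubar) grad(u) . n` (pressure `p = ln u`, mobility
taken equal to `D` so no new parameter enters). The host geometry can be
swapped on days 15/18/22/25 to emulate mass-effect displacement of the
ventricles, and the tumor region is hard-clipped against the ventricles after
every step.

The solution-method details were published separately and are not available
here, so the scheme is the package's own, assembled from standard components
for Stefan-type level-set problems, each isolated behind an interface:

* `phi` is a signed distance function (negative inside), advected with the
  normal speed by first-order Godunov upwinding under a CFL bound
  `dt <= 0.5 min(h)/max|v|` and an additional 6 h cap so the velocity-density
  coupling stays tight when the front is slow.
* **Reinitialisation** (every 5 advection steps) recomputes the exact
  distance to the marching-squares zero contour — but preserves `phi` values
  within 1.5 pixels of the interface. Full reinitialisation against a
  polygonal contour systematically erodes convex interfaces (the polygon cuts
  circle arcs by the chord sagitta, about `h^2/(8R)` per pass); keeping the
  near band pins the interface exactly, and a stationary-interface test holds
  area drift below 0.5%.
* **The interior update** imposes the Dirichlet value at the *sub-cell*
  interface position using cut-cell (Gibou–Fedkiw) second differences, with
  the crossing fraction clamped at 0.35 (closer cells are pinned to `ubar`)
  and the explicit substep reduced accordingly. An earlier one-pixel ghost
  band version displaced the effective interface by O(h) and inflated
  14-day growth by 5–15% at the largest fitted `D`; the cut-cell form brings
  the solver within 1% of the reference solution below.
* **The interface velocity** is evaluated per pixel at its own interface foot
  point `x - phi n`: the normal derivative comes from a one-sided quadratic
  through `u = ubar` at the foot point and two interior probes spaced 1.5
  pixels along the inward normal. Because every pixel queries its own foot
  point, the field is constant along normals by construction — the extension
  velocity comes for free. For axis-wise diffusivity the velocity uses
  `(Dx nx^2 + Dy ny^2) du/dn`, exact when `u` varies only normally, which the
  Dirichlet interface enforces locally.
* Pixels entering `Omega1` as the front passes start from `ubar`, maintained
  on a one-pixel exterior ring.

Verification is against an *independent* 1D radial reference solver
(front-fixing coordinate `xi = r/R(t)`, fine radial grid, explicit Euler,
written separately in the test helpers): interface radii agree within 2% over
14 days for parameter magnitudes spanning the fitted 2D range, and a
prescribed-speed disk grows linearly in time within 3%.

Fitting in 2D minimises `E2 = z_d + 10 * sum_t d_J,t`, where `z_d` sums, over
days 15–25, the RMS of exact point-to-segment distances from each simulated
boundary vertex to the observed boundary polygon. The measure is
one-directional (simulated vertices against the data polygon), exactly as
defined; the factor 10 puts the two terms on comparable scales. On a noiseless
2D phantom whose boundaries come from the same forward code, `E2` at the truth
is exactly zero.

The anisotropic random diffusivity field draws each pixel's value uniformly
from half-plane-specific intervals scaled by `eta = 11120 um^2/h`. The
original description mixes "horizontal direction" and "vertical direction"
halves ambiguously; both readings are implemented behind a `mode` flag —
axis-wise (`Dx` from the left/right intervals, `Dy` from the top/bottom
intervals) and scalar-by-quadrant (interval bounds averaged) — with neither
asserted as the intended one.

## The phantom generator

The synthetic-data module emulates the *registered, segmented* output of the
imaging pipeline, not the physics of MR acquisition: an ellipsoidal
mouse-scale brain with two ellipsoidal ventricle cavities rasterised on the
0.1 x 0.1 x 0.5 mm grid, a spherical day-11 seed, forward-model-generated
visible-tumor masks at the five imaging days, optional nearest-voxel
ventricle drift, and 2D transverse/sagittal/coronal sections. Defaults were
chosen once to match the study conditions: seed volume ~0.7 mm^3 (the
observed day-11 range is ~0.6–1.0 mm^3), true parameters at the constant-fit
estimate for the first mouse (D = 413.77 um^2/h, rho = 0.0188 1/h), detection
threshold 0.16, initial density 0.5. The default 56 x 56 x 18 grid was sized
so the day-25 tumor (which reaches ~26 mm^3, inside the observed 12–62 mm^3
range) fits the brain ellipsoid. Segmentation noise, when enabled, flips
voxels independently within the one-voxel boundary shell of each mask —
emulating rater uncertainty at the tumor rim without destroying topology; the
default is noiseless, and all randomness is reproducible from the spec seed.

What the phantom does *not* emulate — real anatomy, partial-volume effects,
intensity-based segmentation error away from the rim, registration error, and
genuinely unknown biology (density-dependent motility, phenotype switching) —
bounds what passing tests show: they demonstrate that the pipeline recovers
what it is built to recover under the model's own assumptions, not that the
model describes any particular animal.

## Problem sizes and runtime choices

The shipped analyses and tests use: the 56 x 56 x 18 default phantom
(~19k domain voxels) for fits, surfaces, and sensitivity; a ten-phantom
recovery suite spanning D in [100, 1500] um^2/h and rho in [0.005, 0.05] 1/h
(fixed pairing, median wave-speed recovery reported); 15 x 15 error surfaces;
81 x 81 and 121 x 121 planar grids for the 2D solver; and a coarser
36 x 36 x 12 phantom inside fast unit tests. These sizes were chosen so each
analysis completes in seconds to a couple of minutes on one core while keeping
the day-11 front ~5 voxels across in-plane, comfortably resolving it.

## Known limitations

* The 3D model is isotropic and spatially uniform in `D` by design; only the
  2D solver supports spatially varying or axis-wise diffusivity.
* Discrete masks make single-interval objectives piecewise constant, so
  per-interval estimates inherit plateau ambiguity on top of the physical
  `D`–`rho` nonidentifiability; wave speed is the robust summary.
* The slow-growth corner of the parameter range (wave speeds below ~2.5
  um/h) moves the visible front by only a few voxels between scans and is
  effectively uninformative at imaging resolution — visible in the recovery
  suite as large individual errors at a small median.
* The level-set scheme is first-order in the interface position; the 2%
  radial-oracle agreement is adequate for the fitting application but not a
  high-order benchmark.
* No confidence intervals are produced: the binary observable admits no
  per-voxel error model, which is precisely the practical-nonidentifiability
  finding the identifiability module operationalises.
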