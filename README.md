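# gliomafit

Reaction–diffusion modelling and parameter estimation for murine glioma
growth from segmented MR imaging.

Glioblastoma xenografts in mice are imaged by T2-weighted MRI at days 11, 15,
18, 22 and 25 after implantation; each scan yields a binary "visible tumor"
mask on a 0.1 × 0.1 × 0.5 mm grid, together with brain and ventricle masks.
This package implements the full analysis chain for asking how well the
Fisher–KPP reaction–diffusion model

u_t = ∇·(D∇u) + ρ u(1 − u),  ∂u/∂n = 0 on ∂Ω

explains such series, where `u` is tumor cell density as a fraction of
carrying capacity, `D` (µm²/h) is the diffusion (invasion) coefficient, `ρ`
(1/h) the proliferation rate, and Ω the brain domain with the ventricles
excluded. Densities at or above `ū = 0.16` are "visible tumor". The model's
front advances at the traveling-wave speed `c = 2√(Dρ)`.

The package provides, as testable components behind one R API:

* a **3D forward solver** (flux-form finite differences, adaptive
  Dormand–Prince 4(5) in compiled code) and mask thresholding;
* **Jaccard-distance parameter estimation** of θ = (D, ρ) under three
  hypotheses — constant parameters, per-interval parameters, and
  per-interval parameters with initial-condition resets from each scan —
  plus an initial-density sensitivity analysis;
* **identifiability surfaces** E(D, ρ) with the constant-wave-speed arc
  ρ(D) = c²/4D and a flatness statistic for the nonidentifiability valley;
* a **2D moving-boundary (Stefan) solver** — level-set front tracking with
  Darcy-law interface velocity v·n = −(D/ū)∇u·n, cut-cell Dirichlet
  interior updates, time-updated host geometry, anisotropic random
  diffusivity fields, and fitting via E₂ = z_d + 10·Σ d_J;
* a **phantom generator** that emulates registered, segmented mask series
  (ellipsoidal brain and ventricles, spherical day-11 seed, forward-model
  ground truth, optional boundary noise and ventricle drift), so every
  stage is testable without imaging data;
* NIfTI/YAML/CSV/JSON I/O and reporting tables, including the bundled
  published parameter estimates for the three study mice
  (`reference_table()`).

## Worked example

Generate the default phantom (a mouse-scale brain with a ~0.7 mm³ day-11
seed grown at D = 413.77 µm²/h, ρ = 0.0188 1/h), fit the constant-parameter
hypothesis, and inspect the implied front speed:

```r
library(gliomafit)

spec <- phantom_spec()
gt <- simulate_ground_truth(spec)
gt$series
#> imaging_series:
#>   day 11:     152 voxels,    0.760 mm^3
#>   day 15:     424 voxels,    2.120 mm^3
#>   day 18:    1072 voxels,    5.360 mm^3
#>   day 22:    2852 voxels,   14.260 mm^3
#>   day 25:    5288 voxels,   26.440 mm^3

fit <- fit_hypothesis1(gt$series, fit_config())
fit
#> fit_result (Hypothesis 1), converged
#>   days 11-25: D =   416.44 um^2/h, rho =  0.0187 1/h, c = 5.5873 um/h
#>   error: mean 0.0000 / sum 0.0000 over n = 4
```

The fitted D and ρ need not individually match the truth — many pairs along
the arc ρ(D) = c²/4D fit almost equally well — but the wave speed does:
5.5873 vs 2√(413.77·0.0188) = 5.5781 µm/h, 0.16% off, and `umh_to_cmyr(5.5873)`
≈ 4.89 cm/yr. The same nonidentifiability is quantified by
`compute_error_surface()` + `valley_flatness()`, which on this phantom flags
the valley (flatness ratio ≈ 0.22, below the 0.25 threshold).

Derived tables from the bundled mouse estimates:

```r
rep <- build_report(reference_table("fits3d"))
cmp <- hypothesis_comparison(rep)
attr(cmp, "summary")
#>   hypothesis  mean_pct  min_pct   max_pct
#> 1          2  4.016782  2.152906  6.382511
#> 2          3 20.276301 14.048521 27.980583
```

i.e. per-interval refits improve the Jaccard error by ~4% on average over a
constant fit, and per-interval refits with initial-condition resets by ~20%.

The scripts under `analysis/` run the whole study in order: phantom
generation (`01`), hypothesis fits and u₀ sensitivity (`02`), the
identifiability surface (`03`), the 2D Stefan analyses (`04`) and the
reference-table report (`05`), each writing its tables under `results/`.

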