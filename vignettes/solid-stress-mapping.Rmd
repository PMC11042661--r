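---
title: "Mapping residual solid stress in tissue slices and fitting its viscoelastic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping residual solid stress in tissue slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicestress)
```

## The measurement this package models

Soft tissues store mechanical stress in their solid phase even when no
external load is applied. Cutting a thin slice (here: 250 µm vibratome
sections) releases the confinement, and the stored stress relaxes by
deforming the slice: a stressed slice bows and wrinkles, an unstressed
one stays flat. Imaging the relaxed slice in 3D (a single-channel
confocal z-stack of a fluorescent tissue sheet) and reconstructing its
surface turns that deformation into quantitative indices of residual
solid stress.

`slicestress` implements the full post-acquisition analysis:

1. **Surface reconstruction** — from a 3D stack to a height field
   $z(x,y)$ over the tissue footprint (`segment_tissue()`,
   `extract_height_field()`).
2. **Stress indices** — three scalars plus per-pixel maps
   (`stress_indices()` and friends).
3. **Compression rheology** — Young's modulus, the
   instantaneous/equilibrium modulus ratio and bi-exponential
   stress-relaxation constants from step-hold unconfined compression
   (`analyze_trace()`).
4. **Statistics** — group comparisons and anterior–posterior trend
   tests with mean ± SEM reporting (`compare_two_groups()`,
   `compare_many_groups()`, `spatial_trend()`, `build_report()`).
5. **Synthetic data** — image stacks of analytically known surfaces
   and force traces with known mechanical parameters
   (`make_height_field()`, `render_stack()`, `simulate_trace()`), so
   that every stage of the pipeline can be validated against ground
   truth without access to raw microscopy data.

## The three stress indices

For a height field $z_k$ sampled at $N$ masked pixels with mean height
$\bar z$:

* **Normalized deformation** $D_n = \frac{1}{N}\sum_k |z_k - \bar z|$
  (µm): the mean absolute deviation of the surface from its mean
  plane. Zero for a flat slice; grows with bowing amplitude.
* **Area ratio** $R_a = A_s / A_p$: the true surface area
  $A_s = \int \sqrt{1 + z_x^2 + z_y^2}\,dA$ over the projected area
  $A_p$. Always ≥ 1, with equality only for a constant-height slice.
* **Mean-curvature index**
  $K_m = \frac{1}{N}\sum_k \left|\tfrac12\left(\tfrac{1}{r_{k1}} +
  \tfrac{1}{r_{k2}}\right)\right|$ (µm⁻¹, reported in mm⁻¹): the
  average absolute Monge-patch mean curvature, with $r_{k1}, r_{k2}$
  the principal curvature radii. Computed in closed form from the
  partial derivatives of $z$:
  $H = \frac{(1+z_y^2)z_{xx} - 2 z_x z_y z_{xy} + (1+z_x^2)z_{yy}}
  {2\,(1+z_x^2+z_y^2)^{3/2}}$.

The absolute values follow the index definitions; signed curvature and
deformation maps are also emitted for inspection. Because $D_n$ and
$K_m$ are even functions of $z - \bar z$, all three indices are exactly
invariant under a physical flip of the slice ($z \to -z$ plus an
in-plane mirror, `flip_height_field()`). This is the in-silico version
of the buoyancy control — re-imaging a flipped slice must give the same
indices — and is enforced by tests to six significant figures.

"Midline" is interpreted as the mean height $\bar z$ (not median or
mid-range), matching the conventional reading of $\bar z$. Whether
"normalized deformation" implies a further normalization beyond the
mean absolute deviation is ambiguous; the package always reports both
the raw indices and dimensionless area-normalized variants
($D_n/\sqrt{A_p}$ and $K_m\sqrt{A_p}$, `normalization_mode = "area"`)
so either convention can be compared across slices of different size.
The area-normalized variants are the default input for the
anterior–posterior trend analysis.

## Surface reconstruction choices

The pipeline assumes the relaxed slice is a **Monge patch**: a
single-valued surface $z(x,y)$. Slices that fold over violate this;
columns with several separated bright runs are counted and reported as
`multi_run_fraction` in the provenance, so folded slices surface as a
diagnostic rather than silently corrupt indices.

* **Threshold**: Otsu's histogram split, applied to the
  maximum-intensity projection for the footprint mask and to the full
  voxel histogram for the bright-run detection. No intensity
  calibration is assumed, and the reconstruction is invariant to
  uniform intensity scaling.
* **Surface definition**: `centroid` (default) places the surface at
  the background-subtracted intensity-weighted centroid of the bright
  run — the mid-surface of the fluorescent sheet. It is symmetric
  under flipping and most robust to noise. `max` and `top` are
  available; `top` sits half a thickness above the mid-surface wherever
  the slice tilts, which biases indices, so it is not the default.
  Background subtraction in the centroid weights matters: the constant
  pedestal under the run carries no surface information and would pull
  the estimate onto the voxel grid.
* **Smoothing**: the height map is smoothed in-plane with a Gaussian
  (`smoothing_scale`, default two in-plane pixels). Before convolution
  the surface is continued past the mask edge by first-order
  (gradient-based) extrapolation. Plain mask-normalized convolution
  sees only the inside of the mask and therefore flattens the edge of
  a curved surface; on a spherical cap this depresses the boundary
  curvature by ~15% and leaks several percent into every index, while
  linear continuation makes the edge bias second-order. Curvature is
  scale-dependent, so $K_m$ values are comparable only within a fixed
  smoothing configuration; the scale used is recorded in the result's
  provenance.
* **Boundary stencils**: gradients use centered differences inside the
  mask and one-sided differences at the boundary; second derivatives
  are centered only, so $K_m$ averages over the mask eroded by one
  pixel and reports the interior pixel count.
* **Failed columns** (no above-threshold voxel) are in-filled from
  neighboring columns and counted; more than 10% failures is an error.

## What the synthetic generator emulates — and what it does not

`make_height_field()` samples analytic shapes (flat, spherical cap,
sinusoid, egg-carton composite, each with optional rigid tilt) on disk
or irregular "blob" outlines (seeded low-order Fourier perturbations of
a disk, emulating real slice outlines). `render_stack()` turns a
height field into a synthetic acquisition: a fluorescent sheet of the
slice thickness centered on the surface, with each voxel receiving an
intensity proportional to its z-overlap with the sheet, plus additive
Gaussian noise. The partial-volume intensities mimic a voxel
integrating fluorescence over its extent and give the sheet sub-voxel
edge localization, as the finite axial PSF does in a real microscope; a
binary render instead quantizes both sheet edges in phase (the slice
thickness is an integer multiple of the z-step) and leaves a
long-wavelength sawtooth in the reconstructed surface that survives
in-plane smoothing and measurably inflates $K_m$.

`oracle_indices()` computes $D_n$, $R_a$, $K_m$ by dense quadrature
directly on the analytic surface, using closed-form partial
derivatives — it never touches rendering or reconstruction, so it is an
independent ground truth for the whole imaging pipeline. The
end-to-end agreement enforced by the tests (2% noiseless, 5% median at
SNR 10) is the package's core validity contract.

Default render settings are 10 µm in-plane and 5 µm axial voxel
spacing with foreground/background 100/10 intensity units; SNR is
defined as (foreground − background)/noise SD. The acquisition
parameters of the original experiments (pixel size, z-step, noise) are
not reported, so these defaults were chosen as plausible confocal
values that exercise the pipeline, not as a calibrated instrument
model. The generator does not simulate an optical PSF in-plane,
agarose autofluorescence, depth-dependent attenuation, or multichannel
imaging; passing tests therefore demonstrate correctness of the
*geometry processing*, not robustness to every real-world imaging
artifact.

## Compression rheology

Specimens are 6 mm diameter, 2 mm thick cylinders compressed in four
consecutive steps of 5% strain (1 s ramp, 3 min hold), with
$\sigma = F / (\pi (d/2)^2)$ and $\varepsilon = \Delta h / h$.
Compression is positive throughout. Per hold, the stress decay is
fitted with the bi-exponential relaxation model
$$\sigma(t) = a_1 e^{-t/\tau_{fast}} + a_2 e^{-t/\tau_{slow}} + b,$$
under non-negativity bounds, with parameters reported so that
$\tau_{fast} < \tau_{slow}$ always. Bi-exponential fits are notoriously
initialization-sensitive, so the fit is multistarted: $b$ starts at
the tail-mean equilibrium, the remaining amplitude is split over
{0.25, 0.5, 0.75}, and time constants start on a log-spaced grid over
[0.01, 1] × hold duration crossed pairwise with
$\tau_{fast} < \tau_{slow}$; the three best starts by initial residual
are refined with Levenberg–Marquardt and the best final residual wins,
ties broken toward the smaller $\tau_{slow}$. Non-convergence is
flagged, never silent. A single-exponential comparison fit with a
BIC-based parsimony score flags holds that carry only one time scale
(the two-exponential fit is then degenerate: a vanishing amplitude or
coincident time constants).

Young's modulus is the slope of the linear fit
$\sigma_{eq} = E\varepsilon + C$ across the per-step equilibrium
stresses — a linear model is adequate below ~20% strain, and
hyperelastic models are out of scope. Two estimator families exist for
the equilibrium and instantaneous stresses:

* **Empirical** (`modulus_ratio()`, `analyze_trace(method =
  "empirical")`): $\sigma_{eq}$ = mean of the final 10% of the hold
  (window configurable), $\sigma_{max}$ = observed peak over ramp and
  hold.
* **Model-based** (default in `analyze_trace()`): $\sigma_{eq}$ = the
  fitted asymptote $b$, and $\sigma_{max}$ = the fitted model
  evaluated at the ramp end. With $\tau_{slow} = 60$ s and 180 s
  holds the slow exponential has only decayed to $e^{-3}$, so the
  tail mean overestimates equilibrium by ~2% (inflating $E$ and
  deflating $R_s$ by the same amount), and the observed peak of a
  noisy trace is max-biased by several percent on early, low-stress
  steps. The model-based estimators remove both biases; steps whose
  relaxation fit fails fall back to the empirical values and are
  flagged in the output.

Each hold is fitted independently — no Boltzmann superposition of the
loading history — mirroring how per-step quantities are conventionally
reported; this is a simplification, and per-step parameters at higher
strains should be read as effective values. Poroelastic or
frequency-domain models are out of scope.

The trace simulator (`simulate_trace()`) generates the same protocol
with configurable true parameters (defaults $E = 5$ kPa, $R_s = 1.8$,
$\tau_{fast} = 2$ s, $\tau_{slow} = 60$ s, equal fast/slow amplitude
split, 10 Hz sampling) plus Gaussian stress noise. The defaults place
the parameters in the physiological range for brain tissue and give
$\tau_{slow}/\tau_{fast} = 30$; identifiability of the two time
constants degrades gracefully as that ratio approaches 1, which is why
recovery tolerances are stated at the default regime. The amplitude
split between the fast and slow exponential is not constrained by any
reported value and defaults to 50/50.

## Statistics

Two-group comparisons use the two-tailed t-test with $n \ge 3$ per
group, Welch's unequal-variance form by default (group variances
routinely differ across age groups); the pooled Student form is
available, and the variant used is recorded. Multi-group comparisons
use one-way ANOVA. No multiple-testing correction is applied by
default — p-values are reported as-is. Anterior–posterior trends are
OLS slopes of (area-normalized) indices against slice position within
the three windows 0–1000, 1000–2250 and 2250–4250 µm, with a two-sided
test of zero slope. Error bars are SEM = SD/√n throughout, and the
unit of analysis (animal vs slice) is whatever the metadata grouping
encodes — it is never inferred. Mixed-effects modeling of
slices-within-animal is out of scope.

## Numerical and testing notes

* All generators are bit-reproducible under their integer seeds and
  restore the caller's RNG state.
* Degenerate inputs are handled explicitly: constant holds fit as
  $a_1 = a_2 = 0$, $b$ = stress level; an all-identical ANOVA input
  reports $F = 0$, $p = 1$ and is flagged; empty masks, non-monotone
  time and missing voxel spacing are rejected with named errors (a
  guessed spacing would silently corrupt every index).
* Readers reject malformed files rather than repairing them; every
  writer's output round-trips through its paired reader. TIFF float
  pages are affinely rescaled to [0, 1] with the transform stored in
  the YAML sidecar, since float TIFF storage is undefined outside that
  range.
* Test problem sizes: validation shapes are 1 mm-scale slices at 10 or
  20 µm grid resolution (≈ 50–110 px across), noise ensembles use
  12–20 seeds, and rheology recovery uses 40–100 simulated traces at
  10 Hz — sizes chosen so the full suite exercises every claim in
  minutes on a laptop while leaving Monte-Carlo margins well away from
  the tested tolerances.

## A worked example

```{r example, eval = FALSE}
# ground truth: a spherical cap, R = 1000 um, outline radius 500 um
spec <- slice_shape_spec("spherical_cap", amplitude_or_radius = 1000,
                         outline_radius = 500)
oracle_indices(spec)      # D_n = 33.45 um, R_a = 1.0718, K_m = 1.000 mm^-1

# simulate the acquisition and run the pipeline
hf <- make_height_field(spec, resolution = 10)
st <- render_stack(hf, stack_render_spec(noise_sd = 9, seed = 1))
mask <- segment_tissue(st)
stress_indices(extract_height_field(st, mask))

# viscoelastic analysis of a simulated compression test
tr <- simulate_trace(trace_sim_spec(noise_sd = 0.036, seed = 1))
analyze_trace(tr)
```

## Known limitations

* Folded (non-Monge) slices are detected but not reconstructed.
* $K_m$ is only comparable across analyses run with the same
  smoothing scale and reconstruction method; both are carried in the
  provenance for that reason.
* The synthetic noise model is additive Gaussian; Poisson-dominated
  low-light acquisitions are not emulated.
* Atlas-based anatomical annotation, slice-to-slice registration, and
  conversion of deformation indices into stress in kPa (which would
  require a constitutive inverse model) are all out of scope.
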