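---
title: "Surface strain fields and tactile afferent encoding during partial slip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface strain fields and tactile afferent encoding during partial slip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipstrain)
```

## The problem this package addresses

When a flat plate pressed against the fingerpad at constant normal force is
moved tangentially, the contact does not fail all at once. Slip starts at the
periphery, where the normal pressure is lowest, and an annular slip front
sweeps toward the center of the contact while the central region remains
stuck — the *partial slip* regime. The front carries a traveling wave of
surface strain: skin just inside the front still moves with the plate while
skin just outside has stopped, so the velocity gradient across the front
produces a pair of strain-rate waves of opposite sign (compression at the
leading edge, stretch at the trailing edge) plus shear lobes perpendicular to
the movement axis. When the last stuck point at the center lets go (*full
slip*), the tangential force plateaus at \(\mu F_n\) and the strain waves die
out.

Fast-adapting type I (FA-I) tactile afferents respond vigorously during
exactly this phase, which makes the relationship between the local
strain-rate field and single-afferent spike trains a natural target for
quantitative modeling. This package implements that full analysis chain —
strain-rate fields from tracked skin features, spike-triggered average (STA)
strain maps, and cross-validated linear encoding models with a
reference-frame rotation scan — together with a synthetic experiment
generator that reproduces the statistical structure the analysis assumes, so
every stage can be validated against known ground truth.

## The synthetic experiment generator

The generator is first-class, tested code: its outputs are the study
conditions under which the analysis chain is exercised.

### Slip-front kinematics

There is no attempt at finite-element contact mechanics. Instead, each
tracked feature at initial radius \(r\) (contact radius \(R\)) sticks to the
plate until the cumulative plate displacement exceeds a radius-dependent
threshold

\[ D(r) = D_{\mathrm{full}}\,\mu\,\bigl(1 - (r/R)^p\bigr), \]

after which it holds its position. \(D(r)\) decreases strictly with radius,
so slip begins at the periphery and the front moves inward; the center slips
last at displacement \(D_{\mathrm{full}}\mu\), defining full slip. This is
the simplest mechanism that reproduces the observed phenomenology: an
annular front, a pair of opposite-signed strain-rate waves, and earlier full
slip at lower friction. The backward movement starts from the strained
forward end-state: features re-stick at the reversal and slip again once
displaced to \(-D(r)\), so full backward slip requires roughly twice the
displacement.

Axial displacement couples to a transverse contraction with ratio \(\nu\)
(`lateral_contraction`), giving the strain field a Poisson-like
two-dimensional structure; without it all tensors at a location would be
proportional and preferred-orientation recovery would be degenerate.

Defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| tangential speed | 5.5 mm/s | stimulation protocol |
| forward / backward amplitude | 8 / 12 mm | stimulation protocol |
| normal force | 4 N | stimulation protocol |
| frame / signal rate | 50 Hz / 1 kHz | imaging and DAQ rates |
| pixel pitch | 25.4/1200 mm | 1200 dpi optics |
| contact radius | 300 px (≈ 6.4 mm) | plausible fingerpad contact at 4 N |
| feature spacing | 24 px (≈ 0.5 mm) | fingerprint-ridge scale feature density |
| \(\mu_{\mathrm{high}}, \mu_{\mathrm{low}}\) | 1.0, 0.5 | not reported by the protocol; configurable |
| \(D_{\mathrm{full}}\) | 3 mm | puts full slip at 0.55 s (high) / 0.27 s (low) into the 1.45 s forward movement |
| profile exponent \(p\) | 1 | simplest strictly decreasing profile |
| \(\nu\) | 0.2 | mild transverse coupling |

Strain-rate amplitudes during real manipulation are not well characterized,
so the simulator's amplitudes are free parameters of the model above, not a
calibration to any recording.

### Force traces

The tangential force follows a saturating spring,
\(F_t = \min(k\,x_{\mathrm{plate}}, \mu F_n)\) with
\(k = F_n / D_{\mathrm{full}}\). This choice makes the plateau onset coincide
exactly with the trajectory generator's full-slip time, independent of
\(\mu\), which is what lets the phase-segmentation accuracy be scored against
ground truth. The ideal trace is smoothed with a zero-phase 20 Hz Butterworth
filter and optionally corrupted with Gaussian noise; the normal force is
constant (4 N) with an optional band-limited fluctuation, off by default.

### Afferent model

Each simulated afferent fires as an inhomogeneous Poisson process (thinning
at 1 kHz, at most one spike per 1 ms sample) with rate

\[ \lambda(t) = b + g_c\,[-e_\parallel]^+ + g_t\,[e_\parallel]^+ +
   g_s\,|e'_{xy}|, \]

where \(e_\parallel\) is the axial strain rate (%/s) at the afferent's
receptive-field grid cell after rotating the tensor into its preferred
orientation. The rectified form mirrors the encoding model's predictor
families, so "in-class" ground truth exists for exact-recovery tests; gains
are in spikes/s per %/s. The preferred orientation is an axis and lives in
[0, 180). An afferent placed outside the contact area receives no measured
strain drive and fires at its baseline only — which doubles as a
homogeneous-Poisson null control.

## The strain pipeline

1. **Triangulation.** The reference (first-frame) feature positions are
   Delaunay-triangulated (via the `interp` package); triangles with
   reference area below 10⁻⁶ px² are dropped with a logged count.
2. **Green–Lagrange strain rates.** For each triangle and consecutive frame
   pair the deformation gradient \(F\) is solved exactly from the affine map
   of the three vertices, and \(E = \tfrac12(F^\top F - I)\) is scaled by
   (frame rate × 100) to %/s. \(E\) is invariant to rigid motion, which the
   tests verify to machine precision. A triangle degenerate in a given frame
   yields an undefined value for that frame pair only.
3. **Spatial smoothing.** Jacobi-style Laplacian relaxation over
   edge-adjacent triangles, \(v \leftarrow (1-w)v + w\,\overline{v}_{nbr}\),
   default one iteration with \(w = 0.5\); undefined neighbors are excluded
   from the mean. The original processing names a mesh-smoothing tool without
   parameters, so these are package defaults.
4. **Temporal median.** A window-3 running median per triangle and
   component, applied on the mesh (before gridding). Endpoints use the
   shortened two-point window (the mean), so no values are fabricated.
5. **Gridding.** Linear barycentric interpolation from triangle centroids
   onto the fixed 90 × 120 grid (10 px spacing; columns span x
   = radial-ulnar with ulnar right, rows span y = proximal-distal),
   evaluated at reference coordinates. Cells outside the contact outline or
   the centroid hull are undefined (`NA`), never zero, and no extrapolation
   is performed.

Derived channels — principal strains \(e_1 \le e_2\) (eigenvalues, ascending;
under area conservation \(e_1\) is compressive and \(e_2\) tensile), the
rotation-invariant norm \(\sqrt{e_{xx}^2 + e_{yy}^2 + 2e_{xy}^2}\), tensor
rotation by \(R(\theta) e R(\theta)^\top\) with
\(R = [[\cos\theta, \sin\theta], [-\sin\theta, \cos\theta]]\), and half-wave
rectification — are all closed-form and tested against brute-force oracles.

## Phase segmentation

Each movement is split into onset (first 100 ms), partial slip, and plateau.
"The tangential force derivative returning close to zero" is formalized as:
the zero-phase 10 Hz low-pass filtered derivative of the tangential force
magnitude stays below 5% of its in-movement peak for at least 50 ms; the
first such time is the full-slip time. Both \(\varepsilon\) and the dwell
time are configurable; if the criterion is never met the partial-slip phase
extends to the movement end with a warning and an empty plateau. On noisy
synthetic trapezoids the detected full-slip time is within ±40 ms of ground
truth.

## Firing rates

The smoothed rate convolves the 1 kHz binary spike vector with a 480-point
Gaussian window (shape parameter alpha = 6, i.e. σ ≈ 40 ms). "Normed" is
interpreted as unit-sum, so after the ×1000 scaling the rate integrates to
the spike count for interior spikes (asserted to 10⁻⁶). Resampling to 50 Hz
is frame-aligned decimation — the Gaussian already band-limits the signal, so
averaging would be redundant. Spike bins are half-open \([t, t+20\,\mathrm{ms})\);
a boundary spike belongs to the later bin. The instantaneous rate assigns
\(1/\Delta t\) over the closed interval ending at the second spike of each
pair.

## Spike-triggered averages

STAs pool the 20 ms partial-slip bins of all conditions and repetitions. The
spike selection takes every bin with ≥ 1 spike, entering n times for n
spikes (implemented as integer weights, mathematically identical to frame
repetition); the no-spike selection draws the same number of frames from the
zero-spike bins, seeded and without replacement (falling back to
with-replacement, with a warning, only if the pool is too small). The STA is
the per-cell difference of selection means. Cells are masked when |STA| is
below four times the sum of the two selections' deviations, and when the
cell was in contact for less than half of the pooled partial-slip time.

The deviation is, by default, each selection's standard *error* of the mean.
Read literally as raw standard deviations, the threshold masks essentially
every cell of every map (the per-frame variability of strain is of the same
order as the STA itself, and four times the sum of two such deviations is
never exceeded); the standard-error reading makes the threshold a
significance filter on the mean difference, which is the only reading under
which the published maps could contain defined cells. The literal mode
remains available via `deviation = "sd"`.

## Encoding models

The response is the 50 Hz smoothed rate restricted to partial-slip bins. The
full model regresses it on six nonnegative predictors — stretch and
compression of both axial components and both shear signs — plus an
intercept, by ordinary least squares (deliberately the simplest model in the
class; no regularization). Rectification makes all-zero columns common, so
rank-deficient designs drop aliased columns with a warning. Cross-validation
schemes split by friction (2-fold), movement (2-fold), or direction
(4-fold); models are always fitted excluding one fold and evaluated on it,
and the held-out predictions are pooled into a single
\(R^2 = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}\) with the pooled mean in
the denominator (the per-fold-mean variant is a whisker away and the spec
text does not distinguish them; pooled was chosen). This \(R^2\) can be
negative.

`r2_map()` fits the full model at every grid cell in contact ≥ 50% of the
time; `best_location()` takes the defined maximum within the receptive field
(or the whole contact for units outside it), breaking ties toward the
smallest (row, col). `rotation_scan()` then fixes that location and fits
four single-predictor models — rotated-x compression/stretch and rotated-y
compression/stretch — at rotations 0–90° in 5° steps (19 angles, endpoints
inclusive; shear is not part of the scan). The reported "compressive" and
"tensile" curves are those of the rotated-x component, and the preferred
orientation maximizes their sum; the rotated-y curves are returned too (they
are the same families shifted by 90°).

Direction tuning averages partial-slip rates across repetitions, movements
and frictions per plate direction; ties go to the fixed order (ulnar,
distal, radial, proximal) with a warning. Friction ratios are
low/high-friction rate ratios over matched (direction × movement) pairs,
undefined when the high-friction mean is zero.

## What the tests do and do not show

The synthetic generator reproduces the *structure* the analysis assumes —
an annular strain-rate front, friction-ordered full-slip times, Poisson
spiking driven by rectified local strain rates — but deliberately omits:
fingerprint-scale spatial inhomogeneity, out-of-plane strain components
(unmeasured in the imaging setup), stick-and-slip dynamics, contact-area
changes during loading, and any nonlinearity or multi-site structure in the
afferent transfer function. Passing the recovery tests therefore shows the
pipeline is *correct and well calibrated* (it finds what is there, and finds
nothing in null controls); it does not show that real afferents are linear
encoders.

One structural consequence of the lateral-contraction coupling deserves
mention: while the whole contact is stuck it translates with the plate and
contracts transversely at a constant rate, so axial-compression channels
carry a low-amplitude background from movement onset until the front passes,
in addition to the front-locked wave. The shear channel has no such
background (the stuck region is shear-free), which is why the phasic
"active mostly during partial slip" validation uses a shear-driven unit.

Front symmetry is worth noting: the synthetic annulus is mirror-symmetric
about the movement axis, so a norm-channel STA of an afferent placed far
off-axis has a twin peak at the mirror location. The validation afferents
are placed near a movement axis (localization tests) or on the diagonal
(orientation tests, where both axial components need strong content); real
fingerprint-structured data does not have this exact symmetry.

Problem sizes used by the test suite (the package's own choice of scale):
the STA/R²-map/end-to-end batteries use 20 seeded datasets of the full
40-trial design with two afferents each; orientation recovery uses 20 seeds
per target angle at 2 repetitions per design cell (16 trials); oracle
batteries use 1000 random deformations/tensors. On one CPU the whole suite
runs in roughly a quarter of an hour.

## Numerical choices and degenerate inputs

- Degenerate-triangle tolerance: reference area < 10⁻⁶ px²; per-frame
  degeneracy yields `NA` for that frame pair and propagates.
- Undefined cells are `NA` end to end; they are dropped pairwise with the
  response in regressions and never silently become zero.
- A response with zero variance yields \(R^2 = 0\) with a warning rather
  than NaN; an all-undefined STA yields undefined peak statistics.
- The Poisson thinning caps per-sample probability at 1; rates are clipped
  at zero.
- Per-trial seeds derive from the master seed as
  \(s_i = s + 104729\,i \bmod (2^{31}-1)\), and every stochastic stage
  (force noise, thinning, STA no-spike draw) is seeded, so datasets and maps
  are bit-reproducible.

## Known limitations

Single-location predictors only (no multi-site receptive-field models); no
out-of-plane strain; the generator's slip front is deterministic given the
parameters; cohort-level statistics across real afferents are out of scope.
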