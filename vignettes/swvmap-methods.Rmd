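---
title: "Methods: volumetric muscle SWV mapping, parameterization and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric muscle SWV mapping, parameterization and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swvmap)
```

This vignette documents the models and procedures implemented in `swvmap`,
their assumptions, the tunable parameters, the numerical choices, and what
the built-in synthetic data can and cannot establish about real
elastography data.

## 1. The measurement model

A freehand shear wave elastography (SWE) acquisition produces a sequence of
2D frames. Each frame carries a shear wave velocity image in m/s, a validity
mask (the scanner withholds estimates where the shear wave could not be
tracked), a pixel spacing in mm, and a rigid pose from an optical tracking
system that maps frame-plane coordinates $(u, v, 0)$ into a fixed
right-handed world frame in mm. Conventions, fixed once and used everywhere:

* world coordinates in mm, right-handed;
* voxel indices 0-based, voxel $(i,j,k)$ centered at
  $\mathrm{origin} + s\,(i,j,k)$ and owning the half-open cube
  $[c - s/2, c + s/2)$ per axis;
* frame pixel (row $i$, col $j$) at $u = (j-1)\,du$, $v = (i-1)\,dv$;
* SWV sample values carried at single precision (the scanner's native
  width), which makes file round trips bit-exact and, less obviously, makes
  double-precision sums of samples exactly associative — the basis for
  several *exact* aggregation guarantees below.

We assume the imaged structure does not move during the scan, and that
pose errors are independent across frames (optical tracking has no
integrating drift, unlike inertial tracking).

## 2. Reconstruction

`reconstruct()` projects every valid pixel through its frame pose and
accumulates it into the containing voxel. A voxel's value is the arithmetic
mean of its samples; its count is recorded; voxels with no samples remain
undefined (`NA`). Choices worth stating:

* **Nearest-voxel mean compounding.** The simplest assignment rule that is
  order-independent and unbiased for a locally linear field. Trilinear
  *distribution* of samples would smooth noise slightly better but couples
  neighboring voxels and breaks the "mean of the samples inside" semantics.
  Samples are sorted into a canonical order before summation, so any
  permutation of the input frames produces bit-identical volumes.
* **Voxel spacing** defaults to 1 mm isotropic — on the order of the
  elevation resolution of a linear transducer; it is configurable
  everywhere.
* **No silent inpainting.** Unsampled voxels stay undefined. Behind an
  explicit flag, single-voxel holes (all six face neighbors defined) can be
  filled with the neighbor mean; such voxels are flagged and keep count 0.
  Larger gaps are never invented.
* **Error bound.** For a noiseless scan of a field with Lipschitz constant
  $L$, any voxel's mean-of-samples differs from the field at the voxel
  center by at most $L \sqrt{3}\, s$ (every sample lies within the voxel
  diagonal). `phantom_lipschitz()` returns an analytic $L$ for phantoms
  without an angular gradient (whose slope is unbounded at the axis).

B-mode frames travel through the identical path as a second channel.

## 3. Anatomical parameterization

`parameterize()` maps the masked, defined voxels into an
$(S \times A \times R)$ cell array:

1. **Axis alignment.** The distal–proximal axis is the first principal
   component of the point coordinates; its sign is resolved by an
   orientation hint supplied by the caller. The in-slice x-axis is the
   second principal component with a moment-based deterministic sign (third
   moment of the projections; first-point sign as a tie-break), so the
   whole basis is rigid-motion equivariant.
2. **Slicing.** $S$ uniform half-open bins over the aligned longitudinal
   extent; a point on an interior edge belongs to the upper slice. $S = 8$
   suits a vastus lateralis (VL) scan, $S = 6$ a biceps femoris long head
   (BFlh); presets `vl_config()` / `bflh_config()`.
3. **Polar origin.** Per slice: either the slice centroid (BFlh archetype)
   or the center of an algebraic least-squares circle (Kåsa fit, a closed
   3×3 linear solve) through the slice's outer boundary (VL archetype). The
   boundary is extracted as the outermost point per fine angular bin about
   the centroid — for voxelized slices this is the set of masked points
   with no masked neighbor further from the center. "Geometric mean of the
   mask" is implemented as the coordinate centroid; a literal geometric
   mean is ill-defined for signed coordinates.
4. **Relative coordinates.** The angular coordinate is span-relative:
   centroid mode uses the full circle with zero at the aligned +x axis;
   circle-fit mode detects the mask's angular span as the complement of the
   largest angular gap (gaps under 15° mean the mask surrounds the origin
   and the full circle is used) and normalizes $\varphi$ to it. The radial
   coordinate is normalized per angular *normalization sector* to the local
   extent: $r_{rel} = (\rho - \rho_{\min}) / (\rho_{\max} - \rho_{\min})$,
   so "deep" and "superficial" mean the same thing in a thick and a thin
   part of the muscle. A sector with zero radial extent puts its points at
   $r_{rel} = 0.5$ with a warning.
5. **Cells.** Uniform binning of $(\text{slice}, \varphi_{rel}, r_{rel})$;
   cell value = mean SWV of member points. Cell sums, counts and mean
   radial coordinates are retained.

Two properties are guaranteed *exactly*, not to a tolerance: every input
point lands in exactly one cell (conservation), and merging a map computed
at doubled angular/radial resolution reproduces the directly computed
coarse map (`merge_map()` adds the stored per-cell sums, and sums of
single-precision samples are exactly associative in double arithmetic).

**Normalization sectors.** The radial normalization uses a fixed internal
angular resolution (`n_norm_sectors`, default 12) deliberately decoupled
from the reporting bin count $A$: if the normalization followed $A$, the
same point's relative radius would change when the map resolution changes,
and refinement consistency would be impossible. The default of 12 (30°
wedges) balances two discretization errors: sectors must be narrow enough
to track genuinely non-circular sections, but wide enough that the nearest
sampled point per sector approaches the true mask extent — on a 1 mm grid a
10° wedge near a 25 mm-radius slice origin first contains a sample several
mm out, which systematically compresses the radial coordinate and biases
radial gradient estimates downward.

**Estimating a radial gradient.** `radial_slope()` regresses the
count-weighted radial profile on the *recorded* mean $r_{rel}$ per bin
rather than on nominal bin centers $(r + 0.5)/R$; for non-uniform radial
point densities (area grows with $\rho$) the nominal centers misplace the
bins and bias the slope.

## 4. Reliability and regional statistics

For an $n \times k$ table (targets × sessions) the two-way ANOVA without
replication gives $MS_R, MS_C, MS_E$, and

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

the two-way random-effects, absolute-agreement, single-measure coefficient.
The 95% CI uses the F-based interval for this coefficient (Satterthwaite
degrees of freedom for the lower-tail composite); the point estimate of a
sample may be negative. Implementation notes:

* An all-constant table has no defined ICC and is returned with an explicit
  `undefined` status rather than a silent number; a perfect-agreement table
  returns ICC 1 with a degenerate (NA) interval.
* Rows with missing entries are dropped listwise and counted.
* SEm defaults to $SD \cdot \sqrt{1 - \mathrm{ICC}}$ with the SD over all
  $n \cdot k$ entries; the ANOVA variant $\sqrt{MS_E}$ is available
  (`method = "anova"`). The default follows the common test–retest
  reporting convention.
* Qualitative bands: poor ≤ 0.2 < fair ≤ 0.4 < moderate ≤ 0.6 < good ≤ 0.8
  < very good. The boundaries are applied exactly as printed (0.8 is
  "good", anything above is "very good").

Three framings connect cell maps to reliability questions:
`whole_muscle_reliability()` reduces each map to its voxel-count-weighted
mean (the weighting reflects that cells summarize different tissue
volumes); `regional_reliability()` computes one ICC per subject across
cells (*inter-regional*: can I re-measure this subject's regional pattern?)
or one ICC per cell across subjects (*inter-subject*: can I rank subjects
by this region?), summarized by median and IQR since cell-level ICCs are
skewed.

Contrasts and associations operate on axis profiles (count-weighted
collapses onto the radial, angular or longitudinal axis): paired t per bin
for pre/post contraction (p unadjusted, matching α = 0.05 reporting;
Benjamini–Hochberg behind a flag), Spearman rank correlation per bin
against a covariate, with the p-value from the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — adequate at a 16-subject scale; an
exact permutation p is available for $n \le 8$. With fewer than 4 subjects
the association is reported as undefined rather than estimated. Paired
differences constant to within floating-point resolution are flagged
degenerate instead of producing astronomically large t values.

## 5. The synthetic study conditions

The phantom is an extruded superellipse (exponent 2.5, semi-axes 25 × 15
mm, length 200 mm, linear taper over the last 15% of each end to 40%
scale — a VL/BFlh-like bulk shape without anatomical meshes) with field
$\text{base} + b_r r_{rel} + b_\varphi \cos\varphi + b_z z_{rel} +
\text{smooth}(p)$. The smooth component is a low-order 3D cosine series
with seeded integer mode vectors and phases and fixed per-mode amplitude
(band-limited, differentiable, with an exactly computable Lipschitz
constant); parameters that could drive the field non-positive are rejected
at construction. Defaults: base 1.6 m/s (typical resting muscle), radial
gain 0.4 m/s, smooth SD 0.05 m/s.

The scan simulator sweeps longitudinal planes (probe parallel to the
fibres) along the muscle in laterally offset swipes with a randomized
starting end, 2.5 mm frame spacing (a 2 Hz frame clock at an unreported
manual sweep speed — the spacing, not the speed, is the operative
parameter), independent per-frame pose jitter (0.5 mm / 0.5°,
optical-tracking scale) and additive Gaussian SWV noise (0.1 m/s). The
cohort generator bypasses scanning: cell values are
$\text{base} + \text{region}_c + \text{subject}_i + \varepsilon_{ijc}$ with
the regional field shared across subjects, under which the true
inter-subject ICC of any cell is
$\sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$ in closed form. Because
$\varepsilon$ is drawn per cell, the whole-muscle average of a multi-cell
map has *higher* ICC than the per-cell closed form — use a 1×1×1 map shape
when the closed form should apply to the scalar. All randomness flows from
one integer seed through a documented splitting scheme (`split_seed()`),
and equal seeds reproduce bit-identical phantoms, scans and cohorts.

What passing tests on these conditions do **not** establish: performance
under anisotropic (fibre-direction-dependent) SWV, speckle and
reverberation artifacts, probe-pressure effects, segmentation error, or
motion during the scan — none of which are modeled.

## 6. Problem sizes and determinism

The shipped tests and the acceptance script use reduced but non-toy sizes
chosen as realistic desk-scale experiments: reconstruction checks on
100 mm phantoms at 1–2 mm voxels (10⁵–10⁶ pixel samples), ICC recovery at
200 subjects × 2 sessions × 500 replicates per true ICC, type-I calibration
over 1000 simulated 16-subject cohorts, and a full-pipeline test–retest
study of 8 subjects × 2 scans. Pipeline runs are deterministic given the
configuration: identical config + seed produce byte-identical CSV/JSON
outputs (figures excluded; graphic files embed library metadata).

## 7. Known limitations

* Nearest-voxel compounding leaves unsampled voxels between widely spaced
  swipes; coverage is reported by `apply_mask()` and should be inspected.
* The per-sector radial normalization is sampling-dependent at coarse
  resolutions (Section 3); radial gradient estimates carry a residual
  attenuation of a few percent at 1 mm voxels.
* The Kåsa circle fit is biased toward smaller radii for short, noisy
  arcs; the geometric (nonlinear) fit would reduce this at the cost of an
  iterative solve. For full or near-full boundaries the difference is
  negligible.
* ICC confidence intervals assume Gaussian components; heavy-tailed
  measurement error will degrade coverage.
* The CLI is a thin wrapper over the R API; scripted R use is the primary
  interface.
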