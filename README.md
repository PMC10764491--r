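# swvmap

Three-dimensional, anatomically referenced mapping of skeletal-muscle shear
wave velocity (SWV), with the statistics needed to judge whether such maps
are reliable and meaningful.

Shear wave elastography measures the propagation speed (m/s) of induced
shear waves — a proxy for local tissue stiffness — but a single 2D frame
only samples one plane of a muscle. When the transducer pose is tracked
during freehand sweeps, the 2D frames can be compounded into a volumetric
SWV map, and mapped into a standardized anatomical coordinate system so that
regions can be compared across sessions and subjects. `swvmap` implements
that pipeline for researchers in muscle physiology, sports science and
rehabilitation:

1. **Reconstruction** — valid pixels of each pose-tracked frame are
   projected into a world-aligned isotropic voxel grid; each voxel's value
   is the arithmetic mean of the samples that fall inside it (nearest-voxel
   compounding). Voxels never sampled stay undefined.
2. **Parameterization** — the segmented muscle volume is aligned along its
   distal–proximal axis by PCA, cut into S uniform longitudinal slices, and
   each slice is expressed in polar coordinates (φ, r) about an anatomical
   origin: the center of a least-squares (Kåsa) circle fitted to the slice's
   outer boundary (vastus lateralis archetype) or the slice centroid
   (biceps femoris long head archetype). Points are binned into cells of
   uniform *relative* angular and radial extent, giving an (S × A × R) cell
   map comparable across subjects.
3. **Statistics** — test–retest reliability as the intraclass correlation
   coefficient ICC(2,1) (two-way random effects, absolute agreement, single
   measure),

   ICC(2,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)),

   with its F-based 95% CI and the standard error of measurement
   SEm = SD·√(1 − ICC); whole-muscle, inter-regional (cells within a
   subject) and inter-subject (subjects within a cell) framings; paired
   t-contrasts of pre vs post-contraction maps along the radial, angular and
   longitudinal axes; and Spearman rank association of regional SWV with a
   subject covariate such as normalized maximal eccentric hamstring strength
   (median of six repetition maxima / body mass, N/kg).
4. **Synthetic ground truth** — a muscle-like phantom (superellipse
   cross-section, tapered ends) with a parametric SWV field
   `base + b_r·r_rel + b_φ·cos φ + b_z·z_rel + smooth noise`, a freehand
   scan simulator (multi-swipe trajectories, pose jitter, measurement
   noise) and a test–retest cohort generator with closed-form true ICC, so
   every stage is testable without any data download.

## Worked example

Simulate a 16-subject study (two pre-contraction sessions, one
post-contraction session, a strength covariate), reconstruct and
parameterize every scan, and run the full statistical layer:

```r
library(swvmap)
res <- run_pipeline(system.file("extdata", "demo_config.yaml", package = "swvmap"))
jsonlite::toJSON(res$summary, auto_unbox = TRUE, pretty = TRUE, digits = 4)
```

```json
{
  "n_subjects": 16,
  "whole_muscle": {
    "icc": 0.9982, "ci95": [0.9949, 0.9994],
    "sem_mps": 0.0048, "band": "very_good"
  },
  "inter_regional": {
    "icc_median": 0.7954, "icc_iqr": [0.7065, 0.8453],
    "sem_median": 0.052, "sem_iqr": [0.046, 0.0601]
  },
  "inter_subject": {
    "icc_median": 0.8304, "icc_iqr": [0.7283, 0.9016],
    "sem_median": 0.0514, "sem_iqr": [0.0411, 0.0652]
  },
  "contraction": {
    "mean_pre_mps": 1.9291, "mean_post_mps": 2.1786,
    "t": 162.4473, "df": 15, "p": 9.224e-26
  },
  "association": { "rho": -0.7529, "p": 0.0008 }
}
```

Reading the output: whole-muscle SWV is measured with near-perfect
test–retest agreement (ICC 0.998, "very good" band; SEm ≈ 0.005 m/s) because
averaging over the entire muscle suppresses the per-cell noise; regional
cells are individually noisier (median ICC ≈ 0.8). The simulated contraction
raises mean SWV from 1.93 to 2.18 m/s (paired t, p ≪ 0.001), and
post-contraction SWV is negatively rank-correlated with the simulated
normalized strength covariate (ρ = −0.75, p < 0.001), as the generator
builds in. The run directory additionally contains the masked volumes
(NIfTI), the long-format cell maps and statistics (CSV), profile and
association figures, and a manifest with the config hash.

Lower-level entry points (`make_phantom()`, `simulate_scan()`,
`reconstruct()`, `parameterize()`, `icc_2_1()`, …) are documented
individually; `inst/cli/swvmap.R` exposes them as shell subcommands
(`simulate`, `reconstruct`, `parameterize`, `reliability`, `contrast`,
`associate`, `demo`).

## Limitations

The simulator emulates geometry, sampling and noise, not acoustics: no
speckle, no fibre-direction-dependent (anisotropic) SWV, no probe-pressure
effects. SWV is reported as-is and never converted to shear modulus, since
the isotropic linear-elastic conversion assumptions fail in skeletal muscle.
See the methods vignette (`vignettes/swvmap-methods.Rmd`) for the full model
description and design rationale.
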