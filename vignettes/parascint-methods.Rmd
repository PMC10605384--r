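---
title: "Quantitative dual-phase parathyroid scintigraphy: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative dual-phase parathyroid scintigraphy: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parascint)
```

## The problem

In primary hyperparathyroidism (PHPT) a single parathyroid adenoma
autonomously over-secretes parathormone (PTH), raising serum calcium.
99mTc-sestamibi (MIBI) is retained longer in mitochondria-rich adenoma
tissue than in thyroid, so a dual-phase study — a planar image ~10 min
after injection and a second ~90 min later, plus SPECT when planar
findings are equivocal — both localizes the adenoma and carries
quantitative information about its functional state. `parascint`
implements that quantitative chain end to end:

* **planar uptake ratios** — early/delayed lesion-to-background (eLBR,
  dLBR) and lesion-to-thyroid (eLTR, dLTR) ratios of mean ROI counts, and
  the retention index;
* **SPECT volumetrics** — the scintigraphic adenoma volume (Svol) from a
  percent-of-maximum isocontour VOI, and the PTH/Svol composite;
* **cohort statistics** — severity grouping, normality-gated group
  comparisons, Spearman correlation, ROC/AUC with Youden-optimal
  cut-offs, ICC reliability;
* **synthetic data** — digital phantoms and correlated cohorts with known
  ground truth, because the original patient images and labs are not
  publicly deposited. Every downstream stage is therefore testable
  against analytic or brute-force oracles.

## Planar quantification

A lesion ROI is drawn over the adenoma on the early image. Reference ROIs
of *identical size and shape* are produced by reflecting the lesion mask
across the body-midline column: once into the contralateral thyroid
(thyroid reference), and once more with a caudal translation — by default
one ROI height — into the contralateral background cervical region, so the
background reference does not overlap the contralateral lobe. The same
three masks are applied unchanged to both time points. With $\bar L$,
$\bar T$, $\bar B$ the mean counts per pixel of lesion, thyroid and
background ROIs:

$$\mathrm{LBR} = \bar L / \bar B, \qquad \mathrm{LTR} = \bar L / \bar T,
\qquad \mathrm{RI} = \frac{\mathrm{eLTR} - \mathrm{dLTR}}{\mathrm{eLTR}}.$$

Design choices that were genuinely open:

* **RI precedence.** The retention index is the *fractional change* of
  LTR, `(eLTR - dLTR)/eLTR`, not the literal left-to-right reading
  `eLTR - (dLTR/eLTR)`. Only the fractional-change form is bounded above
  by 1 and matches the reported clinical range (−0.90 to 0.96). Under
  this convention a *retaining* adenoma (delayed accumulation relative to
  thyroid) has RI < 0.
* **"Mean counts" means per-pixel mean**, not ROI-summed counts; this
  makes every ratio independent of ROI area, which the
  same-size-and-shape rule otherwise enforces implicitly.
* **No decay correction** between time points: physical 99mTc decay
  cancels inside each single-time-point ratio.
* Each ratio demands a strictly positive reference mean and errors
  otherwise — a zero or negative reference is an ROI placement bug, not a
  value to propagate.

All ratios are invariant under global intensity scaling (tested), and the
mirrored masks always carry exactly the lesion mask's pixel count
(tested).

## SPECT isocontour volumetry

Svol is measured in three deterministic steps:

1. **Local peak.** The maximum-count voxel inside a search sphere
   (default 15 mm) around an operator seed. The percent-of-max reference
   is this *local* peak, not the global image maximum — thyroid uptake
   can exceed adenoma uptake. Ties are broken by distance to the seed,
   then lexicographic voxel index, so a uniform neighbourhood returns the
   seed voxel.
2. **Isocontour component.** The 26-connected component, containing the
   peak, of voxels with counts ≥ `threshold_pct`/100 × peak (default
   40%). No shape prior is applied; an optional ellipsoid clip mask
   emulates vendor bounding-shape behaviour but is off by default.
   Background is not subtracted before thresholding. A component touching
   the grid edge sets a `touches_boundary` flag.
3. **Volume.** Voxel count × voxel volume, in cm³ (voxel-count volume,
   not an ellipsoid fit — which of the two the vendor tool reported is
   unstated, so the simpler convention is primary). PTH/Svol is the
   per-patient division, in ng/L per cm³.

The 40% default is exposed as a parameter; its provenance in the
emulated study ("previously determined optimal threshold") is not given.

**Partial-volume behaviour.** On digital spheres (2 mm voxels, 50:1
contrast, radii 6–16 mm, sphere centred on a voxel centre) the recovered
Svol stays within ~9% of $(4/3)\pi r^3$ for PSF σ ≤ 1 mm; the worst case
is the smallest sphere, where voxelization dominates (a 6 mm sphere
centred on a voxel *corner* voxelizes ~20% large before any blur).
Against σ the recovered volume is *not* monotone: moderate blur
(σ ≈ 3–4 mm) erodes the peak and slightly shrinks the 40% VOI
(−7% at r = 10 mm), while heavy blur (σ ≈ 6 mm) inflates it strongly
(+40%) once background spill-in joins the isocontour. The tests
characterize this shape rather than asserting unbiasedness, and the
phantom default (σ = 1 mm, deliberately finer than clinical SPECT
resolution) keeps threshold volumetry inside its valid regime; at
clinical σ the 40% rule would need the vendor's own calibration.

## The digital phantom

The phantom is the simplest object that exercises the full measurement
chain: two ellipsoidal thyroid lobes, one ellipsoidal adenoma (taking
precedence where they abut, as at a lower pole), and uniform background
on a regular grid (default 64³ voxels at 2 mm; x right→left, y
anterior→posterior, z inferior→superior, world mm at voxel centres).
Each compartment has an early activity concentration (defaults 12:6:1,
adenoma:thyroid:background — a detectable lesion by construction) and a
mono-exponential effective washout half-life applied over the 80-minute
early→delayed interval (defaults 360/120/180 min). The half-lives are
configuration placeholders chosen so the adenoma retains tracer relative
to thyroid, matching the detection premise of dual-phase imaging; they
are *not* claimed 99mTc-MIBI kinetics. Acquisition is modelled as
isotropic Gaussian PSF blur followed by voxelwise Poisson counts
(`count_scale` sets the dose/duration scale); planar images are exact ray
sums along the anterior–posterior axis, which conserves total counts.

What the phantom deliberately does **not** emulate: tomographic
reconstruction and its artifacts (volumes are "already reconstructed"),
attenuation and scatter, camera dead-time, anatomical realism, patient
motion. Passing recovery tests therefore demonstrates correctness of the
*measurement* chain on ideal reconstructions, not robustness to those
physical effects.

## The correlated cohort generator

`simulate_cohort()` draws nine variables — PTH, calcium, phosphorus,
25(OH)D, eLBR, eLTR, dLBR, dLTR, Svol — from a Gaussian copula and fixed
marginals, then *computes* the composites per record: PTH/Svol and
RI = (eLTR − dLTR)/eLTR are never sampled independently. A configurable
fraction of records (default 41/70) carries SPECT volumetrics, emulating
the subset actually imaged with SPECT/CT.

**Marginals** are moment-matched to the published descriptives of the
emulated 70-patient population: lognormal for the skewed positive
variables (PTH, phosphorus, 25(OH)D, Svol, dLBR, dLTR), with `sdlog`
solved from the printed median and range by reading the extremes as the
$1/(n+1)$ and $n/(n+1)$ order-statistic quantiles (upper-only for dLBR
and dLTR, whose printed minima are outlier-driven); truncated normals for
calcium and the early ratios. One published summary is internally
impossible: calcium "11.02 ± 0.71" under a ≥ 10.5 mg/dL inclusion bound
cannot arise from any normal truncated at 10.5 (that family needs
SD ≤ mean − bound). The printed values are therefore used as
*parent-normal* parameters; the realized truncated marginal has mean
≈ 11.31, SD ≈ 0.55, and a marked-hypercalcemia fraction ≈ 0.33 versus
the reported 0.286.

**Dependence.** Target Spearman correlations $\rho_s$ are mapped to
latent Gaussian correlations by $2\sin(\pi\rho_s/6)$ (exact for
continuous marginals under a Gaussian copula), the matrix is repaired to
the nearest positive-semidefinite correlation matrix when needed (an
error if the repair moves any entry beyond tolerance), and records are
drawn through the copula.

**Ratio calibration.** The published correlation table constrains PTH
mostly through the *derived* PTH/Svol column. Because PTH and Svol are
lognormal, the copula transform is linear on the log scale and
rank(PTH/Svol) = rank($\sigma_1 Z_{\mathrm{PTH}} - \sigma_2
Z_{\mathrm{Svol}}$) exactly, so every Spearman target involving the ratio
reduces to a Pearson correlation among jointly Gaussian variables and can
be solved in closed form for the free latent entries (PTH–Svol,
PTH–calcium, PTH–phosphorus, PTH–25(OH)D, PTH–eLTR, PTH–dLTR). The full
published matrix is *not* jointly attainable this way — e.g. hitting
Spearman(PTH, PTH/Svol) = 0.59 with these marginals forces an implied
Spearman(PTH, Svol) ≈ 0.48, not the printed 0.20 — so the generator
prioritizes the derived-column targets (0.59, 0.38, −0.29, −0.17, 0.21,
−0.10) and takes every directly sampled pair (e.g. calcium–eLBR 0.33)
from the table as printed. Lab–lab pairs reported nowhere are fixed once
at physiologically plausible values (e.g. calcium–phosphorus −0.30).

**Validation mode.** `cohort_spec(empirical = TRUE)` conditions the
latent sample on the exact target correlation matrix (the
`MASS::mvrnorm` empirical option). This is the variance-reduced mode used
by the calibration checks at n = 5000, where residual deviation from the
targets reflects only the rank transform, not latent sampling noise;
records are then not strictly independent, so the default for simulating
study-sized cohorts remains the iid draw.

## Statistical stage

* **Severity**: mild = calcium in [10.5, 11.5), marked = ≥ 11.5 mg/dL.
  The two printed conventions ("10.5 to 11.5" / "exceeding 11.5" and
  "10.50–11.49" / ">11.50") agree at 2-decimal resolution under this
  half-open rule; values below 10.5 are ineligible, excluded with a
  logged message.
* **Summaries and two-group tests** are normality-gated at α = 0.05
  (Shapiro–Wilk per group): mean ± SD with an independent t-test
  (equal-variance decided by Levene's mean-centred test at α = 0.05), or
  median (min–max) with a two-sided Mann–Whitney U (normal approximation,
  tie-corrected, continuity-corrected). p-values below 0.001 *print* as
  "<0.001"; machine output keeps exact values.
* **Spearman** is the Pearson correlation of mid-ranks with the
  t-approximation on n − 2 df, undefined (flagged) under zero rank
  variance.
* **ROC**: the empirical curve over all distinct thresholds; trapezoid
  AUC (identically the tie-corrected U/(n₁n₂), asserted to 1e-12 in the
  tests); direction auto-chosen so AUC ≥ 0.5 unless forced; DeLong
  variance for the 95% CI and the test against AUC = 0.5 (DeLong is
  deterministic; the CI method in the emulated study is unstated).
* **Youden cut-offs** are *realized marker values* with rule "> c" (or
  "< c"), matching published cut-offs that are attainable observations —
  a documented dialect choice, as some tools report midpoints between
  consecutive values instead. Ties in J break by higher sensitivity, then
  the cut-off nearest the marker median, then the smaller value. A
  constant marker yields J = 0 and a degenerate flag.
* **One printed inconsistency**: the phosphorus row of the published
  cut-off table prints Youden 0.47 while its own operating point gives
  0.7368 + 0.7391 − 1 = 0.4759 → 0.48. The reference table flags the row
  (`rounding_consistent = FALSE`) and the worked-example checks exclude
  it.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement, from the standard mean-square decomposition; missing cells
  are an error (no imputation).
* **Multiple testing**: none by default, matching the emulated analysis;
  a Benjamini–Hochberg flag *annotates* raw p-values without replacing
  them.

## Problem sizes and numerical choices

The test-suite and validation runs use: 200 random ROC instances
(n ≤ 40, heavy ties) for the oracle identity; six sphere radii (6–16 mm)
on 49³ grids for volumetric recovery; 100–200 noisy replicates for the
Monte-Carlo consistency checks; n = 5000 for copula calibration and
n = 70 for the study-sized smoke analysis; 20 subjects × 2 readers × 2
replicates for the reliability emulation, where reader variability is
modelled as a jittered seed click (±4 mm), an independent noise
realization, and an operator threshold drawn around 40% (SD 5 percentage
points), yielding ICC(2,1) ≈ 0.94–0.97. Numerical tie-breaks
(peak location, Youden cut-off) are fully specified so every pipeline
output is bit-reproducible under a fixed seed.

## Known limitations

* The phantom's washout kinetics and PSF width are stylized; absolute
  ratio values are not comparable to clinical ones (projection through a
  64-voxel background column dilutes planar contrast below clinical
  eLBR ≈ 2.6).
* The cohort generator reproduces marginals and the calibrated part of
  the rank-correlation structure, not the full (internally inconsistent)
  published matrix, and nothing about treatment, longitudinal course or
  measurement error in the labs.
* Threshold volumetry at clinical SPECT resolution requires a
  resolution-specific threshold calibration that this package does not
  provide; the 40% default is faithful to the emulated protocol, not
  universal.
* ROC confidence intervals are asymptotic (DeLong); with n = 70 and
  20 events the intervals are wide and the n = 70 AUC point estimates in
  the analysis scripts fluctuate accordingly across seeds.
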