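# parascint

Quantitative analysis of dual-phase 99mTc-sestamibi (MIBI) parathyroid
scintigraphy in primary hyperparathyroidism (PHPT), for nuclear-medicine
researchers who want the full measurement-and-statistics chain of a
severity study as tested, reproducible code.

In PHPT a single parathyroid adenoma over-secretes parathormone (PTH).
MIBI washes out of thyroid faster than out of adenoma, so planar images
at ~10 and ~90 min post-injection, plus SPECT, localize the lesion and
quantify its functional state. `parascint` computes, from images and a
lesion ROI:

- **Planar ratios** — with L̄, T̄, B̄ the mean ROI counts of lesion,
  mirrored contralateral thyroid and mirrored contralateral background:
  `LBR = L̄/B̄`, `LTR = L̄/T̄` at each phase (eLBR, dLBR, eLTR, dLTR), and
  the retention index `RI = (eLTR − dLTR)/eLTR`.
- **SPECT volumetrics** — the scintigraphic adenoma volume `Svol` as the
  26-connected component of voxels ≥ 40% of the local peak around an
  operator seed, times the voxel volume; and the secretory composite
  `PTH/Svol` (ng/L per cm³).
- **Cohort statistics** — hypercalcemia severity grouping (mild
  [10.5, 11.5) vs marked ≥ 11.5 mg/dL), normality-gated descriptives and
  two-group tests, Spearman correlations, ROC/AUC with DeLong confidence
  intervals and Youden-index optimal cut-offs, and ICC(2,1) reliability.

Because the original patient data are not publicly deposited, the
package ships first-class synthetic generators: a digital neck phantom
(ellipsoidal adenoma + thyroid lobes, mono-exponential washout, Gaussian
PSF, Poisson counts) and a Gaussian-copula cohort simulator calibrated to
the published marginals and rank-correlation structure. Every stage is
validated against analytic or brute-force oracles; see
`vignettes/parascint-methods.Rmd` for the models and design choices.

## Worked example

```r
library(parascint)

spec <- phantom_spec(count_scale = 20, seed = 1)     # 64^3 grid, 2 mm voxels
dp   <- simulate_dual_phase(spec, noise = TRUE, seed = 1)
roi  <- phantom_lesion_roi(spec, dp$early)           # operator outline stand-in
quantify_patient_planar(dp$early, dp$delayed, roi)
#> planar_params: eLBR 1.504  dLBR 1.568  eLTR 1.398  dLTR 1.495  RI -0.069

measure_adenoma_volume(dp$volumes$delayed, seed_mm = spec$adenoma_center,
                       threshold_pct = 40, pth = 128.3)
#> volumetrics_result: Svol 1.440 cm^3 (180 voxels at 40%), PTH/Svol 89.10
```

The phantom's true adenoma volume is 1.407 cm³, so the 40% isocontour
recovers it to +2.3% here. RI < 0 says the adenoma retained tracer
relative to thyroid between the phases — exactly what the simulated
half-lives (360 min adenoma vs 120 min thyroid) encode. A simulated
cohort then feeds the statistical stage:

```r
co  <- simulate_cohort(cohort_spec(n = 70, seed = 1))  # 50 mild / 20 marked
rep <- run_study_analysis(co)
rep$roc_table[rep$roc_table$variable == "pth", c("auc", "rule", "youden_j")]
```

## Analysis workflow

The `analysis/` scripts run the study end to end (each takes an optional
seed argument) and write tables under `results/tables/`:

| script | what it does |
|---|---|
| `01_simulate.R` | phantom images + lesion ROI + 70-patient cohort (NIfTI/JSON/CSV) |
| `02_planar_quant.R` | dual-phase ratios + 100-replicate noise study |
| `03_spect_volumetrics.R` | Svol, PTH/Svol + sphere recovery study (r = 6–16 mm) |
| `04_cohort_analysis.R` | descriptives, correlations, severity tests, ROC/Youden table, copula calibration |
| `05_reliability.R` | two-reader Svol emulation, ICC(2,1) |

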