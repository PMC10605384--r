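#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs.
#
# Builds the default digital neck phantom (two thyroid lobes, one
# right-lower parathyroid adenoma), simulates the dual-phase planar
# acquisition and the delayed SPECT volume with PSF blur and Poisson
# noise, and simulates the 70-patient correlated cohort. All artifacts are
# written under results/data/.

suppressMessages(library(parascint))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec(count_scale = 20, seed = seed)
cat(sprintf("Phantom: %s grid @ %s mm, adenoma %.2f cm^3 at (%g, %g, %g) mm\n",
            paste(spec$grid_shape, collapse = "x"),
            paste(spec$voxel_spacing, collapse = "x"),
            true_adenoma_volume(spec),
            spec$adenoma_center[1], spec$adenoma_center[2], spec$adenoma_center[3]))

dp <- simulate_dual_phase(spec, noise = TRUE, seed = seed)
write_planar_image(dp$early, file.path(outdir, "planar_early.nii.gz"))
write_planar_image(dp$delayed, file.path(outdir, "planar_delayed.nii.gz"))
write_activity_volume(dp$volumes$delayed, file.path(outdir, "spect_delayed.nii.gz"))
cat(sprintf("Planar counts: early %.3g, delayed %.3g (washout visible: %s)\n",
            sum(dp$early$counts), sum(dp$delayed$counts),
            sum(dp$delayed$counts) < sum(dp$early$counts)))

lesion <- phantom_lesion_roi(spec, dp$early)
write_roi(lesion, file.path(outdir, "lesion_roi.json"))
cat(sprintf("Lesion ROI: %d px around the projected adenoma\n", nrow(lesion$pixels)))

cohort <- simulate_cohort(cohort_spec(n = 70, seed = seed))
write_cohort(cohort, file.path(outdir, "cohort.csv"))
cat(sprintf("Cohort: %d patients (%d mild / %d marked hypercalcemia), %d with SPECT volumetrics\n",
            nrow(cohort), sum(cohort$severity == "mild"),
            sum(cohort$severity == "marked"), sum(!is.na(cohort$svol))))
cat("Artifacts in", outdir, "\n")
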