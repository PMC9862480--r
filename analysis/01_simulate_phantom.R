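#!/usr/bin/env Rscript
# Stage 1: build a synthetic thoracic CT phantom with known per-lobe
# density composition and write it (HU volume + lobe label map) as NIfTI,
# together with the exact ground-truth table.
#
# The phantom carries mild emphysema in the upper lobes and a small
# non-aerated fraction everywhere, a plausible profile for a resection
# candidate with limited smoking-related destruction.

suppressPackageStartupMessages(library(walqct))
dir.create("results", showWarnings = FALSE)

comp <- default_composition()
comp$f_emph <- c(0.07, 0.02, 0.00, 0.05, 0.00)  # RUL, RML, RLL, LUL, LLL
comp$f_nonaer <- 0.08
comp$f_wal <- 1 - comp$f_emph - comp$f_nonaer

spec <- phantom_spec(grid_shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
                     composition = comp, seed = 20230110)
ph <- make_phantom(spec)

write_nifti_volume(ph$ct, "results/phantom_ct.nii.gz")
write_nifti_volume(ph$lobes, "results/phantom_lobes.nii.gz")
write.csv(rbind(ph$truth$lobes, ph$truth$total),
          "results/phantom_truth.csv", row.names = FALSE)

cat("Phantom written to results/phantom_ct.nii.gz (+ lobe map).\n")
cat(sprintf("Lung: %d voxels, %.4f L; ground-truth WAL %.4f L, %%LAA %.2f%%\n",
            ph$truth$total$n_voxels, ph$truth$total$vol_l,
            ph$truth$total$wal_l, ph$truth$pct_laa))
print(ph$truth)
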