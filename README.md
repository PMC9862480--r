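# walqct

Quantitative-CT assessment of **well-aerated lung (WAL)** and prediction of
**postoperative pulmonary function** after lung resection, with the full
agreement battery used to compare predictors against measured outcomes.

It is aimed at thoracic imaging / surgical-planning researchers who want a
transparent, fully tested implementation of:

* **density-mask lung densitometry** — per-lobe and whole-lung WAL volume
  (attenuation in the closed window [−950, −750] HU), low-attenuation areas
  (LAA, strictly below −950 HU) and %LAA, computed on exact integer voxel
  counts from a CT volume plus a lobe label map (NIfTI in, JSON/CSV out);
* **predicted postoperative (ppo) FEV1 and %DLCO** by two estimators —
  anatomical segment counting (ASC),
  `ppo = pre × [1 − S × 0.0526]` with S the number of resected segments
  (RUL 3, RML 2, RLL 5, LUL 4, LLL 5; 19 in total), and the WAL ratio,
  `ppo = pre × [1 − WAL_lobe / WAL_total]`;
* the **agreement battery**: Spearman rho (t-approximation p), Bland–Altman
  limits of agreement (bias ± 1.96 SD), two-way random-effects
  absolute-agreement single-measure ICC with F-based 95% CI and banded
  interpretation (poor/weak/moderate/good/excellent), and the Wilcoxon
  signed-rank test (exact by enumeration up to n = 25);
* **synthetic data generators** — CT phantoms whose per-lobe compartment
  composition (emphysema / WAL / non-aerated) is an exact voxel partition
  with recorded ground truth, and simulated surgical cohorts whose marginals
  emulate a typical resected-NSCLC series (pre-FEV1 median 2.33 L, %DLCO
  median 71%, RUL resected in 45%, 22% segmentectomies), with measured
  postoperative values generated from the WAL prediction under multiplicative
  log-normal noise.

See `vignettes/wal-densitometry-methods.Rmd` for the model conventions and
design choices.

## Worked example

The `analysis/` directory is a five-stage narrative pipeline; each script is
a thin driver over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_phantom.R   # phantom CT + lobe map + ground truth
Rscript analysis/02_quantify_wal.R       # density-mask quantification
Rscript analysis/03_simulate_cohort.R    # 40-patient cohort
Rscript analysis/04_predict_ppo.R        # ASC and WAL ppo predictions
Rscript analysis/05_agreement.R          # six-comparison agreement report
```

Stage 2 prints, for the stage-1 phantom (64³ voxels, 2 mm spacing, mild
upper-lobe emphysema):

```
Density-mask quantification (WAL window [-950, -750] HU, LAA < -950 HU)
       lobe n_voxels n_wal n_laa  vol_l  wal_l  laa_l
        RUL     5244  4458   367 0.0420 0.0357 0.0029
        RML     9516  8565   190 0.0761 0.0685 0.0015
        RLL     5244  4825     0 0.0420 0.0386 0.0000
        LUL    10002  8702   500 0.0800 0.0696 0.0040
        LLL    10002  9202     0 0.0800 0.0736 0.0000
 whole_lung    40008 35752  1057 0.3201 0.2860 0.0085
%LAA: 2.64%
```

Every count matches the phantom's ground truth exactly — the quantification
is an exact voxel-counting operation, so on noise-free input it has zero
error by construction. Stage 5 prints the agreement table for the simulated
cohort (seed 20230110):

```
 comparison                                  rho (p)        LoA              ICC (95% CI)        band
 WAL ppo-FEV1 (L) vs. ASC ppo-FEV1 (L)       0.978 (<0.001) +0.18, -0.28     0.981 (0.960-0.991) excellent
 WAL ppo-FEV1 (L) vs. postoperative FEV1 (L) 0.886 (<0.001) +0.58, -0.39     0.912 (0.830-0.954) excellent
 ASC ppo-FEV1 (L) vs. postoperative FEV1 (L) 0.880 (<0.001) +0.67, -0.39     0.889 (0.749-0.946) excellent
 WAL ppo-%DLCO vs. ASC ppo-%DLCO             0.941 (<0.001) +5.71, -8.84     0.955 (0.906-0.977) excellent
 WAL ppo-%DLCO vs. postoperative %DLCO       0.849 (<0.001) +15.35, -15.92   0.845 (0.725-0.915) good
 ASC ppo-%DLCO vs. postoperative %DLCO       0.832 (<0.001) +18.00, -15.45   0.829 (0.701-0.906) good
```

Read: the two predictors agree near-perfectly with each other (first and
fourth rows); agreement of the WAL prediction with the simulated measured
outcome is excellent for FEV1 and good for %DLCO under the generator's
default noise (σ = 0.12), and the limits of agreement quantify the expected
per-patient disagreement (e.g. −0.39 to +0.58 L for FEV1).

The same flow runs as one call from R:

```r
library(walqct)
cfg <- run_config(ct_path = "ct.nii.gz", lobes_path = "lobes.nii.gz",
                  out_dir = "results", n_patients = 40, seed = 1)
out <- run_pipeline(cfg)   # quantification + cohort + predictions + report
out$report
```

`run_pipeline()` is byte-for-byte reproducible under a fixed seed and writes
a provenance manifest next to its outputs.

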