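---
title: "Methods: well-aerated lung densitometry and predicted postoperative lung function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: well-aerated lung densitometry and predicted postoperative lung function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walqct)
```

## The problem

Before a lobectomy or segmentectomy for lung cancer, surgeons need an
estimate of how much pulmonary function the patient will retain. The
classical estimate is *anatomical segment counting* (ASC): the lung has 19
bronchopulmonary segments (RUL 3, RML 2, RLL 5, LUL 4, LLL 5), and the
predicted postoperative (ppo) value of FEV1 or %DLCO is

$$\mathrm{ppo} = \mathrm{pre} \times \bigl[1 - S \times 0.0526\bigr],$$

where $S$ is the number of segments to be resected and 0.0526 is the
published per-segment coefficient (kept as the literal constant, not
recomputed as $1/19$, so the formula reproduces printed values bit for
bit). ASC treats every segment as contributing equally, which is wrong
when disease is unevenly distributed.

Quantitative CT offers a functional alternative. On an inspiratory CT,
*well-aerated lung* (WAL) — attenuation between −950 and −750 HU — is a
surrogate of functioning parenchyma, while voxels below −950 HU are
*low-attenuation areas* (LAA), an emphysema surrogate. The WAL-ratio
predictor scales the preoperative value by the fraction of whole-lung WAL
that survives resection:

$$\mathrm{ppo} = \mathrm{pre} \times
  \Bigl[1 - \frac{\mathrm{WAL}_{\text{lobe}}}{\mathrm{WAL}_{\text{total}}}\Bigr].$$

This package implements the density-mask quantification, both predictors,
and the full agreement battery used to compare predictions with measured
postoperative values, plus synthetic data generators so the pipeline is
testable end to end without clinical images.

## Density-mask conventions

* **Window boundaries.** The WAL window is closed at both ends,
  $[-950, -750]$ HU; LAA is *strictly* below −950 HU. A voxel at exactly
  −950 HU is therefore counted once, as WAL. Source descriptions of
  commercial densitometry tools rarely state whether thresholds are
  inclusive; this package fixes the convention explicitly and tests it at
  the boundary voxels (−951, −950, −750, −749).
* **Exact counting.** All quantification is on integer voxel counts;
  litre volumes are counts times the voxel volume
  (`prod(spacing_mm) * 1e-6`). Whole-lung litre figures are sums of the
  per-lobe litre figures, so additivity holds exactly in floating point
  as well as in counts. Output files round volumes to 4 decimals;
  internal arithmetic never rounds.
* **Noise reduction.** Clinical densitometry software applies an
  unspecified noise-reduction step before thresholding. Here it is a 3D
  median filter (edge-replicated, cubic neighbourhood, default radius 1
  voxel) — median filtering suppresses single-voxel noise without
  shifting HU histogram edges. It is **off by default** (`noise_radius =
  0`) because the synthetic phantoms are noise-free and exact ground-truth
  recovery is the stronger test.
* **Lobe masks are inputs.** Fissure-based lobar segmentation of real CT
  is out of scope; the lobe label map comes from the phantom generator or
  from external segmentation. A fallback whole-lung segmenter
  (`segment_lungs()`) thresholds at −300 HU, discards 26-connected
  components touching the volume boundary (the surrounding air) and keeps
  the two largest components. Voxels labelled background by the lobe map
  (airways included) are simply excluded from quantification.

## The agreement battery

Six comparisons are reported, mirroring the standard layout: WAL vs ASC,
WAL vs measured, ASC vs measured, each for FEV1 (L) and %DLCO.

* **Spearman rho** is the Pearson correlation of average (tie-corrected)
  ranks; its two-sided p value uses the t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ df, the convention of
  common biostatistics packages. (Base R's `cor.test` uses a different
  p-value algorithm; it serves as a cross-check for the estimate only.)
* **ICC** is the two-way random-effects, absolute-agreement,
  single-measure coefficient (McGraw–Wong ICC(A,1)) with the F-based 95%
  CI. The variant is a deliberate choice: when two measurement methods
  are assessed for interchangeability, a constant bias between them
  should lower the coefficient, which consistency ICCs ignore. Values are
  interpreted in bands — below 0.40 poor, 0.40–0.54 weak, 0.55–0.69
  moderate, 0.70–0.84 good, 0.85–1.00 excellent — with band edges
  belonging to the higher band.
* **Bland–Altman** limits of agreement are $\bar d \pm 1.96\,s_d$ with
  the sample SD ($n-1$) and the literal multiplier 1.96 (not a t
  quantile), matching how LoA are conventionally printed.
* **Wilcoxon signed-rank** drops zero differences, assigns average ranks
  to ties, and reports the smaller rank sum. The two-sided p value is
  exact — computed by a subset-sum dynamic program over doubled ranks,
  equivalent to enumerating all $2^n$ sign patterns — for up to 25
  nonzero differences, and a tie-corrected normal approximation (no
  continuity correction) beyond that. The method used is reported
  alongside the p value.

Tests are two-sided with significance at p < 0.05 and no
multiple-testing correction, matching common practice for agreement
tables. When the two vectors of a comparison are identical (a noise-free
simulated cohort), the Wilcoxon test is degenerate and the report records
`NA` with an explanatory method string instead of failing.

**Numerical tie-breaks.** Computed rho or ICC within $10^{-12}$ of 1 is
snapped to exactly 1: the spacing between attainable Spearman values is
$\approx 6/(n(n^2-1))$ and analogous granularity holds for the ICC, so
anything that close to 1 is a perfect agreement contaminated only by
floating-point cancellation. This makes the noise-free closure identity
(`rho = 1`, `ICC = 1`, `LoA = [0, 0]`) exact. For identical methods the
ICC CI is reported as [1, 1] since the F-based interval is undefined at
zero residual variance.

## The phantom generator

`make_phantom()` builds a 3D HU volume, lobe label map and exact ground
truth. Geometry is deliberately schematic: two ellipsoidal lungs inside a
soft-tissue elliptic-cylinder body (+40 HU) on an air background
(−1000 HU); the right lung is split into three axial slabs (RUL top, RML
middle, RLL bottom) and the left into two (LUL over LLL). This guarantees
five disjoint, nonempty lobes on any grid of at least 16 voxels per axis;
anatomical fidelity is irrelevant to the counting arithmetic being
validated, which is why no fissures, airways or vessels are modelled.

Each lobe's voxel list is partitioned *exactly* among three compartments
— emphysema (< −950 HU), WAL ([−950, −750] HU), non-aerated (> −750 HU) —
by floor allocation (`floor(n * f)` voxels to emphysema and non-aerated,
remainder to WAL), randomizing only *which* voxels get which compartment.
This makes the ground-truth voxel counts exact rather than
binomially distributed, so recovery tests can demand equality, not
approximation. HU values are drawn from truncated normals (defaults:
emphysema −980 ± 15, WAL −850 ± 40, non-aerated −400 ± 150 HU), rounded
to integer HU and clamped back into the compartment interval — truncation
after rounding, so the boundary contract survives the 16-bit integer
cast used on disk. The default composition has no emphysema compartment
(0% LAA, the modal finding in resection candidates) and 8% non-aerated
tissue.

## The cohort generator

`make_cohort()` simulates one row per patient. Marginals are log-normal,
parameterized from the median and quartiles of the quantity they emulate
(`lognormal_from_quartiles()`): preoperative FEV1 median 2.33 L
(IQR 1.68–2.76), %predicted FEV1 85% (67–101), %DLCO 71% (58–83);
per-lobe WAL volumes with medians RUL 1.20, RML 0.45, RLL 1.42, LUL 1.20,
LLL 1.32 L and matching IQR-derived spreads. The resected lobe is drawn
with probabilities RUL 0.45, LUL 0.27, RLL 0.12, LLL 0.16 (RML
resections are not represented, as in typical series); 22% of patients
get a segmentectomy with a uniformly drawn number of segments below the
lobe's total.

Measured postoperative values are generated from the WAL-ratio
prediction perturbed multiplicatively:
$\mathrm{post} = \mathrm{ppo}_{\mathrm{WAL}} \times e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$. The log-normal noise keeps values
positive and makes $\sigma$ a single interpretable knob; FEV1 in litres
and %predicted FEV1 share one draw per patient (they are the same
measurement in different units), %DLCO gets an independent draw. The
default $\sigma = 0.12$ was chosen once so that simulated
WAL-vs-measured ICCs at $n = 40$ fall in the 0.77–0.90 range reported
for such agreement in clinical cohorts; it is a generator default, not
an estimated quantity.

Deliberate independence assumptions, made for lack of published
correlation structure: FEV1 and %DLCO are independent across patients,
and per-lobe WAL volumes are independent within a patient. A consequence
of the latter is that the median whole-lung WAL (≈ 5.6 L, the sum of five
independent lobes) exceeds the ≈ 4.8 L typical of real cohorts, where
lobe volumes are positively correlated within patients but jointly
constrained by thorax size. Downstream arithmetic only uses WAL *ratios*,
so this inflates no agreement statistic.

**Segmentectomy under the WAL formula** is not standardized: published
descriptions use "WAL volume of the lobe to be removed" without saying
how a sub-lobar resection enters. This package scales the lobe's WAL by
$S / \text{segments}(\text{lobe})$ — proportional allocation, the minimal
assumption — and flags those rows (`wal_scaled`) so users can exclude
them. The generator uses the same rule, so the noise-free closure holds
for segmentectomy patients too.

## What the synthetic data do and do not establish

Passing the phantom-recovery tests shows the density-mask arithmetic
(window conventions, counting, volume conversion, lobe aggregation) is
exact; it says nothing about segmentation quality or scanner effects on
real CT, which are out of scope (lobe maps are inputs). Passing the
cohort tests shows the two formulas, their interaction with the noise
model, and the statistical battery behave as specified — including the
qualitative reproduction that WAL predictions sit significantly below ASC
predictions whenever resected lobes carry WAL shares above
$S \times 0.0526$ — but the simulated agreement statistics are properties
of the stated noise model, not estimates of clinical agreement.

## Problem sizes and defaults used by the test-suite

Phantom tests use 64³ grids at 2 mm isotropic spacing (20 random
compositions) plus smaller grids (16³–32³) for geometry and I/O tests;
cohort tests use $n = 40$ (the typical size of single-centre surgical
series) with 200 replicate cohorts per noise level over
$\sigma \in \{0.02, 0.05, 0.1, 0.2\}$ for the monotone ICC-degradation
check; marginal checks use $n = 10{,}000$. These sizes make every
distributional check stable under its stated tolerance while keeping the
full suite fast.

## Known limitations

* No fissure-based lobe segmentation, airway-tree extraction, or
  inspiratory/expiratory registration; real-CT use requires an external
  lobe label map aligned to the CT.
* The phantom has no partial-volume voxels, beam-hardening, or scanner
  noise; `noise_reduce()` exists for real data but is untested against
  clinical noise characteristics.
* The cohort generator models measurement and biological variation as a
  single multiplicative noise term; it does not model systematic
  postoperative over-performance (e.g. lung re-expansion after
  resection of non-functional tissue).
* The ICC confidence interval uses the F-based approximation, which is
  anti-conservative for very small n; `icc_agreement()` requires n ≥ 3
  but 5 or more pairs are recommended.
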