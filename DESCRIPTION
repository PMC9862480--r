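Package: walqct
Title: Well-Aerated Lung CT Densitometry and Predicted Postoperative Lung Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies well-aerated lung (WAL, attenuation between -950 and
    -750 HU) and low-attenuation areas (LAA, below -950 HU) per lobe and for
    the whole lung from 3D CT volumes with a lobe label map, and predicts
    postoperative FEV1 and percent DLCO after lobectomy or segmentectomy by
    both anatomical segment counting and the WAL volume ratio. Includes the
    agreement battery used to compare prediction methods against measured
    postoperative values (Spearman rank correlation, two-way random-effects
    absolute-agreement intraclass correlation with F-based confidence
    intervals and banded interpretation, Bland-Altman limits of agreement,
    Wilcoxon signed-rank tests), plus generators for synthetic thoracic CT
    phantoms with exact per-compartment ground truth and simulated patient
    cohorts, so the whole pipeline runs end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
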