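# Predicted postoperative (ppo) lung function. Two estimators:
#   ASC:  pre * (1 - S * 0.0526), S = number of segments resected
#         (19 bronchopulmonary segments in total; 0.0526 is the literal
#         published constant, not recomputed as 1/19);
#   WAL:  pre * (1 - WAL volume of the resected lobe / whole-lung WAL).
# Both apply identically to FEV1 (litres or % predicted) and %DLCO.

#' Segment-counting coefficient of the ASC formula
#' @keywords internal
ASC_COEF <- 0.0526

#' Predicted postoperative value by anatomical segment counting
#'
#' `ppo = pre_value * (1 - S * 0.0526)`, where S is the number of
#' bronchopulmonary segments resected. Vectorized over both arguments.
#'
#' @param pre_value Preoperative value (> 0); FEV1 in litres, %predicted
#'   FEV1, or %DLCO.
#' @param s Number of segments resected, integer in 0..19 (with
#'   `s * 0.0526 < 1`).
#' @return Predicted postoperative value, same units as `pre_value`.
#' @examples
#' asc_ppo(2.33, 5)  # 2.33 * (1 - 0.263)
#' @export
asc_ppo <- function(pre_value, s) {
  if (any(!is.finite(pre_value)) || any(pre_value <= 0)) {
    stop("`pre_value` must be positive", call. = FALSE)
  }
  if (any(!is.finite(s)) || any(s < 0) || any(s > 19) ||
      any(abs(s - round(s)) > 1e-9)) {
    stop("`s` must be an integer between 0 and 19", call. = FALSE)
  }
  if (any(s * ASC_COEF >= 1)) {
    stop("s * 0.0526 must be < 1", call. = FALSE)
  }
  pre_value * (1 - s * ASC_COEF)
}

#' Predicted postoperative value from the well-aerated-lung ratio
#'
#' `ppo = pre_value * (1 - wal_lobe_l / wal_total_l)`: the preoperative
#' value scaled by the fraction of whole-lung WAL volume that survives
#' resection. Vectorized.
#'
#' @param pre_value Preoperative value (> 0).
#' @param wal_lobe_l WAL volume of the lung tissue to be removed (litres),
#'   `0 <= wal_lobe_l <= wal_total_l`.
#' @param wal_total_l Whole-lung WAL volume (litres, > 0).
#' @return Predicted postoperative value, same units as `pre_value`.
#' @examples
#' wal_ppo(2.33, 1.20, 4.81)
#' @export
wal_ppo <- function(pre_value, wal_lobe_l, wal_total_l) {
  if (any(!is.finite(pre_value)) || any(pre_value <= 0)) {
    stop("`pre_value` must be positive", call. = FALSE)
  }
  if (any(!is.finite(wal_total_l)) || any(wal_total_l <= 0)) {
    stop("`wal_total_l` must be positive", call. = FALSE)
  }
  if (any(!is.finite(wal_lobe_l)) || any(wal_lobe_l < 0) ||
      any(wal_lobe_l > wal_total_l)) {
    stop("`wal_lobe_l` must lie in [0, wal_total_l]", call. = FALSE)
  }
  pre_value * (1 - wal_lobe_l / wal_total_l)
}

#' Predicted postoperative lung function for a cohort
#'
#' Applies both estimators to every patient. The ASC formula uses
#' `segments_resected` directly. The WAL formula uses the resected lobe's
#' WAL volume; for segmentectomies (fewer segments than the lobe holds)
#' that volume is scaled by `segments_resected / segments_for_lobe(lobe)`
#' — proportional sub-lobar allocation — and the row is flagged
#' (`wal_scaled = TRUE`) so such patients can be excluded downstream.
#'
#' @param cohort Cohort data frame in the schema of [make_cohort()]
#'   (validated; per-row violations are collected into one error).
#' @return Data frame with one row per patient: `id`, resection details,
#'   the WAL volumes entering the formula, and four ppo columns
#'   `asc_ppo_fev1_l`, `wal_ppo_fev1_l`, `asc_ppo_dlco_pct`,
#'   `wal_ppo_dlco_pct`, plus the `wal_scaled` flag.
#' @export
predict_cohort <- function(cohort) {
  validate_cohort(cohort)
  wal_cols <- c(RUL = "wal_rul_l", RML = "wal_rml_l", RLL = "wal_rll_l",
                LUL = "wal_lul_l", LLL = "wal_lll_l")
  nseg <- segments_for_lobe(cohort$resected_lobe)
  wal_lobe_l <- as.numeric(as.matrix(cohort[, wal_cols])[
    cbind(seq_len(nrow(cohort)), match(cohort$resected_lobe, names(wal_cols)))])
  scaled <- cohort$segments_resected < nseg
  wal_used_l <- wal_lobe_l * cohort$segments_resected / nseg
  data.frame(id = cohort$id,
             resected_lobe = cohort$resected_lobe,
             segments_resected = cohort$segments_resected,
             lobe_segments = nseg,
             wal_lobe_l = wal_lobe_l,
             wal_lobe_used_l = wal_used_l,
             wal_total_l = cohort$wal_total_l,
             asc_ppo_fev1_l = asc_ppo(cohort$pre_fev1_l, cohort$segments_resected),
             wal_ppo_fev1_l = wal_ppo(cohort$pre_fev1_l, wal_used_l, cohort$wal_total_l),
             asc_ppo_dlco_pct = asc_ppo(cohort$pre_dlco_pct, cohort$segments_resected),
             wal_ppo_dlco_pct = wal_ppo(cohort$pre_dlco_pct, wal_used_l, cohort$wal_total_l),
             wal_scaled = scaled,
             stringsAsFactors = FALSE)
}
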