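#' Lobe labels and bronchopulmonary segment counts
#'
#' The five lung lobes are encoded throughout the package by the integer
#' labels 1--5 in the order RUL, RML, RLL, LUL, LLL (right upper, right
#' middle, right lower, left upper, left lower). Label 0 is background
#' (everything outside the lung, airways included).
#'
#' @format `LOBE_LABELS` is a named integer vector mapping lobe code to
#'   label; `LOBE_SEGMENTS` is a named integer vector of anatomical segment
#'   counts per lobe (3, 2, 5, 4, 5; 19 in total).
#' @export
LOBE_LABELS <- c(RUL = 1L, RML = 2L, RLL = 3L, LUL = 4L, LLL = 5L)

#' @rdname LOBE_LABELS
#' @export
LOBE_SEGMENTS <- c(RUL = 3L, RML = 2L, RLL = 5L, LUL = 4L, LLL = 5L)

#' Number of bronchopulmonary segments in a lobe
#'
#' Segment counts follow the standard anatomical scheme used by the
#' segment-counting formula for predicted postoperative lung function:
#' RUL 3, RML 2, RLL 5, LUL 4, LLL 5 (19 segments over both lungs).
#'
#' @param lobe Character vector of lobe codes (`"RUL"`, `"RML"`, `"RLL"`,
#'   `"LUL"`, `"LLL"`). Case sensitive.
#' @return Integer vector of segment counts, same length as `lobe`.
#' @examples
#' segments_for_lobe("RUL")
#' sum(segments_for_lobe(names(LOBE_SEGMENTS)))  # 19
#' @export
segments_for_lobe <- function(lobe) {
  if (!is.character(lobe)) {
    stop("`lobe` must be a character vector of lobe codes", call. = FALSE)
  }
  idx <- match(lobe, names(LOBE_SEGMENTS))
  if (anyNA(idx)) {
    bad <- unique(lobe[is.na(idx)])
    stop("unknown lobe label(s): ", paste(bad, collapse = ", "),
         " (expected RUL, RML, RLL, LUL, LLL)", call. = FALSE)
  }
  unname(LOBE_SEGMENTS[idx])
}
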