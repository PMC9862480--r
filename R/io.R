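# File formats: NIfTI for volumes (int16 HU, spacing in the header, RAS
# orientation), CSV for cohorts/predictions/reports (comma-separated,
# UTF-8, '.' decimal, mandatory header), JSON for quantification results
# and run manifests. Litre volumes are rounded to 4 decimals on output;
# internal arithmetic stays on exact voxel counts.

read_nifti_3d <- function(path, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop(what, " must be a 3D volume (got ", length(dim(img)), "D): ", path,
         call. = FALSE)
  }
  if (RNifti::orientation(img) != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  img
}

#' Read a CT volume from NIfTI
#'
#' Voxel spacing is taken from the header; the image is reoriented to RAS
#' if stored otherwise.
#'
#' @param path Path to a `.nii` / `.nii.gz` file with 3D integer HU data.
#' @return A [ct_volume].
#' @export
read_ct <- function(path) {
  img <- read_nifti_3d(path, "CT")
  ct_volume(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img))
}

#' Read a lobe label map from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file with integer labels in
#'   0..5.
#' @return A [lobe_label_map].
#' @export
read_lobes <- function(path) {
  img <- read_nifti_3d(path, "lobe label map")
  lobe_label_map(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img))
}

#' Write a CT volume or lobe label map as NIfTI
#'
#' HU volumes are stored as 16-bit signed integers; label maps as 8-bit
#' unsigned. Spacing goes into the header; orientation is RAS.
#'
#' @param x A [ct_volume] or [lobe_label_map].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "ct_volume") || inherits(x, "lobe_label_map"))
  img <- RNifti::asNifti(array(as.integer(x), dim = dim(x)))
  RNifti::pixdim(img) <- spacing_mm(x)
  dtype <- if (inherits(x, "ct_volume")) "int16" else "uint8"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Check that a CT volume and lobe label map are aligned
#' @param ct A [ct_volume].
#' @param lobes A [lobe_label_map].
#' @return Invisibly `TRUE`; errors on shape or spacing mismatch.
#' @export
check_aligned <- function(ct, lobes) {
  if (!identical(dim(ct), dim(lobes))) {
    stop("shape mismatch: CT is ", paste(dim(ct), collapse = "x"),
         ", lobe map is ", paste(dim(lobes), collapse = "x"), call. = FALSE)
  }
  if (max(abs(spacing_mm(ct) - spacing_mm(lobes))) > 1e-6) {
    stop("voxel spacing mismatch between CT and lobe map", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a cohort table as CSV
#'
#' Comma-separated, UTF-8, '.' decimal, one header row; columns as
#' documented in [make_cohort()]. Reading validates the schema and row
#' invariants.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: `path` invisibly; `read_cohort_csv`: the
#'   validated cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_cohort(df)
  df
}

#' Write a density-mask result as JSON or CSV
#'
#' The JSON form carries the per-lobe table, whole-lung totals, %LAA and
#' the settings (WAL window, LAA threshold, noise radius). The CSV form is
#' one row per lobe plus a whole-lung row. Volumes are rounded to 4
#' decimal places.
#'
#' @param result A `density_mask_result` from [quantify_lobes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantification_json <- function(result, path) {
  stopifnot(inherits(result, "density_mask_result"))
  payload <- list(
    wal_window_hu = result$wal_window,
    laa_threshold_hu = result$laa_threshold,
    noise_radius = result$noise_radius,
    voxel_volume_l = result$voxel_volume_l,
    pct_laa = round(result$pct_laa, 4),
    lobes = round_volumes(result$lobes),
    whole_lung = round_volumes(result$total))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_quantification_json
#' @export
write_quantification_csv <- function(result, path) {
  stopifnot(inherits(result, "density_mask_result"))
  df <- rbind(round_volumes(result$lobes), round_volumes(result$total))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

round_volumes <- function(df) {
  for (cl in intersect(c("vol_l", "wal_l", "laa_l"), names(df))) {
    df[[cl]] <- round(df[[cl]], 4)
  }
  df
}

#' Write an agreement report as CSV or JSON
#'
#' @param report An `agreement_report` from [build_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
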