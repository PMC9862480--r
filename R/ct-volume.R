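# CT volumes and lobe label maps are plain 3D arrays carrying a voxel
# spacing attribute (mm per edge, length 3). HU are stored as integers,
# matching 16-bit signed storage on disk.

HU_MIN <- -1024L
HU_MAX <- 3071L

#' Construct a CT volume
#'
#' A CT volume is a 3D integer array of Hounsfield units with a voxel
#' spacing in millimetres. HU must lie in the physical range
#' \[-1024, 3071\].
#'
#' @param values 3D numeric array of HU; coerced to integer (values must
#'   already be whole numbers).
#' @param spacing_mm Numeric length-3 vector of voxel edge lengths in mm,
#'   strictly positive.
#' @return An object of class `ct_volume`: the integer array with a
#'   `spacing_mm` attribute.
#' @export
ct_volume <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L) {
    stop("CT values must be a 3D array", call. = FALSE)
  }
  check_spacing(spacing_mm)
  v <- values
  if (!is.integer(v)) {
    if (any(abs(v - round(v)) > 1e-9)) {
      stop("HU values must be whole numbers", call. = FALSE)
    }
    v <- array(as.integer(round(v)), dim = dim(values))
  }
  rng <- range(v)
  if (rng[1] < HU_MIN || rng[2] > HU_MAX) {
    stop(sprintf("HU outside physical range [%d, %d]", HU_MIN, HU_MAX),
         call. = FALSE)
  }
  structure(v, spacing_mm = as.numeric(spacing_mm), class = "ct_volume")
}

#' Construct a lobe label map
#'
#' @param labels 3D array of integer labels in \{0..5\} (0 background,
#'   1..5 = RUL, RML, RLL, LUL, LLL).
#' @param spacing_mm Voxel spacing in mm (length 3, positive).
#' @return An object of class `lobe_label_map`.
#' @export
lobe_label_map <- function(labels, spacing_mm) {
  if (length(dim(labels)) != 3L) {
    stop("lobe labels must be a 3D array", call. = FALSE)
  }
  check_spacing(spacing_mm)
  lv <- array(as.integer(round(labels)), dim = dim(labels))
  u <- sort(unique(as.vector(lv)))
  if (any(!u %in% 0:5)) {
    stop("unknown lobe label(s): ", paste(setdiff(u, 0:5), collapse = ", "),
         " (labels must be in 0..5)", call. = FALSE)
  }
  structure(lv, spacing_mm = as.numeric(spacing_mm), class = "lobe_label_map")
}

#' Voxel spacing of a volume
#' @param x A `ct_volume` or `lobe_label_map`.
#' @return Numeric length-3 spacing in mm.
#' @export
spacing_mm <- function(x) attr(x, "spacing_mm")

check_spacing <- function(spacing_mm) {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L ||
      any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("voxel spacing must be 3 strictly positive finite numbers (mm)",
         call. = FALSE)
  }
  invisible(spacing_mm)
}

#' Voxel volume in litres
#'
#' Product of the voxel edge lengths (mm^3) converted to litres
#' (1 L = 1e6 mm^3).
#'
#' @param spacing_mm Numeric length-3 voxel spacing in mm, positive.
#' @return Voxel volume in litres.
#' @examples
#' voxel_volume_liters(c(10, 10, 10))     # 0.001 L (1 mL)
#' voxel_volume_liters(c(0.7, 0.7, 1.25)) # 6.125e-7 L
#' @export
voxel_volume_liters <- function(spacing_mm) {
  check_spacing(spacing_mm)
  prod(spacing_mm) * 1e-6
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("CT volume %d x %d x %d voxels, spacing %s mm, HU range [%d, %d]\n",
              d[1], d[2], d[3],
              paste(format(spacing_mm(x)), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.lobe_label_map <- function(x, ...) {
  d <- dim(x)
  tab <- table(factor(as.vector(x), levels = 0:5,
                      labels = c("background", names(LOBE_LABELS))))
  cat(sprintf("Lobe label map %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(spacing_mm(x)), collapse = " x ")))
  print(tab)
  invisible(x)
}
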