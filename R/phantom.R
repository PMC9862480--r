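# Synthetic thoracic phantoms: two ellipsoidal lungs inside a soft-tissue
# body shell, the right lung split axially into RUL/RML/RLL and the left
# into LUL/LLL. Each lobe's voxels are partitioned exactly (floor
# allocation, remainder to the well-aerated compartment) among three HU
# compartments, so the recorded ground truth is exact at voxel level.

# Integer HU intervals per compartment. Emphysema is strictly below
# -950 HU, well-aerated lung (WAL) lies in the closed window
# [-950, -750] HU, non-aerated tissue is strictly above -750 HU.
COMPARTMENT_BOUNDS <- list(
  emphysema  = c(HU_MIN, -951L),
  wal        = c(-950L, -750L),
  nonaerated = c(-749L, HU_MAX)
)

#' Specification of a synthetic CT phantom
#'
#' @param grid_shape Integer length-3 voxel grid size; each axis must be at
#'   least 16 so all five lobes are nonempty.
#' @param spacing_mm Voxel spacing in mm (length 3, positive).
#' @param composition Data frame with columns `lobe`, `f_emph`, `f_wal`,
#'   `f_nonaer`: per-lobe compartment fractions, each row summing to 1
#'   (within 1e-12). Default: no emphysema, 92% well-aerated, 8%
#'   non-aerated in every lobe (a lung with 0% LAA, the modal case in
#'   resection candidates).
#' @param hu_params List with elements `emphysema`, `wal`, `nonaerated`,
#'   each `c(mean, sd)` of the HU draw for that compartment (draws are
#'   rounded to integers and clamped into the compartment's HU interval).
#' @param body_hu Soft-tissue HU of the body shell (default 40).
#' @param background_hu Air HU outside the body (default -1000).
#' @param seed Optional integer seed; fixed seed gives a bit-identical
#'   phantom.
#' @return A `phantom_spec` list.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(2, 2, 2),
                         composition = default_composition(),
                         hu_params = list(emphysema = c(mean = -980, sd = 15),
                                          wal = c(mean = -850, sd = 40),
                                          nonaerated = c(mean = -400, sd = 150)),
                         body_hu = 40L,
                         background_hu = -1000L,
                         seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || anyNA(grid_shape)) {
    stop("`grid_shape` must be 3 integers", call. = FALSE)
  }
  if (any(grid_shape < 16L)) {
    stop("geometry error: grid too small to place 5 nonempty lobes ",
         "(each axis must be >= 16 voxels)", call. = FALSE)
  }
  check_spacing(spacing_mm)
  composition <- validate_composition(composition)
  for (comp in names(COMPARTMENT_BOUNDS)) {
    p <- hu_params[[comp]]
    if (is.null(p) || length(p) != 2L || !is.numeric(p) || p[2] < 0) {
      stop("`hu_params$", comp, "` must be c(mean, sd) with sd >= 0",
           call. = FALSE)
    }
  }
  structure(list(grid_shape = grid_shape,
                 spacing_mm = as.numeric(spacing_mm),
                 composition = composition,
                 hu_params = hu_params,
                 body_hu = as.integer(body_hu),
                 background_hu = as.integer(background_hu),
                 seed = seed),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_composition <- function() {
  data.frame(lobe = names(LOBE_LABELS),
             f_emph = 0,
             f_wal = 0.92,
             f_nonaer = 0.08,
             stringsAsFactors = FALSE)
}

validate_composition <- function(composition) {
  req <- c("lobe", "f_emph", "f_wal", "f_nonaer")
  if (!is.data.frame(composition) || !all(req %in% names(composition))) {
    stop("`composition` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!setequal(composition$lobe, names(LOBE_LABELS)) ||
      nrow(composition) != 5L) {
    stop("`composition` must have exactly one row per lobe (RUL, RML, RLL, LUL, LLL)",
         call. = FALSE)
  }
  fr <- as.matrix(composition[, c("f_emph", "f_wal", "f_nonaer")])
  if (any(fr < 0) || any(fr > 1)) {
    stop("compartment fractions must lie in [0, 1]", call. = FALSE)
  }
  bad <- abs(rowSums(fr) - 1) > 1e-12
  if (any(bad)) {
    stop("compartment fractions must sum to 1 per lobe (off in: ",
         paste(composition$lobe[bad], collapse = ", "), ")", call. = FALSE)
  }
  composition[match(names(LOBE_LABELS), composition$lobe), , drop = FALSE]
}

# Runs `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample HU values for one phantom compartment
#'
#' Draws from a normal distribution truncated to the compartment's HU
#' interval, rounds to integer HU, and clamps back into the interval so the
#' boundary contract survives integer casting: emphysema values are strictly
#' below -950, WAL values lie in \[-950, -750\], non-aerated values are
#' strictly above -750.
#'
#' @param compartment One of `"emphysema"`, `"wal"`, `"nonaerated"`.
#' @param mean,sd Parameters of the underlying normal (HU).
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n` inside the compartment's interval.
#' @export
sample_lobe_hu <- function(compartment, mean, sd, n, seed = NULL) {
  bounds <- COMPARTMENT_BOUNDS[[compartment]]
  if (is.null(bounds)) {
    stop("unknown compartment: ", compartment,
         " (expected emphysema, wal or nonaerated)", call. = FALSE)
  }
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  if (n == 0) return(integer(0))
  with_seed(seed, {
    lo <- bounds[1]; hi <- bounds[2]
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    x <- if (phi - plo < 1e-12) {
      # interval far in the tail of the draw distribution: collapse to the
      # nearest admissible value
      rep(min(max(mean, lo), hi), n)
    } else {
      stats::qnorm(stats::runif(n, plo, phi), mean, sd)
    }
    as.integer(pmin(pmax(round(x), lo), hi))
  })
}

# Lobe label geometry: two ellipsoidal lungs in normalized coordinates,
# right lung (x ~ 0.30) split into three axial slabs (RUL on top, then RML,
# RLL), left lung (x ~ 0.70) into two (LUL over LLL). Returns the integer
# label array plus the body-shell mask.
lobe_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  x <- (seq_len(nx) - 0.5) / nx
  y <- (seq_len(ny) - 0.5) / ny
  z <- (seq_len(nz) - 0.5) / nz

  ellipsoid <- function(cx, ax) {
    dx2 <- ((x - cx) / ax)^2
    dy2 <- ((y - 0.5) / 0.30)^2
    dz2 <- ((z - 0.5) / 0.38)^2
    outer(outer(dx2, dy2, "+"), dz2, "+") < 1
  }
  right <- ellipsoid(0.30, 0.16)
  left  <- ellipsoid(0.70, 0.16)

  zidx <- function(mask) apply(mask, 3, any)
  split_z <- function(mask, n_slabs) {
    zs <- which(zidx(mask))
    cuts <- zs[1] - 1 + (zs[length(zs)] - zs[1] + 1) * seq_len(n_slabs - 1) / n_slabs
    findInterval(seq_len(nz), cuts + 1e-9) + 1L  # slab id per z plane, 1 = bottom
  }

  labels <- array(0L, dim = grid_shape)
  slab_r <- split_z(right, 3L)  # 1 bottom (RLL), 2 mid (RML), 3 top (RUL)
  slab_l <- split_z(left, 2L)   # 1 bottom (LLL), 2 top (LUL)
  map_r <- c(LOBE_LABELS[["RLL"]], LOBE_LABELS[["RML"]], LOBE_LABELS[["RUL"]])
  map_l <- c(LOBE_LABELS[["LLL"]], LOBE_LABELS[["LUL"]])
  for (k in seq_len(nz)) {
    labels[, , k][right[, , k]] <- map_r[slab_r[k]]
    labels[, , k][left[, , k]]  <- map_l[slab_l[k]]
  }

  body_xy <- outer(((x - 0.5) / 0.45)^2, ((y - 0.5) / 0.40)^2, "+") < 1
  body <- array(body_xy, dim = grid_shape) &
    array(rep(z >= 0.08 & z <= 0.92, each = nx * ny), dim = grid_shape)
  list(labels = labels, body = body)
}

#' Generate a synthetic CT phantom with exact compartment ground truth
#'
#' Builds the HU volume, the lobe label map and a ground-truth record of
#' how many voxels of each lobe were assigned to each compartment
#' (emphysema, well-aerated, non-aerated). Assignment is by exact partition
#' of each lobe's voxel list: `floor(n * f_emph)` voxels to emphysema,
#' `floor(n * f_nonaer)` to non-aerated tissue, the remainder to WAL; which
#' voxels get which compartment is randomized under the spec's seed. All
#' ground-truth volumes are voxel counts times the voxel volume, so
#' density-mask quantification (with noise reduction off) recovers them
#' exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `ct` ([ct_volume]), `lobes`
#'   ([lobe_label_map]) and `truth` (a `phantom_truth` list: per-lobe data
#'   frame `lobes` with voxel counts and litre volumes, one-row `total`,
#'   `pct_laa`, and `voxel_volume_l`).
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(24, 24, 24), seed = 1))
#' ph$truth$total
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    geo <- lobe_geometry(spec$grid_shape)
    labels <- geo$labels
    counts_present <- tabulate(labels[labels > 0L], nbins = 5L)
    if (any(counts_present == 0L)) {
      stop("geometry error: empty lobe region(s): ",
           paste(names(LOBE_LABELS)[counts_present == 0L], collapse = ", "),
           call. = FALSE)
    }

    hu <- array(spec$background_hu, dim = spec$grid_shape)
    hu[geo$body] <- spec$body_hu

    per_lobe <- vector("list", 5L)
    for (i in seq_along(LOBE_LABELS)) {
      lobe <- names(LOBE_LABELS)[i]
      idx <- which(labels == LOBE_LABELS[[i]])
      n <- length(idx)
      row <- spec$composition[spec$composition$lobe == lobe, ]
      # guard against binary-representation error in n * fraction before floor
      n_emph <- as.integer(floor(n * row$f_emph + 1e-9))
      n_nonaer <- as.integer(floor(n * row$f_nonaer + 1e-9))
      n_wal <- n - n_emph - n_nonaer
      perm <- sample(idx)
      take <- function(k, from) if (k > 0) perm[from:(from + k - 1)] else integer(0)
      i_emph <- take(n_emph, 1L)
      i_nonaer <- take(n_nonaer, n_emph + 1L)
      i_wal <- take(n_wal, n_emph + n_nonaer + 1L)
      hp <- spec$hu_params
      hu[i_emph] <- sample_lobe_hu("emphysema", hp$emphysema[1], hp$emphysema[2], n_emph)
      hu[i_wal] <- sample_lobe_hu("wal", hp$wal[1], hp$wal[2], n_wal)
      hu[i_nonaer] <- sample_lobe_hu("nonaerated", hp$nonaerated[1], hp$nonaerated[2], n_nonaer)
      per_lobe[[i]] <- data.frame(lobe = lobe, n_voxels = n, n_emph = n_emph,
                                  n_wal = n_wal, n_nonaer = n_nonaer,
                                  stringsAsFactors = FALSE)
    }
    lob <- do.call(rbind, per_lobe)
    vv <- voxel_volume_liters(spec$spacing_mm)
    lob$vol_l <- lob$n_voxels * vv
    lob$wal_l <- lob$n_wal * vv
    lob$laa_l <- lob$n_emph * vv
    lob$n_voxels <- as.integer(lob$n_voxels)
    lob$n_wal <- as.integer(lob$n_wal)
    total <- data.frame(lobe = "whole_lung",
                        n_voxels = sum(lob$n_voxels), n_emph = sum(lob$n_emph),
                        n_wal = sum(lob$n_wal), n_nonaer = sum(lob$n_nonaer),
                        vol_l = sum(lob$vol_l),
                        wal_l = sum(lob$wal_l),
                        laa_l = sum(lob$laa_l),
                        stringsAsFactors = FALSE)
    truth <- structure(list(lobes = lob, total = total,
                            pct_laa = 100 * total$n_emph / total$n_voxels,
                            voxel_volume_l = vv),
                       class = "phantom_truth")
    list(ct = ct_volume(hu, spec$spacing_mm),
         lobes = lobe_label_map(labels, spec$spacing_mm),
         truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("Phantom ground truth (volumes in L):\n")
  print(rbind(x$lobes, x$total), row.names = FALSE)
  cat(sprintf("%%LAA: %.3f%%\n", x$pct_laa))
  invisible(x)
}
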