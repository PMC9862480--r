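# Simulated lobectomy/segmentectomy cohorts. Marginal distributions are
# log-normal, parameterized from median and quartiles of the quantity they
# emulate; measured postoperative values are the WAL-ratio prediction
# perturbed by multiplicative log-normal noise, so sigma = 0 closes the
# loop (prediction == measurement) exactly.

#' Log-normal parameters from median and quartiles
#'
#' Returns `c(meanlog, sdlog)` such that the log-normal has the given
#' median and (approximately) the given interquartile spread:
#' `meanlog = log(median)`, `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#'
#' @param median,q25,q75 Positive quantile targets.
#' @export
lognormal_from_quartiles <- function(median, q25, q75) {
  stopifnot(median > 0, q25 > 0, q75 > q25)
  c(meanlog = log(median), sdlog = log(q75 / q25) / (2 * stats::qnorm(0.75)))
}

#' Specification of a simulated surgical cohort
#'
#' Defaults emulate a typical resected-NSCLC cohort: preoperative FEV1
#' median 2.33 L (IQR 1.68-2.76), %predicted FEV1 median 85% (67-101),
#' %DLCO median 71% (58-83); per-lobe well-aerated-lung volumes with
#' medians RUL 1.20, RML 0.45, RLL 1.42, LUL 1.20, LLL 1.32 L; resection
#' site frequencies RUL 45%, LUL 27%, RLL 12%, LLL 16% (RML resections not
#' represented); segmentectomy in 22% of patients, lobectomy otherwise.
#'
#' @param n_patients Cohort size (>= 2).
#' @param pre_fev1,pre_fev1_pct,pre_dlco `c(meanlog, sdlog)` of the
#'   log-normal marginals for preoperative FEV1 (L), %predicted FEV1 and
#'   %DLCO.
#' @param wal_lobe Named list (RUL, RML, RLL, LUL, LLL) of `c(meanlog,
#'   sdlog)` for per-lobe WAL volumes in litres.
#' @param lobe_probs Named probabilities of the resected lobe; must sum
#'   to 1.
#' @param seg_prob Probability that the resection is a segmentectomy
#'   (fewer than all segments of the lobe removed).
#' @param sigma Standard deviation (log scale) of the multiplicative noise
#'   linking measured postoperative values to the WAL-ratio prediction;
#'   must be >= 0. `sigma = 0` makes measurements equal predictions.
#' @param seed Optional integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 40L,
                        pre_fev1 = lognormal_from_quartiles(2.33, 1.68, 2.76),
                        pre_fev1_pct = lognormal_from_quartiles(85, 67, 101),
                        pre_dlco = lognormal_from_quartiles(71, 58, 83),
                        wal_lobe = list(
                          RUL = lognormal_from_quartiles(1.20, 1.08, 1.33),
                          RML = lognormal_from_quartiles(0.45, 0.39, 0.57),
                          RLL = lognormal_from_quartiles(1.42, 1.11, 1.58),
                          LUL = lognormal_from_quartiles(1.20, 1.06, 1.35),
                          LLL = lognormal_from_quartiles(1.32, 1.12, 1.51)),
                        lobe_probs = c(RUL = 0.45, RML = 0, RLL = 0.12,
                                       LUL = 0.27, LLL = 0.16),
                        seg_prob = 0.22,
                        sigma = 0.12,
                        seed = NULL) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L) {
    stop("`n_patients` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single number >= 0", call. = FALSE)
  }
  if (!setequal(names(lobe_probs), names(LOBE_LABELS)) ||
      any(lobe_probs < 0) || abs(sum(lobe_probs) - 1) > 1e-9) {
    stop("`lobe_probs` must be named over the 5 lobes, nonnegative, summing to 1",
         call. = FALSE)
  }
  if (seg_prob < 0 || seg_prob > 1) {
    stop("`seg_prob` must be in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(wal_lobe), names(LOBE_LABELS))) {
    stop("`wal_lobe` must be a named list over the 5 lobes", call. = FALSE)
  }
  structure(list(n_patients = n_patients, pre_fev1 = pre_fev1,
                 pre_fev1_pct = pre_fev1_pct, pre_dlco = pre_dlco,
                 wal_lobe = wal_lobe,
                 lobe_probs = lobe_probs[names(LOBE_LABELS)] / sum(lobe_probs),
                 seg_prob = seg_prob, sigma = sigma, seed = seed),
            class = "cohort_spec")
}

#' Columns of the cohort table, in order
#' @keywords internal
cohort_columns <- function() {
  c("id", "pre_fev1_l", "pre_fev1_pct", "pre_dlco_pct",
    "wal_rul_l", "wal_rml_l", "wal_rll_l", "wal_lul_l", "wal_lll_l",
    "wal_total_l", "resected_lobe", "segments_resected",
    "post_fev1_l", "post_fev1_pct", "post_dlco_pct")
}

#' Simulate a surgical cohort
#'
#' Draws one row per patient: preoperative pulmonary function, per-lobe WAL
#' volumes, the resected lobe and number of segments resected, and measured
#' postoperative values generated as the WAL-ratio prediction times
#' `exp(eps)`, `eps ~ Normal(0, sigma^2)`. FEV1 in litres and %predicted
#' FEV1 share one noise draw per patient; %DLCO gets an independent draw.
#' For segmentectomies the WAL volume entering the prediction is the lobe's
#' WAL scaled by the fraction of its segments removed.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with the columns of `cohort_columns()`, one row per
#'   patient; deterministic under the spec's seed.
#' @examples
#' coh <- make_cohort(cohort_spec(n_patients = 10, seed = 1))
#' summary(coh$pre_fev1_l)
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    rln <- function(p, m) stats::rlnorm(m, p[["meanlog"]], p[["sdlog"]])
    pre_fev1_l <- rln(spec$pre_fev1, n)
    pre_fev1_pct <- rln(spec$pre_fev1_pct, n)
    pre_dlco_pct <- rln(spec$pre_dlco, n)
    wal <- sapply(names(LOBE_LABELS), function(lb) rln(spec$wal_lobe[[lb]], n))
    wal_total <- rowSums(wal)

    resected <- sample(names(LOBE_LABELS), n, replace = TRUE,
                       prob = spec$lobe_probs)
    nseg <- segments_for_lobe(resected)
    is_seg <- stats::runif(n) < spec$seg_prob & nseg > 1L
    s <- ifelse(is_seg,
                vapply(nseg, function(k) sample.int(k - 1L, 1L), integer(1)),
                nseg)

    wal_lobe_l <- wal[cbind(seq_len(n), match(resected, names(LOBE_LABELS)))]
    wal_used_l <- wal_lobe_l * s / nseg
    eps_fev1 <- stats::rnorm(n, 0, spec$sigma)
    eps_dlco <- stats::rnorm(n, 0, spec$sigma)
    post_fev1_l <- wal_ppo(pre_fev1_l, wal_used_l, wal_total) * exp(eps_fev1)
    post_fev1_pct <- wal_ppo(pre_fev1_pct, wal_used_l, wal_total) * exp(eps_fev1)
    post_dlco_pct <- wal_ppo(pre_dlco_pct, wal_used_l, wal_total) * exp(eps_dlco)

    out <- data.frame(id = sprintf("P%03d", seq_len(n)),
                      pre_fev1_l = pre_fev1_l,
                      pre_fev1_pct = pre_fev1_pct,
                      pre_dlco_pct = pre_dlco_pct,
                      wal_rul_l = wal[, "RUL"], wal_rml_l = wal[, "RML"],
                      wal_rll_l = wal[, "RLL"], wal_lul_l = wal[, "LUL"],
                      wal_lll_l = wal[, "LLL"],
                      wal_total_l = wal_total,
                      resected_lobe = resected,
                      segments_resected = as.integer(s),
                      post_fev1_l = post_fev1_l,
                      post_fev1_pct = post_fev1_pct,
                      post_dlco_pct = post_dlco_pct,
                      stringsAsFactors = FALSE)
    validate_cohort(out)
    out
  })
}

#' Validate a cohort table against the expected schema and invariants
#'
#' Checks column presence, positivity of volumes and PFT values, that the
#' whole-lung WAL equals the sum of lobe WAL volumes (to 1e-9 L), and that
#' `segments_resected` lies between 1 and the resected lobe's segment
#' count. All violations are collected and reported together.
#'
#' @param cohort Data frame to validate.
#' @return The cohort, invisibly, if valid; otherwise an error listing
#'   every violation.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(cohort_columns(), c("id", "resected_lobe"))
  for (cl in num_cols) {
    bad <- which(!is.finite(cohort[[cl]]) | cohort[[cl]] <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("non-positive or missing %s in row(s) %s",
                                      cl, paste(bad, collapse = ",")))
    }
  }
  wal_sum <- cohort$wal_rul_l + cohort$wal_rml_l + cohort$wal_rll_l +
    cohort$wal_lul_l + cohort$wal_lll_l
  bad <- which(abs(wal_sum - cohort$wal_total_l) > 1e-9)
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "wal_total_l != sum of lobe WAL volumes in row(s) %s",
      paste(bad, collapse = ",")))
  }
  known <- cohort$resected_lobe %in% names(LOBE_LABELS)
  if (any(!known)) {
    problems <- c(problems, sprintf("unknown resected_lobe in row(s) %s",
                                    paste(which(!known), collapse = ",")))
  }
  nseg <- rep(NA_integer_, nrow(cohort))
  nseg[known] <- segments_for_lobe(cohort$resected_lobe[known])
  bad <- which(known & (cohort$segments_resected < 1L |
                          cohort$segments_resected > nseg))
  if (length(bad) > 0) {
    problems <- c(problems, sprintf(
      "segments_resected outside 1..lobe segment count in row(s) %s",
      paste(bad, collapse = ",")))
  }
  if (length(problems) > 0) {
    stop("invalid cohort:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cohort)
}
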