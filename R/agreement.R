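# Agreement battery for comparing two measurement methods on paired data:
# Spearman rank correlation, Bland-Altman limits of agreement, two-way
# random-effects absolute-agreement single-measure ICC with F-based 95% CI
# and banded interpretation, and the Wilcoxon signed-rank test (exact by
# enumeration for small samples).

drop_incomplete_pairs <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(a) & is.finite(b)
  list(a = a[ok], b = b[ok])
}

#' Spearman rank correlation with t-approximation p value
#'
#' Computes rho as the Pearson correlation of average (tie-corrected)
#' ranks, with a two-sided p value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with missing values are dropped first.
#'
#' @param a,b Paired numeric vectors (n >= 3 complete pairs).
#' @return List with `rho`, `p`, `n`.
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # rho = 1
#' @export
spearman_rho <- function(a, b) {
  s <- drop_incomplete_pairs(a, b)
  n <- length(s$a)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(s$a) == 0 || stats::sd(s$b) == 0) {
    stop("Spearman rho undefined: constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(s$a), rank(s$b))
  # the attainable rho values are spaced ~ 6/(n(n^2-1)) apart, so anything
  # within 1e-12 of +/-1 is a perfect (anti)ranking up to rounding noise
  if (abs(rho) > 1 - 1e-12) rho <- sign(rho)
  p <- if (abs(rho) >= 1 - 1e-15) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are `a - b`; bias is their mean, `sd` the sample standard
#' deviation (n - 1 denominator), and the limits of agreement are
#' `bias +/- 1.96 * sd` (1.96 literally, not a t quantile).
#'
#' @param a,b Paired numeric vectors (n >= 2 complete pairs).
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`, `n`, plus the
#'   per-pair `differences` and `means` for plotting.
#' @export
bland_altman <- function(a, b) {
  s <- drop_incomplete_pairs(a, b)
  n <- length(s$a)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- s$a - s$b
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, sd = sdd,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       n = n, differences = d, means = (s$a + s$b) / 2)
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (McGraw-Wong ICC(A,1)) from the two-way ANOVA decomposition of the
#' n x 2 table (subjects x methods), with the F-based 95% confidence
#' interval. Unlike a consistency ICC, a constant offset between the two
#' methods lowers this coefficient.
#'
#' @param a,b Paired numeric vectors (n >= 3 complete pairs; n >= 5
#'   recommended for a stable interval).
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `n`, and the mean squares
#'   `ms` of the decomposition.
#' @export
icc_agreement <- function(a, b, conf_level = 0.95) {
  s <- drop_incomplete_pairs(a, b)
  n <- length(s$a)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  k <- 2
  x <- cbind(s$a, s$b)
  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  sst <- sum((x - gm)^2)
  if (sst < 1e-300) {
    stop("ICC undefined: zero total variance", call. = FALSE)
  }
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # catastrophic-cancellation cleanup for (near-)identical methods
  if (icc > 1 - 1e-12) icc <- 1

  alpha <- 1 - conf_level
  if (abs(1 - icc) < 1e-12 || (mse <= 0 && msc <= msr * 1e-15)) {
    ci <- c(icc, icc)
  } else {
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(ci_low, ci_high)
  }
  ci <- pmax(pmin(ci, 1), -1)
  list(icc = icc, ci_low = min(ci[1], icc), ci_high = max(ci[2], icc),
       n = n, ms = c(msr = msr, msc = msc, mse = mse))
}

#' Interpretation band of an ICC value
#'
#' Bands: below 0.40 poor; 0.40-0.54 weak; 0.55-0.69 moderate; 0.70-0.84
#' good; 0.85-1.00 excellent. Band edges belong to the higher band
#' (0.40 is weak, 0.55 moderate, 0.70 good, 0.85 excellent); negative
#' values are poor.
#'
#' @param icc Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @examples
#' interpret_icc(c(0.904, 0.770, 0.39))
#' @export
interpret_icc <- function(icc) {
  if (any(!is.finite(icc)) || any(icc < -1) || any(icc > 1)) {
    stop("`icc` must lie in [-1, 1]", call. = FALSE)
  }
  cut_labels <- c("poor", "weak", "moderate", "good", "excellent")
  as.character(cut(icc, breaks = c(-1, 0.40, 0.55, 0.70, 0.85, 1 + 1e-9),
                   labels = cut_labels, right = FALSE, include.lowest = TRUE))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `a - b`; zero differences are dropped, ties in the absolute
#' differences get average ranks. The statistic is the smaller of the
#' positive- and negative-rank sums. The two-sided p value is exact — by
#' dynamic-programming enumeration over all sign assignments — when the
#' number of nonzero differences is at most `exact_limit`, and uses the
#' normal approximation with tie correction otherwise.
#'
#' @param a,b Paired numeric vectors.
#' @param exact_limit Largest effective n for which the exact distribution
#'   is enumerated (default 25).
#' @return List with `statistic` (min rank sum), `w_plus`, `w_minus`, `p`,
#'   `n` (nonzero differences), `n_zero` (dropped), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  s <- drop_incomplete_pairs(a, b)
  d <- s$a - s$b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    # doubled ranks are integers even with average ranks (.5 steps)
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in dr) {
      f[(ri + 1):(total + 1)] <- f[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
    }
    w2 <- as.integer(round(2 * w))
    p <- min(1, 2 * sum(f[seq_len(w2 + 1)]) / 2^n)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = w, w_plus = w_plus, w_minus = w_minus, p = p,
       n = n, n_zero = n_zero, method = method)
}

#' Full agreement report for a predicted cohort
#'
#' Assembles the six pairwise comparisons of predicted and measured
#' postoperative lung function — WAL vs ASC, WAL vs measured, ASC vs
#' measured, for FEV1 (L) and %DLCO — each with Spearman rho (and p),
#' Bland-Altman bias and limits of agreement, ICC with 95% CI and band
#' label, and the Wilcoxon signed-rank p value. Significance is flagged at
#' p < 0.05 (two-sided, uncorrected). A comparison whose differences are
#' all zero (e.g. a noise-free simulated cohort) gets `NA` for the
#' Wilcoxon entry rather than an error.
#'
#' @param cohort Cohort data frame ([make_cohort()] schema) holding the
#'   measured postoperative values.
#' @param predictions Output of [predict_cohort()] for the same patients.
#' @return An `agreement_report` data frame, one row per comparison, with
#'   columns `comparison`, `n`, `rho`, `rho_p`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `icc`, `icc_ci_low`, `icc_ci_high`, `icc_band`,
#'   `wilcoxon_w`, `wilcoxon_p`, `wilcoxon_method`, `significant`.
#' @export
build_report <- function(cohort, predictions) {
  validate_cohort(cohort)
  if (!all(c("wal_ppo_fev1_l", "asc_ppo_fev1_l") %in% names(predictions))) {
    stop("`predictions` must come from predict_cohort()", call. = FALSE)
  }
  if (nrow(cohort) != nrow(predictions) ||
      !identical(as.character(cohort$id), as.character(predictions$id))) {
    stop("cohort and predictions are not aligned (same patients, same order)",
         call. = FALSE)
  }
  comparisons <- list(
    list(label = "WAL ppo-FEV1 (L) vs. ASC ppo-FEV1 (L)",
         a = predictions$wal_ppo_fev1_l, b = predictions$asc_ppo_fev1_l),
    list(label = "WAL ppo-FEV1 (L) vs. postoperative FEV1 (L)",
         a = predictions$wal_ppo_fev1_l, b = cohort$post_fev1_l),
    list(label = "ASC ppo-FEV1 (L) vs. postoperative FEV1 (L)",
         a = predictions$asc_ppo_fev1_l, b = cohort$post_fev1_l),
    list(label = "WAL ppo-%DLCO vs. ASC ppo-%DLCO",
         a = predictions$wal_ppo_dlco_pct, b = predictions$asc_ppo_dlco_pct),
    list(label = "WAL ppo-%DLCO vs. postoperative %DLCO",
         a = predictions$wal_ppo_dlco_pct, b = cohort$post_dlco_pct),
    list(label = "ASC ppo-%DLCO vs. postoperative %DLCO",
         a = predictions$asc_ppo_dlco_pct, b = cohort$post_dlco_pct))
  rows <- lapply(comparisons, function(cmp) {
    sp <- spearman_rho(cmp$a, cmp$b)
    ba <- bland_altman(cmp$a, cmp$b)
    ic <- icc_agreement(cmp$a, cmp$b)
    wx <- tryCatch(wilcoxon_signed_rank(cmp$a, cmp$b),
                   error = function(e) list(statistic = NA_real_, p = NA_real_,
                                            method = conditionMessage(e)))
    data.frame(comparison = cmp$label, n = sp$n,
               rho = sp$rho, rho_p = sp$p,
               bias = ba$bias, sd_diff = ba$sd,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
               icc_band = interpret_icc(ic$icc),
               wilcoxon_w = wx$statistic, wilcoxon_p = wx$p,
               wilcoxon_method = wx$method,
               significant = !is.na(wx$p) & wx$p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  attr(out, "alpha") <- 0.05
  out
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Agreement analysis (two-sided tests, significance at p < 0.05)\n\n")
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  df <- data.frame(
    comparison = x$comparison,
    `rho (p)` = sprintf("%.3f (%s)", x$rho, fmt_p(x$rho_p)),
    `LoA` = sprintf("%+.2f, %+.2f", x$loa_high, x$loa_low),
    `ICC (95%% CI)` = sprintf("%.3f (%.3f-%.3f)", x$icc, x$icc_ci_low,
                              x$icc_ci_high),
    band = x$icc_band,
    check.names = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
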