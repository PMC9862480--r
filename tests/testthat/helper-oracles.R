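# Independent brute-force reference implementations used as oracles.
# These deliberately use the most naive textbook route (loops, full
# enumeration, aov-derived mean squares) rather than the package's code.

# Spearman rho by the sum-of-squared-rank-differences formula (valid only
# without ties).
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# ICC(A,1) with mean squares taken from stats::aov on the long-format
# two-way layout.
oracle_icc_aov <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subject = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(c("A", "B"), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Bland-Altman by direct formulas.
oracle_bland_altman <- function(a, b) {
  d <- a - b
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  c(bias = m, sd = s, lo = m - 1.96 * s, hi = m + 1.96 * s)
}

# Exact two-sided Wilcoxon signed-rank p by full enumeration over all 2^n
# sign patterns (zeros dropped, average ranks). Only for small n.
oracle_wilcoxon_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * mean(w_all <= w_obs + 1e-9))
}

# Naive triple-loop density-mask count.
oracle_density_count <- function(hu_array, mask, lo, hi) {
  d <- dim(hu_array)
  count <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] && hu_array[i, j, k] >= lo && hu_array[i, j, k] <= hi) {
      count <- count + 1L
    }
  }
  count
}

# Queue-based flood fill counting 26-connected components of a mask.
oracle_component_count <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, dim = d)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  ncomp <- 0L
  for (start in which(mask & !visited)) {
    if (visited[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      idx <- arrayInd(v, d)
      for (o in seq_len(nrow(offsets))) {
        p <- idx + offsets[o, ]
        if (all(p >= 1) && all(p <= d)) {
          lin <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
          if (mask[lin] && !visited[lin]) {
            visited[lin] <- TRUE
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  ncomp
}

# Small helper: random paired vectors with controllable ties.
random_pair <- function(n, ties = FALSE) {
  a <- stats::rnorm(n)
  b <- 0.6 * a + stats::rnorm(n, sd = 0.8)
  if (ties) {
    a <- round(a, 1)
    b <- round(b, 1)
  }
  list(a = a, b = b)
}
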