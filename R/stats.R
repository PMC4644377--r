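#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value is the
#' sum of probabilities of all margin-consistent tables whose probability does
#' not exceed that of the observed table (within a small tolerance guarding
#' floating-point ties), the convention used throughout the pipeline for
#' read-depth and peak-count comparisons between sample groups.
#'
#' @param table 2x2 integer matrix (rows = groups, columns = outcome classes).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 9), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("'table' must be a 2x2 matrix")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be nonnegative integers")
  }
  if (sum(table) == 0) {
    stop("all-zero table")
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Upper-tail binomial probability
#'
#' P(X >= k) for X ~ Binomial(n, p0), the one-sided test used for
#' per-chromosome enrichment of peak sets against a background composition.
#'
#' @param k Observed count (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return Upper-tail probability P(X >= k).
#' @export
binomial_upper_tail <- function(k, n, p0) {
  stopifnot(length(k) == 1L || length(n) == 1L || length(k) == length(n))
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  if (any(p0 <= 0) || any(p0 >= 1)) stop("require 0 < p0 < 1")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment, returned in input order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return q-values, monotone in p.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Paired t-test
#'
#' Two-sided paired t-test on the differences x - y. Identical vectors (all
#' differences zero) return p = 1 by convention rather than erroring.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, and two-sided `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (all(d == 0) || stats::sd(d) == 0 && mean(d) == 0) {
    return(list(t = 0, df = length(d) - 1L, p = 1))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged); the p-value
#' uses the t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2
#' degrees of freedom. An exact permutation p-value is available for n <= 10.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact Use exhaustive permutation of one vector's ranks (n <= 10).
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p only for n <= 10")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

# All permutations of 1..n as a matrix (n! rows); n kept small by callers.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
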