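# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Enumerate all 2x2 tables with the observed margins; two-sided p = sum of
# probabilities <= observed (with a small tolerance against float ties).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Term-by-term binomial upper tail.
oracle_binom_upper <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# Hand step-up BH.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Explicit O/E/V log-rank over distinct event times (group1 observed).
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood (tie-free data) and its analytic score,
# written as an explicit loop over events.
oracle_cox_score <- function(x, time, event, beta) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  g <- rep(0, ncol(x))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    w <- exp(eta[risk])
    g <- g + x[i, ] - colSums(x[risk, , drop = FALSE] * w) / sum(w)
  }
  g
}

# Per-base consensus scan on a small genome: maximal runs of covered bases,
# occupancy = number of samples touching the run. `peaksets` is a list of
# two-column start/end matrices (1-based closed) on one chromosome.
oracle_consensus <- function(peaksets, genome_len, k) {
  cov <- matrix(FALSE, nrow = length(peaksets), ncol = genome_len)
  for (s in seq_along(peaksets)) {
    m <- peaksets[[s]]
    for (i in seq_len(nrow(m))) cov[s, m[i, 1]:m[i, 2]] <- TRUE
  }
  any_cov <- colSums(cov) > 0
  runs <- rle(any_cov)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- NULL
  for (j in which(runs$values)) {
    occ <- sum(apply(cov[, starts[j]:ends[j], drop = FALSE], 1, any))
    if (occ >= k) out <- rbind(out, c(starts[j], ends[j], occ))
  }
  out
}

# Tiny GRanges builder for one-chromosome fixtures.
gr1 <- function(start, end, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}
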