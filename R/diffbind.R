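#' Build a peak count matrix
#'
#' Wraps a region x sample count matrix, its regions and per-sample library
#' sizes in a `SummarizedExperiment` (regions as `rowRanges`, `lib_size` in
#' `colData`), the container consumed by the differential-binding functions.
#'
#' @param counts Integer matrix, regions x samples.
#' @param regions `GRanges` parallel to the rows.
#' @param lib_sizes Per-sample library sizes (>= column sums).
#' @return `RangedSummarizedExperiment` with a `counts` assay.
#' @export
peak_count_matrix <- function(counts, regions, lib_sizes) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(regions)) stop("counts/regions mismatch")
  if (ncol(counts) != length(lib_sizes)) stop("counts/lib_sizes mismatch")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(colSums(counts) > lib_sizes)) {
    stop("library sizes must be >= column sums")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  rownames(counts) <- region_keys(regions)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = regions,
    colData = S4Vectors::DataFrame(lib_size = as.numeric(lib_sizes),
                                   row.names = colnames(counts))
  )
}

#' Count fragments in regions
#'
#' A fragment is counted in a region when its midpoint falls inside the
#' region; with disjoint regions every fragment contributes to at most one
#' region. Library size is the total number of fragments per sample,
#' whether or not they land in a region.
#'
#' @param fragments Named list of `GRanges` (one per sample).
#' @param regions `GRanges` of (disjoint) regions, e.g. consensus peaks.
#' @return A [peak_count_matrix()] `SummarizedExperiment`.
#' @export
count_fragments_in_regions <- function(fragments, regions) {
  if (length(regions) == 0) stop("no regions")
  counts <- vapply(fragments, function(fr) {
    if (length(fr) == 0) return(integer(length(regions)))
    GenomicRanges::countOverlaps(regions, midpoint_granges(fr))
  }, integer(length(regions)))
  empty <- vapply(fragments, length, integer(1)) == 0
  if (any(empty)) {
    warning("empty fragment set(s): ",
            paste(names(fragments)[empty], collapse = ", "))
  }
  if (!is.null(names(fragments))) colnames(counts) <- names(fragments)
  peak_count_matrix(counts, regions,
                    vapply(fragments, length, integer(1)))
}

#' Normalized log2 signal
#'
#' Counts-per-million on the log2 scale with a half-count offset:
#' `y[i, j] = log2((count[i, j] + 0.5) / lib_size_j * 1e6)`. Invariant to
#' jointly doubling counts and library sizes (up to the offset).
#'
#' @param x A [peak_count_matrix()] object, or a count matrix if `lib_sizes`
#'   is given.
#' @param lib_sizes Library sizes when `x` is a bare matrix.
#' @return Real matrix of log2-CPM values.
#' @export
normalize_log_signal <- function(x, lib_sizes = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    lib_sizes <- x$lib_size
  } else {
    counts <- as.matrix(x)
    if (is.null(lib_sizes)) stop("lib_sizes required for a bare matrix")
  }
  log2(sweep(counts + 0.5, 2, lib_sizes, "/") * 1e6)
}

# Moment-matched scaled inverse-chi-square prior for region variances:
# marginally s2_g ~ s0^2 * F(d, d0); matching mean and variance of {s2_g}
# gives closed-form (d0, s0^2). Excess-dispersion-free data -> d0 = Inf.
fit_variance_prior <- function(s2, d) {
  m1 <- mean(s2)
  v <- stats::var(s2)
  if (!is.finite(v) || v <= 0 || m1 <= 0) {
    return(list(d0 = Inf, s02 = max(m1, .Machine$double.eps)))
  }
  r <- v / m1^2
  denom <- r * d - 2
  if (denom <= 0) return(list(d0 = Inf, s02 = m1))
  d0 <- (2 * d - 4 + 4 * r * d) / denom
  list(d0 = d0, s02 = m1 * (d0 - 2) / d0)
}

#' Moderated two-group differential binding test
#'
#' Compares normalized log2 signal between two sample groups per region with
#' empirical-Bayes variance moderation: the pooled within-group variance
#' `s2_g` (d = n_A + n_B - 2 df) is shrunk toward a prior `s0^2` with `d0`
#' prior df estimated by moment-matching a scaled inverse-chi-square
#' distribution to the observed variances, giving
#' `s2_tilde = (d0 s0^2 + d s2_g) / (d0 + d)` and a moderated t on `d + d0`
#' df. Two-sided p-values are Benjamini-Hochberg adjusted; regions with
#' q <= `fdr_threshold` are labeled by the sign of the mean difference.
#'
#' @param x A [peak_count_matrix()] object or a count matrix.
#' @param groups Two-level factor (or vector) over samples; the log2 fold
#'   change is level 2 minus level 1. Each group needs >= 2 samples.
#' @param fdr_threshold Significance threshold on q (default 0.10).
#' @param prior_df Override for `d0`: `0` gives the ordinary t-test, `Inf` a
#'   pooled-variance z-like statistic; `NULL` (default) moment-matches.
#' @param lib_sizes Library sizes when `x` is a bare matrix.
#' @return data.frame: region, mean_A, mean_B, lfc, t_mod, p, q, direction
#'   (`A`, `B` or `ns`), plus attributes `prior_df` and `prior_var`.
#' @export
moderated_differential_test <- function(x, groups, fdr_threshold = 0.10,
                                        prior_df = NULL, lib_sizes = NULL) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be in (0, 1)")
  }
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  nA <- sum(groups == levels(groups)[1])
  nB <- sum(groups == levels(groups)[2])
  if (nA < 2 || nB < 2) stop("each group needs >= 2 samples")
  y <- normalize_log_signal(x, lib_sizes)
  region <- rownames(y)
  if (is.null(region)) region <- as.character(seq_len(nrow(y)))
  ia <- groups == levels(groups)[1]
  ib <- groups == levels(groups)[2]
  mA <- rowMeans(y[, ia, drop = FALSE])
  mB <- rowMeans(y[, ib, drop = FALSE])
  ssA <- rowSums((y[, ia, drop = FALSE] - mA)^2)
  ssB <- rowSums((y[, ib, drop = FALSE] - mB)^2)
  d <- nA + nB - 2
  s2 <- (ssA + ssB) / d
  if (is.null(prior_df)) {
    if (nrow(y) < 10) {
      warning("fewer than 10 regions: prior df unstable, using ordinary t")
      prior <- list(d0 = 0, s02 = 0)
    } else {
      prior <- fit_variance_prior(s2, d)
    }
  } else {
    prior <- list(d0 = prior_df,
                  s02 = if (prior_df > 0) fit_variance_prior(s2, d)$s02 else 0)
  }
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s02, length(s2)) else
    (d0 * prior$s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / nA + 1 / nB))
  lfc <- mB - mA
  tmod <- lfc / se
  df_total <- d + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tmod)) else
    2 * stats::pt(-abs(tmod), df = df_total)
  q <- bh_fdr(p)
  direction <- ifelse(q <= fdr_threshold,
                      ifelse(lfc > 0, levels(groups)[2], levels(groups)[1]),
                      "ns")
  out <- data.frame(region = region, mean_A = mA, mean_B = mB, lfc = lfc,
                    t_mod = tmod, p = p, q = q, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- prior$s02
  out
}

#' Exhaustive label-permutation robustness
#'
#' Enumerates every distinct assignment of the samples into groups of the
#' observed sizes (C(n_A + n_B, n_B) relabelings, including the true one),
#' reruns the moderated differential test for each, and reports the number of
#' significant regions per relabeling together with the rank of the true
#' labeling (1 = most significant regions). A well-powered true labeling
#' should rank first; mislabeled designs should find few or no regions.
#'
#' @inheritParams moderated_differential_test
#' @param max_relabelings Guard on C(n, n_B); larger designs should be
#'   subsampled upstream.
#' @return List: `per_relabeling` data.frame (labeling, n_significant,
#'   is_true), `true_count`, `rank` (ties counted favorably: 1 + number of
#'   relabelings strictly exceeding the true count).
#' @export
permutation_robustness <- function(x, groups, fdr_threshold = 0.10,
                                   prior_df = NULL, lib_sizes = NULL,
                                   max_relabelings = 10000) {
  groups <- as.factor(groups)
  n <- length(groups)
  lev <- levels(groups)
  nB <- sum(groups == lev[2])
  if (choose(n, nB) > max_relabelings) {
    stop("C(n, n_B) = ", choose(n, nB),
         " relabelings exceed the limit; subsample the design")
  }
  combos <- utils::combn(n, nB)
  true_b <- which(groups == lev[2])
  counts <- integer(ncol(combos))
  is_true <- logical(ncol(combos))
  labeling <- character(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    g <- rep(lev[1], n)
    g[combos[, j]] <- lev[2]
    res <- moderated_differential_test(x, factor(g, levels = lev),
                                       fdr_threshold = fdr_threshold,
                                       prior_df = prior_df,
                                       lib_sizes = lib_sizes)
    counts[j] <- sum(res$direction != "ns")
    is_true[j] <- setequal(combos[, j], true_b)
    labeling[j] <- paste(combos[, j], collapse = ",")
  }
  true_count <- counts[is_true]
  list(
    per_relabeling = data.frame(labeling = labeling,
                                n_significant = counts,
                                is_true = is_true,
                                stringsAsFactors = FALSE),
    true_count = true_count,
    rank = 1L + sum(counts > true_count)
  )
}

# Shared correlation-distance average-linkage clustering over rows of `mat`.
correlation_hclust <- function(mat, what = "sample") {
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ", what, "(s): ",
         paste(rownames(mat)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = "average")
}

#' Cluster samples on a region subset
#'
#' Hierarchical clustering of samples on normalized log2 signal over the
#' given regions, with distance 1 - Pearson correlation and average linkage,
#' cut into two groups. Deterministic: ties resolve by sample order.
#'
#' @inheritParams moderated_differential_test
#' @param regions_subset Indices (or region keys) of the rows to use; >= 2.
#' @return List with `hclust` (dendrogram) and `labels` (2-group cut,
#'   named by sample).
#' @export
cluster_samples <- function(x, regions_subset = NULL, lib_sizes = NULL) {
  y <- normalize_log_signal(x, lib_sizes)
  if (!is.null(regions_subset)) y <- y[regions_subset, , drop = FALSE]
  if (nrow(y) < 2) stop("need >= 2 regions to cluster on")
  hc <- correlation_hclust(t(y), what = "sample")
  list(hclust = hc, labels = stats::cutree(hc, k = 2))
}

#' Enrichment-ratio classification of validation samples
#'
#' For each sample, the mean enrichment over primary-tumor-associated regions
#' is divided by the mean over resistance-associated regions; samples with
#' ratio > 1 are called primary-like, the boundary ratio of exactly 1 (and
#' any smaller value) resistant-like. A zero denominator yields +Inf
#' (primary-like) and is flagged.
#'
#' @param enrichment Sample x region matrix of nonnegative enrichment values.
#' @param primary_regions,resistant_regions Column indices or names of the
#'   two region groups; both nonempty.
#' @return data.frame: sample, ratio, label, flagged.
#' @export
enrichment_ratio_classifier <- function(enrichment, primary_regions,
                                        resistant_regions) {
  enrichment <- as.matrix(enrichment)
  if (length(primary_regions) == 0 || length(resistant_regions) == 0) {
    stop("both region lists must be nonempty")
  }
  if (any(enrichment < 0)) stop("enrichment must be >= 0")
  num <- rowMeans(enrichment[, primary_regions, drop = FALSE])
  den <- rowMeans(enrichment[, resistant_regions, drop = FALSE])
  ratio <- ifelse(den == 0, Inf, num / den)
  samples <- rownames(enrichment)
  if (is.null(samples)) samples <- as.character(seq_len(nrow(enrichment)))
  data.frame(sample = samples, ratio = ratio,
             label = ifelse(ratio > 1, "primary-like", "resistant-like"),
             flagged = den == 0, stringsAsFactors = FALSE, row.names = NULL)
}
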