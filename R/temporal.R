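#' Temporal clustering parameters
#'
#' @param c_max Maximum integer level change between consecutive timepoints
#'   in a candidate model profile (default 2).
#' @param m Number of representative profiles kept by greedy max-min
#'   selection (default 50).
#' @param min_change Minimum absolute log-ratio (relative to time 0) a gene
#'   must reach at some timepoint to enter clustering (default 0.5).
#' @param n_permutations Null draws per gene when the exhaustive permutation
#'   null (T! <= 5040) is infeasible.
#' @param alpha Profile significance level, Bonferroni-corrected over `m`.
#' @return List of class `temporal_params`.
#' @export
temporal_params <- function(c_max = 2L, m = 50L, min_change = 0.5,
                            n_permutations = 1000L, alpha = 0.05) {
  if (c_max < 1) stop("c_max must be >= 1")
  if (m < 2) stop("m must be >= 2")
  if (min_change < 0) stop("min_change must be >= 0")
  structure(list(c_max = as.integer(c_max), m = as.integer(m),
                 min_change = min_change,
                 n_permutations = as.integer(n_permutations), alpha = alpha),
            class = "temporal_params")
}

#' Filter genes by minimum expression change
#'
#' A gene is retained when its log-ratio reaches `min_change` in absolute
#' value at some timepoint (difference from the time-0 reference of 0).
#'
#' @param timecourse Gene x timepoint matrix of log-ratios (first column 0).
#' @param params A [temporal_params()] object.
#' @return List with `retained` and `removed` gene-name vectors.
#' @export
filter_min_change <- function(timecourse, params = temporal_params()) {
  timecourse <- as.matrix(timecourse)
  if (any(!is.finite(timecourse))) stop("values must be finite")
  genes <- rownames(timecourse)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(timecourse)))
  keep <- apply(abs(timecourse), 1, max) >= params$min_change
  list(retained = genes[keep], removed = genes[!keep])
}

#' Enumerate candidate model profiles
#'
#' All integer-level profiles over `T` timepoints starting at level 0 with
#' consecutive changes in {-c, ..., +c}: exactly `(2c+1)^(T-1)` profiles, in
#' a deterministic order (steps enumerated lexicographically, earliest
#' timepoint varying slowest).
#'
#' @param n_timepoints Number of timepoints T (>= 2).
#' @param c_max Maximum unit change per step.
#' @return Integer matrix, one profile per row, first column 0; row order is
#'   the profile id.
#' @export
enumerate_candidate_profiles <- function(n_timepoints, c_max = 2L) {
  if (n_timepoints < 2) stop("need at least 2 timepoints")
  steps <- -c_max:c_max
  n_prof <- length(steps)^(n_timepoints - 1)
  if (n_prof > 1e6) {
    stop("(2c+1)^(T-1) = ", n_prof, " exceeds 1e6; reduce c_max")
  }
  grid <- as.matrix(rev(expand.grid(rev(replicate(
    n_timepoints - 1, steps, simplify = FALSE
  )))))
  levels <- if (ncol(grid) > 1) t(apply(grid, 1, cumsum)) else grid
  profiles <- cbind(0L, levels)
  dimnames(profiles) <- list(NULL, NULL)
  storage.mode(profiles) <- "integer"
  profiles
}

# Correlation of each row of `a` with each row of `b`; zero-variance rows
# correlate 0 with everything (flat-profile convention).
row_correlations <- function(a, b) {
  sa <- apply(a, 1, stats::sd)
  sb <- apply(b, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(a), t(b)))
  cc[sa == 0, ] <- 0
  cc[, sb == 0] <- 0
  cc
}

#' Greedy max-min selection of representative profiles
#'
#' Starting from the flat (all-zero) profile, repeatedly adds the candidate
#' maximizing its minimum distance (1 - Pearson correlation of level vectors;
#' correlation with the zero-variance flat profile defined as 0) to the
#' selected set. Ties break by enumeration order, so the selection is fully
#' deterministic.
#'
#' @param candidates Profile matrix from [enumerate_candidate_profiles()].
#' @param m Number of profiles to select (flat profile always included).
#' @return List with `profiles` (m x T matrix) and `ids` (row indices into
#'   `candidates`).
#' @export
select_representative_profiles <- function(candidates, m = 50L) {
  n <- nrow(candidates)
  flat <- which(rowSums(candidates != 0) == 0)
  if (length(flat) != 1) stop("candidates must contain the flat profile once")
  if (m > n) stop("m exceeds the number of candidates")
  selected <- flat
  if (m > 1) {
    # distance to the flat profile is 1 - 0 = 1 for every candidate
    mindist <- rep(1, n)
    mindist[flat] <- -Inf
    for (step in seq_len(m - 1)) {
      nxt <- which.max(mindist)  # ties -> lowest enumeration order
      selected <- c(selected, nxt)
      mindist[nxt] <- -Inf
      d_new <- 1 - drop(row_correlations(candidates,
                                         candidates[nxt, , drop = FALSE]))
      mindist <- pmin(mindist, ifelse(is.infinite(mindist), -Inf, d_new))
    }
  }
  list(profiles = candidates[selected, , drop = FALSE], ids = selected)
}

#' Assign genes to model profiles
#'
#' Each gene goes to the profile maximizing the Pearson correlation between
#' its log-ratio vector and the profile's level vector; zero-variance genes
#' go to the flat profile; ties break by lowest profile index.
#'
#' @param timecourse Gene x timepoint log-ratio matrix.
#' @param profiles Profile matrix (rows = profiles), e.g. from
#'   [select_representative_profiles()].
#' @return Integer vector of profile row indices, named by gene.
#' @export
assign_genes_to_profiles <- function(timecourse, profiles) {
  timecourse <- as.matrix(timecourse)
  flat <- which(rowSums(profiles != 0) == 0)
  cc <- row_correlations(timecourse, profiles)
  assign <- apply(cc, 1, which.max)  # ties -> lowest profile index
  zero_var <- apply(timecourse, 1, stats::sd) == 0
  if (any(zero_var)) {
    if (length(flat) == 0) stop("zero-variance gene but no flat profile")
    assign[zero_var] <- flat
  }
  genes <- rownames(timecourse)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(timecourse)))
  stats::setNames(as.integer(assign), genes)
}

#' Profile enrichment significance
#'
#' Null model: each gene's timepoint order is permuted independently
#' (exhaustively over all T! orders when T! <= 5040, otherwise
#' `n_permutations` seeded draws). The expected count per profile is the
#' mean assigned count under this null; the p-value is the upper tail of
#' Binomial(n_genes, expected / n_genes) at the observed count, Bonferroni
#' corrected over the number of profiles.
#'
#' @inheritParams assign_genes_to_profiles
#' @param assignments Output of [assign_genes_to_profiles()] on the same
#'   matrix and profiles.
#' @param params A [temporal_params()] object.
#' @param seed Seed for the sampled null (ignored when exhaustive).
#' @return data.frame: profile (row index), observed, expected, p_value,
#'   p_bonferroni, significant.
#' @export
profile_significance <- function(assignments, timecourse, profiles,
                                 params = temporal_params(), seed = 1L) {
  timecourse <- as.matrix(timecourse)
  n_genes <- nrow(timecourse)
  tt <- ncol(timecourse)
  m <- nrow(profiles)
  if (factorial(tt) <= 5040) {
    orders <- permutations_of(tt)
  } else {
    set.seed(seed)
    orders <- t(replicate(params$n_permutations, sample.int(tt)))
  }
  null_counts <- numeric(m)
  flat <- which(rowSums(profiles != 0) == 0)
  for (i in seq_len(nrow(orders))) {
    perm_assign <- assign_genes_to_profiles(
      timecourse[, orders[i, ], drop = FALSE], profiles
    )
    tab <- tabulate(perm_assign, nbins = m)
    null_counts <- null_counts + tab
  }
  expected <- null_counts / nrow(orders)
  observed <- tabulate(assignments, nbins = m)
  rate <- pmin(pmax(expected / n_genes, 1e-12), 1 - 1e-12)
  p <- binomial_upper_tail(observed, n_genes, rate)
  p_bonf <- pmin(1, p * m)
  data.frame(profile = seq_len(m), observed = observed, expected = expected,
             p_value = p, p_bonferroni = p_bonf,
             significant = p_bonf <= params$alpha, row.names = NULL)
}

#' Partition genes into up / unaffected / down sets
#'
#' Significant profiles are classed by the sign of their mean level
#' (positive = up-regulated, zero = unaffected, negative = down-regulated),
#' and genes assigned to them inherit the class. Genes removed by the
#' minimum-change filter join the unaffected set (no meaningful response to
#' the stimulus). Genes on non-significant profiles stay unclassified.
#'
#' @inheritParams profile_significance
#' @param significance Output of [profile_significance()].
#' @param filtered_out_genes Genes removed by [filter_min_change()].
#' @return List of gene-name vectors: `up`, `flat`, `down`, `unclassified`.
#' @export
partition_gene_sets <- function(assignments, significance, profiles,
                                filtered_out_genes = character()) {
  mean_level <- rowMeans(profiles)
  class_of <- ifelse(mean_level > 0, "up",
                     ifelse(mean_level < 0, "down", "flat"))
  sig <- significance$profile[significance$significant]
  genes <- names(assignments)
  up <- genes[assignments %in% sig[class_of[sig] == "up"]]
  down <- genes[assignments %in% sig[class_of[sig] == "down"]]
  flat <- genes[assignments %in% sig[class_of[sig] == "flat"]]
  flat <- union(flat, filtered_out_genes)
  unclassified <- setdiff(genes, c(up, down, flat))
  list(up = up, flat = flat, down = down, unclassified = unclassified)
}

#' Run the full temporal partition
#'
#' Convenience wrapper: minimum-change filter, candidate enumeration,
#' representative selection, assignment, permutation significance, and the
#' three-way partition.
#'
#' @param timecourse Gene x timepoint log-ratio matrix (first column 0).
#' @param params A [temporal_params()] object.
#' @param seed Seed for the sampled permutation null.
#' @return List: `sets` (up/flat/down/unclassified), `assignments`,
#'   `significance`, `profiles`, `filter`.
#' @export
temporal_partition <- function(timecourse, params = temporal_params(),
                               seed = 1L) {
  timecourse <- as.matrix(timecourse)
  flt <- filter_min_change(timecourse, params)
  candidates <- enumerate_candidate_profiles(ncol(timecourse), params$c_max)
  m <- min(params$m, nrow(candidates))
  sel <- select_representative_profiles(candidates, m)
  kept <- timecourse[flt$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(sets = list(up = character(), flat = flt$removed,
                            down = character(), unclassified = character()),
                assignments = integer(), significance = NULL,
                profiles = sel$profiles, filter = flt))
  }
  assignments <- assign_genes_to_profiles(kept, sel$profiles)
  significance <- profile_significance(assignments, kept, sel$profiles,
                                       params, seed = seed)
  sets <- partition_gene_sets(assignments, significance, sel$profiles,
                              flt$removed)
  list(sets = sets, assignments = assignments, significance = significance,
       profiles = sel$profiles, filter = flt)
}
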