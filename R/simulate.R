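#' Simulate a per-sample peak landscape
#'
#' Emulates group-structured peak occupancy: shared peaks appear (with
#' per-sample positional jitter) in every sample, group-specific peaks only
#' in their group's samples. Toy gene models are laid out so a configurable
#' fraction of peak slots sit in promoters, gene bodies or distal space,
#' exercising annotation and target-gene assignment downstream. Pure
#' function of its seed.
#'
#' @param n_per_group Integer vector of samples per group, default `c(5, 3)`
#'   (primary vs resistant profiling design).
#' @param n_shared Peaks present in all samples.
#' @param n_group_specific Peaks private to each group (recycled over
#'   groups).
#' @param genome Named chromosome lengths; default one 10-Mb chromosome.
#' @param peak_width Width of every simulated peak (bp).
#' @param jitter_bp Max absolute per-sample positional jitter (bp).
#' @param gene_fraction Fraction of peak slots given an overlapping gene
#'   (promoter or body placement alternates); the rest stay distal.
#' @param seed Random seed.
#' @return List: `peaks` (named list of `GRanges` per sample), `genes`
#'   ([gene_models()]), `groups` (factor per sample), `truth` (slot table).
#' @export
simulate_peak_landscape <- function(n_per_group = c(5L, 3L),
                                    n_shared = 40L,
                                    n_group_specific = 15L,
                                    genome = c(chrSim = 1e7),
                                    peak_width = 400L,
                                    jitter_bp = 20L,
                                    gene_fraction = 0.5,
                                    seed = 1L) {
  set.seed(seed)
  n_groups <- length(n_per_group)
  n_group_specific <- rep_len(n_group_specific, n_groups)
  n_slots <- n_shared + sum(n_group_specific)
  chrom <- names(genome)[1]
  spacing <- floor(genome[[1]] / (n_slots + 1))
  if (spacing < peak_width + 2 * jitter_bp + 1000) {
    stop("genome too small for the requested peaks without forced overlap")
  }
  slot_start <- spacing * seq_len(n_slots)
  slot_kind <- c(rep("shared", n_shared),
                 rep(paste0("group", seq_len(n_groups)), n_group_specific))
  perm <- sample(n_slots)
  slot_kind <- slot_kind[perm]
  samples <- unlist(lapply(seq_len(n_groups), function(g) {
    paste0("g", g, "_s", seq_len(n_per_group[g]))
  }))
  groups <- factor(rep(paste0("group", seq_len(n_groups)), n_per_group))
  names(groups) <- samples
  peaks <- lapply(seq_along(samples), function(si) {
    g <- as.character(groups[si])
    use <- slot_kind == "shared" | slot_kind == g
    jit <- if (jitter_bp > 0) {
      sample(seq(-jitter_bp, jitter_bp), sum(use), replace = TRUE)
    } else 0L
    st <- slot_start[use] + jit
    GenomicRanges::sort(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = st, width = peak_width)
    ))
  })
  names(peaks) <- samples
  # gene layout: alternate promoter-overlapping and body-overlapping genes
  with_gene <- which(seq_len(n_slots) <= round(gene_fraction * n_slots))
  gene_start <- integer(0)
  gene_end <- integer(0)
  gene_strand <- character(0)
  for (i in with_gene) {
    mid <- slot_start[i] + floor(peak_width / 2)
    if (i %% 2 == 0) {       # peak midpoint ~2 kb upstream of a + TSS
      gene_start <- c(gene_start, mid + 2000)
      gene_end <- c(gene_end, mid + 7000)
      gene_strand <- c(gene_strand, "+")
    } else {                 # peak inside the gene body
      gene_start <- c(gene_start, mid - 2000)
      gene_end <- c(gene_end, mid + 3000)
      gene_strand <- c(gene_strand, "+")
    }
  }
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(gene_start, gene_end), strand = gene_strand,
    gene_id = sprintf("SIMG%03d", seq_along(gene_start))
  )
  truth <- data.frame(slot = seq_len(n_slots), start = slot_start,
                      kind = slot_kind, stringsAsFactors = FALSE)
  list(peaks = peaks, genes = gene_models(genes), groups = groups,
       truth = truth)
}

#' Simulate negative-binomial peak counts
#'
#' Counts for each region and sample are drawn negative-binomial with mean
#' `baseline_mean * lib_size / 1e6` and dispersion `dispersion`
#' (variance = mu + dispersion * mu^2). A random subset of `n_diff` regions
#' is differential: group-B means are multiplied by `fold_change` (half of
#' them) or divided by it (the other half), and the planted truth is
#' returned alongside the counts.
#'
#' @param n_regions Number of consensus regions (ignored when `regions` is
#'   given).
#' @param regions Optional `GRanges` to attach the counts to (e.g. a real
#'   consensus set); default is an autogenerated non-overlapping layout.
#' @param groups Two-level factor over samples.
#' @param baseline_mean Expected count at a 1e6 library.
#' @param dispersion NB dispersion (> 0).
#' @param n_diff Number of planted differential regions.
#' @param fold_change Planted fold change (> 0).
#' @param lib_sizes Per-sample library sizes (default 1e6 each).
#' @param seed Random seed.
#' @return List: `counts` (a [peak_count_matrix()]), `truth` (data.frame of
#'   planted region indices and the applied fold change).
#' @export
simulate_counts <- function(n_regions = 2000L, groups,
                            baseline_mean = 50, dispersion = 0.05,
                            n_diff = 0L, fold_change = 4,
                            lib_sizes = NULL, regions = NULL, seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (fold_change <= 0) stop("fold_change must be > 0")
  if (!is.null(regions)) n_regions <- length(regions)
  groups <- as.factor(groups)
  n_samples <- length(groups)
  if (is.null(lib_sizes)) lib_sizes <- rep(1e6, n_samples)
  set.seed(seed)
  diff_idx <- if (n_diff > 0) sort(sample.int(n_regions, n_diff)) else integer()
  fc_applied <- rep(1, n_regions)
  if (n_diff > 0 && fold_change != 1) {
    up <- sample(c(TRUE, FALSE), n_diff, replace = TRUE)
    fc_applied[diff_idx] <- ifelse(up, fold_change, 1 / fold_change)
  }
  is_b <- groups == levels(groups)[2]
  mu <- outer(rep(baseline_mean, n_regions), lib_sizes / 1e6)
  mu[, is_b] <- mu[, is_b] * fc_applied
  counts <- matrix(
    stats::rnbinom(n_regions * n_samples, mu = mu, size = 1 / dispersion),
    nrow = n_regions
  )
  colnames(counts) <- if (!is.null(names(groups))) names(groups) else
    paste0("s", seq_len(n_samples))
  if (is.null(regions)) {
    regions <- GenomicRanges::GRanges(
      "chrSim", IRanges::IRanges(start = 1000 * seq_len(n_regions) + 1,
                                 width = 400)
    )
  }
  truth <- data.frame(region = seq_len(n_regions),
                      differential = seq_len(n_regions) %in% diff_idx,
                      fold_change = fc_applied)
  list(counts = peak_count_matrix(counts, regions,
                                  pmax(lib_sizes, colSums(counts))),
       truth = truth)
}

#' Simulate a short time course with planted temporal classes
#'
#' Up-regulated genes follow a monotone rising log-ratio profile reaching
#' `amplitude` at the last timepoint, down-regulated genes its negation, and
#' unaffected genes are pure noise; the first timepoint is exactly 0 for all
#' genes (log-ratios relative to time 0). Gaussian noise of sd `noise_sd` is
#' added to every later timepoint.
#'
#' @param n_up,n_flat,n_down Genes per planted class.
#' @param n_timepoints Number of timepoints (>= 3).
#' @param amplitude Final log-ratio of the rising profile.
#' @param noise_sd Noise standard deviation.
#' @param seed Random seed.
#' @return List: `timecourse` (gene x timepoint matrix), `truth` (named
#'   class vector: up/flat/down).
#' @export
simulate_timecourse <- function(n_up = 40L, n_flat = 50L, n_down = 10L,
                                n_timepoints = 6L, amplitude = 1,
                                noise_sd = 0.15, seed = 1L) {
  if (n_timepoints < 3) stop("need >= 3 timepoints")
  set.seed(seed)
  ramp <- seq(0, amplitude, length.out = n_timepoints)
  classes <- rep(c("up", "flat", "down"), c(n_up, n_flat, n_down))
  n_genes <- length(classes)
  base <- matrix(0, n_genes, n_timepoints)
  base[classes == "up", ] <- matrix(ramp, sum(classes == "up"),
                                    n_timepoints, byrow = TRUE)
  base[classes == "down", ] <- matrix(-ramp, sum(classes == "down"),
                                      n_timepoints, byrow = TRUE)
  noise <- matrix(stats::rnorm(n_genes * n_timepoints, sd = noise_sd),
                  n_genes, n_timepoints)
  noise[, 1] <- 0
  base[, 1] <- 0
  tc <- base + noise
  rownames(tc) <- sprintf("gene%03d", seq_len(n_genes))
  colnames(tc) <- paste0("t", seq_len(n_timepoints) - 1)
  list(timecourse = tc, truth = stats::setNames(classes, rownames(tc)))
}

#' Simulate an expression + survival cohort
#'
#' Gene expression is standard normal per gene; event times follow an
#' exponential Cox model with hazard
#' `baseline_hazard * exp(sum(beta_i * x_i))` over the planted signature
#' genes, with independent exponential censoring calibrated (by root
#' finding on the marginal censoring probability) to the requested rate.
#' Clinical covariates are drawn independently of expression by default;
#' `clinical_model = "confounded"` ties the Gleason score to the linear
#' predictor to exercise adjusted-hazard analyses.
#'
#' @param n_patients,n_genes Cohort dimensions (defaults emulate a 131-
#'   patient primary-tumor training cohort).
#' @param signature Named numeric vector of true coefficients over a subset
#'   of genes (names like "g3"); `NULL` for a pure-null cohort.
#' @param baseline_hazard Events per month at linear predictor 0.
#' @param censoring_rate Target fraction censored, in [0, 1).
#' @param clinical_model `"independent"` or `"confounded"`.
#' @param seed Random seed.
#' @return List: `expression` (patients x genes, named g1..gN), `time`
#'   (months), `event`, `clinical` (gleason, pT, pN, psa, cT), `truth`
#'   (signature, linear predictor, realized censoring rate).
#' @export
simulate_cohort <- function(n_patients = 131L, n_genes = 100L,
                            signature = NULL, baseline_hazard = 0.01,
                            censoring_rate = 0.8,
                            clinical_model = c("independent", "confounded"),
                            seed = 1L) {
  clinical_model <- match.arg(clinical_model)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)")
  }
  set.seed(seed)
  x <- matrix(stats::rnorm(n_patients * n_genes), n_patients, n_genes)
  colnames(x) <- paste0("g", seq_len(n_genes))
  rownames(x) <- sprintf("pt%03d", seq_len(n_patients))
  eta <- rep(0, n_patients)
  if (!is.null(signature)) {
    if (!all(names(signature) %in% colnames(x))) {
      stop("signature names must be gene columns")
    }
    eta <- drop(x[, names(signature), drop = FALSE] %*% signature)
  }
  rate_event <- baseline_hazard * exp(eta)
  t_event <- stats::rexp(n_patients, rate_event)
  if (censoring_rate > 0) {
    # P(censored | rates) = mean(c / (c + rate_event)); solve for c
    f <- function(cr) mean(cr / (cr + rate_event)) - censoring_rate
    cr <- stats::uniroot(f, c(1e-10, 1e6))$root
    t_cens <- stats::rexp(n_patients, cr)
  } else {
    t_cens <- rep(Inf, n_patients)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  gleason_raw <- if (clinical_model == "confounded") {
    pmin(9, pmax(6, round(7 + scale(eta)[, 1] + stats::rnorm(n_patients, 0, 0.5))))
  } else {
    sample(6:9, n_patients, replace = TRUE, prob = c(0.4, 0.35, 0.15, 0.1))
  }
  clinical <- data.frame(
    gleason = as.integer(gleason_raw),
    pT = sample(c("T2a", "T2b", "T2c", "T3a", "T3b"), n_patients,
                replace = TRUE, prob = c(0.2, 0.2, 0.3, 0.2, 0.1)),
    pN = stats::rbinom(n_patients, 1, 0.1),
    psa = round(exp(stats::rnorm(n_patients, log(8), 0.6)), 1),
    cT = sample(c("T1c", "T2a", "T2b", "T2c"), n_patients,
                replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15)),
    row.names = rownames(x), stringsAsFactors = FALSE
  )
  list(expression = x, time = time, event = event, clinical = clinical,
       truth = list(signature = signature, eta = eta,
                    censoring_rate = mean(event == 0)))
}
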