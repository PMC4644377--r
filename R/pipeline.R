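#' Pipeline configuration
#'
#' Bundles every tunable parameter of the discovery pipeline with its seed.
#' All values are validated against their stated bounds before any stage
#' runs.
#'
#' @param seed Master seed; every stochastic stage derives from it.
#' @param consensus_k Minimum sample occupancy for consensus peaks.
#' @param fdr_threshold Differential-binding FDR threshold, in (0, 1).
#' @param run_permutations Run the exhaustive label-permutation robustness
#'   stage.
#' @param upstream_window_bp Target-gene upstream window (bp).
#' @param n_diff,fold_change,dispersion,baseline_mean Planted differential
#'   signal in the synthetic count stage.
#' @param temporal A [temporal_params()] object.
#' @param train A [train_params()] object.
#' @param n_patients,n_genes,signature,censoring_rate Synthetic cohort shape
#'   (see [simulate_cohort()]); `signature = NULL` plants a default 8-gene
#'   signature.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, consensus_k = 3L,
                            fdr_threshold = 0.10, run_permutations = TRUE,
                            upstream_window_bp = 20000,
                            n_diff = 30L, fold_change = 4,
                            dispersion = 0.05, baseline_mean = 50,
                            temporal = temporal_params(),
                            train = train_params(seed = seed),
                            n_patients = 131L, n_genes = 100L,
                            signature = NULL, censoring_rate = 0.7) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must be in (0, 1)")
  }
  if (consensus_k < 1) stop("consensus_k must be >= 1")
  if (upstream_window_bp < 0) stop("upstream_window_bp must be >= 0")
  if (is.null(signature)) {
    signature <- stats::setNames(
      c(0.9, -0.9, 0.7, -0.7, 0.8, -0.8, 0.6, -0.6),
      paste0("g", 1:8)
    )
  }
  structure(list(seed = as.integer(seed), consensus_k = as.integer(consensus_k),
                 fdr_threshold = fdr_threshold,
                 run_permutations = run_permutations,
                 upstream_window_bp = upstream_window_bp,
                 n_diff = as.integer(n_diff), fold_change = fold_change,
                 dispersion = dispersion, baseline_mean = baseline_mean,
                 temporal = temporal, train = train,
                 n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes), signature = signature,
                 censoring_rate = censoring_rate),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the discovery pipeline on a synthetic bundle
#'
#' End-to-end, deterministic given the config: simulate a peak landscape,
#' build consensus peaks, simulate group-structured counts over them, run
#' the moderated differential test (optionally with exhaustive
#' label-permutation robustness), map significant regions to proximal target
#' genes, partition a simulated androgen time course, and train the
#' nested-CV survival signature on a simulated cohort. Every intermediate
#' table is written to `out_dir` together with a provenance record
#' (parameters, seeds, package version, config hash).
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @return List of stage results: `consensus`, `differential`,
#'   `permutations`, `targets`, `temporal`, `signature`, `provenance`.
#' @export
run_discovery <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  landscape <- simulate_peak_landscape(seed = config$seed)
  consensus <- consensus_peaks(landscape$peaks,
                               min_samples = config$consensus_k)
  sim <- simulate_counts(groups = landscape$groups,
                         baseline_mean = config$baseline_mean,
                         dispersion = config$dispersion,
                         n_diff = config$n_diff,
                         fold_change = config$fold_change,
                         regions = consensus,
                         seed = config$seed + 1L)
  diff <- moderated_differential_test(sim$counts, landscape$groups,
                                      fdr_threshold = config$fdr_threshold)
  perms <- NULL
  if (config$run_permutations) {
    perms <- permutation_robustness(sim$counts, landscape$groups,
                                    fdr_threshold = config$fdr_threshold)
  }
  sig_idx <- which(diff$direction != "ns")
  targets <- assign_peaks_to_genes(
    consensus[sig_idx], landscape$genes,
    annotation_params(upstream_window_bp = config$upstream_window_bp)
  )
  tc <- simulate_timecourse(seed = config$seed + 2L)
  temporal <- temporal_partition(tc$timecourse, config$temporal,
                                 seed = config$seed + 3L)
  cohort <- simulate_cohort(n_patients = config$n_patients,
                            n_genes = config$n_genes,
                            signature = config$signature,
                            censoring_rate = config$censoring_rate,
                            seed = config$seed + 4L)
  expr <- center_expression(cohort$expression)
  signature <- nested_cv_signature(expr, cohort$time, cohort$event,
                                   config$train)
  provenance <- list(package_version = as.character(
    utils::packageVersion("chromsig")
  ), config = unclass(config), config_hash = config_hash(config))
  result <- list(consensus = consensus, counts = sim$counts,
                 differential = diff, permutations = perms,
                 targets = targets, temporal = temporal, cohort = cohort,
                 signature = signature, provenance = provenance)
  if (!is.null(out_dir)) write_discovery_outputs(result, out_dir)
  result
}

write_discovery_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_bed(result$consensus, file.path(out_dir, "consensus_peaks.bed"),
            score_col = "occupancy")
  tsv(result$differential, "differential_binding.tsv")
  if (!is.null(result$permutations)) {
    tsv(result$permutations$per_relabeling, "permutation_robustness.tsv")
  }
  tsv(result$targets$assignments, "peak_gene_assignments.tsv")
  writeLines(result$targets$genes, file.path(out_dir, "target_genes.txt"))
  for (set in c("up", "flat", "down")) {
    writeLines(result$temporal$sets[[set]],
               file.path(out_dir, paste0("temporal_", set, ".txt")))
  }
  tsv(data.frame(patient = names(result$signature$pi),
                 pi = result$signature$pi,
                 risk = result$signature$risk), "prognostic_index.tsv")
  write_signature_model(result$signature$model,
                        file.path(out_dir, "signature_model.json"))
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Validate a signature on an independent cohort
#'
#' Applies a trained [signature_model()] to a validation cohort: prognostic
#' index and risk groups, Kaplan-Meier curves per risk group, log-rank test,
#' time-horizon ROC AUC, a D'Amico cross-tabulation (when clinical T stage,
#' Gleason and PSA are available), and the PCA projection on the signature
#' genes. Errors listing any signature gene absent from the cohort.
#'
#' @param model A [signature_model()].
#' @param cohort List with `expression` (patients x genes), `time`, `event`,
#'   and optionally `clinical` (columns `cT`, `gleason`, `psa`).
#' @param horizon Months for the ROC horizon (default 60).
#' @param out_dir Optional output directory for the TSV/JSON report.
#' @return List: `pi` (data.frame pi/risk), `km` (per risk group),
#'   `logrank`, `auc`, `damico_table`, `pca`.
#' @export
run_validation <- function(model, cohort, horizon = 60, out_dir = NULL) {
  pir <- prognostic_index(cohort$expression, model)
  lr <- logrank_test(cohort$time, cohort$event, pir$risk)
  km <- lapply(split(seq_along(cohort$time), pir$risk), function(idx) {
    km_curve(cohort$time[idx], cohort$event[idx])
  })
  auc <- tryCatch(
    auc_at_horizon(pir$pi, cohort$time, cohort$event, horizon),
    error = function(e) NULL
  )
  damico_table <- NULL
  if (!is.null(cohort$clinical) &&
        all(c("cT", "gleason", "psa") %in% colnames(cohort$clinical))) {
    dam <- damico_classify(cohort$clinical$cT, cohort$clinical$gleason,
                           cohort$clinical$psa)
    damico_table <- table(damico = dam, signature_risk = pir$risk)
  }
  pca <- pca_projection(cohort$expression, model$genes)
  report <- list(pi = pir, km = km, logrank = lr, auc = auc,
                 damico_table = damico_table, pca = pca)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(patient = rownames(pir), pir),
      file.path(out_dir, "validation_pi.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      list(logrank_p = lr$p, auc = if (is.null(auc)) NA else auc$auc,
           n_high = sum(pir$risk == "high"),
           n_low = sum(pir$risk == "low")),
      file.path(out_dir, "validation_report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  report
}
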