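#' Signature training parameters
#'
#' @param alpha Elastic-net mixing (default 0.5).
#' @param inner_folds Inner cross-validation folds (default 10).
#' @param nlambda,lambda_min_ratio Lambda grid: log-spaced values down to
#'   `lambda_min_ratio * lambda_max`.
#' @param risk_threshold Prognostic-index split point (default 0; PI <= 0 is
#'   low risk).
#' @param horizon Months for the time-horizon ROC (default 60).
#' @param seed Seed controlling inner-fold assignment.
#' @return List of class `train_params`.
#' @export
train_params <- function(alpha = 0.5, inner_folds = 10L, nlambda = 100L,
                         lambda_min_ratio = 0.05, risk_threshold = 0,
                         horizon = 60, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  structure(list(alpha = alpha, inner_folds = as.integer(inner_folds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 risk_threshold = risk_threshold, horizon = horizon,
                 seed = as.integer(seed)),
            class = "train_params")
}

#' Nested cross-validated signature training
#'
#' Double-loop scheme: the outer loop is leave-one-out; for each held-out
#' patient the inner loop chooses the elastic-net penalty `lambda_p` by
#' `inner_folds`-fold cross-validated partial-likelihood deviance on the
#' remaining patients, takes the active gene set at `lambda_p`, refits an
#' unpenalized Cox model on that set, and scores the held-out patient's
#' prognostic index with the refit coefficients — so no patient's own data
#' enters its PI. The final model takes the active set at the average of the
#' per-patient lambdas on the full data and refits unpenalized Cox to give
#' the published-style per-gene coefficients.
#'
#' @param expression Patient x gene matrix (centered; see
#'   [center_expression()]).
#' @param time,event Survival outcome.
#' @param params A [train_params()] object.
#' @return List of class `signature_cv`: `pi` (cross-validated prognostic
#'   index per patient), `risk` (low/high from [prognostic_index()]'s rule),
#'   `model` (a `signature_model`), `lambda` (per-patient lambdas),
#'   `lambda_bar`, `empty_folds` (outer folds with empty active sets,
#'   scored PI = 0), `truncated_folds` (folds whose active set exceeded the
#'   event count and was capped at the largest penalized coefficients so the
#'   unpenalized refit stays identifiable).
#' @export
nested_cv_signature <- function(expression, time, event,
                                params = train_params()) {
  x <- as.matrix(expression)
  n <- nrow(x)
  if (n < 30) stop("need >= 30 patients")
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  y_all <- survival::Surv(time, event)
  pi_cv <- numeric(n)
  lambdas <- numeric(n)
  empty <- logical(n)
  truncated <- logical(n)
  # unpenalized refit needs far fewer covariates than events to stay
  # identifiable; keep the strongest penalized coefficients (at most one
  # covariate per three events) when the active set is too rich
  cap_active <- function(active, n_events) {
    limit <- max(1L, floor(n_events / 3))
    if (length(active) > limit) {
      active <- active[order(-abs(active))[seq_len(limit)]]
    }
    active
  }
  # monotone-likelihood folds fall back to the penalized coefficients
  safe_refit <- function(xa, tt, ee, penalized) {
    out <- tryCatch(suppressWarnings(cox_fit(xa, tt, ee))$coefficients,
                    error = function(e) NULL)
    if (is.null(out) || any(abs(out) > 15)) penalized else out
  }
  for (p in seq_len(n)) {
    xt <- x[-p, , drop = FALSE]
    yt <- y_all[-p]
    set.seed(params$seed + p)
    foldid <- sample(rep_len(seq_len(params$inner_folds), n - 1))
    cvfit <- glmnet::cv.glmnet(xt, yt, family = "cox",
                               alpha = params$alpha,
                               type.measure = "deviance",
                               foldid = foldid,
                               nlambda = params$nlambda,
                               lambda.min.ratio = params$lambda_min_ratio)
    lambdas[p] <- cvfit$lambda.min
    active <- active_coefficients(cvfit, s = "lambda.min")
    if (length(active) == 0) {
      empty[p] <- TRUE
      pi_cv[p] <- 0
      next
    }
    capped <- cap_active(active, sum(event[-p]))
    truncated[p] <- length(capped) < length(active)
    active <- capped
    beta <- safe_refit(xt[, names(active), drop = FALSE],
                       time[-p], event[-p], active)
    pi_cv[p] <- sum(beta * x[p, names(active)])
  }
  lambda_bar <- mean(lambdas)
  full <- glmnet::glmnet(x, y_all, family = "cox", alpha = params$alpha,
                         nlambda = params$nlambda,
                         lambda.min.ratio = params$lambda_min_ratio)
  final_active <- active_coefficients(full, s = lambda_bar)
  if (length(final_active) == 0) stop("empty final active set")
  final_active <- cap_active(final_active, sum(event))
  final_beta <- safe_refit(x[, names(final_active), drop = FALSE],
                           time, event, final_active)
  model <- signature_model(genes = names(final_active),
                           coefficients = final_beta,
                           alpha = params$alpha, lambda_bar = lambda_bar,
                           seed = params$seed)
  names(pi_cv) <- rownames(x)
  structure(list(
    pi = pi_cv,
    risk = factor(ifelse(pi_cv <= params$risk_threshold, "low", "high"),
                  levels = c("low", "high")),
    model = model, lambda = lambdas, lambda_bar = lambda_bar,
    empty_folds = which(empty), truncated_folds = which(truncated)
  ), class = "signature_cv")
}

#' Signature model container
#'
#' Selected genes with their (nonzero) Cox coefficients and training
#' metadata; the basis of the prognostic index `PI = sum(beta_i * x_i)`.
#'
#' @param genes Gene labels.
#' @param coefficients Cox coefficients, parallel to `genes`, all nonzero.
#' @param alpha,lambda_bar,seed Training metadata.
#' @return List of class `signature_model`.
#' @export
signature_model <- function(genes, coefficients, alpha = NA_real_,
                            lambda_bar = NA_real_, seed = NA_integer_) {
  if (length(genes) != length(coefficients)) {
    stop("genes and coefficients must be parallel")
  }
  if (any(coefficients == 0)) stop("zero coefficients must not be stored")
  structure(list(genes = as.character(genes),
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                genes),
                 alpha = alpha, lambda_bar = lambda_bar, seed = seed),
            class = "signature_model")
}

#' @exportS3Method base::print
print.signature_model <- function(x, ...) {
  cat("signature_model:", length(x$genes), "genes (alpha =", x$alpha,
      ", lambda_bar =", signif(x$lambda_bar, 4), ")\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Write / read a signature model as JSON
#'
#' @param model A [signature_model()].
#' @param path Output (input) path.
#' @return `path` (write) or the model (read).
#' @export
write_signature_model <- function(model, path) {
  jsonlite::write_json(
    list(genes = model$genes,
         coefficients = as.numeric(model$coefficients),
         alpha = model$alpha, lambda_bar = model$lambda_bar,
         seed = model$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_model(j$genes, j$coefficients, j$alpha, j$lambda_bar, j$seed)
}

#' Prognostic index and risk group
#'
#' `PI = sum(beta_i * x_i)` over the signature genes; patients with PI at or
#' below the threshold (default 0) are low risk, above it high risk.
#'
#' @param expression Patient x gene matrix (or a single named row) containing
#'   every signature gene.
#' @param model A [signature_model()].
#' @param threshold Risk split point (default 0).
#' @return data.frame with `pi` and `risk` per patient.
#' @export
prognostic_index <- function(expression, model, threshold = 0) {
  if (is.null(dim(expression))) {
    expression <- matrix(expression, nrow = 1,
                         dimnames = list(NULL, names(expression)))
  }
  missing <- setdiff(model$genes, colnames(expression))
  if (length(missing) > 0) {
    stop("missing signature gene(s): ", paste(missing, collapse = ", "))
  }
  pi <- drop(expression[, model$genes, drop = FALSE] %*%
               model$coefficients)
  data.frame(
    pi = pi,
    risk = factor(ifelse(pi <= threshold, "low", "high"),
                  levels = c("low", "high")),
    row.names = rownames(expression)
  )
}

# T-stage strings ("T1a".."T4") to an ordinal scale; errors on junk.
t_stage_ordinal <- function(t_stage) {
  levels <- toupper(c("T1", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T2c",
                      "T3", "T3a", "T3b", "T4"))
  t_clean <- toupper(gsub("\\s", "", as.character(t_stage)))
  idx <- match(t_clean, levels)
  if (any(is.na(idx))) {
    stop("unparseable T stage(s): ",
         paste(unique(t_stage[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Multivariate adjustment of the prognostic index
#'
#' Joint Cox fit of the PI with the standard clinical covariates: Gleason
#' score (ordinal), pathologic T stage (ordinal), lymph node status (binary)
#' and log2 pretreatment PSA. Reports the PI's adjusted hazard ratio.
#'
#' @param pi Prognostic index per patient.
#' @param clinical data.frame with columns `gleason`, `pT`, `pN`, `psa`.
#' @param time,event Survival outcome.
#' @return A [cox_fit()] result over (pi, gleason, pT, pN, log2 psa).
#' @export
multivariate_adjustment <- function(pi, clinical, time, event) {
  need <- c("gleason", "pT", "pN", "psa")
  if (!all(need %in% colnames(clinical))) {
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  }
  covs <- cbind(
    pi = pi,
    gleason = as.numeric(clinical$gleason),
    t_stage = t_stage_ordinal(clinical$pT),
    node = as.numeric(clinical$pN),
    log2_psa = log2(as.numeric(clinical$psa))
  )
  cox_fit(covs, time, event)
}

#' ROC AUC at a time horizon
#'
#' Cases are patients with an event within the horizon; controls are
#' patients followed event-free beyond it; patients censored before the
#' horizon without an event are excluded. The AUC is the Mann-Whitney
#' probability that a case's score exceeds a control's, ties counted 1/2 —
#' invariant under any strictly increasing transform of the score.
#'
#' @param score Risk score (e.g. prognostic index), higher = riskier.
#' @param time,event Survival outcome (months).
#' @param horizon Months (default 60).
#' @return List with `auc`, `n_cases`, `n_controls`, `n_excluded`.
#' @export
auc_at_horizon <- function(score, time, event, horizon = 60) {
  case <- event == 1 & time <= horizon
  control <- time > horizon
  excluded <- !(case | control)
  if (sum(case) == 0 || sum(control) == 0) {
    stop("need at least one case and one control within the horizon")
  }
  r <- rank(c(score[case], score[control]))
  n1 <- sum(case)
  n0 <- sum(control)
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, n_cases = n1, n_controls = n0,
       n_excluded = sum(excluded))
}

#' D'Amico clinical risk classification
#'
#' Standard three-group stratification from clinical T stage, biopsy Gleason
#' score and pretreatment PSA: high risk if cT >= T2c or Gleason >= 8 or
#' PSA > 20 ng/ml; otherwise intermediate if cT = T2b or Gleason = 7 or
#' 10 <= PSA <= 20; otherwise low.
#'
#' @param clinical_t Clinical T stage strings (e.g. "T1c", "T2b").
#' @param gleason Biopsy Gleason scores.
#' @param psa Pretreatment PSA (ng/ml).
#' @return Factor with levels low, intermediate, high.
#' @export
damico_classify <- function(clinical_t, gleason, psa) {
  ord <- t_stage_ordinal(clinical_t)
  t2b <- t_stage_ordinal("T2b")
  t2c <- t_stage_ordinal("T2c")
  high <- ord >= t2c | gleason >= 8 | psa > 20
  inter <- !high & (ord == t2b | gleason == 7 | (psa >= 10 & psa <= 20))
  out <- ifelse(high, "high", ifelse(inter, "intermediate", "low"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' PCA projection on a gene set
#'
#' Principal-component scores of the centered gene-set submatrix. The sign
#' of each component is fixed by making its largest-magnitude loading
#' positive, so projections are reproducible.
#'
#' @param expression Patient x gene matrix (>= 3 patients).
#' @param gene_set Genes to project on (>= 2 present).
#' @param n_components Number of components (default 2).
#' @return List with `scores` (patients x components) and `loadings`.
#' @export
pca_projection <- function(expression, gene_set, n_components = 2L) {
  present <- intersect(gene_set, colnames(expression))
  if (length(present) < 2) stop("need >= 2 genes present")
  if (nrow(expression) < 3) stop("need >= 3 samples")
  mat <- expression[, present, drop = FALSE]
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  list(scores = scores, loadings = rot)
}
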