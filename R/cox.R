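#' Center an expression matrix
#'
#' Averages multiple probes per gene (when a probe-to-gene map is given) and
#' centers each gene column to mean zero.
#'
#' @param expression Patient x probe (or gene) numeric matrix.
#' @param gene_of Optional character vector mapping columns to gene ids;
#'   columns sharing a gene are averaged first.
#' @return Patient x gene matrix with zero column means.
#' @export
center_expression <- function(expression, gene_of = NULL) {
  expression <- as.matrix(expression)
  if (any(!is.finite(expression))) stop("expression must be finite")
  if (!is.null(gene_of)) {
    if (length(gene_of) != ncol(expression)) {
      stop("gene_of must map every column")
    }
    genes <- unique(gene_of)
    expression <- vapply(genes, function(g) {
      rowMeans(expression[, gene_of == g, drop = FALSE])
    }, numeric(nrow(expression)))
    colnames(expression) <- genes
  }
  sweep(expression, 2, colMeans(expression), "-")
}

#' Cluster patients on a gene set
#'
#' Hierarchical clustering of patients with distance 1 - Pearson correlation
#' over the gene subset, average linkage, cut into two groups. Signature
#' genes absent from the matrix are dropped with a warning.
#'
#' @param expression Patient x gene matrix.
#' @param gene_set Genes to cluster on (>= 2 present).
#' @return List with `hclust` and `labels` (2-group cut, named by patient).
#' @export
cluster_patients <- function(expression, gene_set) {
  present <- intersect(gene_set, colnames(expression))
  if (length(present) < length(gene_set)) {
    warning("dropping genes absent from the matrix: ",
            paste(setdiff(gene_set, present), collapse = ", "))
  }
  if (length(present) < 2) stop("need >= 2 genes present")
  mat <- expression[, present, drop = FALSE]
  hc <- correlation_hclust(mat, what = "patient")
  list(hclust = hc, labels = stats::cutree(hc, k = 2))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function. With every subject
#' censored the estimate is identically 1 and the result is flagged.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return data.frame with columns time, n_risk, n_event, surv (right-
#'   continuous, non-increasing, S(0) = 1); attribute `all_censored`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  out <- out[out$n_event > 0, , drop = FALSE]  # steps at event times
  rownames(out) <- NULL
  attr(out, "all_censored") <- sum(event) == 0
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic `(sum(O - E))^2 / sum(V)` over event times,
#' referred to a chi-square distribution with 1 df.
#'
#' @param time,event Survival outcome.
#' @param groups Two-level grouping, each level with >= 1 subject.
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2) stop("exactly two non-empty groups required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit with Efron tie handling; standard
#' errors from the observed information, hazard ratios with 95% Wald
#' confidence intervals.
#'
#' @param covariates Numeric matrix or data.frame (no constant column).
#' @param time,event Survival outcome (events >= number of covariates).
#' @return List of class `cox_fit`: coefficients, se, hr, ci_lower,
#'   ci_upper, loglik, n_events, plus the underlying `coxph` fit.
#' @export
cox_fit <- function(covariates, time, event) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant covariate(s): ",
         paste(colnames(x)[apply(x, 2, stats::sd) == 0], collapse = ", "))
  }
  if (sum(event) < ncol(x)) stop("fewer events than covariates")
  df <- data.frame(x, check.names = FALSE)
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta))) stop("Cox fit did not converge (monotone likelihood?)")
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(x)),
    se = stats::setNames(as.numeric(se), colnames(x)),
    hr = exp(as.numeric(beta)),
    ci_lower = exp(as.numeric(beta) - 1.96 * as.numeric(se)),
    ci_upper = exp(as.numeric(beta) + 1.96 * as.numeric(se)),
    loglik = fit$loglik[2],
    n_events = sum(event),
    fit = fit
  ), class = "cox_fit")
}

#' @exportS3Method base::print
print.cox_fit <- function(x, ...) {
  cat("Cox fit (Efron ties),", x$n_events, "events\n")
  print(data.frame(coef = x$coefficients, se = x$se, HR = x$hr,
                   lower95 = x$ci_lower, upper95 = x$ci_upper))
  invisible(x)
}

#' Elastic-net penalized Cox coefficient path
#'
#' Fits the penalized partial likelihood
#' `-(1/n) pl(beta) + lambda * sum(alpha |beta_j| + (1 - alpha) beta_j^2 / 2)`
#' over a decreasing log-spaced lambda grid (covariates standardized
#' internally, coefficients reported on the original scale).
#'
#' @param covariates Numeric matrix (patients x genes).
#' @param time,event Survival outcome.
#' @param alpha Elastic-net mixing in (0, 1], default 0.5.
#' @param lambda Optional explicit lambda grid; otherwise `nlambda`
#'   log-spaced values down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and lower endpoint ratio.
#' @param thresh Coordinate-descent convergence threshold.
#' @return List of class `enet_cox_path`: lambda, beta (genes x lambda,
#'   sparse), df (active-set size per lambda), and the `glmnet` fit.
#' @export
elastic_net_cox_path <- function(covariates, time, event, alpha = 0.5,
                                 lambda = NULL, nlambda = 100,
                                 lambda_min_ratio = 0.05, thresh = 1e-16) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  x <- as.matrix(covariates)
  y <- survival::Surv(time, event)
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                        lambda = lambda, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        thresh = thresh)
  structure(list(lambda = fit$lambda, beta = fit$beta, df = fit$df,
                 alpha = alpha, fit = fit), class = "enet_cox_path")
}

#' Active set at a penalty value
#'
#' @param path An [elastic_net_cox_path()] object (or `glmnet`/`cv.glmnet`).
#' @param s Penalty value lambda.
#' @return Named coefficient vector of the nonzero entries at `s`.
#' @export
active_coefficients <- function(path, s) {
  fit <- if (inherits(path, "enet_cox_path")) path$fit else path
  cf <- as.matrix(stats::coef(fit, s = s))
  nz <- cf[, 1] != 0
  stats::setNames(cf[nz, 1], rownames(cf)[nz])
}

# Breslow partial-likelihood gradient of the scaled glmnet Cox objective
# (1/n) d pl / d beta, used for KKT verification on tie-free data.
cox_gradient <- function(x, time, event, beta) {
  n <- nrow(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(time)
  xo <- x[ord, , drop = FALSE]
  wo <- w[ord]
  eo <- event[ord]
  # suffix cumulative sums over the risk set (time >= t_i)
  rev_cum <- function(v) rev(cumsum(rev(v)))
  s0 <- rev_cum(wo)
  s1 <- apply(xo * wo, 2, rev_cum)
  g <- colSums(xo[eo == 1, , drop = FALSE]) -
    colSums(s1[eo == 1, , drop = FALSE] / s0[eo == 1])
  g / n
}

#' Check elastic-net KKT conditions along a path
#'
#' For each lambda: active coefficients must satisfy the stationarity
#' equation and inactive ones the subgradient bound
#' `|(1/n) grad_j| <= lambda * alpha`. Gradients use the Breslow partial
#' likelihood on internally standardized covariates (tie-free data assumed).
#'
#' @inheritParams elastic_net_cox_path
#' @param path An [elastic_net_cox_path()] object fitted on the same data.
#' @return Numeric vector of the maximum KKT violation per lambda.
#' @export
check_kkt <- function(path, covariates, time, event) {
  x <- as.matrix(covariates)
  n <- nrow(x)
  # glmnet standardizes with 1/n variance
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  alpha <- path$alpha
  vapply(seq_along(path$lambda), function(k) {
    lam <- path$lambda[k]
    beta_s <- as.numeric(path$beta[, k]) * scl  # standardized-scale coefs
    g <- cox_gradient(xs, time, event, beta_s)
    active <- beta_s != 0
    viol_active <- if (any(active)) {
      max(abs(g[active] - lam * (alpha * sign(beta_s[active]) +
                                   (1 - alpha) * beta_s[active])))
    } else 0
    viol_inactive <- if (any(!active)) {
      max(0, max(abs(g[!active])) - lam * alpha)
    } else 0
    max(viol_active, viol_inactive)
  }, numeric(1))
}
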