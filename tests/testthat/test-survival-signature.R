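test_that("expression centering averages probes and is idempotent", {
  m <- cbind(a = c(1, 2, 3))
  expect_equal(unname(center_expression(m)[, 1]), c(-1, 0, 1))
  centered <- center_expression(m)
  expect_equal(center_expression(centered), centered)
  probes <- cbind(p1 = c(1, 3), p2 = c(3, 5))
  out <- center_expression(probes, gene_of = c("G", "G"))
  expect_equal(unname(out[, "G"]), c(-1, 1))  # averaged (2,4) then centered
})

test_that("Kaplan-Meier estimate matches hand computations", {
  # no censoring: empirical survival function
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$surv[km$time == 2], 0.5)
  # single censored patient
  km1 <- km_curve(5, 0)
  expect_true(all(km1$surv == 1))
  expect_true(attr(km1, "all_censored"))
  # six-patient worked table: events at 2 (1/6), 4 (1/4), censored 3, 5
  time <- c(2, 3, 4, 5, 6, 7)
  event <- c(1, 0, 1, 0, 1, 1)
  km6 <- km_curve(time, event)
  s <- cumprod(c(1 - 1 / 6, 1 - 1 / 4, 1 - 1 / 2, 1 - 1))
  expect_equal(km6$surv, s)
})

test_that("log-rank test matches the O/E/V oracle and is symmetric", {
  time <- c(3, 5, 7, 9, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  grp <- rep(c("x", "y"), each = 4)
  res <- logrank_test(time, event, grp)
  want <- oracle_logrank(time, event, grp)
  expect_equal(res$chisq, want$chisq, tolerance = 1e-9)
  expect_equal(res$p, want$p, tolerance = 1e-9)
  expect_equal(logrank_test(time, event, rev(grp))$chisq, res$chisq,
               tolerance = 1e-9)
  # identical groups: statistic 0, p 1
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                       rep(c("x", "y"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
})

test_that("log-rank matches the oracle on an exhaustive small-sample
           fixture suite", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    time <- sample(1:20, n)  # distinct times
    event <- rbinom(n, 1, 0.7)
    grp <- c("x", "y", sample(c("x", "y"), n - 2, replace = TRUE))
    if (sum(event[grp == "x"]) + sum(event[grp == "y"]) == 0) next
    res <- logrank_test(time, event, grp)
    want <- oracle_logrank(time, event, grp)
    expect_equal(res$chisq, want$chisq, tolerance = 1e-9)
  }
})

test_that("Cox fit recovers planted coefficients and sits at a stationary
           point of the partial likelihood", {
  errs <- vapply(1:10, function(s) {
    ch <- simulate_cohort(n_patients = 2000, n_genes = 3,
                          signature = c(g1 = 0.7), censoring_rate = 0.3,
                          seed = s)
    fit <- cox_fit(ch$expression[, "g1", drop = FALSE], ch$time, ch$event)
    fit$coefficients - 0.7
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.1)
  # bias over replicates stays small at larger n
  bias <- mean(vapply(1:10, function(s) {
    ch <- simulate_cohort(n_patients = 5000, n_genes = 2,
                          signature = c(g1 = 0.7), censoring_rate = 0.3,
                          seed = 40 + s)
    cox_fit(ch$expression[, "g1", drop = FALSE], ch$time,
            ch$event)$coefficients - 0.7
  }, numeric(1)))
  expect_lt(abs(bias), 0.05)
  # analytic score at beta-hat vanishes
  ch <- simulate_cohort(n_patients = 300, n_genes = 3,
                        signature = c(g1 = 0.5, g2 = -0.5),
                        censoring_rate = 0.3, seed = 99)
  x <- ch$expression[, 1:3]
  fit <- cox_fit(x, ch$time, ch$event)
  score <- oracle_cox_score(x, ch$time, ch$event, fit$coefficients)
  expect_lt(sqrt(sum(score^2)), 1e-6)
  expect_equal(fit$hr, exp(unname(fit$coefficients)))
  expect_true(all(fit$ci_lower < fit$ci_upper))
})

test_that("Cox fit rejects degenerate designs and null covariates stay
           within 3 SE of zero", {
  ch <- simulate_cohort(n_patients = 800, n_genes = 2, signature = NULL,
                        censoring_rate = 0.3, seed = 5)
  fit <- cox_fit(ch$expression[, "g1", drop = FALSE], ch$time, ch$event)
  expect_lt(abs(unname(fit$coefficients)), 3 * unname(fit$se))
  expect_error(cox_fit(matrix(1, 10, 1), 1:10, rep(1, 10)), "constant")
})

test_that("elastic-net Cox path: penalty limit, cox_fit equivalence at
           lambda 0, KKT along the path, strong covariate enters first", {
  set.seed(81)
  n <- 300; p <- 25
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("g", 1:p)))
  beta <- c(1, rep(0, p - 1))
  t_ev <- rexp(n, 0.01 * exp(x %*% beta))
  t_cn <- rexp(n, 0.004)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  path <- elastic_net_cox_path(x, time, event, alpha = 0.5)
  # all-zero at the top of the path
  expect_equal(path$df[1], 0)
  # KKT within tolerance everywhere
  expect_lt(max(check_kkt(path, x, time, event)), 1e-7)
  # strongest covariate activates first
  first_nz <- apply(as.matrix(path$beta) != 0, 1, function(r) {
    if (any(r)) which(r)[1] else Inf
  })
  expect_equal(names(which.min(first_nz)), "g1")
  # lambda -> 0 limit equals the unpenalized fit
  grid <- c(exp(seq(log(0.5), log(1e-4), length.out = 50)), 0)
  path0 <- elastic_net_cox_path(x, time, event, alpha = 0.5, lambda = grid)
  bz <- as.numeric(path0$beta[, length(path0$lambda)])
  cf <- cox_fit(x, time, event)
  expect_equal(bz, unname(cf$coefficients), tolerance = 1e-4)
})

test_that("nested CV recovers planted signature genes, stratifies risk,
           and computes PI without the held-out patient", {
  planted <- stats::setNames(c(0.9, -0.9, 0.8, -0.8, 0.7, -0.7, 0.6, -0.6),
                             paste0("g", 1:8))
  ch <- simulate_cohort(n_patients = 120, n_genes = 40, signature = planted,
                        censoring_rate = 0.3, seed = 301)
  expr <- center_expression(ch$expression)
  cv <- nested_cv_signature(expr, ch$time, ch$event,
                            train_params(seed = 301))
  hits <- intersect(cv$model$genes, names(planted))
  expect_gte(length(hits), 6)
  expect_true(all(sign(cv$model$coefficients[hits]) ==
                    sign(planted[hits])))
  lr <- logrank_test(ch$time, ch$event, cv$risk)
  expect_lt(lr$p, 0.01)
  expect_equal(length(cv$lambda), 120)
  expect_equal(cv$lambda_bar, mean(cv$lambda))
})

test_that("prognostic index applies the boundary and bilinearity rules", {
  model <- signature_model(c("a", "b"), c(0.5, -1))
  res <- prognostic_index(c(a = 2, b = 1), model)
  expect_equal(res$pi, 0)
  expect_equal(as.character(res$risk), "low")  # PI = 0 is low risk
  res0 <- prognostic_index(c(a = 0, b = 0), model)
  expect_equal(as.character(res0$risk), "low")
  # negating both coefficients and expressions leaves PI unchanged
  neg_model <- signature_model(c("a", "b"), c(-0.5, 1))
  expect_equal(prognostic_index(c(a = -2, b = -1), neg_model)$pi, res$pi)
  expect_error(prognostic_index(c(a = 1), model), "missing.*b")
})

test_that("multivariate adjustment shrinks a confounded PI and preserves an
           independent one", {
  ch <- simulate_cohort(n_patients = 600, n_genes = 10,
                        signature = c(g1 = 0.8), censoring_rate = 0.3,
                        seed = 88)
  pi_v <- ch$expression[, "g1"] * 0.8
  marg <- cox_fit(cbind(pi = pi_v), ch$time, ch$event)
  adj <- multivariate_adjustment(pi_v, ch$clinical, ch$time, ch$event)
  expect_lt(abs(adj$coefficients["pi"] - marg$coefficients["pi"]), 0.15)
  # confounded: gleason tracks the linear predictor
  chc <- simulate_cohort(n_patients = 600, n_genes = 10,
                         signature = c(g1 = 0.8), censoring_rate = 0.3,
                         clinical_model = "confounded", seed = 89)
  pic <- chc$expression[, "g1"] * 0.8
  margc <- cox_fit(cbind(pi = pic), chc$time, chc$event)
  adjc <- multivariate_adjustment(pic, chc$clinical, chc$time, chc$event)
  expect_lt(adjc$coefficients["pi"], margc$coefficients["pi"])
  # constant clinical covariates are rejected
  const_clin <- ch$clinical
  const_clin$gleason <- 7
  const_clin$pT <- "T2a"
  const_clin$pN <- 0
  const_clin$psa <- 10
  expect_error(multivariate_adjustment(pi_v, const_clin, ch$time, ch$event),
               "constant")
})

test_that("horizon AUC is the Mann-Whitney concordance and a rank
           statistic", {
  time <- c(10, 20, 90, 100, 30, 80)
  event <- c(1, 1, 0, 0, 0, 1)
  score <- c(5, 4, 1, 2, 3, 6)
  res <- auc_at_horizon(score, time, event, horizon = 60)
  # cases: patients 1,2 (events <= 60); controls: 3,4,6 (beyond 60);
  # patient 5 censored early -> excluded
  expect_equal(res$n_cases, 2)
  expect_equal(res$n_controls, 3)
  expect_equal(res$n_excluded, 1)
  # concordant pairs: scores (5,4) vs (1,2,6) -> 4 of 6
  expect_equal(res$auc, 4 / 6)
  # invariance under strictly increasing transform
  expect_equal(auc_at_horizon(exp(score), time, event, 60)$auc, res$auc)
  # perfect separation
  expect_equal(auc_at_horizon(c(9, 9, 0, 0, 0, 0),
                              c(10, 20, 90, 100, 95, 80),
                              c(1, 1, 0, 0, 0, 0), 60)$auc, 1)
  skip_if_not_installed("pROC")
  labels <- c(1, 1, 0, 0, 0)
  sc <- c(5, 4, 1, 2, 6)
  got <- auc_at_horizon(sc, c(10, 20, 90, 100, 80), c(1, 1, 0, 0, 0), 60)
  want <- as.numeric(pROC::auc(pROC::roc(labels, sc, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got$auc, want)
})

test_that("null scores give AUC near one half", {
  set.seed(91)
  n <- 2000
  time <- rexp(n, 0.01); event <- rbinom(n, 1, 0.8)
  score <- rnorm(n)
  res <- auc_at_horizon(score, time, event, 60)
  expect_lt(abs(res$auc - 0.5), 0.03)
})

test_that("D'Amico classification implements the published thresholds", {
  expect_equal(as.character(damico_classify("T1c", 6, 5)), "low")
  expect_equal(as.character(damico_classify("T2a", 7, 6)), "intermediate")
  expect_equal(as.character(damico_classify("T2b", 6, 5)), "intermediate")
  expect_equal(as.character(damico_classify("T1c", 6, 12)), "intermediate")
  expect_equal(as.character(damico_classify("T2a", 6, 25)), "high")
  expect_equal(as.character(damico_classify("T2c", 6, 5)), "high")
  expect_equal(as.character(damico_classify("T1c", 9, 4)), "high")
  expect_error(damico_classify("banana", 6, 5), "unparseable")
})

test_that("patient clustering separates planted populations and is
           equivariant to relabeling", {
  set.seed(92)
  n <- 40
  genes <- paste0("g", 1:10)
  profile <- c(rep(2, 5), rep(-2, 5))
  # anti-correlated patient profiles across the gene set
  x <- rbind(matrix(profile, 20, 10, byrow = TRUE),
             matrix(-profile, 20, 10, byrow = TRUE)) +
    matrix(rnorm(n * 10, sd = 0.5), n)
  colnames(x) <- genes
  rownames(x) <- paste0("p", 1:n)
  cl <- cluster_patients(x, genes)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:40])), 1)
  expect_true(cl$labels[1] != cl$labels[21])
  expect_warning(cluster_patients(x, c(genes, "missing_gene")), "absent")
  perm <- sample(n)
  cl2 <- cluster_patients(x[perm, ], genes)
  agree <- mean((cl$labels[perm] == cl$labels[perm][1]) ==
                  (cl2$labels == cl2$labels[1]))
  expect_equal(agree, 1)
})

test_that("PCA projection separates planted groups with a fixed sign
           convention", {
  set.seed(93)
  x <- rbind(matrix(rnorm(15 * 6), 15), matrix(rnorm(15 * 6, mean = 3), 15))
  colnames(x) <- paste0("g", 1:6)
  pc <- pca_projection(x, paste0("g", 1:6))
  expect_gte(var(pc$scores[, 1]), var(pc$scores[, 2]))
  expect_true(abs(mean(pc$scores[1:15, 1]) - mean(pc$scores[16:30, 1])) > 2)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  # invariant to per-gene constant shifts
  shifted <- sweep(x, 2, 1:6, "+")
  pc2 <- pca_projection(shifted, paste0("g", 1:6))
  expect_equal(pc$scores, pc2$scores, tolerance = 1e-9)
})

test_that("signature model JSON round-trips", {
  model <- signature_model(c("DNER", "XBP1"), c(0.4, -0.3), alpha = 0.5,
                           lambda_bar = 0.12, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(model, path)
  back <- read_signature_model(path)
  expect_equal(back$genes, model$genes)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$lambda_bar, model$lambda_bar)
  expect_error(signature_model("a", 0), "zero")
})
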