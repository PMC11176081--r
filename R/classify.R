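#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' AUC = U / (n1 * n0) with ties counted as half-wins, computed from the
#' rank-sum of case scores.
#'
#' @param scores numeric classifier scores.
#' @param labels BD/HC labels (BD is the positive class) or logicals.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "BD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_validation("both classes must be present")
  r <- rank(scores)  # midranks handle ties (0.5 per tied pair)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nagelkerke pseudo R-squared of a univariate logistic regression
#'
#' Fits diagnosis ~ predictor by maximum likelihood and rescales the
#' Cox-Snell R^2: R2_CS = 1 - (L0/L1)^(2/N), R2_N = R2_CS / (1 - L0^(2/N)).
#'
#' @param labels BD/HC labels or 0/1.
#' @param predictor numeric predictor (e.g. SI score or a probability).
#' @return Nagelkerke R^2 on the observed scale.
#' @export
nagelkerke_r2 <- function(labels, predictor) {
  y <- if (is.numeric(labels)) labels else as.numeric(labels == "BD")
  if (length(unique(y)) < 2L) stop_validation("both classes must be present")
  fit <- suppressWarnings(stats::glm(y ~ predictor, family = stats::binomial()))
  n <- length(y)
  ll1 <- -fit$deviance / 2
  ll0 <- -fit$null.deviance / 2
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

#' Liability-scale conversion of an observed-scale R-squared
#'
#' Lee et al. (2012) transformation for ascertained case-control samples:
#' with t the liability threshold at population prevalence K, z the normal
#' density at t and m = z/K,
#' C = K(1-K)/z^2 * K(1-K)/(P(1-P)) and
#' theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t);
#' R2_liab = C R2 / (1 + C theta R2).
#'
#' @param r2 observed-scale (Nagelkerke) R^2.
#' @param K population prevalence (default 0.02 for bipolar disorder).
#' @param P case fraction in the sample.
#' @return liability-scale R^2.
#' @export
liability_r2 <- function(r2, K = 0.02, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) {
    stop_validation("K and P must lie in (0, 1)")
  }
  if (r2 < 0) stop_validation("r2 must be non-negative")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  C * r2 / (1 + C * theta * r2)
}

#' Diagnostic-performance report for a per-individual metric
#'
#' The three tests applied to every classification metric: a two-sided
#' Wilcoxon rank-sum test of case-control difference, the AUC, and the
#' Nagelkerke R^2 of a univariate logistic regression, both on the observed
#' scale and converted to the liability scale at the assumed population
#' prevalence.
#'
#' @param score per-individual metric (SI score or predicted probability).
#' @param diagnosis BD/HC labels.
#' @param prevalence population prevalence K for the liability conversion.
#' @param metric metric name carried into the report.
#' @return one-row data.frame: metric, n_bd, n_hc, p, auc, r2_nagelkerke,
#'   r2_liability, prevalence.
#' @export
si_performance <- function(score, diagnosis, prevalence = 0.02,
                           metric = "metric") {
  bd <- diagnosis == "BD"
  p <- suppressWarnings(
    stats::wilcox.test(score[bd], score[!bd], exact = FALSE,
                       correct = TRUE)$p.value)
  a <- auc(score, diagnosis)
  r2 <- nagelkerke_r2(diagnosis, score)
  r2l <- liability_r2(r2, K = prevalence, P = mean(bd))
  data.frame(metric = metric, n_bd = sum(bd), n_hc = sum(!bd), p = p,
             auc = a, r2_nagelkerke = r2, r2_liability = r2l,
             prevalence = prevalence, stringsAsFactors = FALSE)
}

#' Cross-cohort predicted probabilities of diagnosis
#'
#' For the target cohort, fits a maximum-likelihood logistic regression of
#' diagnosis on the per-gene standardised residuals (relative level: sWSR;
#' absolute level: HC-standardised residualised expression) using the pooled
#' samples of all *other* cohorts, then predicts probabilities for the
#' target cohort. Gene sets are intersected across cohorts first. Perfect
#' separation (or non-convergence) falls back to a weak ridge fit with a
#' logged warning.
#'
#' @param matrices named list, one entry per cohort, each an individuals x
#'   genes matrix of standardised residuals. `si_fit` objects are accepted
#'   and contribute their sWSR.
#' @param diagnoses named list of BD/HC label vectors aligned with the rows
#'   of each matrix (taken from the fits when omitted).
#' @param target name of the cohort to predict.
#' @param ridge_lambda penalty used by the separation fallback.
#' @return list of class `si_probs`: `probabilities` (named vector for the
#'   target cohort), `diagnosis`, `genes_used`, `coefficients`, `target`,
#'   `separation_fallback`.
#' @export
cross_cohort_probabilities <- function(matrices, diagnoses = NULL, target,
                                       ridge_lambda = 1e-3) {
  mats <- lapply(matrices, function(m) {
    if (inherits(m, "si_fit")) m$sWSR else as.matrix(m)
  })
  if (is.null(diagnoses)) {
    diagnoses <- lapply(matrices, function(m) {
      if (inherits(m, "si_fit")) m$diagnosis else
        stop_validation("diagnoses must be supplied for matrix input")
    })
  }
  if (!(target %in% names(mats))) stop_validation("unknown target cohort")
  if (length(mats) < 3L) {
    stop_validation("need at least two training cohorts besides the target")
  }
  genes <- Reduce(intersect, lapply(mats, colnames))
  if (length(genes) < 2L) stop_validation("gene intersection too small")
  train_names <- setdiff(names(mats), target)
  xtr <- do.call(rbind, lapply(train_names,
                               function(nm) mats[[nm]][, genes, drop = FALSE]))
  ytr <- as.numeric(unlist(lapply(train_names, function(nm)
    diagnoses[[nm]] == "BD")))
  # leakage audit: the target cohort must not contribute training rows
  if (any(rownames(mats[[target]]) %in% rownames(xtr))) {
    stop("target cohort contributes to its own training data")
  }
  xte <- mats[[target]][, genes, drop = FALSE]

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, xtr), ytr, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # quasi-separation can slip past glm's warnings: enormous coefficients or
  # degenerate fitted probabilities are treated the same way
  mu <- fit$fitted.values
  if (!sep && (any(!is.finite(fit$coefficients)) ||
               max(abs(fit$coefficients[-1])) > 10 ||
               all(mu < 1e-6 | mu > 1 - 1e-6))) {
    sep <- TRUE
  }
  if (sep || !fit$converged) {
    warning("separation or non-convergence; refitting with a weak ridge")
    rf <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                         lambda = ridge_lambda)
    coefs <- c(`(Intercept)` = as.numeric(rf$a0),
               stats::setNames(as.numeric(rf$beta), genes))
  } else {
    coefs <- stats::setNames(fit$coefficients, c("(Intercept)", genes))
  }
  eta <- as.numeric(cbind(1, xte) %*% coefs)
  probs <- stats::setNames(stats::plogis(eta), rownames(xte))
  structure(list(probabilities = probs,
                 diagnosis = diagnoses[[target]],
                 genes_used = genes, coefficients = coefs, target = target,
                 separation_fallback = sep),
            class = "si_probs")
}

#' @export
print.si_probs <- function(x, ...) {
  cat("Cross-cohort diagnosis probabilities for", x$target, ":",
      length(x$probabilities), "samples,", length(x$genes_used),
      "genes", if (x$separation_fallback) "(ridge fallback)" else "", "\n")
  invisible(x)
}

#' Pooled per-gene logistic coefficients
#'
#' Logistic regression of diagnosis against the standardised residuals of
#' all genes, fitted on all cohorts pooled; used to rank genes by their
#' effect on the predicted probability.
#'
#' @inheritParams cross_cohort_probabilities
#' @return data.frame gene, coefficient, se, z, p, ordered by p.
#' @export
pooled_gene_coefficients <- function(matrices, diagnoses = NULL) {
  mats <- lapply(matrices, function(m) {
    if (inherits(m, "si_fit")) m$sWSR else as.matrix(m)
  })
  if (is.null(diagnoses)) {
    diagnoses <- lapply(matrices, function(m) {
      if (inherits(m, "si_fit")) m$diagnosis else
        stop_validation("diagnoses must be supplied for matrix input")
    })
  }
  genes <- Reduce(intersect, lapply(mats, colnames))
  x <- do.call(rbind, lapply(mats, function(m) m[, genes, drop = FALSE]))
  y <- as.numeric(unlist(diagnoses) == "BD")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  sm <- sm[-1, , drop = FALSE]
  out <- data.frame(gene = genes, coefficient = sm[, 1], se = sm[, 2],
                    z = sm[, 3], p = sm[, 4], stringsAsFactors = FALSE)
  out[order(out$p), ]
}
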