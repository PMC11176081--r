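#' Resampling plan for control-based gene modelling
#'
#' Draws `iterations` modelling subsets of size `model_size` from the
#' reference (modelling) samples, uniformly without replacement. In every
#' iteration the implied test set is everyone not in the modelling subset,
#' so no individual is ever scored by a model it helped fit. With
#' `ensure_coverage = TRUE` (default) the plan is deterministically repaired
#' so that every reference sample is left out at least once, which small
#' iteration counts on lopsided splits cannot otherwise guarantee.
#'
#' @param controls character vector of reference sample ids.
#' @param model_size number of samples per modelling subset.
#' @param iterations number of resampling iterations.
#' @param seed plan seed.
#' @param ensure_coverage repair the plan so each reference id is tested.
#' @return object of class `si_plan`.
#' @export
make_plan <- function(controls, model_size, iterations, seed = 1L,
                      ensure_coverage = TRUE) {
  n <- length(controls)
  if (model_size >= n) {
    stop_validation("model_size must be smaller than the number of controls")
  }
  if (iterations < 1L) stop_validation("iterations must be >= 1")
  model_sets <- with_seed(seed, {
    lapply(seq_len(iterations), function(k) sort(sample(controls, model_size)))
  })
  if (ensure_coverage) {
    model_sets <- repair_coverage(model_sets, controls)
  }
  structure(list(model_sets = model_sets, controls = controls,
                 model_size = model_size, iterations = iterations,
                 seed = seed),
            class = "si_plan")
}

# Deterministic repair: for each reference sample that appears in every
# modelling subset, remove it from one subset and promote the most-covered
# held-out sample of that subset in its place. When full coverage is
# arithmetically impossible (too few held-out slots) the plan is returned
# unchanged with a warning; downstream aggregation will refuse to score a
# never-held-out individual.
repair_coverage <- function(model_sets, controls) {
  slots <- length(model_sets) *
    (length(controls) - length(model_sets[[1]]))
  if (slots < length(controls)) {
    warning("plan cannot hold out every reference sample; ",
            "increase iterations to score all controls")
    return(model_sets)
  }
  repeat {
    test_count <- vapply(controls, function(id) {
      sum(!vapply(model_sets, function(m) id %in% m, logical(1)))
    }, numeric(1))
    uncovered <- controls[test_count == 0]
    if (length(uncovered) == 0L) return(model_sets)
    id <- uncovered[1]
    # choose the iteration whose held-out set has the most redundancy
    best_k <- 0L; best_d <- NULL; best_cov <- -1
    for (k in seq_along(model_sets)) {
      held <- setdiff(controls, model_sets[[k]])
      held <- held[test_count[held] > 1]
      if (length(held)) {
        d <- held[order(-test_count[held], held)][1]
        if (test_count[d] > best_cov) {
          best_cov <- test_count[d]; best_k <- k; best_d <- d
        }
      }
    }
    if (best_k == 0L) {
      stop_validation("cannot repair plan coverage; increase iterations")
    }
    m <- model_sets[[best_k]]
    model_sets[[best_k]] <- sort(c(setdiff(m, id), best_d))
  }
}

#' @export
print.si_plan <- function(x, ...) {
  cat("Resampling plan:", x$iterations, "iterations, modelling",
      x$model_size, "of", length(x$controls), "reference samples\n")
  invisible(x)
}

#' Published per-cohort resampling plans
#'
#' The model/test splits of control samples and iteration counts used for
#' the four cortical cohorts: CMC-HBCC 94/71 (100), CMC-Pitt 69/23 (100),
#' BrainGVEX-SMRI 67/8 (1000), BipSeq-sACC 93/47 (100).
#'
#' @param name cohort name.
#' @return list with `model_size` and `iterations`.
#' @export
published_plan <- function(name = c("CMC-HBCC", "CMC-Pitt", "BrainGVEX-SMRI",
                                    "BipSeq-sACC")) {
  name <- match.arg(name)
  switch(name,
         "CMC-HBCC" = list(model_size = 94L, iterations = 100L),
         "CMC-Pitt" = list(model_size = 69L, iterations = 100L),
         "BrainGVEX-SMRI" = list(model_size = 67L, iterations = 1000L),
         "BipSeq-sACC" = list(model_size = 93L, iterations = 100L))
}

# LASSO path + 10-fold cross-validation with the one-standard-error rule.
# Covariate columns (penalty factor 0) are never shrunk. A lean loop around
# single glmnet path calls: one full-data path fixes the lambda grid, each
# fold refits on that grid, and lambda is the largest value whose CV error
# is within one SE of the minimum.
lasso_cv_1se <- function(x, y, penalty_factor, nfolds = 10, nlambda = 100,
                         lambda_min_ratio = 0.02, thresh = 1e-7,
                         seed = NULL) {
  fit0 <- glmnet::glmnet(x, y, penalty.factor = penalty_factor,
                         nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio, thresh = thresh)
  lam <- fit0$lambda
  n <- nrow(x)
  nfolds <- min(nfolds, n)
  foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  errs <- matrix(NA_real_, n, length(lam))
  for (f in unique(foldid)) {
    idx <- foldid == f
    ff <- glmnet::glmnet(x[!idx, , drop = FALSE], y[!idx],
                         penalty.factor = penalty_factor, lambda = lam,
                         thresh = thresh)
    if (length(ff$lambda) == 0L) next
    pred <- as.matrix(x[idx, , drop = FALSE] %*% ff$beta)
    pred <- sweep(pred, 2, as.numeric(ff$a0), "+")
    errs[idx, seq_len(ncol(pred))] <- (y[idx] - pred)^2
  }
  cvm <- colMeans(errs, na.rm = TRUE)
  # grouped-by-fold standard error (the cv.glmnet convention): variance of
  # per-fold mean errors, weighted by fold size, over nfolds - 1
  fold_n <- rowsum((!is.na(errs)) * 1, foldid)
  fold_means <- rowsum(errs, foldid, na.rm = TRUE) / pmax(fold_n, 1)
  nf_eff <- nrow(fold_means)
  fw <- as.numeric(table(foldid))
  dev2 <- (fold_means - matrix(cvm, nf_eff, length(lam), byrow = TRUE))^2
  cvsd <- sqrt(apply(dev2, 2, stats::weighted.mean, w = fw, na.rm = TRUE) /
                 (nf_eff - 1))
  i_min <- which.min(cvm)
  i_1se <- which(cvm <= cvm[i_min] + cvsd[i_min])[1]  # lam is decreasing
  beta <- fit0$beta[, i_1se]
  a0 <- fit0$a0[i_1se]
  fitted0 <- as.numeric(x %*% beta) + a0
  list(beta = beta, a0 = a0, lambda = lam[i_1se], lambda_path = lam,
       cvm = cvm, cvsd = cvsd, fitted = fitted0, foldid = foldid)
}

#' Fit one gene's expression model on a modelling subset
#'
#' Models the target gene's log2 RPKM as a LASSO-penalised linear function
#' of all other genes in the set plus the clinical covariates (unpenalised),
#' fitted on the modelling samples only. The penalty is chosen by 10-fold
#' cross-validation with the one-standard-error rule. The reported R^2 is
#' the squared correlation of fitted and observed values on the modelling
#' subset.
#'
#' @param expr genes x samples log2 RPKM matrix (gene set rows only).
#' @param covars samples x covariates numeric design (no intercept).
#' @param target target gene id (row of `expr`).
#' @param model_ids sample ids of the modelling subset.
#' @param nfolds,nlambda,lambda_min_ratio,thresh tuning of the CV/LASSO path.
#' @param seed fold seed.
#' @param min_model_size minimal allowed modelling subset.
#' @return list of class `si_gene_model`: coefficients, `lambda`, `r2`,
#'   `target`, and a `predict` closure over new samples.
#' @export
fit_gene_model <- function(expr, covars, target, model_ids,
                           nfolds = 10, nlambda = 100,
                           lambda_min_ratio = 0.02, thresh = 1e-7,
                           seed = NULL, min_model_size = 20) {
  if (length(model_ids) < min_model_size) {
    stop_validation("modelling subset below the minimal size")
  }
  y <- expr[target, model_ids]
  if (stats::sd(y) == 0) {
    stop_validation(paste("constant target gene", target,
                          "on the modelling subset"),
                    class = "stoichsi_constant_target")
  }
  # canonical (sorted) predictor order: coordinate descent is then
  # independent of the storage order of the expression matrix
  others <- sort(setdiff(rownames(expr), target))
  xm <- cbind(t(expr[others, model_ids, drop = FALSE]),
              covars[model_ids, , drop = FALSE])
  pf <- c(rep(1, length(others)), rep(0, ncol(covars)))
  cv <- lasso_cv_1se(xm, y, pf, nfolds = nfolds, nlambda = nlambda,
                     lambda_min_ratio = lambda_min_ratio, thresh = thresh,
                     seed = seed)
  r2 <- suppressWarnings(stats::cor(cv$fitted, y)^2)
  if (is.na(r2)) r2 <- 0
  structure(list(target = target, beta = cv$beta, a0 = cv$a0,
                 lambda = cv$lambda, r2 = r2, predictors = others),
            class = "si_gene_model")
}

#' @export
predict.si_gene_model <- function(object, expr, covars, ids, ...) {
  xm <- cbind(t(expr[object$predictors, ids, drop = FALSE]),
              covars[ids, , drop = FALSE])
  as.numeric(xm %*% object$beta) + object$a0
}

#' Weighted scaled residual (single gene, iteration and individuals)
#'
#' wsr = R2 * (observed - predicted) / gene mean, where the gene mean is the
#' mean observed log2 RPKM of the gene across all individuals in the
#' dataset (cases and controls alike).
#'
#' @param y_obs observed values.
#' @param y_pred predicted values.
#' @param r2 the model's R^2 in that iteration.
#' @param gene_mean mean observed value of the gene across all individuals.
#' @return numeric vector of weighted scaled residuals.
#' @export
compute_wsr <- function(y_obs, y_pred, r2, gene_mean) {
  if (gene_mean == 0) {
    stop_validation("zero gene mean; gene must be excluded")
  }
  r2 * (y_obs - y_pred) / gene_mean
}

#' Average weighted scaled residuals across qualifying iterations
#'
#' Per (individual, gene): the mean of wsr over exactly the iterations in
#' which that individual was not part of the modelling subset. Individuals
#' never held out are a plan violation.
#'
#' @param wsr 3-d array individuals x genes x iterations (NA where the
#'   individual was in the modelling subset).
#' @param in_model logical matrix individuals x iterations, TRUE when the
#'   individual was in the modelling subset.
#' @return individuals x genes matrix of iteration-averaged residuals.
#' @export
aggregate_wsr <- function(wsr, in_model) {
  n_used <- rowSums(!in_model)
  if (any(n_used == 0)) {
    stop_validation("an individual was modelled in every iteration")
  }
  out <- apply(wsr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  dimnames(out) <- dimnames(wsr)[1:2]
  out
}

#' Per-individual stoichiometric imbalance score
#'
#' The mean absolute standardised weighted scaled residual across genes.
#'
#' @param swsr individuals x genes matrix of standardised residuals, or a
#'   single individual's vector.
#' @return numeric vector of SI scores (one per individual).
#' @export
si_score <- function(swsr) {
  if (is.null(dim(swsr))) return(mean(abs(swsr)))
  rowMeans(abs(swsr))
}

#' Fit the stoichiometric-imbalance model to a cohort
#'
#' The central fitting routine. For each resampling iteration a LASSO model
#' of every gene is fitted on the modelling subset (controls by default);
#' weighted scaled residuals of all held-out individuals are averaged across
#' qualifying iterations, standardised against the reference group, and
#' aggregated into a per-individual SI score. Strict model/test separation
#' is asserted on every iteration.
#'
#' @param x an `si_prep` object (from [preprocess_cohort()]) or a genes x
#'   samples log2 RPKM matrix.
#' @param samples validated sample metadata (ignored when `x` is `si_prep`,
#'   which carries its own).
#' @param genes optional character vector restricting the gene set.
#' @param mode `model_on_controls` (default), `model_on_cases` (the
#'   case-modelling control analysis, scaled by case mean/sd), or
#'   `hc_split_null` (controls split in two, one half modelled and scored
#'   against the other; a negative-control analysis).
#' @param iterations,model_size resampling plan parameters (defaults:
#'   2/3 of the reference group, 100 iterations).
#' @param plan an explicit [make_plan()] object overriding the above.
#' @param seed master seed for the plan and CV folds.
#' @param nfolds,nlambda,lambda_min_ratio,thresh LASSO/CV tuning; reduce
#'   `nlambda` for a coarser, faster penalty path.
#' @param keep_iterations retain the full per-iteration wsr array (memory
#'   heavy; for diagnostics and equivalence checks).
#' @param min_model_size minimal allowed modelling subset.
#' @return object of class `si_fit`; see Details.
#' @details The returned object contains `WSR` and `sWSR` (individuals x
#'   genes), `si` (named per-individual score), `r2` (genes x iterations),
#'   `diagnosis` (the labels used for scaling and testing; pseudo-labels in
#'   `hc_split_null` mode, where held-out first-half controls are "HC" and
#'   second-half controls are "BD"), `plan`, `mode`, `gene_means`,
#'   `dropped_genes` and `n_iterations_used`.
#' @export
si_fit <- function(x, samples = NULL, genes = NULL,
                   mode = c("model_on_controls", "model_on_cases",
                            "hc_split_null"),
                   iterations = 100L, model_size = NULL, plan = NULL,
                   seed = 1L, nfolds = 10, nlambda = 100,
                   lambda_min_ratio = 0.02, thresh = 1e-7,
                   keep_iterations = FALSE, min_model_size = 20) {
  mode <- match.arg(mode)
  if (inherits(x, "si_prep")) {
    samples <- x$samples
    expr <- x$log2_rpkm
  } else {
    expr <- as.matrix(x)
    if (is.null(samples)) stop_validation("samples metadata is required")
  }
  stopifnot(ncol(expr) == nrow(samples))
  if (!is.null(genes)) {
    if (inherits(genes, "si_gene_set")) genes <- genes$gene_id
    genes <- intersect(genes, rownames(expr))
    expr <- expr[genes, , drop = FALSE]
  }
  ids <- samples$sample_id
  colnames(expr) <- ids
  diag_true <- stats::setNames(samples$diagnosis, ids)

  hc_ids <- ids[diag_true == "HC"]
  bd_ids <- ids[diag_true == "BD"]
  if (mode == "model_on_controls") {
    ref_ids <- hc_ids          # resampled for modelling; also scaling group
    scored_ids <- ids
    diag_used <- diag_true
    scale_label <- "HC"
  } else if (mode == "model_on_cases") {
    ref_ids <- bd_ids          # cases modelled; case mean/sd used for scaling
    scored_ids <- ids
    diag_used <- diag_true
    scale_label <- "BD"
  } else {
    if (length(hc_ids) < 2 * max(4, min_model_size)) {
      stop_validation("too few controls for an hc_split_null analysis")
    }
    halves <- with_seed(derive_seed(seed, 7L), {
      g1 <- sort(sample(hc_ids, ceiling(length(hc_ids) / 2)))
      list(g1 = g1, g2 = setdiff(hc_ids, g1))
    })
    ref_ids <- halves$g1
    scored_ids <- hc_ids
    diag_used <- stats::setNames(
      ifelse(hc_ids %in% halves$g1, "HC", "BD"), hc_ids)
    scale_label <- "HC"  # held-out first-half controls
    expr <- expr[, hc_ids, drop = FALSE]
    samples <- samples[match(hc_ids, samples$sample_id), , drop = FALSE]
    ids <- hc_ids
  }

  if (is.null(plan)) {
    if (is.null(model_size)) model_size <- floor(2 / 3 * length(ref_ids))
    plan <- make_plan(ref_ids, model_size, iterations,
                      seed = derive_seed(seed, 1L))
  } else {
    if (!all(unlist(plan$model_sets) %in% ref_ids)) {
      stop_validation("plan modelling sets are not a subset of the reference group")
    }
  }
  p <- plan$iterations
  covars <- covariate_design(samples, c("age", "sex", "ethnicity",
                                        "RIN", "PMI"))[, -1, drop = FALSE]
  rownames(covars) <- ids

  gene_ids <- rownames(expr)
  gene_means <- rowMeans(expr)  # over all individuals in the analysis
  dropped <- gene_ids[gene_means == 0]
  if (length(dropped)) {
    warning("dropping gene(s) with zero mean expression: ",
            paste(dropped, collapse = ", "))
  }
  active <- setdiff(gene_ids, dropped)

  n_sc <- length(scored_ids)
  wsr_sum <- matrix(0, n_sc, length(active),
                    dimnames = list(scored_ids, active))
  in_model <- matrix(FALSE, n_sc, p, dimnames = list(scored_ids, NULL))
  r2_mat <- matrix(NA_real_, length(active), p,
                   dimnames = list(active, NULL))
  wsr_keep <- if (keep_iterations) {
    array(NA_real_, dim = c(n_sc, length(active), p),
          dimnames = list(scored_ids, active, NULL))
  } else NULL
  newly_dropped <- character()

  for (k in seq_len(p)) {
    mk <- plan$model_sets[[k]]
    test_ids <- setdiff(scored_ids, mk)
    if (length(intersect(mk, test_ids)) > 0L) {
      stop("leakage: modelling and test sets overlap")  # structural assert
    }
    in_model[match(intersect(mk, scored_ids), scored_ids), k] <- TRUE
    for (j in active) {
      if (j %in% newly_dropped) next
      fm <- tryCatch(
        fit_gene_model(expr, covars, j, mk, nfolds = nfolds,
                       nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio, thresh = thresh,
                       seed = derive_seed(seed,
                                          1000L * string_index(j) + k),
                       min_model_size = min_model_size),
        stoichsi_constant_target = function(e) NULL)
      if (is.null(fm)) {
        newly_dropped <- c(newly_dropped, j)
        next
      }
      r2_mat[j, k] <- fm$r2
      pred <- predict(fm, expr, covars, test_ids)
      w <- compute_wsr(expr[j, test_ids], pred, fm$r2, gene_means[j])
      idx <- match(test_ids, scored_ids)
      wsr_sum[idx, j] <- wsr_sum[idx, j] + w
      if (keep_iterations) wsr_keep[idx, match(j, active), k] <- w
    }
  }

  if (length(newly_dropped)) {
    warning("dropping gene(s) with a constant modelling target: ",
            paste(newly_dropped, collapse = ", "))
    keep_g <- setdiff(active, newly_dropped)
    wsr_sum <- wsr_sum[, keep_g, drop = FALSE]
    r2_mat <- r2_mat[keep_g, , drop = FALSE]
    if (keep_iterations) {
      wsr_keep <- wsr_keep[, match(keep_g, active), , drop = FALSE]
    }
    dropped <- c(dropped, newly_dropped)
    active <- keep_g
  }

  n_used <- rowSums(!in_model)
  if (any(n_used == 0)) {
    stop_validation("an individual was modelled in every iteration")
  }
  WSR <- sweep(wsr_sum, 1, n_used, "/")
  diag_scored <- diag_used[scored_ids]
  sWSR <- t(standardize_by_hc(t(WSR), diag_scored, hc_label = scale_label))
  si <- si_score(sWSR)

  structure(list(WSR = WSR, sWSR = sWSR, si = si,
                 diagnosis = diag_scored,
                 true_diagnosis = diag_true[scored_ids],
                 r2 = r2_mat, plan = plan, mode = mode,
                 gene_means = gene_means[colnames(sWSR)],
                 dropped_genes = dropped,
                 n_iterations_used = n_used,
                 in_model = in_model,
                 wsr_iterations = wsr_keep,
                 samples = samples),
            class = "si_fit")
}

#' Audit strict model/test separation of a fitted SI object
#'
#' Recomputes, from the stored plan, the number of qualifying iterations per
#' individual and verifies it matches what the fit used, and that no scored
#' individual appears in a modelling subset of an iteration that scored it.
#'
#' @param fit an `si_fit` object.
#' @return TRUE (invisibly) if the audit passes; otherwise an error.
#' @export
audit_leakage <- function(fit) {
  scored <- rownames(fit$WSR)
  p <- fit$plan$iterations
  for (k in seq_len(p)) {
    mk <- fit$plan$model_sets[[k]]
    contributed <- scored[!fit$in_model[, k]]
    if (length(intersect(mk, contributed)) > 0L) {
      stop("leakage detected in iteration ", k)
    }
  }
  expected <- vapply(scored, function(id) {
    sum(!vapply(fit$plan$model_sets, function(m) id %in% m, logical(1)))
  }, numeric(1))
  if (!all(expected == fit$n_iterations_used)) {
    stop("iteration bookkeeping does not match the plan")
  }
  invisible(TRUE)
}

#' @export
print.si_fit <- function(x, ...) {
  cat("Stoichiometric imbalance fit (", x$mode, ")\n", sep = "")
  cat("  ", ncol(x$sWSR), "genes x", nrow(x$sWSR), "scored individuals;",
      x$plan$iterations, "iterations\n")
  cat("  mean model R2:", round(mean(x$r2, na.rm = TRUE), 3), "\n")
  grp <- split(x$si, x$diagnosis)
  for (g in names(grp)) {
    cat(sprintf("  median SI %s: %.3f (n = %d)\n", g,
                stats::median(grp[[g]]), length(grp[[g]])))
  }
  if (length(x$dropped_genes)) {
    cat("  dropped genes:", paste(x$dropped_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.si_fit <- function(object, prevalence = 0.02, ...) {
  perf <- si_performance(object$si, object$diagnosis, prevalence = prevalence,
                         metric = "SI score")
  de <- wilcoxon_de(object$WSR, object$diagnosis)
  structure(list(performance = perf, de = de, mode = object$mode,
                 n = table(object$diagnosis)), class = "summary.si_fit")
}

#' @export
print.summary.si_fit <- function(x, ...) {
  cat("SI fit summary (", x$mode, "): ",
      paste(names(x$n), as.integer(x$n), collapse = " / "), "\n", sep = "")
  cat("SI score performance:\n")
  print(x$performance, row.names = FALSE)
  cat("\nTop case-control genes (Wilcoxon on WSR):\n")
  de <- x$de[order(x$de$p), ]
  print(utils::head(de, 8), row.names = FALSE)
  invisible(x)
}

#' @export
residuals.si_fit <- function(object, standardized = TRUE, ...) {
  if (standardized) object$sWSR else object$WSR
}

#' @export
plot.si_fit <- function(x, ...) {
  grp <- split(x$si, x$diagnosis)
  dens <- lapply(grp, stats::density)
  xr <- range(unlist(lapply(dens, `[[`, "x")))
  yr <- range(unlist(lapply(dens, `[[`, "y")))
  cols <- c(HC = "#2e8b57", BD = "#e0a800")
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "SI score",
                 ylab = "density", main = "SI score by diagnosis", ...)
  for (g in names(dens)) {
    graphics::lines(dens[[g]], col = cols[[g]] %||% "grey40", lwd = 2)
  }
  graphics::legend("topright", legend = names(dens),
                   col = vapply(names(dens),
                                function(g) cols[[g]] %||% "grey40",
                                character(1)),
                   lwd = 2, bty = "n")
  invisible(x)
}
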