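#' Trimmed mean of M-values normalisation factors
#'
#' Between-sample scaling factors by the Robinson-Oshlack TMM method
#' (computed with edgeR): the reference sample is the one whose 75th
#' percentile count fraction is closest to the mean, M-values are doubly
#' trimmed (30 percent on M, 5 percent on A), the weighted mean uses inverse
#' asymptotic variances, and factors are rescaled to geometric mean one.
#'
#' @param counts an `si_counts` object or a non-negative count matrix.
#' @param trim_M two-sided trim fraction on log ratios.
#' @param trim_A two-sided trim fraction on average log intensity.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  m <- count_matrix(counts)
  if (ncol(m) < 2L) stop_validation("TMM needs at least two samples")
  if (any(colSums(m) == 0)) stop_validation("all-zero sample in counts")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A,
                              doWeighting = TRUE)
  names(f) <- colnames(m)
  f
}

count_matrix <- function(counts) {
  if (inherits(counts, "si_counts")) counts$counts else as.matrix(counts)
}

#' Log2 RPKM with TMM-effective library sizes
#'
#' RPKM = 1e9 * count / (length_bp * effective library size), where the
#' effective library size is the raw column sum times the sample's TMM
#' factor. Returns log2(RPKM + pseudocount).
#'
#' @param counts `si_counts` with gene lengths, or a count matrix.
#' @param tmm per-sample TMM factors; computed if `NULL`, or use 1 to skip.
#' @param gene_lengths named lengths (bp); taken from `counts` if absent.
#' @param pseudocount added inside the log; default 1 keeps zero counts
#'   finite at log2(pseudocount).
#' @return list of class `si_norm`: `log2_rpkm` matrix, `tmm_factor`,
#'   `effective_lib`, `pseudocount`.
#' @export
log2_rpkm <- function(counts, tmm = NULL, gene_lengths = NULL,
                      pseudocount = 1) {
  m <- count_matrix(counts)
  if (is.null(gene_lengths) && inherits(counts, "si_counts")) {
    gene_lengths <- counts$gene_lengths
  }
  if (is.null(gene_lengths)) stop_validation("gene lengths are required")
  gene_lengths <- match_gene_lengths(gene_lengths, rownames(m))
  if (is.null(tmm)) tmm <- tmm_factors(m)
  if (length(tmm) == 1L) tmm <- rep(tmm, ncol(m))
  eff <- colSums(m) * tmm
  if (any(eff <= 0)) stop_validation("zero effective library size")
  rpkm <- 1e9 * sweep(sweep(m, 1, gene_lengths, "/"), 2, eff, "/")
  structure(list(log2_rpkm = log2(rpkm + pseudocount),
                 tmm_factor = tmm, effective_lib = eff,
                 pseudocount = pseudocount),
            class = "si_norm")
}

#' Low-expression gene filter
#'
#' A gene is kept iff at least 70 percent of samples reach the CPM
#' equivalent of `min_count` reads at the median library depth
#' (threshold CPM = min_count / (median library size / 1e6)); equivalently,
#' removed iff more than `max_low_fraction` of samples fall below it.
#'
#' @param counts `si_counts` or count matrix.
#' @param min_count count threshold at the median depth.
#' @param max_low_fraction maximal tolerated fraction of below-threshold
#'   samples.
#' @return named logical vector, TRUE = keep.
#' @export
filter_low_expression <- function(counts, min_count = 10,
                                  max_low_fraction = 0.30) {
  m <- count_matrix(counts)
  lib <- colSums(m)
  thr_cpm <- min_count / (stats::median(lib) / 1e6)
  cpm <- sweep(m, 2, lib / 1e6, "/")
  low_frac <- rowMeans(cpm < thr_cpm)
  keep <- low_frac <= max_low_fraction
  names(keep) <- rownames(m)
  keep
}

#' Residualise expression against clinical covariates
#'
#' Per gene, ordinary least squares of expression on age, sex, ethnicity,
#' RIN and PMI over all samples (cases and controls together); returns the
#' residuals. Categorical covariates are one-hot encoded against a reference
#' level; constant columns (e.g. a single-ethnicity cohort) are dropped with
#' a warning.
#'
#' @param mat genes x samples matrix (e.g. log2 RPKM).
#' @param samples validated metadata data.frame aligned with the columns.
#' @param covariates covariate column names to use.
#' @return list of class `si_residuals`: `residual` matrix and
#'   `covariates_used`.
#' @export
residualize_covariates <- function(mat, samples,
                                   covariates = c("age", "sex", "ethnicity",
                                                  "RIN", "PMI")) {
  stopifnot(ncol(mat) == nrow(samples))
  X <- covariate_design(samples, covariates)
  qr_X <- qr(X)
  res <- t(qr.resid(qr_X, t(mat)))
  dimnames(res) <- dimnames(mat)
  structure(list(residual = res, covariates_used = colnames(X)[-1]),
            class = "si_residuals")
}

# Design matrix with intercept; drops constant covariate columns.
covariate_design <- function(samples, covariates) {
  cols <- lapply(covariates, function(v) {
    x <- samples[[v]]
    if (is.null(x)) stop_validation(paste("missing covariate", v))
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      lv <- levels(x)
      if (length(lv) < 2L) return(NULL)
      sapply(lv[-1], function(l) as.numeric(x == l))
    } else {
      as.numeric(x)
    }
  })
  names(cols) <- covariates
  keep <- !vapply(cols, is.null, logical(1))
  dropped <- covariates[!keep]
  cols <- cols[keep]
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  const <- apply(X[, -1, drop = FALSE], 2, function(x) stats::var(x) == 0)
  if (any(const) || length(dropped)) {
    warning("dropping constant covariate column(s): ",
            paste(c(dropped, colnames(X)[-1][const]), collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  colnames(X)[1] <- "(Intercept)"
  X
}

#' PCA outlier screen
#'
#' Centered PCA of samples on the top components; a sample is flagged when
#' any retained score lies more than `k` median absolute deviations from the
#' per-component median. An explicit, automated counterpart of visual PC1/PC2
#' inspection.
#'
#' @param mat genes x samples matrix.
#' @param n_components number of components to screen (default 2).
#' @param k MAD multiplier (default 6).
#' @return data.frame with sample_id, scores PC1..PCk, and `outlier` flag.
#' @export
pca_screen <- function(mat, n_components = 2, k = 6) {
  if (ncol(mat) < 3L) stop_validation("PCA screen needs >= 3 samples")
  keep <- apply(mat, 1, function(x) stats::var(x) > 0)
  pc <- stats::prcomp(t(mat[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  sc <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- rep(FALSE, nrow(sc))
  for (j in seq_len(ncol(sc))) {
    med <- stats::median(sc[, j])
    mad_j <- stats::mad(sc[, j])
    if (mad_j > 0) out <- out | abs(sc[, j] - med) > k * mad_j
  }
  data.frame(sample_id = colnames(mat), sc, outlier = out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardise a matrix against its healthy controls
#'
#' Per gene (row), subtracts the HC mean and divides by the HC standard
#' deviation (n-1 denominator), applied to all samples. Genes with zero HC
#' variance are dropped with a warning.
#'
#' @param mat genes x samples matrix.
#' @param diagnosis character vector (BD/HC) aligned with columns; values
#'   equal to `hc_label` define the reference group.
#' @param hc_label label of the reference group.
#' @return standardised matrix (possibly fewer rows).
#' @export
standardize_by_hc <- function(mat, diagnosis, hc_label = "HC") {
  hc <- diagnosis == hc_label
  if (sum(hc) < 2L) stop_validation("need >= 2 reference samples")
  mu <- rowMeans(mat[, hc, drop = FALSE])
  sdv <- apply(mat[, hc, drop = FALSE], 1, stats::sd)
  bad <- sdv == 0 | is.na(sdv)
  if (any(bad)) {
    warning("dropping ", sum(bad), " gene(s) with zero HC variance")
    mat <- mat[!bad, , drop = FALSE]
    mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  sweep(sweep(mat, 1, mu, "-"), 1, sdv, "/")
}

#' One-step preprocessing of a cohort
#'
#' Low-expression filter, TMM factors, log2 RPKM, covariate residualisation
#' and the PCA outlier screen, in the order a cohort is prepared for SI
#' fitting. Outliers are flagged, and removed when `drop_outliers = TRUE`.
#'
#' @param counts `si_counts` with gene lengths.
#' @param samples validated metadata (samples with `excluded = TRUE`, i.e.
#'   age below 18, are removed first).
#' @param pseudocount passed to [log2_rpkm()].
#' @param drop_outliers whether to remove PCA-flagged samples.
#' @param k MAD multiplier for the outlier screen.
#' @return list of class `si_prep`: `log2_rpkm`, `residual`, `samples`,
#'   `kept_genes`, `tmm_factor`, `outliers`.
#' @export
preprocess_cohort <- function(counts, samples, pseudocount = 1,
                              drop_outliers = TRUE, k = 6) {
  samples <- validate_samples(samples, counts)
  m <- counts$counts
  if (any(samples$excluded)) {
    keep_s <- !samples$excluded
    m <- m[, keep_s, drop = FALSE]
    samples <- samples[keep_s, , drop = FALSE]
  }
  keep <- filter_low_expression(m)
  m <- m[keep, , drop = FALSE]
  lengths <- counts$gene_lengths[rownames(m)]
  tmm <- tmm_factors(m)
  norm <- log2_rpkm(m, tmm = tmm, gene_lengths = lengths,
                    pseudocount = pseudocount)
  scr <- pca_screen(norm$log2_rpkm, k = k)
  if (drop_outliers && any(scr$outlier)) {
    keep_s <- !scr$outlier
    m <- m[, keep_s, drop = FALSE]
    samples <- samples[keep_s, , drop = FALSE]
    norm <- log2_rpkm(m, tmm = tmm_factors(m), gene_lengths = lengths,
                      pseudocount = pseudocount)
  }
  resid <- residualize_covariates(norm$log2_rpkm, samples)
  structure(list(log2_rpkm = norm$log2_rpkm, residual = resid$residual,
                 samples = samples, kept_genes = rownames(m),
                 tmm_factor = norm$tmm_factor, outliers = scr),
            class = "si_prep")
}

#' @export
print.si_prep <- function(x, ...) {
  cat("Preprocessed cohort:", length(x$kept_genes), "genes x",
      nrow(x$samples), "samples;", sum(x$outliers$outlier),
      "PCA outlier(s) flagged\n")
  invisible(x)
}
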