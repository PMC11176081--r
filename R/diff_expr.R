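#' Gene-level case-control Wilcoxon tests
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test per gene, on residualised
#' absolute expression or on iteration-averaged weighted scaled residuals.
#' The exact null is used for combined group sizes up to `exact_max`
#' (and no ties); the normal approximation with tie and continuity
#' correction otherwise. Direction is the sign of (median BD - median HC);
#' all-tied genes get p = 1.
#'
#' @param values individuals x genes matrix (or genes x individuals with
#'   `genes_in_rows = TRUE`), or a single numeric vector.
#' @param diagnosis BD/HC labels aligned with individuals.
#' @param genes_in_rows orientation flag for matrix input.
#' @param exact_max maximal combined sample size for the exact null.
#' @return data.frame with gene, p, direction (`up-in-BD`, `down-in-BD`,
#'   `none`).
#' @export
wilcoxon_de <- function(values, diagnosis, genes_in_rows = FALSE,
                        exact_max = 30) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, "gene"))
  if (genes_in_rows) values <- t(values)
  stopifnot(nrow(values) == length(diagnosis))
  bd <- diagnosis == "BD"
  hc <- diagnosis == "HC"
  if (sum(bd) < 2 || sum(hc) < 2) {
    stop_validation("need >= 2 samples per group")
  }
  res <- lapply(colnames(values), function(g) {
    x <- values[bd, g]
    y <- values[hc, g]
    if (length(unique(c(x, y))) == 1L) {
      return(data.frame(gene = g, p = 1, direction = "none",
                        stringsAsFactors = FALSE))
    }
    use_exact <- (length(x) + length(y)) <= exact_max
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
    dmed <- stats::median(x) - stats::median(y)
    dir <- if (dmed > 0) "up-in-BD" else if (dmed < 0) "down-in-BD" else "none"
    data.frame(gene = g, p = p, direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin wrapper kept so that the
#' pooling convention (across all genes and datasets at once) has one named
#' entry point.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pooled differential-expression table across cohorts
#'
#' Runs [wilcoxon_de()] per cohort on the chosen level and applies
#' Benjamini-Hochberg correction pooled across all genes and all cohorts.
#'
#' @param fits named list of `si_fit` objects (relative level), or named
#'   list of lists with elements `values` (individuals x genes) and
#'   `diagnosis` for the absolute level.
#' @param level `"relative"` tests the iteration-averaged WSR;
#'   `"absolute"` expects residualised expression supplied as above.
#' @param fdr flagging threshold.
#' @return data.frame with gene, dataset, level, p, direction, q, nominal,
#'   significant.
#' @export
de_table <- function(fits, level = c("relative", "absolute"), fdr = 0.05) {
  level <- match.arg(level)
  parts <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    de <- if (inherits(f, "si_fit")) {
      wilcoxon_de(f$WSR, f$diagnosis)
    } else {
      wilcoxon_de(f$values, f$diagnosis)
    }
    de$dataset <- nm
    de
  })
  out <- do.call(rbind, parts)
  out$level <- level
  out$q <- bh_adjust(out$p)
  out$nominal <- out$p < 0.05
  out$significant <- out$q < fdr
  out[, c("gene", "dataset", "level", "p", "q", "direction",
          "nominal", "significant")]
}
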