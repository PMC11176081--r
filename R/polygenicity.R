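#' Number of imbalanced genes per individual
#'
#' Counts, per individual, the genes whose standardised residual exceeds
#' the threshold in absolute value (strict inequality: |sWSR| > threshold).
#'
#' @param swsr individuals x genes matrix of standardised residuals, or an
#'   `si_fit` object.
#' @param threshold imbalance threshold in HC standard deviations.
#' @return named integer vector of per-individual counts.
#' @export
imbalance_counts <- function(swsr, threshold = 2) {
  if (inherits(swsr, "si_fit")) swsr <- swsr$sWSR
  rowSums(abs(swsr) > threshold)
}

#' Per-gene fractions of imbalanced individuals by group
#'
#' For every gene, the proportion of HC and of BD individuals whose
#' |sWSR| exceeds the threshold, with group-level summaries (mean fraction
#' across genes, maximal BD fraction).
#'
#' @param swsr individuals x genes matrix or `si_fit`.
#' @param diagnosis BD/HC labels (taken from the fit when omitted).
#' @param threshold imbalance threshold.
#' @return data.frame gene, hc_fraction, bd_fraction, with attributes
#'   `mean_hc`, `mean_bd`, `max_bd`.
#' @export
gene_imbalance_fractions <- function(swsr, diagnosis = NULL, threshold = 2) {
  if (inherits(swsr, "si_fit")) {
    if (is.null(diagnosis)) diagnosis <- swsr$diagnosis
    swsr <- swsr$sWSR
  }
  stopifnot(nrow(swsr) == length(diagnosis))
  ext <- abs(swsr) > threshold
  hc <- diagnosis == "HC"
  bd <- diagnosis == "BD"
  if (!any(hc) || !any(bd)) stop_validation("both groups must be present")
  out <- data.frame(gene = colnames(swsr),
                    hc_fraction = colMeans(ext[hc, , drop = FALSE]),
                    bd_fraction = colMeans(ext[bd, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean_hc") <- mean(out$hc_fraction)
  attr(out, "mean_bd") <- mean(out$bd_fraction)
  attr(out, "max_bd") <- max(out$bd_fraction)
  out
}

#' Polygenicity summary of a fitted SI object
#'
#' Summarises the gene x individual imbalance matrix along both dimensions:
#' the distribution of imbalanced-gene counts per individual (with group
#' medians, lower-median convention) and the per-gene fractions of
#' imbalanced individuals per group.
#'
#' @param fit `si_fit` object (or an sWSR matrix with `diagnosis` given).
#' @param diagnosis BD/HC labels when `fit` is a matrix.
#' @param threshold imbalance threshold in HC standard deviations.
#' @return object of class `si_imbalance`: `counts`, `fractions`,
#'   `median_hc`, `median_bd`, `mean_fraction_hc`, `mean_fraction_bd`,
#'   `max_fraction_bd`, `threshold`.
#' @export
imbalance_summary <- function(fit, diagnosis = NULL, threshold = 2) {
  if (inherits(fit, "si_fit")) {
    swsr <- fit$sWSR
    if (is.null(diagnosis)) diagnosis <- fit$diagnosis
  } else {
    swsr <- fit
    if (is.null(diagnosis)) stop_validation("diagnosis labels are required")
  }
  counts <- imbalance_counts(swsr, threshold)
  fr <- gene_imbalance_fractions(swsr, diagnosis, threshold)
  structure(list(counts = counts,
                 fractions = fr,
                 diagnosis = diagnosis,
                 median_hc = median_lower(counts[diagnosis == "HC"]),
                 median_bd = median_lower(counts[diagnosis == "BD"]),
                 mean_fraction_hc = attr(fr, "mean_hc"),
                 mean_fraction_bd = attr(fr, "mean_bd"),
                 max_fraction_bd = attr(fr, "max_bd"),
                 threshold = threshold),
            class = "si_imbalance")
}

#' @export
print.si_imbalance <- function(x, ...) {
  cat("Imbalance summary (|sWSR| >", x$threshold, "):\n")
  cat(sprintf("  median imbalanced genes: HC %d, BD %d\n",
              x$median_hc, x$median_bd))
  cat(sprintf("  mean imbalanced fraction per gene: HC %.2f%%, BD %.2f%% (max BD %.1f%%)\n",
              100 * x$mean_fraction_hc, 100 * x$mean_fraction_bd,
              100 * x$max_fraction_bd))
  invisible(x)
}

#' @export
plot.si_imbalance <- function(x, ...) {
  grp <- split(x$counts, x$diagnosis)
  brk <- seq(-0.5, max(x$counts) + 0.5, by = 1)
  old <- graphics::par(mfrow = c(1, length(grp)))
  on.exit(graphics::par(old))
  for (g in names(grp)) {
    graphics::hist(grp[[g]], breaks = brk, main = g,
                   xlab = "imbalanced genes per individual", col = "grey80")
    graphics::abline(v = median_lower(grp[[g]]), lty = 2)
  }
  invisible(x)
}
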