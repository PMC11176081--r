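#' Simulation configuration for synthetic case-control cohorts
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults emulate the structure the SI analysis assumes in cortical
#' case-control brain RNA-seq: a gene set of 54 GWAS-prioritised genes of
#' which 24 form one strongly positively co-expressed module plus two smaller
#' modules that are anti-correlated with each other; four cohorts with the
#' published case/control sample sizes; five clinical covariates (age, sex,
#' ethnicity, RIN, PMI) with small random per-gene slopes; and sparse
#' per-case stoichiometric perturbation, a Poisson-distributed number of
#' genes per case (mean 3) shifted by `delta` healthy-control residual
#' standard deviations on the log2 scale.
#'
#' @param n_genes number of genes in the analysis panel.
#' @param n_background number of additional background transcriptome genes
#'   simulated alongside the panel (independent expression, no modules, no
#'   perturbation). They absorb most sequencing reads, so that library sizes
#'   and the compositional RPKM normalisation behave as they do when a small
#'   GWAS panel is embedded in a full transcriptome; they are excluded from
#'   the SI gene set.
#' @param modules data.frame with columns `size`, `r` (target within-module
#'   Pearson correlation of the latent log2 expression), `factor` (integer id
#'   of the shared latent factor) and `sign` (+1/-1 loading sign; modules
#'   sharing a factor with opposite signs are anti-correlated).
#' @param cohorts data.frame with columns `name`, `n_cases`, `n_controls`;
#'   defaults to the four cortical cohorts (71/165, 35/93, 73/75, 125/142).
#' @param covariate_effects named numeric: standard deviation of the random
#'   per-gene slope on each standardised covariate, in log2 units.
#' @param lambda_imbalance mean number of perturbed genes per case (Poisson).
#' @param delta perturbation magnitude in units of the gene's latent residual
#'   (noise) standard deviation; `delta = 0` is the null configuration.
#' @param nb_dispersion negative-binomial overdispersion of counts.
#' @param lib_size_range range (reads) of the per-sample sequencing depth
#'   over the simulated gene set.
#' @param gene_length_range range (bp) of simulated gene lengths.
#' @param gene_mean_log2_range range of per-gene mean latent log2 expression.
#' @param gene_sd total latent per-gene standard deviation (log2 units).
#' @param seed master seed; per-cohort sub-seeds are derived deterministically
#'   from it and the cohort index.
#' @return an object of class `si_sim_config`.
#' @export
si_sim_config <- function(n_genes = 54L,
                          n_background = 150L,
                          modules = data.frame(
                            size = c(24L, 10L, 8L),
                            r = c(0.7, 0.6, 0.6),
                            factor = c(1L, 2L, 2L),
                            sign = c(1, 1, -1)
                          ),
                          cohorts = data.frame(
                            name = c("CMC-HBCC", "CMC-Pitt",
                                     "BrainGVEX-SMRI", "BipSeq-sACC"),
                            n_cases = c(71L, 35L, 73L, 125L),
                            n_controls = c(165L, 93L, 75L, 142L),
                            stringsAsFactors = FALSE
                          ),
                          covariate_effects = c(age = 0.08, sex = 0.08,
                                                ethnicity = 0.08, RIN = 0.12,
                                                PMI = 0.08),
                          lambda_imbalance = 3,
                          delta = 2,
                          nb_dispersion = 0.05,
                          lib_size_range = c(1e7, 4e7),
                          gene_length_range = c(500L, 5000L),
                          gene_mean_log2_range = c(3, 6),
                          gene_sd = 0.8,
                          seed = 1L) {
  stopifnot(is.data.frame(modules),
            all(c("size", "r", "factor", "sign") %in% names(modules)),
            is.data.frame(cohorts),
            all(c("n_cases", "n_controls") %in% names(cohorts)))
  if (n_genes < 1L) stop_validation("n_genes must be >= 1")
  if (sum(modules$size) > n_genes) {
    stop_validation("module sizes exceed n_genes")
  }
  if (any(modules$r < -1 | modules$r > 1)) {
    stop_validation("module correlations must lie in [-1, 1]")
  }
  if (delta < 0) stop_validation("delta must be >= 0")
  if (lambda_imbalance < 0) stop_validation("lambda_imbalance must be >= 0")
  if (any(cohorts$n_cases < 0L) || any(cohorts$n_controls <= 0L)) {
    stop_validation("cohorts need n_cases >= 0 and n_controls > 0")
  }
  if (!("name" %in% names(cohorts))) {
    cohorts$name <- paste0("cohort", seq_len(nrow(cohorts)))
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_background = as.integer(n_background),
    modules = modules,
    cohorts = cohorts,
    covariate_effects = covariate_effects,
    lambda_imbalance = lambda_imbalance,
    delta = delta,
    nb_dispersion = nb_dispersion,
    lib_size_range = lib_size_range,
    gene_length_range = gene_length_range,
    gene_mean_log2_range = gene_mean_log2_range,
    gene_sd = gene_sd,
    seed = seed
  )
  class(cfg) <- "si_sim_config"
  cfg
}

#' @export
print.si_sim_config <- function(x, ...) {
  cat("Synthetic SI cohort configuration\n")
  cat("  genes:", x$n_genes, "in", nrow(x$modules), "co-expression modules (",
      paste(x$modules$size, collapse = "/"), ")\n")
  cat("  cohorts:", nrow(x$cohorts), "-",
      paste(sprintf("%s (%d BD / %d HC)", x$cohorts$name, x$cohorts$n_cases,
                    x$cohorts$n_controls), collapse = ", "), "\n")
  cat("  perturbation: delta =", x$delta, "resid-SD, mean genes/case =",
      x$lambda_imbalance, "\n")
  invisible(x)
}

# Gene -> module assignment (0 = no module), in gene order.
module_assignment <- function(config) {
  m <- integer(config$n_genes)
  at <- 1L
  for (k in seq_len(nrow(config$modules))) {
    sz <- config$modules$size[k]
    m[at:(at + sz - 1L)] <- k
    at <- at + sz
  }
  m
}

#' Simulate one case-control cohort with latent co-expression structure
#'
#' Draws a count matrix, sample metadata and a ground-truth perturbation
#' table for one cohort. Latent log2 expression of each gene is the sum of a
#' gene mean, a shared module factor (scaled so the within-module latent
#' correlation matches the module's target `r`), small random covariate
#' effects, and gene-level Gaussian noise. For each case, a
#' Poisson(`lambda_imbalance`) number of genes receives an additive shift of
#' `delta` latent residual SDs with random sign -- conditional on the module
#' factor, so the gene leaves its stoichiometric relation while the factor
#' itself is untouched. Counts are negative-binomial around the expected
#' per-gene share of a sample's sequencing depth, so relative (not absolute)
#' expression carries the signal.
#'
#' @param config an [si_sim_config()] object.
#' @param cohort cohort index (1-based) into `config$cohorts`.
#' @return a list of class `si_cohort` with elements `counts` (integer
#'   genes x samples), `samples` (data.frame: sample_id, diagnosis, age, sex,
#'   ethnicity, RIN, PMI), `gene_lengths` (named integer), `truth`
#'   (data.frame: sample_id, gene_id, shift; zero rows when `delta = 0`),
#'   `latent` (latent log2 expression matrix, for diagnostics) and `name`.
#' @export
simulate_cohort <- function(config, cohort = 1L) {
  stopifnot(inherits(config, "si_sim_config"))
  if (cohort < 1L || cohort > nrow(config$cohorts)) {
    stop_validation("cohort index out of range")
  }
  n_cases <- config$cohorts$n_cases[cohort]
  n_controls <- config$cohorts$n_controls[cohort]
  n <- n_cases + n_controls
  g <- config$n_genes
  sub_seed <- derive_seed(config$seed, cohort)

  nb <- config$n_background
  with_seed(sub_seed, {
    panel_ids <- sprintf("G%03d", seq_len(g))
    bg_ids <- if (nb > 0) sprintf("BG%03d", seq_len(nb)) else character()
    gene_ids <- c(panel_ids, bg_ids)
    g_all <- g + nb
    gene_lengths <- as.integer(round(stats::runif(
      g_all, config$gene_length_range[1], config$gene_length_range[2])))
    names(gene_lengths) <- gene_ids
    mu <- stats::runif(g_all, config$gene_mean_log2_range[1],
                       config$gene_mean_log2_range[2])

    cohort_name <- config$cohorts$name[cohort]
    sample_ids <- sprintf("%s_S%03d", gsub("[^A-Za-z0-9]", "", cohort_name),
                          seq_len(n))
    diagnosis <- c(rep("BD", n_cases), rep("HC", n_controls))
    samples <- data.frame(
      sample_id = sample_ids,
      diagnosis = diagnosis,
      age = round(pmin(90, pmax(18, stats::rnorm(n, 46, 13)))),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.65, 0.35)),
      ethnicity = sample(c("Cauc", "Other"), n, replace = TRUE,
                         prob = c(0.8, 0.2)),
      RIN = round(stats::runif(n, 5, 9), 1),
      PMI = round(stats::runif(n, 5, 50), 1),
      stringsAsFactors = FALSE
    )

    # Latent structure: module factors (panel only), covariate slopes,
    # gene noise. Background genes are plain independent transcripts.
    mod <- c(module_assignment(config), integer(nb))
    n_factors <- max(config$modules$factor, 0L)
    factors <- matrix(stats::rnorm(n * max(n_factors, 1L)), nrow = n)
    loading <- sqrt(ifelse(mod > 0, config$modules$r[pmax(mod, 1L)], 0))
    fsign <- ifelse(mod > 0, config$modules$sign[pmax(mod, 1L)], 0)
    noise_sd <- config$gene_sd * sqrt(1 - loading^2)

    covar_z <- scale(cbind(
      age = samples$age,
      sex = as.numeric(samples$sex == "M"),
      ethnicity = as.numeric(samples$ethnicity == "Cauc"),
      RIN = samples$RIN,
      PMI = samples$PMI
    ))
    eff <- config$covariate_effects[colnames(covar_z)]
    slopes <- matrix(stats::rnorm(g_all * length(eff)), nrow = g_all) *
      rep(eff, each = g_all)  # genes x covariates

    latent <- matrix(mu, nrow = g_all, ncol = n)
    for (j in seq_len(g_all)) {
      fpart <- if (mod[j] > 0) {
        config$gene_sd * loading[j] * fsign[j] *
          factors[, config$modules$factor[mod[j]]]
      } else 0
      latent[j, ] <- latent[j, ] + fpart +
        as.numeric(covar_z %*% slopes[j, ]) +
        stats::rnorm(n, 0, noise_sd[j])
    }
    rownames(latent) <- gene_ids
    colnames(latent) <- sample_ids

    # Sparse per-case perturbation of the latent residual.
    truth <- list()
    if (n_cases > 0 && config$delta > 0) {
      for (i in seq_len(n_cases)) {
        k <- min(stats::rpois(1, config$lambda_imbalance), g)
        if (k > 0) {
          genes <- sample.int(g, k)  # panel genes only
          sgn <- sample(c(-1, 1), k, replace = TRUE)
          shift <- sgn * config$delta * noise_sd[genes]
          latent[genes, i] <- latent[genes, i] + shift
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sample_ids[i], gene_id = panel_ids[genes],
            shift = shift, stringsAsFactors = FALSE)
        }
      }
    } else if (n_cases > 0 && config$lambda_imbalance > 0 && config$delta == 0) {
      # Null configuration: draw nothing, truth stays empty.
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(), gene_id = character(),
                 shift = numeric(), stringsAsFactors = FALSE)

    # Counts: expected reads proportional to expression times length,
    # against a fixed expected-transcriptome denominator, so a shared
    # module factor moves its genes' counts rather than being cancelled
    # by closing the compositional sum; NB noise on top. Expected column
    # totals equal the drawn depth.
    lib <- round(stats::runif(n, config$lib_size_range[1],
                              config$lib_size_range[2]))
    e2x <- 2^mu * exp((config$gene_sd * log(2))^2 / 2)
    denom <- sum(e2x * gene_lengths)
    mu_counts <- sweep(2^latent * gene_lengths, 2, lib / denom, "*")
    counts <- matrix(
      stats::rnbinom(g_all * n, mu = as.numeric(mu_counts),
                     size = 1 / config$nb_dispersion),
      nrow = g_all, dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"

    structure(list(counts = counts, samples = samples,
                   gene_lengths = gene_lengths, truth = truth,
                   latent = latent, name = cohort_name,
                   gene_set = panel_ids,
                   target_lib = lib),
              class = "si_cohort")
  })
}

#' @export
print.si_cohort <- function(x, ...) {
  cat("Synthetic cohort", x$name, ":", length(x$gene_set), "panel +",
      nrow(x$counts) - length(x$gene_set), "background genes x",
      ncol(x$counts), "samples (",
      sum(x$samples$diagnosis == "BD"), "BD /",
      sum(x$samples$diagnosis == "HC"), "HC )\n")
  cat("  perturbed gene-sample pairs:", nrow(x$truth), "\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Serialises counts (TSV, gene_id first column), sample metadata (TSV), gene
#' lengths (TSV) and the perturbation truth table (JSON map sample_id ->
#' perturbed genes and shifts). Round-trips losslessly through
#' [read_counts()] / [read_samples()].
#'
#' @param cohort an `si_cohort` object.
#' @param dir output directory (created if missing).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "si_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    truth = file.path(dir, "truth.json")
  )
  cdf <- data.frame(gene_id = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cohort$gene_lengths),
               length_bp = as.integer(cohort$gene_lengths)),
    paths["gene_lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth_map <- lapply(split(cohort$truth, cohort$truth$sample_id),
                      function(d) list(gene_id = d$gene_id, shift = d$shift))
  jsonlite::write_json(truth_map, paths["truth"], auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
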