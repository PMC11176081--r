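#' Run the full SI study end-to-end
#'
#' Orchestrates simulate -> preprocess -> SI fitting -> differential
#' expression -> cross-cohort classification -> polygenicity under a single
#' configuration, writing every artifact plus a manifest (parameters, seeds,
#' file checksums) to one run directory. Reruns with the same configuration
#' are bit-identical.
#'
#' @param config a list or a YAML file path. Recognised fields:
#'   \describe{
#'     \item{out_dir}{output directory (required when writing).}
#'     \item{seed}{master seed (default 1).}
#'     \item{simulate}{arguments to [si_sim_config()]; a synthetic study is
#'       generated when present (the default).}
#'     \item{iterations, model_size}{resampling defaults for every cohort;
#'       `model_size = "published"` uses the per-cohort published splits.}
#'     \item{nlambda, nfolds}{LASSO/CV tuning (defaults 100 / 10).}
#'     \item{thresholds}{list: `imbalance` (2), `fdr` (0.05),
#'       `prevalence` (0.02).}
#'     \item{control_analyses}{logical; additionally run the case-modelling
#'       swap and (where control numbers allow) the HC-split null.}
#'   }
#' @param write whether to write artifacts to `out_dir`.
#' @return list of class `si_study`: cohorts, fits, DE tables, performance
#'   table, imbalance summaries, control-analysis fits, manifest.
#' @export
run_si_study <- function(config = list(), write = !is.null(config$out_dir)) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  thr <- config$thresholds %||% list()
  thr_imb <- thr$imbalance %||% 2
  thr_fdr <- thr$fdr %||% 0.05
  prevalence <- thr$prevalence %||% 0.02
  nlambda <- config$nlambda %||% 100
  nfolds <- config$nfolds %||% 10
  iterations <- config$iterations %||% 100L

  min_model_size <- config$min_model_size %||% 20

  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  # YAML deserialises data.frames as plain lists; coerce them back
  for (fld in c("modules", "cohorts")) {
    if (!is.null(sim_args[[fld]]) && !is.data.frame(sim_args[[fld]])) {
      sim_args[[fld]] <- as.data.frame(sim_args[[fld]],
                                       stringsAsFactors = FALSE)
    }
  }
  cfg <- do.call(si_sim_config, sim_args)
  cohort_names <- cfg$cohorts$name

  cohorts <- lapply(seq_len(nrow(cfg$cohorts)), function(i)
    simulate_cohort(cfg, i))
  names(cohorts) <- cohort_names

  preps <- lapply(cohorts, function(co)
    preprocess_cohort(as_si_counts(co$counts, co$gene_lengths), co$samples))

  fit_one <- function(nm, mode = "model_on_controls") {
    prep <- preps[[nm]]
    n_ref <- sum(prep$samples$diagnosis ==
                   if (mode == "model_on_cases") "BD" else "HC")
    if (mode == "hc_split_null") n_ref <- ceiling(n_ref / 2)
    ms <- config$model_size
    if (identical(ms, "published") && nm %in% c("CMC-HBCC", "CMC-Pitt",
                                                "BrainGVEX-SMRI",
                                                "BipSeq-sACC") &&
        mode == "model_on_controls") {
      pub <- published_plan(nm)
      ms <- pub$model_size
    } else if (!is.numeric(ms)) {
      ms <- floor(2 / 3 * n_ref)
    }
    si_fit(prep, genes = cohorts[[nm]]$gene_set,
           mode = mode, iterations = iterations,
           model_size = min(ms, n_ref - 1L),
           seed = derive_seed(seed, match(nm, cohort_names) * 11L),
           nfolds = nfolds, nlambda = nlambda,
           min_model_size = min_model_size)
  }
  fits <- lapply(cohort_names, fit_one)
  names(fits) <- cohort_names
  for (f in fits) audit_leakage(f)

  de_rel <- de_table(fits, level = "relative", fdr = thr_fdr)
  abs_std <- lapply(cohort_names, function(nm) {
    prep <- preps[[nm]]
    panel <- intersect(cohorts[[nm]]$gene_set, rownames(prep$residual))
    std <- standardize_by_hc(prep$residual[panel, , drop = FALSE],
                             prep$samples$diagnosis)
    list(values = t(std),
         diagnosis = stats::setNames(prep$samples$diagnosis,
                                     prep$samples$sample_id))
  })
  names(abs_std) <- cohort_names
  de_abs <- de_table(abs_std, level = "absolute", fdr = thr_fdr)

  perf <- list()
  for (nm in cohort_names) {
    f <- fits[[nm]]
    perf[[length(perf) + 1L]] <-
      cbind(dataset = nm, genes = ncol(f$sWSR),
            si_performance(f$si, f$diagnosis, prevalence, "SI score"))
    pr <- cross_cohort_probabilities(fits, target = nm)
    perf[[length(perf) + 1L]] <-
      cbind(dataset = nm, genes = length(pr$genes_used),
            si_performance(pr$probabilities, pr$diagnosis, prevalence,
                           "relative probabilities"))
    pa <- cross_cohort_probabilities(
      lapply(abs_std, `[[`, "values"),
      lapply(abs_std, `[[`, "diagnosis"), target = nm)
    perf[[length(perf) + 1L]] <-
      cbind(dataset = nm, genes = length(pa$genes_used),
            si_performance(pa$probabilities, pa$diagnosis, prevalence,
                           "absolute probabilities"))
  }
  perf <- do.call(rbind, perf)

  imbalance <- lapply(fits, imbalance_summary, threshold = thr_imb)

  controls <- NULL
  if (isTRUE(config$control_analyses)) {
    controls <- list(model_on_cases = lapply(cohort_names, fit_one,
                                             mode = "model_on_cases"))
    names(controls$model_on_cases) <- cohort_names
    big <- cohort_names[vapply(preps, function(p)
      sum(p$samples$diagnosis == "HC"), numeric(1)) >= 80]
    controls$hc_split_null <- lapply(big, fit_one, mode = "hc_split_null")
    names(controls$hc_split_null) <- big
  }

  study <- structure(list(config = cfg, fits = fits, preps = preps,
                          cohorts = cohorts, de_relative = de_rel,
                          de_absolute = de_abs, performance = perf,
                          imbalance = imbalance, controls = controls,
                          seed = seed),
                     class = "si_study")
  if (write) {
    study$manifest <- write_study(study, config$out_dir)
  }
  study
}

#' @export
print.si_study <- function(x, ...) {
  cat("SI study:", length(x$fits), "cohorts, seed", x$seed, "\n\n")
  print(x$performance[, c("dataset", "metric", "genes", "p", "auc",
                          "r2_liability")], row.names = FALSE)
  invisible(x)
}

write_study <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  for (nm in names(study$fits)) {
    f <- study$fits[[nm]]
    tag <- gsub("[^A-Za-z0-9]", "", nm)
    wr(data.frame(sample_id = rownames(f$sWSR), f$sWSR, check.names = FALSE),
       paste0(tag, "_sWSR.tsv"))
    wr(data.frame(sample_id = names(f$si), diagnosis = f$diagnosis,
                  si_score = f$si),
       paste0(tag, "_si_scores.tsv"))
  }
  wr(study$de_relative, "de_relative.tsv")
  wr(study$de_absolute, "de_absolute.tsv")
  wr(study$performance, "performance.tsv")
  imb <- do.call(rbind, lapply(names(study$imbalance), function(nm) {
    s <- study$imbalance[[nm]]
    cbind(dataset = nm, s$fractions)
  }))
  wr(imb, "gene_imbalance_fractions.tsv")
  manifest <- list(
    seed = study$seed,
    parameters = list(n_genes = study$config$n_genes,
                      delta = study$config$delta,
                      lambda_imbalance = study$config$lambda_imbalance),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(paths, manifest = mp)
}
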