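# Shared fixtures, built once per test run and cached so several test
# blocks can reuse expensive objects (notably fitted SI objects).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small single-cohort configuration used throughout the unit tests.
small_config <- function(n_cases = 20L, n_controls = 40L, delta = 2,
                         n_genes = 20L, seed = 11L, ...) {
  si_sim_config(
    n_genes = n_genes,
    n_background = 60L,
    modules = data.frame(size = min(10L, n_genes), r = 0.7,
                         factor = 1L, sign = 1),
    cohorts = data.frame(name = "toy", n_cases = n_cases,
                         n_controls = n_controls),
    delta = delta, seed = seed, ...)
}

small_prep <- function(...) {
  co <- simulate_cohort(small_config(...), 1)
  list(cohort = co,
       prep = preprocess_cohort(as_si_counts(co$counts, co$gene_lengths),
                                co$samples))
}

# One moderately sized fitted object with genuine imbalance signal, reused
# by the si-core, polygenicity and classify tests.
signal_fit <- function() {
  cached("signal_fit", {
    sp <- small_prep(n_cases = 30L, n_controls = 60L, delta = 3,
                     n_genes = 20L, seed = 21L)
    fit <- si_fit(sp$prep, genes = sp$cohort$gene_set,
                  iterations = 12, nlambda = 10, seed = 21L)
    list(fit = fit, cohort = sp$cohort, prep = sp$prep)
  })
}

null_fit <- function() {
  cached("null_fit", {
    sp <- small_prep(n_cases = 25L, n_controls = 50L, delta = 0,
                     n_genes = 16L, seed = 31L)
    fit <- si_fit(sp$prep, genes = sp$cohort$gene_set,
                  iterations = 10, nlambda = 10, seed = 31L)
    list(fit = fit, cohort = sp$cohort, prep = sp$prep)
  })
}
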