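---
title: "Quantifying stoichiometric imbalance in case-control brain transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stoichiometric imbalance in case-control brain transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichsi)
```

## The model

Genome-wide association studies of bipolar disorder implicate dozens of loci
whose candidate genes are strongly co-expressed in cortical tissue. If healthy
function depends on the *relative* expression levels of these genes being held
in balance, disease-associated dysregulation should be visible not as a shift
in any single gene's absolute level, but as a departure of a gene from the
level predicted by its co-regulated partners — stoichiometric imbalance (SI).

`stoichsi` quantifies this per individual. For each gene $j$ in the panel, its
log2 RPKM expression is modelled as a linear function of the other panel genes
plus five clinical covariates (age, sex, ethnicity, RIN, PMI). Because the
predictors are many and collinear, the model is fitted by LASSO with the
covariates left unpenalised (`penalty.factor = 0`), and the penalty is chosen
by 10-fold cross-validation with the one-standard-error rule — the most
regularised model whose CV error is within one SE of the minimum.

Models are fitted on healthy controls only, because cases show absolute-level
differences for several genes. Fitting and scoring on the same controls would
bias control residuals downward, so the control set is split into a modelling
subset $M^k$ and a held-out test set, and the split is resampled $p$ times.
In iteration $k$, every individual $i \notin M^k$ receives a weighted scaled
residual for gene $j$:

$$\mathrm{wsr}_{i,j}^{k} \;=\; R^{2\,k}_{j}\,
  \frac{y_{i,j} - \hat y_{i,j}^{k}}{\tfrac1m \sum_{l=1}^m y_{l,j}},$$

where $R^{2\,k}_j$ is the model's fit in that iteration (squared correlation
of fitted and observed values on $M^k$) and the denominator is the gene's
mean observed log2 RPKM over *all* $m$ individuals in the dataset. Weighting
by $R^2$ silences genes whose models carry no information; scaling by the
gene mean makes residuals comparable across expression levels. Residuals are
then averaged over exactly the iterations in which $i$ was held out,

$$\mathrm{WSR}_{i,j} = \frac{1}{\#\{k : i \notin M^k\}}
  \sum_{k:\,i \notin M^k} \mathrm{wsr}_{i,j}^{k},$$

standardised per gene against the healthy-control mean and SD (giving
$\mathrm{sWSR}_{i,j}$), and aggregated into the per-individual SI score

$$\mathrm{SI}_i = \frac1n \sum_{j=1}^n \lvert \mathrm{sWSR}_{i,j}\rvert .$$

A gene-individual pair with $\lvert\mathrm{sWSR}\rvert > 2$ is called
*imbalanced*; under a well-calibrated null this happens for about
$2(1-\Phi(2)) \approx 4.55\%$ of control observations.

## Fitting

```{r, eval = FALSE}
cfg  <- si_sim_config(delta = 2, lambda_imbalance = 3, seed = 1)
co   <- simulate_cohort(cfg, 1)
prep <- preprocess_cohort(as_si_counts(co$counts, co$gene_lengths), co$samples)
fit  <- si_fit(prep, genes = co$gene_set, iterations = 100, seed = 1)
summary(fit)
plot(fit)
```

`si_fit()` is the central fitting function and returns a classed object with
`print`, `summary`, `plot` and `residuals` methods. Downstream,
`wilcoxon_de()`/`de_table()` test gene-level case-control differences (exact
rank-sum null for combined $n \le 30$, normal approximation with tie
correction otherwise; Benjamini–Hochberg correction pooled across all genes
and datasets), `cross_cohort_probabilities()` fits the leave-one-dataset-out
logistic regression on the sWSR of every gene, `si_performance()` reports
Wilcoxon $p$, AUC (Mann–Whitney with half-credit ties) and Nagelkerke $R^2$
converted to the liability scale, and `imbalance_summary()` summarises
polygenicity along both matrix dimensions.

## Tunable parameters

* **Resampling plan** (`model_size`, `iterations`): defaults to modelling
  two thirds of the reference group with 100 iterations;
  `published_plan()` returns the per-cohort splits used for the four
  cortical datasets (94/71, 69/23, 67/8 with 1000 iterations, 93/47).
  Plans are drawn uniformly without replacement; when the iteration count
  cannot cover every control, the plan is deterministically repaired so
  each control is held out at least once.
* **LASSO path** (`nlambda`, `lambda_min_ratio`, `thresh`): `nlambda = 100`
  mirrors the glmnet default; the examples and tests use a coarser path
  (8–20 values, `lambda_min_ratio` 0.1) because the one-SE selection on
  null-like data is insensitive to path resolution while fitting is several
  times faster. CV folds are seeded per (gene, iteration) from the master
  seed, with the gene's *name* hashed into the stream so results are
  invariant to gene order.
* **Pseudocount** for log2 RPKM: default 1, keeping zero counts finite.
  The analysis panel is filtered for low expression first (a gene is kept
  iff at least 70% of samples reach the CPM equivalent of 10 reads at the
  median library depth), so the pseudocount rarely matters.
* **Imbalance threshold**: 2 HC standard deviations, strict inequality.
* **Liability conversion**: population prevalence $K = 0.02$; the published
  case-control conversion for ascertained samples (threshold $t=\Phi^{-1}(1-K)$,
  $C$ and $\theta$ as in the classical formula) is used, with the sample case
  fraction $P$ taken from the data.

## The synthetic-data generator

Real cohort data sit behind controlled access, so the package ships a
generator whose defaults encode the study conditions: four cohorts with
case/control sizes 71/165, 35/93, 73/75 and 125/142; a 54-gene panel with a
24-gene positively co-expressed module (target within-module $r = 0.7$) plus
two smaller modules (10 and 8 genes) that are anti-correlated with each
other; five covariates with small random per-gene slopes (so
residualisation is non-trivial); and sparse case perturbation — each case
has Poisson(mean 3) genes shifted by `delta` latent residual SDs with random
sign, applied *conditional on the module factor*, so the gene leaves its
stoichiometric relation while the factor is untouched. `delta` is a free
parameter (the study data do not pin a per-gene effect size); it is swept in
the tests, with `delta = 0` as the calibration null and `delta = 2` as the
default signal condition.

Counts are negative-binomial (dispersion 0.05) around each gene's expected
share of the sample's sequencing depth. The panel is treated as embedded in
a background transcriptome: 150 additional independent background genes
absorb most reads, so library sizes and the compositional RPKM
normalisation behave as they do when a small panel sits inside a full
transcriptome. Without this, the shared module factor dominates the panel's
read total and normalising by the column sum cancels the very co-expression
the method relies on. Background genes are excluded from the SI gene set.

What the generator does *not* emulate: isoform structure, batch effects
beyond the five covariates, cell-type composition shifts, and any
directional consistency of perturbation across cases (signs are random per
gene-case pair, so gene-level mean differences are weaker than in the real
data, where several genes show consistent over- or under-expression).
Passing tests therefore demonstrate calibration and recovery of injected
relative-expression perturbation under these idealised conditions — not
performance on real brain tissue.

## Numerical choices and degenerate inputs

* The in-sample $R^2$ on $M^k$ is used as the model weight; held-out $R^2$
  would be unstable at test sizes as small as 8.
* Genes with zero mean expression or a constant value on some modelling
  subset are dropped from that dataset's gene set with a warning, mirroring
  the 54–55 genes analysed per dataset out of 61.
* Genes with zero HC variance cannot be standardised and are dropped.
* The cross-dataset logistic fit is unpenalised maximum likelihood; perfect
  or quasi-separation (non-convergence, coefficient magnitudes above 10 on
  the sWSR scale, or degenerate fitted probabilities) falls back to a weak
  ridge fit with a warning.
* Rank-deficient covariate designs (e.g. a single-ethnicity cohort) drop
  the constant column with a warning.
* Ties at the nearest-gene fallback of locus prioritisation break by gene
  id, lexicographically; the L2G tie tolerance defaults to 0.05 absolute
  units.
* Medians of imbalanced-gene counts use the lower-median convention.

## Design decisions that were genuinely open

* **PCA outlier screen**: the original procedure is visual inspection of
  PC1/PC2. An automated proxy is used instead: flag samples more than 6
  MADs from the median on either of the first two components. On
  homogeneous Gaussian data this flags fewer than 1% of samples.
* **Case-modelling control analysis**: each mode standardises against its
  own modelling group, so the comparable quantity across modes is the
  per-gene case-vs-control contrast of mean sWSR, not the raw case mean
  (which is centred at zero under case-scaling by construction).
* **HC-split null**: controls are halved; models are fitted on resampled
  subsets of the first half and scores compared between held-out first-half
  members and the second half. Group labels in the returned object are
  pseudo-labels for exactly this comparison.
* **Cross-validation fold assignment** is unstratified uniform.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at reduced resampling depth (12–15
iterations instead of 100–1000, coarse LASSO paths) for the four-cohort
signal-recovery and control-analysis properties, and at the full 100
iterations for the null-calibration check, which is also what
`scripts/acceptance.R` recomputes over ten simulation replicates. These
sizes were chosen so the whole suite completes on a single CPU in well
under half an hour while leaving every scientific contrast comfortably
identified.

## Known limitations

* The SI score weights all genes equally; the cross-dataset logistic
  probabilities exist precisely because gene effects differ.
* Covariate residualisation is linear; non-linear age effects or hidden
  confounders are out of scope (no surrogate-variable correction).
* The liability-scale conversion assumes a single population prevalence and
  random ascertainment of cases given liability.
* With fewer than ~40 controls the resampling plan cannot both model and
  cover reliably; the plan repair warns rather than silently under-testing.
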