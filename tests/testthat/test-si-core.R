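test_that("resampling plans have the declared shape and are deterministic", {
  controls <- sprintf("c%03d", 1:165)
  plan <- make_plan(controls, model_size = 94, iterations = 100, seed = 2)
  expect_equal(plan$iterations, 100L)
  expect_true(all(vapply(plan$model_sets, length, numeric(1)) == 94))
  expect_true(all(vapply(plan$model_sets,
                         function(m) all(m %in% controls), logical(1))))
  # test sets have 71 controls each
  expect_true(all(vapply(plan$model_sets,
                         function(m) length(setdiff(controls, m)),
                         numeric(1)) == 71))
  plan2 <- make_plan(controls, 94, 100, seed = 2)
  expect_identical(plan$model_sets, plan2$model_sets)
  plan3 <- make_plan(controls, 94, iterations = 1, seed = 2,
                     ensure_coverage = FALSE)
  expect_equal(length(plan3$model_sets), 1L)
  expect_error(make_plan(controls, 165, 10),
               class = "stoichsi_validation_error")
})

test_that("coverage repair guarantees every control is tested at least once", {
  controls <- sprintf("c%02d", 1:20)
  # 15 of 20 modelled per iteration: some control is likely uncovered at
  # 5 iterations unless the plan is repaired
  plan <- make_plan(controls, model_size = 15, iterations = 5, seed = 3)
  tested <- unique(unlist(lapply(plan$model_sets,
                                 function(m) setdiff(controls, m))))
  expect_setequal(tested, controls)
  # a single split can never cover the modelled controls: warn, keep plan
  expect_warning(p1 <- make_plan(controls, 15, iterations = 1, seed = 3),
                 "cannot hold out")
  expect_equal(length(p1$model_sets), 1L)
})

test_that("weighted scaled residuals follow the defining arithmetic", {
  expect_equal(compute_wsr(10, 9, 0.8, 10), 0.08)
  expect_equal(compute_wsr(7, 7, 0.9, 3), 0)       # perfect prediction
  expect_equal(compute_wsr(10, 2, 0, 5), 0)        # uninformative model
  expect_error(compute_wsr(1, 0, 0.5, 0), class = "stoichsi_validation_error")
})

test_that("iteration averaging uses only qualifying iterations", {
  # 2 individuals x 1 gene x 4 iterations; individual a in model sets 1,2
  wsr <- array(NA_real_, c(2, 1, 4), dimnames = list(c("a", "b"), "g", NULL))
  wsr["a", "g", 3:4] <- c(4, 6)
  wsr["b", "g", ] <- c(1, 2, 3, 4)  # a case: scored in all iterations
  in_model <- rbind(a = c(TRUE, TRUE, FALSE, FALSE),
                    b = rep(FALSE, 4))
  agg <- aggregate_wsr(wsr, in_model)
  expect_equal(agg["a", "g"], 5)        # mean of iterations 3,4 only
  expect_equal(agg["b", "g"], 2.5)
  in_model_bad <- rbind(a = rep(TRUE, 4), b = rep(FALSE, 4))
  expect_error(aggregate_wsr(wsr, in_model_bad),
               class = "stoichsi_validation_error")
})

test_that("SI score is the mean absolute standardised residual", {
  expect_equal(si_score(c(0, 0, 0)), 0)
  expect_equal(si_score(c(1, -1, 1, -1)), 1)
  expect_equal(si_score(c(2, 0, 0, 0)), 0.5)
  m <- rbind(a = c(2, 0, 0, 0), b = c(1, -1, 1, -1))
  expect_equal(unname(si_score(m)), c(0.5, 1))
})

test_that("gene models recover exact linear structure and reject noise", {
  set.seed(4)
  n <- 60
  ids <- paste0("s", 1:n)
  g2 <- rnorm(n); g3 <- rnorm(n)
  expr <- rbind(target = 2 * g2 - g3, g2 = g2, g3 = g3,
                noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(expr) <- ids
  covars <- cbind(age = rnorm(n), RIN = rnorm(n))
  rownames(covars) <- ids
  fm <- fit_gene_model(expr, covars, "target", ids[1:50], seed = 1)
  expect_gt(fm$r2, 0.98)
  expect_gt(abs(fm$beta["g2"]), 1)      # true predictors retained
  expect_gt(abs(fm$beta["g3"]), 0.5)
  expect_lt(abs(fm$beta["noise1"]), 0.1)

  # independent target: all gene coefficients shrunk away at lambda_1se
  expr2 <- expr
  expr2["target", ] <- rnorm(n)
  fm2 <- fit_gene_model(expr2, covars, "target", ids[1:50], seed = 1)
  expect_lt(fm2$r2, 0.3)
  expect_true(all(abs(fm2$beta[c("g2", "g3", "noise1", "noise2")]) < 1e-8))

  # unpenalised covariate with a strong effect is always retained
  expr3 <- expr
  expr3["target", ] <- 3 * covars[, "age"] + rnorm(n, 0, 0.1)
  fm3 <- fit_gene_model(expr3, covars, "target", ids[1:50], seed = 1)
  expect_gt(abs(fm3$beta["age"]), 1)

  expect_error(fit_gene_model(rbind(expr, const = rep(1, n)), covars,
                              "const", ids[1:50], seed = 1),
               class = "stoichsi_constant_target")
})

test_that("the lean 1-SE cross-validation agrees with cv.glmnet", {
  set.seed(14)
  n <- 80; p <- 12
  x <- matrix(rnorm(n * p), n, p)
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(n)
  pf <- c(rep(1, p - 2), 0, 0)
  lean <- stoichsi:::lasso_cv_1se(x, y, pf, nfolds = 10, nlambda = 40,
                                  seed = 99)
  cvg <- glmnet::cv.glmnet(x, y, penalty.factor = pf,
                           lambda = lean$lambda_path,
                           foldid = lean$foldid)
  expect_equal(unname(lean$cvm), unname(cvg$cvm), tolerance = 1e-8)
  expect_equal(lean$lambda, cvg$lambda.1se, tolerance = 1e-10)
})

test_that("the full pipeline matches a brute-force Eq-chain recomputation", {
  # 4 genes, 20 samples, 2 iterations: recompute wsr/WSR/sWSR/SI by loops
  set.seed(15)
  n <- 20
  ids <- paste0("s", 1:n)
  # sex/ethnicity held constant: with 7-sample modelling sets the design
  # must stay comfortably overdetermined for the unpenalised block
  samples <- data.frame(sample_id = ids,
                        diagnosis = rep(c("BD", "HC"), c(6, 14)),
                        age = runif(n, 20, 80),
                        sex = rep("M", n),
                        ethnicity = rep("Cauc", n),
                        RIN = runif(n, 5, 9), PMI = runif(n, 5, 50))
  f <- rnorm(n)
  expr <- rbind(g1 = 4 + f + rnorm(n, 0, 0.4),
                g2 = 5 + f + rnorm(n, 0, 0.4),
                g3 = 6 - f + rnorm(n, 0, 0.4),
                g4 = 5 + rnorm(n, 0, 0.4))
  colnames(expr) <- ids
  hc_ids <- ids[samples$diagnosis == "HC"]
  plan <- make_plan(hc_ids, model_size = 7, iterations = 2, seed = 8)
  fit <- suppressWarnings(
    si_fit(expr, samples, plan = plan, seed = 8, nlambda = 20,
           min_model_size = 5, keep_iterations = TRUE))
  oracle <- suppressWarnings(
    oracle_si_chain(expr, samples, plan, seed = 8, nlambda = 20))
  scored <- rownames(fit$WSR)
  expect_equal(fit$WSR, oracle$WSR[scored, , drop = FALSE],
               tolerance = 1e-10)
  expect_equal(fit$sWSR, oracle$sWSR[scored, , drop = FALSE],
               tolerance = 1e-10)
  expect_equal(fit$si, oracle$si[scored], tolerance = 1e-10)
})

test_that("no scored individual ever contributes to its own model", {
  sf <- signal_fit()
  expect_true(audit_leakage(sf$fit))
  # tamper with the bookkeeping: the audit must catch it
  bad <- sf$fit
  bad$n_iterations_used[1] <- bad$n_iterations_used[1] + 1
  expect_error(audit_leakage(bad), "bookkeeping")
})

test_that("SI scores are invariant to gene and sample order", {
  sp <- small_prep(n_cases = 10L, n_controls = 24L, n_genes = 8L, seed = 51)
  prep <- sp$prep
  panel <- intersect(sp$cohort$gene_set, prep$kept_genes)
  expr1 <- prep$log2_rpkm[panel, ]
  fit1 <- si_fit(expr1, prep$samples, iterations = 4, nlambda = 10, seed = 5,
                 min_model_size = 10)
  fit2 <- si_fit(expr1[rev(panel), ], prep$samples, iterations = 4,
                 nlambda = 10, seed = 5, min_model_size = 10)
  expect_equal(fit2$si[names(fit1$si)], fit1$si, tolerance = 1e-8)
})

test_that("mean case SI increases with the perturbation magnitude", {
  mean_case_si <- function(delta) {
    sp <- small_prep(n_cases = 15L, n_controls = 30L, delta = delta,
                     n_genes = 12L, seed = 61L)
    fit <- si_fit(sp$prep, genes = sp$cohort$gene_set, iterations = 6,
                  nlambda = 10, seed = 61, min_model_size = 10)
    mean(fit$si[fit$diagnosis == "BD"])
  }
  vals <- vapply(c(0, 1, 2, 4), mean_case_si, numeric(1))
  expect_true(all(diff(vals) > -0.02))  # monotone up to small jitter
  expect_gt(vals[4], vals[1])
})

test_that("null data give indistinguishable case and control SI", {
  nf <- null_fit()
  fit <- nf$fit
  ks <- suppressWarnings(
    ks.test(fit$si[fit$diagnosis == "BD"], fit$si[fit$diagnosis == "HC"]))
  expect_gt(ks$p.value, 0.05)
})

test_that("perturbed genes score extreme sWSR in the cases carrying them", {
  sf <- signal_fit()
  fit <- sf$fit
  truth <- sf$cohort$truth
  truth <- truth[truth$gene_id %in% colnames(fit$sWSR) &
                   truth$sample_id %in% rownames(fit$sWSR), ]
  hit <- abs(fit$sWSR[cbind(truth$sample_id, truth$gene_id)])
  background <- mean(abs(fit$sWSR[fit$diagnosis == "HC", ]))
  expect_gt(mean(hit), 2 * background)
})

test_that("case-modelling swap reproduces the gene-level imbalance pattern", {
  sp <- cached("swap_prep", small_prep(n_cases = 40L, n_controls = 40L,
                                       delta = 3, n_genes = 16L, seed = 71L))
  fit_hc <- si_fit(sp$prep, genes = sp$cohort$gene_set, iterations = 8,
                   nlambda = 10, seed = 71, mode = "model_on_controls")
  fit_bd <- si_fit(sp$prep, genes = sp$cohort$gene_set, iterations = 8,
                   nlambda = 10, seed = 72, mode = "model_on_cases")
  genes <- intersect(colnames(fit_hc$sWSR), colnames(fit_bd$sWSR))
  # compare the per-gene case-vs-control contrast: the scaling reference
  # differs between the two modes, the group contrast must not
  contrast <- function(fit) {
    bd <- fit$true_diagnosis == "BD"
    colMeans(fit$sWSR[bd, genes, drop = FALSE]) -
      colMeans(fit$sWSR[!bd, genes, drop = FALSE])
  }
  # at this panel size the sign concordance is noisy; the fitted patterns
  # must nonetheless agree as continuous quantities (the sharp threshold is
  # checked at full cohort scale in the acceptance suite)
  expect_gt(cor(contrast(fit_hc), contrast(fit_bd)), 0.3)
  # the case-modelled run scales by the case group: its cases centre near 0
  bd2 <- fit_bd$true_diagnosis == "BD"
  expect_lt(abs(mean(fit_bd$sWSR[bd2, ])), 0.1)
})

test_that("hc-split null mode uses only controls and finds no signal", {
  sp <- small_prep(n_cases = 10L, n_controls = 60L, delta = 3,
                   n_genes = 12L, seed = 81L)
  fit <- si_fit(sp$prep, genes = sp$cohort$gene_set,
                mode = "hc_split_null", iterations = 6,
                nlambda = 10, seed = 81, min_model_size = 15)
  expect_true(all(fit$true_diagnosis == "HC"))
  p <- suppressWarnings(wilcox.test(fit$si[fit$diagnosis == "BD"],
                                    fit$si[fit$diagnosis == "HC"])$p.value)
  expect_gt(p, 0.01)
})
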