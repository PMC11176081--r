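test_that("TMM factors are 1 for depth-only differences", {
  set.seed(1)
  a <- rpois(100, 50) + 1L
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("g", 1:100)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(s1 = a, s2 = 2L * a)  # doubled depth, same composition
  rownames(m2) <- rownames(m)
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches a brute-force trimmed weighted mean oracle", {
  set.seed(42)
  for (rep in 1:3) {
    a <- rpois(100, 80) + 1L
    b <- a
    half <- sample(100, 50)
    b[half] <- 2L * b[half]  # composition shift in half the genes
    m <- cbind(s1 = a, s2 = b)
    rownames(m) <- paste0("g", 1:100)
    expect_equal(unname(tmm_factors(m)), unname(oracle_tmm(m)),
                 tolerance = 1e-8)
  }
})

test_that("scaling one library leaves other TMM factors unchanged", {
  set.seed(7)
  m <- matrix(rpois(300, 60) + 1L, 100, 3,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  f1 <- tmm_factors(m)
  m2 <- m; m2[, 2] <- 5L * m2[, 2]
  f2 <- tmm_factors(m2)
  expect_equal(f1[c(1, 3)] / f1[1], f2[c(1, 3)] / f2[1], tolerance = 1e-6)
})

test_that("log2 RPKM arithmetic is exact", {
  m <- matrix(c(1000L, 0L), 2, 1,
              dimnames = list(c("g1", "g2"), "s1"))
  # force the effective library to 1e7 via tmm factor
  lib <- sum(m)
  norm <- log2_rpkm(m, tmm = 1e7 / lib,
                    gene_lengths = c(g1 = 2000L, g2 = 500L), pseudocount = 0)
  expect_equal(norm$log2_rpkm["g1", 1], log2(50))  # ~5.644
  expect_equal(2^norm$log2_rpkm["g1", 1], 50)
  norm1 <- log2_rpkm(m, tmm = 1e7 / lib,
                     gene_lengths = c(g1 = 2000L, g2 = 500L), pseudocount = 1)
  expect_equal(norm1$log2_rpkm["g2", 1], 0)  # zero count, pseudocount 1
})

test_that("RPKM is invariant to joint count/library doubling", {
  set.seed(3)
  m <- matrix(rpois(60, 40) + 1L, 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  len <- setNames(rep(1000L, 20), rownames(m))
  r1 <- log2_rpkm(m, tmm = 1, gene_lengths = len, pseudocount = 0)
  r2 <- log2_rpkm(2L * m, tmm = 1, gene_lengths = len, pseudocount = 0)
  expect_equal(r1$log2_rpkm, r2$log2_rpkm, tolerance = 1e-12)
})

test_that("low-expression filter applies the 30% CPM boundary exactly", {
  # 10 samples, library sizes all 1e6 so CPM == count, threshold = 10
  base <- matrix(1000L, 3, 10,
                 dimnames = list(c("high", "seven", "six"), paste0("s", 1:10)))
  base["seven", ] <- c(rep(50L, 7), rep(1L, 3))   # above in 7/10: keep
  base["six", ] <- c(rep(50L, 6), rep(1L, 4))     # above in 6/10: remove
  filler <- matrix(rep((1e6 - colSums(base)) %/% 97L, each = 97),
                   97, 10, byrow = FALSE)
  m <- rbind(base, filler)
  rownames(m) <- c(rownames(base), paste0("f", 1:97))
  keep <- filter_low_expression(m)
  expect_true(keep[["high"]])
  expect_true(keep[["seven"]])
  expect_false(keep[["six"]])
  # all-zero gene is always removed
  m0 <- rbind(m, zero = rep(0L, 10))
  expect_false(filter_low_expression(m0)[["zero"]])
})

test_that("filter is monotone: adding counts never removes a kept gene", {
  set.seed(9)
  m <- matrix(rpois(200, 12), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  keep1 <- filter_low_expression(m)
  # boosting a gene's own counts can only help that gene
  for (g in c("g3", "g5", "g11")) {
    m2 <- m
    m2[g, ] <- m2[g, ] + 100L
    keep2 <- filter_low_expression(m2)
    expect_true(keep2[[g]] >= keep1[[g]], info = g)
  }
})

test_that("residualisation removes covariate effects and is orthogonal", {
  set.seed(5)
  n <- 80
  s <- data.frame(sample_id = paste0("s", 1:n),
                  diagnosis = rep(c("BD", "HC"), each = n / 2),
                  age = runif(n, 20, 80),
                  sex = sample(c("M", "F"), n, TRUE),
                  ethnicity = sample(c("Cauc", "Other"), n, TRUE),
                  RIN = runif(n, 5, 9), PMI = runif(n, 5, 50))
  g_age <- 2 * s$age + rnorm(n, 0, 1)
  g_flat <- rnorm(n)
  mat <- rbind(aged = g_age, flat = g_flat)
  colnames(mat) <- s$sample_id
  res <- residualize_covariates(mat, s)
  expect_lt(var(res$residual["aged", ]), 0.05 * var(g_age))
  expect_lt(abs(sum(res$residual["aged", ] * (s$age - mean(s$age)))), 1e-6)
  expect_lt(abs(sum(res$residual["flat", ])), 1e-8)  # intercept removed
})

test_that("covariate-free expression residualises to centred values", {
  set.seed(6)
  n <- 30
  s <- data.frame(sample_id = paste0("s", 1:n),
                  diagnosis = rep("HC", n),
                  age = rep(50, n), sex = rep("M", n),
                  ethnicity = rep("Cauc", n),
                  RIN = rep(7, n), PMI = rep(20, n))
  mat <- matrix(rnorm(2 * n), 2, n,
                dimnames = list(c("g1", "g2"), s$sample_id))
  expect_warning(res <- residualize_covariates(mat, s),
                 "constant covariate")
  expect_equal(res$residual, mat - rowMeans(mat), tolerance = 1e-10)
})

test_that("PCA screen flags gross outliers and ignores sample order", {
  set.seed(8)
  m <- matrix(rnorm(50 * 40), 50, 40,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  m[, 40] <- m[, 40] + 20  # one sample displaced on all genes
  scr <- pca_screen(m)
  expect_true(scr$outlier[scr$sample_id == "s40"])
  perm <- sample(40)
  scr2 <- pca_screen(m[, perm])
  expect_equal(scr2$outlier[match(scr$sample_id, scr2$sample_id)],
               scr$outlier)
})

test_that("PCA screen rarely flags homogeneous data", {
  set.seed(10)
  flags <- replicate(20, {
    m <- matrix(rnorm(30 * 50), 30, 50,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:50)))
    sum(pca_screen(m)$outlier)
  })
  expect_lt(mean(flags) / 50, 0.01)  # false-positive rate below 1%
})

test_that("HC standardisation yields mean 0 / sd 1 and is idempotent", {
  set.seed(12)
  m <- matrix(rnorm(5 * 30, mean = 4, sd = 2), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  diag <- rep(c("BD", "HC"), c(10, 20))
  z <- standardize_by_hc(m, diag)
  hc <- diag == "HC"
  expect_equal(unname(rowMeans(z[, hc])), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z[, hc], 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(standardize_by_hc(z, diag), z, tolerance = 1e-12)
  # a case sitting at HC mean + 2 sd maps to 2
  m2 <- m
  m2[1, 1] <- mean(m[1, hc]) + 2 * sd(m[1, hc])
  z2 <- standardize_by_hc(m2, diag)
  expect_equal(z2[1, 1], 2, tolerance = 1e-12)
  # zero-variance gene dropped with warning
  m3 <- m; m3[2, hc] <- 7
  expect_warning(z3 <- standardize_by_hc(m3, diag), "zero HC variance")
  expect_equal(nrow(z3), 4L)
})

test_that("preprocess_cohort drops under-18 samples and keeps dimensions consistent", {
  sp <- small_prep(seed = 41)
  co <- sp$cohort
  co$samples$age[1] <- 17
  prep <- preprocess_cohort(as_si_counts(co$counts, co$gene_lengths),
                            co$samples)
  expect_false(co$samples$sample_id[1] %in% prep$samples$sample_id)
  expect_equal(ncol(prep$log2_rpkm), nrow(prep$samples))
  expect_equal(rownames(prep$residual), prep$kept_genes)
})
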