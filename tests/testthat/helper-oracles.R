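# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, enumeration, closed forms) and share no code
# with the package internals.

# Robinson-Oshlack TMM, written directly from the definition: reference is
# the sample whose upper-quartile count fraction is closest to the mean;
# per sample, the doubly trimmed, inverse-variance-weighted mean of M-values
# against the reference; factors rescaled to geometric mean 1.
oracle_tmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    obs <- counts[, i] / lib[i]
    rf <- counts[, ref] / lib[ref]
    keep <- obs > 0 & rf > 0
    M <- log2(obs[keep] / rf[keep])
    A <- (log2(obs[keep]) + log2(rf[keep])) / 2
    w <- 1 / ((lib[i] - counts[keep, i]) / (lib[i] * counts[keep, i]) +
              (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref]))
    if (max(abs(M)) < 1e-6) return(1)  # edgeR short-circuit for equal libs
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1
    hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of group
# assignments (no ties assumed).
oracle_wilcoxon_exact <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  m <- length(x)
  idx <- utils::combn(n, m)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ws <- apply(idx, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  mu <- m * (n - m) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# BH step-up, computed from the definition m*p/i with cumulative minima.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# AUC by trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  pos <- labels == "BD" | labels == TRUE
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Nagelkerke R^2 via grid-search maximisation of the Bernoulli likelihood
# (intercept x slope grid), independent of glm.
oracle_nagelkerke_grid <- function(y, x, b0 = seq(-6, 6, by = 0.01),
                                   b1 = seq(-6, 6, by = 0.01)) {
  loglik <- function(a, b) {
    p <- 1 / (1 + exp(-(a + b * x)))
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  ll1 <- max(outer(b0, b1, Vectorize(loglik)))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  n <- length(y)
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

# Liability-scale conversion, transcribed independently (different algebraic
# arrangement of the same published transformation).
oracle_liability <- function(r2, K, P) {
  thd <- stats::qnorm(K, lower.tail = FALSE)
  zv <- stats::dnorm(thd)
  mv <- zv / K
  cc <- (K * (1 - K))^2 / (P * (1 - P)) / zv^2
  theta <- mv * ((P - K) / (1 - K)) * (mv * ((P - K) / (1 - K)) - thd)
  (cc * r2) / (1 + cc * theta * r2)
}

# Brute-force recomputation of the wsr / WSR / sWSR / SI chain from a fitted
# object that kept its per-iteration residual tensor inputs. Refits every
# (gene, iteration) model with fit_gene_model (same seeds), then rebuilds
# the aggregation with plain loops.
oracle_si_chain <- function(expr, samples, plan, seed, nlambda, nfolds = 10,
                            min_model_size = 5) {
  ids <- samples$sample_id
  gene_ids <- rownames(expr)
  covars <- stoichsi:::covariate_design(
    samples, c("age", "sex", "ethnicity", "RIN", "PMI"))[, -1, drop = FALSE]
  rownames(covars) <- ids
  gm <- rowMeans(expr)
  p <- plan$iterations
  wsr <- array(NA_real_, c(length(ids), length(gene_ids), p),
               dimnames = list(ids, gene_ids, NULL))
  for (k in seq_len(p)) {
    mk <- plan$model_sets[[k]]
    test_ids <- setdiff(ids, mk)
    for (j in seq_along(gene_ids)) {
      g <- gene_ids[j]
      fm <- fit_gene_model(
        expr, covars, g, mk, nfolds = nfolds, nlambda = nlambda,
        min_model_size = min_model_size,
        seed = stoichsi:::derive_seed(seed,
                                      1000L * stoichsi:::string_index(g) + k))
      pred <- predict(fm, expr, covars, test_ids)
      for (t in seq_along(test_ids)) {
        i <- test_ids[t]
        wsr[i, g, k] <- fm$r2 * (expr[g, i] - pred[t]) / gm[g]
      }
    }
  }
  WSR <- matrix(NA_real_, length(ids), length(gene_ids),
                dimnames = list(ids, gene_ids))
  for (i in ids) for (g in gene_ids) {
    v <- wsr[i, g, ]
    WSR[i, g] <- mean(v[!is.na(v)])
  }
  hc <- samples$diagnosis == "HC"
  sWSR <- WSR
  for (g in gene_ids) {
    mu <- mean(WSR[hc, g])
    sdv <- stats::sd(WSR[hc, g])
    sWSR[, g] <- (WSR[, g] - mu) / sdv
  }
  si <- apply(abs(sWSR), 1, mean)
  list(wsr = wsr, WSR = WSR, sWSR = sWSR, si = si)
}
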