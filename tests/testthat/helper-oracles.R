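# Independent oracle implementations used to cross-check the package.
# These deliberately work in plain probability space with stats densities,
# not the package's log-space / FFT code paths.

# NB (+) Poisson convolution pmf by direct summation
oracle_delap_pmf <- function(x, alpha, beta, lambda) {
  vapply(x, function(xi) {
    k <- 0:xi
    sum(dnbinom(k, size = alpha, prob = 1 / (beta + 1)) *
          dpois(xi - k, lambda))
  }, numeric(1))
}

# Null parameters of the pooled-count exact test, re-derived from the
# documented contract: common per-sample signal mean, each group keeps its
# own scale and background; pooling over n samples multiplies shape and
# Poisson mean by n.
oracle_null_params <- function(pa, pb, n1, n2) {
  mu0 <- (n1 * pa$alpha * pa$beta + n2 * pb$alpha * pb$beta) / (n1 + n2)
  list(a = list(alpha = n1 * mu0 / pa$beta, beta = pa$beta,
                lambda = n1 * pa$lambda),
       b = list(alpha = n2 * mu0 / pb$beta, beta = pb$beta,
                lambda = n2 * pb$lambda))
}

# Brute-force enumeration of the conditional exact test over a + b = x + y.
# The relative tie tolerance is part of the test's definition (as in
# fisher.test); probabilities come from the independent pmf above.
oracle_exact_p <- function(x, y, pa, pb, n1 = 1, n2 = 1) {
  z <- x + y
  if (z == 0) return(1)
  np <- oracle_null_params(pa, pb, n1, n2)
  fa <- oracle_delap_pmf(0:z, np$a$alpha, np$a$beta, np$a$lambda)
  fb <- oracle_delap_pmf(0:z, np$b$alpha, np$b$beta, np$b$lambda)
  terms <- fa * rev(fb)
  pobs <- terms[x + 1]
  sum(terms[terms <= pobs * (1 + 1e-7)]) / sum(terms)
}

# Beta-approximation p-value re-evaluated from the printed formulas with
# stats::dbeta/qbeta
oracle_beta_p <- function(x, y, n1, n2) {
  z <- x + y
  if (z == 0) return(1)
  mu <- z / (n1 + n2)
  a <- n1 * mu / (1 + n1 / mu)
  b <- n2 * mu / (1 + n2 / mu)
  med <- qbeta(0.5, a, b)
  kp <- (x + 0.5) / z
  km <- (x - 0.5) / z
  if (kp < med) k <- kp
  else if (km > med) k <- km
  else return(1)
  min(2 * dbeta(k, a, b), 1)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood rule)
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m + n == 0) return(1)
  a_all <- max(0, k - n):min(k, m)
  probs <- dhyper(a_all, m, n, k)
  pobs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the textbook step-up recipe
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# AUC by explicit concordant-pair counting
oracle_auc <- function(pvals, labels) {
  de <- pvals[labels]
  nde <- pvals[!labels]
  conc <- 0
  for (a in de) conc <- conc + sum(a < nde) + 0.5 * sum(a == nde)
  conc / (length(de) * length(nde))
}

extdata <- function(f) system.file("extdata", f, package = "dexbg")

`%||%` <- function(a, b) if (is.null(a)) b else a
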