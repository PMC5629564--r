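#' Moderated exact test for two pooled Delaporte counts
#'
#' Conditional exact test of equal signal means between two groups, given
#' pooled per-group counts `x` and `y` and per-group Delaporte parameter
#' estimates.  All outcomes \eqn{(a, b)} with \eqn{a + b = x + y} are
#' enumerated; the probability of each is the product of per-group Delaporte
#' densities evaluated under the null of a common signal mean, and the
#' p-value is the total probability of outcomes no more likely than the one
#' observed, normalized by the total over all outcomes.
#'
#' The null parameters are built by rescaling both groups' gamma shapes so
#' their per-sample signal means equal the pooled signal mean
#' \eqn{\mu_0 = (n_1 \alpha_A \beta_A + n_2 \alpha_B \beta_B)/(n_1 + n_2)}
#' while each group keeps its own scale \eqn{\beta} (and hence its own
#' mean-variance relationship) and its own background mean \eqn{\lambda}.
#' Because `x` is a sum over \eqn{n_1} samples, the pooled count follows a
#' Delaporte with shape \eqn{n_1 \mu_0/\beta_A} and Poisson mean
#' \eqn{n_1 \lambda_A} (sums of iid negative binomials and Poissons stay in
#' family), and correspondingly for `y`.
#'
#' @param x,y pooled (summed) depth-normalized counts of groups A and B,
#'   rounded to integers.
#' @param params_a,params_b lists with per-sample `alpha`, `beta`, `lambda`
#'   estimates for each group (e.g. from [estimate_params_np()]).
#' @param n1,n2 number of samples pooled into `x` and `y`.
#' @return two-sided p-value in (0, 1].  `x + y = 0` returns 1 by convention.
#' @seealso [beta_approx_test()] for the large-count approximation.
#' @examples
#' pp <- list(alpha = 2, beta = 2, lambda = 1)
#' delap_exact_test(15, 5, pp, pp, n1 = 3, n2 = 3)
#' @export
delap_exact_test <- function(x, y, params_a, params_b, n1 = 1, n2 = 1) {
  stopifnot(x >= 0, y >= 0, n1 >= 1, n2 >= 1)
  z <- x + y
  if (z == 0) return(1)
  mu0 <- (n1 * params_a$alpha * params_a$beta +
            n2 * params_b$alpha * params_b$beta) / (n1 + n2)
  mu0 <- max(mu0, 1e-8)
  beta_a <- max(params_a$beta, 1e-8)
  beta_b <- max(params_b$beta, 1e-8)
  pa <- delap_pmf_vec(z, n1 * mu0 / beta_a, beta_a, n1 * params_a$lambda)
  pb <- delap_pmf_vec(z, n2 * mu0 / beta_b, beta_b, n2 * params_b$lambda)
  terms <- pa * rev(pb)                    # P(a, z - a) for a = 0..z
  tot <- sum(terms)
  if (tot <= 0) return(1)
  pobs <- terms[x + 1]
  # relative tolerance on the tie comparison, as in standard exact tests
  p <- sum(terms[terms <= pobs * (1 + 1e-7)]) / tot
  min(max(p, 1e-320), 1)
}

#' Beta-approximation test for two pooled counts
#'
#' Fast large-count approximation to the exact test.  With pooled counts
#' \eqn{x} and \eqn{y}, \eqn{z = x + y} and \eqn{\mu = z/(n_1 + n_2)}, the
#' proportion \eqn{x/z} is referred to a beta distribution with shapes
#' \eqn{\alpha = n_1\mu/(1 + n_1/\mu)} and \eqn{\beta = n_2\mu/(1 + n_2/\mu)}.
#' The evaluation point is continuity-corrected toward the central beta
#' quantile `med = qbeta(0.5, alpha, beta)`: \eqn{k = (x + 0.5)/z} when that
#' is below `med`, \eqn{k = (x - 0.5)/z} when that is above `med`, and the
#' statistic is twice the beta density at \eqn{k}:
#' \deqn{p = 2 k^{\alpha-1} (1-k)^{\beta-1} / B(\alpha, \beta).}
#' This expression is a (doubled) density, not a tail integral, and can
#' exceed 1; it is clamped into (0, 1].  When the corrected points straddle
#' `med` the observation sits at the distribution's center and p = 1.
#'
#' @inheritParams delap_exact_test
#' @return p-value in (0, 1]; vectorized over `x` and `y`.
#' @examples
#' beta_approx_test(600, 400, n1 = 3, n2 = 3)
#' @export
beta_approx_test <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), n1 >= 1, n2 >= 1)
  n <- max(length(x), length(y))
  x <- rep_len(as.double(x), n); y <- rep_len(as.double(y), n)
  z <- x + y
  p <- rep(1, n)
  ok <- z > 0
  if (!any(ok)) return(p)
  mu <- z[ok] / (n1 + n2)
  a <- n1 * mu / (1 + n1 / mu)
  b <- n2 * mu / (1 + n2 / mu)
  med <- qbeta(0.5, a, b)
  kp <- (x[ok] + 0.5) / z[ok]
  km <- (x[ok] - 0.5) / z[ok]
  k <- ifelse(kp < med, kp, ifelse(km > med, km, NA_real_))
  lp <- log(2) + (a - 1) * log(k) + (b - 1) * log1p(-k) - lbeta(a, b)
  pv <- exp(pmin(lp, 0))                   # clamp at 1
  pv[is.na(k)] <- 1                        # straddle: central observation
  pv <- pmax(pv, 1e-320)
  p[ok] <- pv
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper around
#' [stats::p.adjust()] with input validation).
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) ||
      any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Background-aware differential expression testing
#'
#' Fits the Poisson-negative binomial convolution model gene by gene and
#' tests for differential expression between two groups.  The observed
#' exonic count of a gene is modelled as latent negative binomial signal
#' plus Poisson background noise, with the background level measured by a
#' matched matrix of non-exonic counts.  Per group, the three Delaporte
#' parameters are estimated (moment-based by default, maximum likelihood on
#' request); per-group counts are depth-normalized, summed and rounded, and
#' the pooled pair is tested with the moderated exact test
#' ([delap_exact_test()]) when the pooled total is at most `big_count`, or
#' with the fast beta approximation ([beta_approx_test()]) above it.
#'
#' Genes with zero total count are untestable and reported with p = 1; they
#' are excluded from the Benjamini-Hochberg denominator so that hypotheses
#' that cannot reject do not dilute the correction.
#'
#' @param X gene-by-sample matrix of observed exonic counts.
#' @param B gene-by-sample matrix of observed background counts, congruent
#'   with `X`.
#' @param groups two-level factor (or coercible) of length `ncol(X)`; the
#'   first level is treated as the reference group.
#' @param est_method `"np"` for moment estimation (default, preferred for
#'   small groups) or `"mle"` for per-gene maximum likelihood (recommended
#'   for more than about 10 samples per group).
#' @param big_count pooled-count threshold routing a gene from the exact
#'   enumeration (cost linear in the pooled total) to the beta
#'   approximation.  Default 900.
#' @param size_factors optional per-sample depth factors; computed by
#'   [estimate_size_factors()] from `X` when omitted.
#' @return an object of class `"dexbg"`: a list with elements `results` (a
#'   data frame with columns `gene_id`, `mean_A`, `mean_B`, `mean_expr`,
#'   `log2fc`, `pval`, `padj`, `test`), `params` (per-group parameter
#'   matrices), `size_factors`, `groups`, `est_method`, `big_count`, `call`.
#'   Methods: [print.dexbg()], [summary.dexbg()], [coef.dexbg()],
#'   [plot.dexbg()], [simulate.dexbg()], [de_results()], [filter_de()].
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 200, seed = 7))
#' fit <- dexbg(sim$X, sim$B, sim$groups)
#' head(de_results(fit))
#' @export
dexbg <- function(X, B, groups, est_method = c("np", "mle"), big_count = 900,
                  size_factors = NULL) {
  est_method <- match.arg(est_method)
  X <- as.matrix(X); B <- as.matrix(B)
  if (!identical(dim(X), dim(B)))
    stop("'X' and 'B' must have identical dimensions", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  groups <- as.factor(groups)
  if (length(groups) != ncol(X))
    stop("'groups' must have one label per sample", call. = FALSE)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two group levels are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples for parameter estimation",
         call. = FALSE)
  lvl <- levels(groups)
  ia <- which(groups == lvl[1]); ib <- which(groups == lvl[2])
  n1 <- length(ia); n2 <- length(ib)

  if (is.null(size_factors)) size_factors <- estimate_size_factors(X)
  stopifnot(length(size_factors) == ncol(X), all(size_factors > 0))
  Xn <- sweep(X, 2, size_factors, "/")
  Bn <- sweep(B, 2, size_factors, "/")

  est_group <- function(idx) {
    if (est_method == "np")
      return(np_estimate_matrix(Xn[, idx, drop = FALSE],
                                Bn[, idx, drop = FALSE]))
    t(vapply(seq_len(nrow(X)), function(i) {
      f <- estimate_params_mle(Xn[i, idx], Bn[i, idx])
      c(alpha = f$alpha, beta = f$beta, lambda = f$lambda)
    }, numeric(3)))
  }
  pa <- est_group(ia)
  pb <- est_group(ib)

  xs <- as.integer(round(rowSums(Xn[, ia, drop = FALSE])))
  ys <- as.integer(round(rowSums(Xn[, ib, drop = FALSE])))
  z <- xs + ys
  pval <- rep(1, nrow(X))
  test <- rep("none", nrow(X))

  beta_idx <- which(z > big_count)
  if (length(beta_idx)) {
    pval[beta_idx] <- beta_approx_test(xs[beta_idx], ys[beta_idx], n1, n2)
    test[beta_idx] <- "beta"
  }
  exact_idx <- which(z > 0 & z <= big_count)
  for (i in exact_idx) {
    pval[i] <- delap_exact_test(
      xs[i], ys[i],
      list(alpha = pa[i, 1], beta = pa[i, 2], lambda = pa[i, 3]),
      list(alpha = pb[i, 1], beta = pb[i, 2], lambda = pb[i, 3]),
      n1 = n1, n2 = n2)
    test[i] <- "exact"
  }

  padj <- rep(1, nrow(X))
  tested <- z > 0
  padj[tested] <- bh_adjust(pval[tested])

  mean_a <- rowMeans(Xn[, ia, drop = FALSE])
  mean_b <- rowMeans(Xn[, ib, drop = FALSE])
  res <- data.frame(
    gene_id = rownames(X),
    mean_A = mean_a,
    mean_B = mean_b,
    mean_expr = (n1 * mean_a + n2 * mean_b) / (n1 + n2),
    log2fc = log2((mean_b + 1e-8) / (mean_a + 1e-8)),
    pval = pval,
    padj = padj,
    test = test,
    row.names = NULL,
    stringsAsFactors = FALSE)

  structure(list(results = res,
                 params = list(A = pa, B = pb),
                 size_factors = size_factors,
                 groups = groups,
                 est_method = est_method,
                 big_count = big_count,
                 call = match.call()),
            class = "dexbg")
}

#' Extract the per-gene result table
#'
#' @param object a fitted `"dexbg"` object.
#' @return the result data frame (see [dexbg()]).
#' @export
de_results <- function(object) {
  stopifnot(inherits(object, "dexbg"))
  object$results
}

#' @export
print.dexbg <- function(x, ...) {
  tab <- table(x$results$test)
  cat("Background-aware differential expression fit\n")
  cat(sprintf("  %d genes, %d + %d samples (%s vs %s)\n",
              nrow(x$results), sum(x$groups == levels(x$groups)[1]),
              sum(x$groups == levels(x$groups)[2]),
              levels(x$groups)[1], levels(x$groups)[2]))
  cat(sprintf("  estimation: %s; big_count = %g\n", x$est_method,
              x$big_count))
  cat("  test routing:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  genes with padj < 0.1: %d\n", sum(x$results$padj < 0.1)))
  invisible(x)
}

#' @export
summary.dexbg <- function(object, fc_min = 1.5, expr_quantile = 0.5,
                          padj_max = 0.1, ...) {
  hits <- filter_de(object, fc_min = fc_min, expr_quantile = expr_quantile,
                    padj_max = padj_max)
  out <- list(n_genes = nrow(object$results),
              n_tested = sum(object$results$test != "none"),
              n_signif = nrow(hits),
              thresholds = c(fc_min = fc_min, expr_quantile = expr_quantile,
                             padj_max = padj_max),
              size_factors = object$size_factors,
              top = utils::head(hits[order(hits$padj), ], 10))
  class(out) <- "summary.dexbg"
  out
}

#' @export
print.summary.dexbg <- function(x, ...) {
  cat(sprintf("%d genes (%d testable); %d pass |FC| >= %.2g, expression > %g quantile, padj < %.2g\n",
              x$n_genes, x$n_tested, x$n_signif, x$thresholds["fc_min"],
              x$thresholds["expr_quantile"], x$thresholds["padj_max"]))
  if (nrow(x$top)) {
    cat("Top genes:\n")
    print(x$top, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dexbg <- function(object, ...) {
  out <- cbind(object$params$A, object$params$B)
  colnames(out) <- c(paste0(colnames(object$params$A), "_A"),
                     paste0(colnames(object$params$B), "_B"))
  rownames(out) <- object$results$gene_id
  out
}

#' MA-style plot of a differential expression fit
#'
#' @param x a `"dexbg"` object.
#' @param padj_max genes below this adjusted p are highlighted.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dexbg <- function(x, padj_max = 0.1, ...) {
  r <- x$results
  sig <- r$padj < padj_max
  plot(log10(r$mean_expr + 1), r$log2fc,
       pch = 20, cex = 0.4, col = ifelse(sig, "red3", "grey50"),
       xlab = "log10 mean normalized count + 1",
       ylab = "log2 fold change", ...)
  abline(h = 0, col = "grey30", lty = 2)
  invisible(x)
}

#' Simulate counts from a fitted model
#'
#' Draws new exonic count matrices from the fitted per-group Delaporte
#' parameters, one replicate dataset per `nsim`.
#'
#' @param object a `"dexbg"` object.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` gene-by-sample integer matrices with the same
#'   shape and group layout as the fitted data.
#' @export
simulate.dexbg <- function(object, nsim = 1, seed = 1, ...) {
  gr <- object$groups
  lvl <- levels(gr)
  ng <- nrow(object$results)
  with_seed(seed, lapply(seq_len(nsim), function(s) {
    m <- matrix(0L, ng, length(gr))
    for (g in 1:2) {
      idx <- which(gr == lvl[g])
      p <- object$params[[g]]
      for (j in idx)
        m[, j] <- rnbinom(ng, size = p[, "alpha"],
                          prob = 1 / (1 + p[, "beta"])) +
          rpois(ng, p[, "lambda"])
    }
    dimnames(m) <- list(object$results$gene_id, names(object$size_factors))
    m
  }))
}

#' Filter differential expression results
#'
#' Applies the standard reporting filter: two-sided fold change at least
#' `fc_min`, mean normalized expression above the `expr_quantile` quantile of
#' all genes' means, and adjusted p below `padj_max`.
#'
#' @param object a `"dexbg"` fit or its result data frame.
#' @param fc_min minimum fold change, applied two-sidedly (a gene passes if
#'   its fold change is >= `fc_min` or <= 1/`fc_min`).
#' @param expr_quantile expression-quantile cutoff in \[0, 1\] (0.5 keeps
#'   genes above the median).
#' @param padj_max adjusted-p cutoff (exclusive).
#' @return the filtered result data frame.
#' @export
filter_de <- function(object, fc_min = 1.5, expr_quantile = 0.5,
                      padj_max = 0.1) {
  res <- if (inherits(object, "dexbg")) object$results else object
  stopifnot(is.data.frame(res), nrow(res) > 0)
  fc_ok <- abs(res$log2fc) >= log2(max(fc_min, 1))
  expr_thr <- if (expr_quantile <= 0) -Inf else
    quantile(res$mean_expr, expr_quantile)
  expr_ok <- res$mean_expr > expr_thr
  p_ok <- res$padj < padj_max
  res[fc_ok & expr_ok & p_ok & !is.na(p_ok), , drop = FALSE]
}
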