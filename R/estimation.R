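#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed by the median-of-ratios
#' convention: each sample's counts are divided by the per-gene geometric
#' mean across samples, and the sample's factor is the median of those ratios
#' over genes with strictly positive counts in every sample.  Factors are
#' rescaled to geometric mean 1 so that normalized counts stay on the scale
#' of the raw data.
#'
#' @param counts gene-by-sample matrix of non-negative counts.
#' @return numeric vector of positive size factors, one per sample, with
#'   geometric mean 1.
#' @examples
#' m <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2)
#' estimate_size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(counts) == 1L) {
    sf <- 1
    names(sf) <- colnames(counts)
    return(sf)
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; size factors are ",
         "undefined (consider a pseudo-reference fallback)", call. = FALSE)
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric mean per gene
  sf <- exp(apply(lg - ref, 2, median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Background Poisson mean estimate
#'
#' Estimates the Poisson background mean \eqn{\lambda} of a gene as the mean
#' of its depth-normalized background counts.
#'
#' @param b per-sample observed background counts for one gene.
#' @param sf per-sample size factors (default all 1).
#' @return non-negative scalar estimate of \eqn{\lambda}.
#' @export
estimate_lambda <- function(b, sf = rep(1, length(b))) {
  stopifnot(length(b) == length(sf), all(sf > 0))
  mean(b / sf)
}

# Vectorized moment estimation across the rows of normalized count matrices.
# Returns a matrix with columns alpha, beta, lambda.
np_estimate_matrix <- function(xn, bn, eps = 1e-8) {
  lam <- rowMeans(bn)
  mu_x <- rowMeans(xn)
  v_x <- apply(xn, 1, var)
  mu_s <- pmax(mu_x - lam, eps)
  v_s <- pmax(v_x - lam, mu_s * (1 + eps))
  beta <- v_s / mu_s - 1
  alpha <- mu_s / beta
  cbind(alpha = alpha, beta = beta, lambda = lam)
}

#' Moment-based (non-parametric) parameter estimation
#'
#' Estimates the Delaporte parameters \eqn{(\alpha, \beta, \lambda)} of one
#' gene from its observed exonic counts `x` and background counts `b` by
#' moment matching.  After depth normalization, \eqn{\lambda} is the mean of
#' the background counts; the signal mean and variance are the observed mean
#' and variance of the exonic counts minus the Poisson background
#' contribution (\eqn{\lambda} for both, since a Poisson's variance equals
#' its mean); and \eqn{(\alpha, \beta)} invert the negative binomial moments
#' \eqn{\mu_S = \alpha\beta}, \eqn{v_S = \alpha\beta(1+\beta)}.
#'
#' The signal mean is floored at `eps` and the signal variance at
#' \eqn{\mu_S (1 + eps)}, so apparently under-dispersed genes degrade to a
#' near-Poisson signal (tiny \eqn{\beta}) rather than an invalid fit.
#'
#' @param x per-sample observed exonic counts for one gene (length >= 2).
#' @param b per-sample observed background counts for the same gene.
#' @param sf per-sample size factors.
#' @param eps numerical floor guarding the moment inversion.
#' @return a list with components `alpha`, `beta`, `lambda`.
#' @examples
#' estimate_params_np(x = c(18, 20, 25, 17), b = c(4, 6, 5, 5))
#' @export
estimate_params_np <- function(x, b, sf = rep(1, length(x)), eps = 1e-8) {
  if (length(x) < 2)
    stop("moment estimation needs at least 2 replicates", call. = FALSE)
  stopifnot(length(b) == length(x), length(sf) == length(x), all(sf > 0))
  est <- np_estimate_matrix(matrix(x / sf, nrow = 1), matrix(b / sf, nrow = 1),
                            eps = eps)
  list(alpha = unname(est[1, "alpha"]), beta = unname(est[1, "beta"]),
       lambda = unname(est[1, "lambda"]))
}

#' Joint log-likelihood of one gene's counts
#'
#' The log of the product of the Delaporte likelihood of the observed exonic
#' counts and the Poisson likelihood of the observed background counts, with
#' one \eqn{\lambda} shared across samples and both factors.
#'
#' @inheritParams estimate_params_np
#' @param alpha,beta,lambda Delaporte parameters.
#' @return scalar log-likelihood.
#' @export
delap_loglik <- function(x, b, alpha, beta, lambda) {
  xmax <- max(x)
  pmf <- delap_pmf_vec(xmax, alpha, beta, lambda)
  lx <- log(pmax(pmf[x + 1], 1e-320))
  sum(lx) + sum(dpois(b, lambda, log = TRUE))
}

#' Maximum likelihood parameter estimation
#'
#' Maximizes the joint likelihood of one gene's exonic and background counts
#' over \eqn{(\alpha, \beta, \lambda)} by quasi-Newton (BFGS) iteration with
#' numerical gradients.  Optimization is performed over the log parameters,
#' which enforces positivity without a constrained solver.  Counts are
#' depth-normalized and rounded to integers before the likelihood is
#' evaluated (the convolution density has integer support).
#'
#' On non-convergence the best point found is returned with
#' `converged = FALSE`; the returned log-likelihood is never allowed to fall
#' below the initial value minus `tol` (the initial point is returned
#' instead).
#'
#' @inheritParams estimate_params_np
#' @param init optional list with `alpha`, `beta`, `lambda` starting values;
#'   defaults to the moment estimate ([estimate_params_np()]).
#' @param max_iter maximum BFGS iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @return a list with `alpha`, `beta`, `lambda`, `loglik`, `converged`.
#' @examples
#' x <- rdelap(20, alpha = 3, beta = 1.5, lambda = 2, seed = 1)
#' b <- rdelap(20, alpha = 1, beta = 1e-8, lambda = 2, seed = 2)  # ~ Poisson(2)
#' estimate_params_mle(x, b)
#' @export
estimate_params_mle <- function(x, b, sf = rep(1, length(x)), init = NULL,
                                max_iter = 200, tol = 1e-8) {
  if (length(x) < 2)
    stop("maximum likelihood estimation needs at least 2 replicates",
         call. = FALSE)
  stopifnot(length(b) == length(x), length(sf) == length(x), all(sf > 0))
  xi <- as.integer(round(x / sf))
  bi <- as.integer(round(b / sf))
  if (is.null(init)) init <- estimate_params_np(x, b, sf)
  th0 <- log(pmax(c(init$alpha, init$beta, init$lambda), 1e-8))
  nll <- function(th) {
    p <- exp(pmin(th, 30))
    -delap_loglik(xi, bi, p[1], p[2], p[3])
  }
  ll0 <- -nll(th0)
  fit <- tryCatch(
    stats::optim(th0, nll, method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol)),
    error = function(e) NULL)
  if (is.null(fit) || -fit$value < ll0 - tol) {
    p <- exp(th0)
    return(list(alpha = p[1], beta = p[2], lambda = p[3], loglik = ll0,
                converged = FALSE))
  }
  p <- exp(pmin(fit$par, 30))
  list(alpha = p[1], beta = p[2], lambda = p[3], loglik = -fit$value,
       converged = fit$convergence == 0L)
}
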