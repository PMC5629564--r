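#' The Delaporte distribution
#'
#' Density, distribution function and random generation for the Delaporte
#' distribution: the law of \eqn{X = S + B} where \eqn{S} follows a negative
#' binomial distribution with gamma-mixing shape \eqn{\alpha} and scale
#' \eqn{\beta}, and \eqn{B} follows an independent Poisson distribution with
#' mean \eqn{\lambda}.  In the RNA-seq setting \eqn{S} is the latent true
#' expression signal of a gene and \eqn{B} is background noise from
#' sequencing error or misalignment.
#'
#' The density is the finite convolution
#' \deqn{P(X = x) = \sum_{k=0}^{x} \mathrm{NB}(k; r = \alpha, p = 1/(\beta+1))
#'   \cdot \mathrm{Pois}(x - k; \lambda),}
#' evaluated in log space with log-gamma terms so that counts far beyond the
#' factorial overflow point (x > 170) remain exact to double precision.  The
#' sum is truncated at \eqn{k = x} exactly; the support is finite so no
#' approximation is involved.
#'
#' With \eqn{\lambda = 0} the distribution collapses to the negative binomial
#' with size \eqn{\alpha} and success probability \eqn{1/(\beta+1)}; with
#' \eqn{\beta = 0} it collapses to Poisson(\eqn{\lambda}).  The mean is
#' \eqn{\alpha\beta + \lambda} and the variance \eqn{\alpha\beta(1+\beta) +
#' \lambda}.
#'
#' @param x,q vector of non-negative integer quantiles.
#' @param n number of draws.
#' @param alpha gamma shape of the signal component; must be positive.
#' @param beta gamma scale of the signal component; must be non-negative.
#' @param lambda Poisson mean of the background component; must be
#'   non-negative.
#' @param log logical; if `TRUE`, log densities are returned.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's random-number state is left untouched.
#'
#' @return `ddelap` and `pdelap` return numeric vectors of (log) probabilities;
#'   `rdelap` returns an integer vector of length `n`.
#'
#' @examples
#' ddelap(0:5, alpha = 2, beta = 1, lambda = 0.5)
#' pdelap(10, alpha = 2, beta = 1, lambda = 3)
#' mean(rdelap(1e4, alpha = 2, beta = 1, lambda = 3, seed = 1))  # ~ 2*1 + 3
#' @name delaporte
NULL

check_delap_params <- function(alpha, beta, lambda) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(beta)) || any(beta < 0))
    stop("'beta' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("'lambda' must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}

# log-sum-exp over a vector; -Inf-safe
lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' @rdname delaporte
#' @export
ddelap <- function(x, alpha, beta, lambda, log = FALSE) {
  check_delap_params(alpha, beta, lambda)
  n <- max(length(x), length(alpha), length(beta), length(lambda))
  x <- rep_len(x, n); alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n); lambda <- rep_len(lambda, n)
  out <- vapply(seq_len(n), function(i) {
    xi <- x[i]
    if (is.na(xi)) return(NA_real_)
    if (xi < 0 || xi != floor(xi)) return(-Inf)
    if (lambda[i] == 0)
      return(dnbinom(xi, size = alpha[i], prob = 1 / (1 + beta[i]), log = TRUE))
    if (beta[i] == 0)
      return(dpois(xi, lambda[i], log = TRUE))
    k <- 0:xi
    lse(dnbinom(k, size = alpha[i], prob = 1 / (1 + beta[i]), log = TRUE) +
          dpois(xi - k, lambda[i], log = TRUE))
  }, numeric(1))
  if (log) out else exp(out)
}

# Full pmf vector on 0:xmax for scalar parameters.  Direct convolution for
# short supports; FFT convolution (stats::convolve) beyond that, where the
# O(n^2) sum would dominate the differential-expression exact test.
delap_pmf_vec <- function(xmax, alpha, beta, lambda) {
  check_delap_params(alpha, beta, lambda)
  stopifnot(length(alpha) == 1L, xmax >= 0)
  nb <- dnbinom(0:xmax, size = alpha, prob = 1 / (1 + beta))
  if (lambda == 0) return(nb)
  if (beta == 0) return(dpois(0:xmax, lambda))
  po <- dpois(0:xmax, lambda)
  if (xmax <= 128) {
    out <- vapply(0:xmax, function(x)
      sum(nb[1:(x + 1)] * po[(x + 1):1]), numeric(1))
  } else {
    out <- stats::convolve(nb, rev(po), type = "open")[1:(xmax + 1)]
    out[out < 0] <- 0
  }
  pmin(out, 1)
}

#' @rdname delaporte
#' @export
pdelap <- function(q, alpha, beta, lambda) {
  check_delap_params(alpha, beta, lambda)
  stopifnot(length(alpha) == 1L, length(beta) == 1L, length(lambda) == 1L)
  if (any(q < 0)) stop("'q' must be non-negative", call. = FALSE)
  qmax <- max(q)
  cdf <- cumsum(delap_pmf_vec(qmax, alpha, beta, lambda))
  pmin(cdf[floor(q) + 1], 1)
}

#' @rdname delaporte
#' @export
rdelap <- function(n, alpha, beta, lambda, seed = NULL) {
  check_delap_params(alpha, beta, lambda)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  with_seed(seed, {
    s <- rnbinom(n, size = alpha, prob = 1 / (1 + beta))
    b <- rpois(n, lambda)
    s + b
  })
}

#' Negative binomial parameters of the signal component
#'
#' Converts the gamma parameterization of the Delaporte signal component to
#' the classical negative binomial one: size \eqn{r = \alpha} and success
#' probability \eqn{p = 1/(\beta + 1)}.
#'
#' @inheritParams delaporte
#' @return a list with components `size` and `prob`.
#' @examples
#' delap_to_nb(alpha = 2, beta = 1)  # size 2, prob 0.5
#' @export
delap_to_nb <- function(alpha, beta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(beta)) || any(beta < 0))
    stop("'beta' must be finite and >= 0", call. = FALSE)
  list(size = alpha, prob = 1 / (beta + 1))
}
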