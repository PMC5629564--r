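#' Simulation scenario configuration
#'
#' Bundles the parameters of one synthetic two-group RNA-seq experiment:
#' `n_genes` genes of which a fraction `prop_de` are differentially
#' expressed at `fold_change` (half up, half down), `n_per_group` replicates
#' per condition, and a background-noise regime in which every gene receives
#' baseline Poisson noise while `M` randomly chosen genes receive inflated
#' noise whose Poisson mean is raised by the noise factor `NF` and whose
#' draw passes through a normal stage with standard deviation `sigma` (see
#' [simulate_background()]).  `NF` of 0, 7 and 20 represent low,
#' intermediate and high background noise.
#'
#' @param n_genes number of genes.
#' @param prop_de fraction of genes differentially expressed, in (0, 1).
#' @param fold_change fold change applied to DE genes (> 1).
#' @param n_per_group replicates per condition.
#' @param M number of genes receiving inflated background noise.
#' @param sigma standard deviation of the normal stage of the inflated
#'   noise draw.
#' @param NF noise factor added to the Poisson mean of inflated genes.
#' @param n_reps number of replicate simulations for benchmarking.
#' @param seed master integer seed; all randomness derives from it.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000, prop_de = 0.1, fold_change = 1.5,
                       n_per_group = 3, M = 100, sigma = 3, NF = 0,
                       n_reps = 100, seed = 1) {
  stopifnot(n_genes >= 1, prop_de > 0, prop_de < 1, fold_change >= 1,
            n_per_group >= 1, M >= 0, M <= n_genes, sigma >= 0, NF >= 0,
            n_reps >= 1)
  structure(list(n_genes = n_genes, prop_de = prop_de,
                 fold_change = fold_change, n_per_group = n_per_group,
                 M = M, sigma = sigma, NF = NF, n_reps = n_reps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  for (f in names(x)) cat(sprintf("  %-12s %g\n", f, x[[f]]))
  invisible(x)
}

#' Synthetic per-gene parameter pool
#'
#' Generates a pool of per-gene (mean, dispersion, lambda) triples emulating
#' parameter estimates from a typical bulk RNA-seq dataset: gene means are
#' log-normal (log10 mean 2.0, log10 sd 0.8) truncated to \[10, 1e5\];
#' negative binomial dispersions follow the decreasing mean-dispersion trend
#' `0.1 + 4/mean` with multiplicative log-normal jitter (sd 0.3 on the log
#' scale); and the Poisson background mean `lambda` is drawn as 1-5% of the
#' gene's signal mean.  Mirroring the usual pre-filtering of estimated
#' pools, genes in the top 10% of dispersion (and any with mean below 10)
#' are discarded and re-drawn, so the returned pool has exactly `n` rows
#' none of which fall in the discarded strata.
#'
#' @param n pool size.
#' @param seed integer seed.
#' @param log10_mean,log10_sd location and scale of the log10 gene-mean
#'   distribution.
#' @param mean_range truncation bounds for gene means.
#' @param disp_jitter_sd log-scale jitter of the dispersion trend.
#' @param bg_frac range of background-to-signal mean ratios.
#' @return data frame with columns `mean`, `dispersion`, `lambda` and an
#'   attribute `prefilter_disp_q90` (the 90% dispersion quantile of the
#'   unfiltered draw).
#' @export
make_parameter_pool <- function(n, seed = 1, log10_mean = 2, log10_sd = 0.8,
                                mean_range = c(10, 1e5),
                                disp_jitter_sd = 0.3,
                                bg_frac = c(0.01, 0.05)) {
  stopifnot(n >= 1)
  with_seed(seed, {
    draw <- function(k) {
      mu <- 10^rnorm(k, log10_mean, log10_sd)
      # redraw outside the truncation bounds
      bad <- mu < mean_range[1] | mu > mean_range[2]
      while (any(bad)) {
        mu[bad] <- 10^rnorm(sum(bad), log10_mean, log10_sd)
        bad <- mu < mean_range[1] | mu > mean_range[2]
      }
      disp <- (0.1 + 4 / mu) * exp(rnorm(k, 0, disp_jitter_sd))
      data.frame(mean = mu, dispersion = disp)
    }
    first <- draw(max(n * 2L, 50L))
    q90 <- quantile(first$dispersion, 0.9)
    pool <- first[first$dispersion < q90 & first$mean >= 10, ]
    while (nrow(pool) < n) {
      extra <- draw(n)
      keep <- extra[extra$dispersion < q90 & extra$mean >= 10, ]
      pool <- rbind(pool, keep)
    }
    pool <- pool[seq_len(n), ]
    pool$lambda <- pool$mean * runif(n, bg_frac[1], bg_frac[2])
    rownames(pool) <- NULL
    attr(pool, "prefilter_disp_q90") <- unname(q90)
    pool
  })
}

#' Simulate the true expression signal
#'
#' Samples `n_genes` parameter triples with replacement from the pool,
#' flags `round(n_genes * prop_de)` random genes as differentially
#' expressed (half with the second condition's mean multiplied by the fold
#' change, half divided), and draws the signal matrix from negative
#' binomial distributions (size `1/dispersion`, the chosen means).
#'
#' @param pool parameter pool from [make_parameter_pool()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a list with `S` (gene-by-sample integer matrix), `de` (logical),
#'   `direction` (+1/-1/0), `mu1`, `mu2` (per-gene condition means),
#'   `dispersion`, `lambda`, `groups` (factor), `pool_idx`.
#' @export
simulate_signal <- function(pool, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    ng <- config$n_genes
    idx <- sample.int(nrow(pool), ng, replace = TRUE)
    mu1 <- pool$mean[idx]
    disp <- pool$dispersion[idx]
    lam <- pool$lambda[idx]
    n_de <- round(ng * config$prop_de)
    de_idx <- sample.int(ng, n_de)
    direction <- integer(ng)
    n_up <- ceiling(n_de / 2)
    direction[de_idx[seq_len(n_up)]] <- 1L
    if (n_de > n_up) direction[de_idx[(n_up + 1):n_de]] <- -1L
    mu2 <- mu1 * config$fold_change^direction
    npg <- config$n_per_group
    size <- 1 / disp
    S <- cbind(
      matrix(rnbinom(ng * npg, size = size, mu = mu1), ng, npg),
      matrix(rnbinom(ng * npg, size = size, mu = mu2), ng, npg))
    storage.mode(S) <- "integer"
    groups <- factor(rep(c("cond1", "cond2"), each = npg))
    dimnames(S) <- list(paste0("gene", seq_len(ng)),
                        paste0(groups, "_", rep(seq_len(npg), 2)))
    list(S = S, de = direction != 0L, direction = direction,
         mu1 = mu1, mu2 = mu2, dispersion = disp, lambda = lam,
         groups = groups, pool_idx = idx)
  })
}

#' Simulate background noise
#'
#' Every gene receives baseline Poisson noise with its own mean `lambda`.
#' In addition, `M` randomly chosen genes receive inflated noise drawn
#' through a hybrid hierarchy: per sample, a mean is drawn as
#' `mu ~ Poisson(lambda + NF)` and the noise is `round(Normal(mu, sigma))`
#' clipped at zero.  A second, independent draw from the same per-gene law
#' gives the observed background measurement `B_obs` (the separately
#' measured non-exonic counts), while `B_true` is the noise actually added
#' to the signal.
#'
#' @param config a [sim_config()].
#' @param lambda per-gene baseline Poisson means.
#' @param n_samples number of samples (default `2 * n_per_group`).
#' @param seed integer seed.
#' @return list with integer matrices `B_true`, `B_obs` and logical
#'   `inflated` flagging the `M` noise-inflated genes.
#' @export
simulate_background <- function(config, lambda,
                                n_samples = 2 * config$n_per_group,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            length(lambda) >= 1, all(lambda >= 0))
  ng <- length(lambda)
  stopifnot(config$M <= ng)
  with_seed(seed, {
    inflated <- rep(FALSE, ng)
    inflated[sample.int(ng, config$M)] <- TRUE
    draw <- function() {
      b <- matrix(rpois(ng * n_samples, lambda), ng, n_samples)
      ni <- sum(inflated)
      if (ni > 0) {
        mu <- matrix(rpois(ni * n_samples, lambda[inflated] + config$NF),
                     ni, n_samples)
        b[inflated, ] <- pmax(round(matrix(
          rnorm(ni * n_samples, mean = mu, sd = config$sigma),
          ni, n_samples)), 0)
      }
      storage.mode(b) <- "integer"
      b
    }
    list(B_true = draw(), B_obs = draw(), inflated = inflated)
  })
}

#' Simulate a complete two-group experiment
#'
#' Composes [make_parameter_pool()], [simulate_signal()] and
#' [simulate_background()] into one dataset: the observed exonic count
#' matrix is `X = S + B_true`, and `B` is the independently measured
#' background matrix.  Fully deterministic given `config$seed` and `rep`;
#' the replicate index perturbs the derived seeds reproducibly.
#'
#' @param config a [sim_config()].
#' @param rep replicate index (>= 1).
#' @param pool optional pre-built parameter pool; generated from the config
#'   seed when omitted.
#' @return a list of class `"sim_truth"` with elements `X`, `B`, `S`,
#'   `B_true`, `de`, `direction`, `mu1`, `mu2`, `true_mean` (the average of
#'   the two condition means), `dispersion`, `lambda`, `inflated`, `groups`,
#'   `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, seed = 3))
#' stopifnot(identical(sim$X, sim$S + sim$B_true))
#' @export
simulate_experiment <- function(config, rep = 1, pool = NULL) {
  stopifnot(inherits(config, "sim_config"), rep >= 1)
  base <- derive_seed(config$seed, rep)
  if (is.null(pool))
    pool <- make_parameter_pool(config$n_genes,
                                seed = derive_seed(base, 1))
  sig <- simulate_signal(pool, config, seed = derive_seed(base, 2))
  bg <- simulate_background(config, sig$lambda,
                            seed = derive_seed(base, 3))
  X <- sig$S + bg$B_true
  dimnames(X) <- dimnames(bg$B_obs) <- dimnames(bg$B_true) <- dimnames(sig$S)
  structure(list(X = X, B = bg$B_obs, S = sig$S, B_true = bg$B_true,
                 de = sig$de, direction = sig$direction,
                 mu1 = sig$mu1, mu2 = sig$mu2,
                 true_mean = (sig$mu1 + sig$mu2) / 2,
                 dispersion = sig$dispersion, lambda = sig$lambda,
                 inflated = bg$inflated, groups = sig$groups,
                 config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d genes x %d samples, %d DE, NF = %g, %d noise-inflated genes\n",
              nrow(x$X), ncol(x$X), sum(x$de), x$config$NF,
              sum(x$inflated)))
  invisible(x)
}
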