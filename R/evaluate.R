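#' Rank-based ROC AUC
#'
#' Area under the ROC curve for discriminating truly differentially
#' expressed genes from the rest, scoring genes by `-p` (smaller p ranks
#' higher).  Computed by the Mann-Whitney identity with midrank tie
#' handling, so it is invariant under any strictly monotone transform of
#' the score.
#'
#' @param pvals per-gene p-values.
#' @param labels logical (or 0/1) vector; `TRUE` marks truly DE genes.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pvals, labels) {
  labels <- as.logical(labels)
  stopifnot(length(pvals) == length(labels), !any(is.na(pvals)))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(-pvals)                       # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' False-discovery curve
#'
#' `FD(k)`: the number of truly non-DE genes among the `k` smallest
#' p-values, for `k = 1..k_max`.  Ties in p are broken by the stable
#' original gene order, so the curve is reproducible.
#'
#' @inheritParams roc_auc
#' @param k_max curve length.
#' @return integer vector of length `k_max`, non-decreasing, `FD(k) <= k`.
#' @export
fd_curve <- function(pvals, labels, k_max = 500) {
  labels <- as.logical(labels)
  stopifnot(length(pvals) == length(labels))
  if (k_max > length(pvals))
    stop("'k_max' exceeds the number of genes", call. = FALSE)
  ord <- order(pvals)                     # stable for ties
  cumsum(!labels[ord])[seq_len(k_max)]
}

#' Statistical power at a p-value cutoff
#'
#' Fraction of truly DE genes detected at raw `p < alpha`.
#'
#' @inheritParams roc_auc
#' @param alpha p-value cutoff.
#' @return proportion in \[0, 1\].
#' @export
power_at <- function(pvals, labels, alpha = 0.05) {
  labels <- as.logical(labels)
  stopifnot(length(pvals) == length(labels))
  if (!any(labels)) stop("no truly DE genes", call. = FALSE)
  mean(pvals[labels] < alpha)
}

#' Expression strata
#'
#' Splits genes into a low-expression set (true signal mean strictly below
#' the `q_low` empirical quantile) and a high-expression set (strictly above
#' the `q_high` quantile).  Strata are defined on true simulated signal
#' means so they are identical for every method evaluated.
#'
#' @param mean_expr per-gene true signal means.
#' @param q_low,q_high quantile cutoffs.
#' @return list with integer index vectors `low` and `high`.
#' @export
stratify_expression <- function(mean_expr, q_low = 0.25, q_high = 0.75) {
  stopifnot(length(mean_expr) >= 4)
  ql <- quantile(mean_expr, q_low)
  qh <- quantile(mean_expr, q_high)
  list(low = which(mean_expr < ql), high = which(mean_expr > qh))
}

# p-values of one method on one simulated dataset
benchmark_pvals <- function(sim, method, big_count = 900) {
  switch(method,
         "delap" = de_results(dexbg(sim$X, sim$B, sim$groups,
                                    big_count = big_count))$pval,
         "delap-beta" = de_results(dexbg(sim$X, sim$B, sim$groups,
                                         big_count = 0))$pval,
         "naive-nb" = de_results(dexbg(sim$X, 0L * sim$B, sim$groups,
                                       big_count = big_count))$pval,
         stop("unknown method '", method, "'", call. = FALSE))
}

#' Benchmark differential expression methods on simulated data
#'
#' Runs `n_reps` replicate simulations of a scenario, applies each method,
#' and averages ROC AUC, the number of false discoveries among the
#' top-ranked genes, and statistical power at `alpha`, overall and within
#' the low/high expression strata.  The top-ranked list length for the
#' false-discovery count equals the number of truly DE genes in the
#' evaluated set (500 overall at the default design), so a perfect method
#' scores 0.
#'
#' Available methods: `"delap"` (the background-aware pipeline with default
#' exact/beta routing), `"delap-beta"` (beta approximation for every gene),
#' and `"naive-nb"` (the identical pipeline with the background matrix
#' zeroed, quantifying the value of background correction).
#'
#' @param config a [sim_config()].
#' @param methods character vector of method names.
#' @param n_reps replicates to average over (default from `config`).
#' @param big_count routing threshold passed to [dexbg()].
#' @param alpha power cutoff.
#' @return data frame with columns `method`, `stratum` (`all`, `high`,
#'   `low`), `nf`, `auc`, `power`, `fd`, `n_reps`.
#' @export
run_benchmark <- function(config, methods = c("delap", "naive-nb"),
                          n_reps = config$n_reps, big_count = 900,
                          alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  acc <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_experiment(config, rep = r)
    strata <- stratify_expression(sim$true_mean)
    sets <- list(all = seq_along(sim$de), high = strata$high,
                 low = strata$low)
    for (m in methods) {
      p <- benchmark_pvals(sim, m, big_count = big_count)
      for (sname in names(sets)) {
        idx <- sets[[sname]]
        lab <- sim$de[idx]
        if (!any(lab) || all(lab)) next
        k <- sum(lab)
        acc[[length(acc) + 1L]] <- data.frame(
          method = m, stratum = sname, rep = r,
          auc = roc_auc(p[idx], lab),
          power = power_at(p[idx], lab, alpha),
          fd = fd_curve(p[idx], lab, k_max = k)[k])
      }
    }
  }
  acc <- do.call(rbind, acc)
  agg <- aggregate(cbind(auc, power, fd) ~ method + stratum, acc, mean)
  agg$nf <- config$NF
  agg$n_reps <- n_reps
  agg[order(agg$method, agg$stratum),
      c("method", "stratum", "nf", "auc", "power", "fd", "n_reps")]
}
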