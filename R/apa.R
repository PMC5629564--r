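#' Length-normalized short/long isoform expression ratio (m/M)
#'
#' For a gene with two 3'UTR isoforms, the PRE region is covered by both the
#' short and the long isoform while the POST region (the long isoform's
#' extension) is covered only by the long one.  The m/M ratio compares their
#' length-normalized read densities:
#' \deqn{m/M = \frac{l_{post} \, r_{pre}}{l_{pre} \, r_{post}} - 1,}
#' where `l_pre` is the length of the shorter isoform's region, `l_post` the
#' extra length of the longer isoform, and `r_pre`, `r_post` the reads
#' assigned to each region.  Larger values indicate relatively heavier use of
#' the short isoform (3'UTR shortening).
#'
#' @param l_pre,l_post region lengths in bases; both must be positive.
#' @param r_pre,r_post read counts in the PRE region and in the POST-only
#'   region.
#' @return the m/M ratio, or `NA` when `r_post` is 0 (the ratio is undefined
#'   and the gene is flagged untestable rather than erroring).  Vectorized.
#' @examples
#' mM_ratio(l_pre = 100, l_post = 100, r_pre = 30, r_post = 10)  # 2
#' @export
mM_ratio <- function(l_pre, l_post, r_pre, r_post) {
  if (any(l_pre <= 0) || any(l_post <= 0))
    stop("region lengths must be positive", call. = FALSE)
  if (any(r_pre < 0) || any(r_post < 0))
    stop("read counts must be non-negative", call. = FALSE)
  out <- (l_post * r_pre) / (l_pre * r_post) - 1
  out[r_post == 0] <- NA_real_
  out
}

#' Ratio of m/M ratios between conditions
#'
#' The APA effect size: the treatment group's m/M ratio divided by the
#' control group's.  Values far from 1 in either direction indicate a shift
#' in relative isoform usage.
#'
#' @param mM_treatment,mM_control group-level m/M ratios.
#' @return the ratio, or `NA` when the control ratio is 0 or either input is
#'   undefined.  Vectorized.
#' @export
roar_ratio <- function(mM_treatment, mM_control) {
  out <- mM_treatment / mM_control
  out[!is.na(mM_control) & mM_control == 0] <- NA_real_
  out[is.na(mM_treatment) | is.na(mM_control)] <- NA_real_
  out
}

#' Fisher's exact test on a PRE/POST 2x2 table
#'
#' Two-sided Fisher's exact test (minimum-likelihood rule) on the table
#' `rbind(c(r_pre1, r_post1), c(r_pre2, r_post2))` contrasting PRE/POST read
#' allocation between two samples.
#'
#' @param c1,c2 length-2 numeric vectors `(r_pre, r_post)` for the two
#'   samples.
#' @return two-sided p-value; an all-zero table returns 1 by convention.
#' @export
apa_fisher <- function(c1, c2) {
  stopifnot(length(c1) == 2L, length(c2) == 2L,
            all(c1 >= 0), all(c2 >= 0))
  tab <- matrix(as.integer(round(c(c1, c2))), nrow = 2, byrow = TRUE)
  if (sum(tab) == 0) return(1)
  fisher.test(tab)$p.value
}

#' Combine p-values by Fisher's method
#'
#' Combines k independent p-values through \eqn{X^2 = -2 \sum \log p_i},
#' referred to a chi-square distribution with 2k degrees of freedom.
#' Zero p-values are clamped to the smallest positive normalized double
#' before taking logs.
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @return the combined upper-tail p-value.
#' @examples
#' fisher_combine(0.05)          # identity at k = 1
#' fisher_combine(c(0.5, 0.5))   # ~ 0.5966
#' @export
fisher_combine <- function(pvals) {
  if (!length(pvals) || any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pvals <- pmax(pvals, .Machine$double.xmin)
  stat <- -2 * sum(log(pvals))
  pchisq(stat, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Differential alternative-polyadenylation usage test
#'
#' Tests each gene for a shift in relative short/long 3'UTR isoform usage
#' between two groups.  Per gene: the m/M ratio ([mM_ratio()]) is computed
#' per sample and, from group-pooled counts, per group (pooling before the
#' ratio is stable at low counts); the effect size is the ratio of group
#' ratios ([roar_ratio()], treatment = second group level over control =
#' first level); every cross-group sample pair is contrasted with a 2x2
#' Fisher exact test on (r_pre, r_post), and the n1 x n2 pairwise p-values
#' are combined with Fisher's method.  Combined p-values are BH-adjusted
#' across testable genes.
#'
#' Genes whose pooled POST count is zero in either group have an undefined
#' m/M ratio; they are reported with `NA` effect sizes and excluded from the
#' adjustment.
#'
#' @param pre,post gene-by-sample count matrices for the PRE region and the
#'   POST-only region (same genes and samples).
#' @param geometry data frame with columns `gene_id`, `l_pre`, `l_post`
#'   (lengths in bases) covering the genes of `pre`.
#' @param groups two-level factor over the samples; first level = control.
#' @return an object of class `"dexbg_apa"`: a data frame with columns
#'   `gene_id`, `mM_control`, `mM_treatment`, `roar`, `mean_expr`, `pval`,
#'   `padj`.
#' @examples
#' pre <- rbind(gA = c(30, 28, 10, 9), gB = c(20, 22, 21, 19))
#' post <- rbind(gA = c(10, 11, 30, 31), gB = c(20, 18, 19, 21))
#' geom <- data.frame(gene_id = c("gA", "gB"), l_pre = 100, l_post = 100)
#' apa_test(pre, post, geom, groups = c("ctl", "ctl", "trt", "trt"))
#' @export
apa_test <- function(pre, post, geometry, groups) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post)))
    stop("'pre' and 'post' must have identical dimensions", call. = FALSE)
  if (is.null(rownames(pre)))
    stop("'pre' must carry gene identifiers as row names", call. = FALSE)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two group levels are required", call. = FALSE)
  if (length(groups) != ncol(pre))
    stop("'groups' must have one label per sample", call. = FALSE)
  gi <- match(rownames(pre), geometry$gene_id)
  if (any(is.na(gi)))
    stop("geometry missing for: ",
         paste(utils::head(rownames(pre)[is.na(gi)]), collapse = ", "),
         call. = FALSE)
  geom <- geometry[gi, ]
  lvl <- levels(groups)
  ic <- which(groups == lvl[1]); it <- which(groups == lvl[2])

  pool <- function(m, idx) rowSums(m[, idx, drop = FALSE])
  mM_c <- mM_ratio(geom$l_pre, geom$l_post, pool(pre, ic), pool(post, ic))
  mM_t <- mM_ratio(geom$l_pre, geom$l_post, pool(pre, it), pool(post, it))
  roar <- roar_ratio(mM_t, mM_c)

  ng <- nrow(pre)
  pval <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    pp <- vapply(ic, function(j1) vapply(it, function(j2)
      apa_fisher(c(pre[g, j1], post[g, j1]), c(pre[g, j2], post[g, j2])),
      numeric(1)), numeric(length(it)))
    pval[g] <- fisher_combine(as.numeric(pp))
  }
  testable <- !is.na(mM_c) & !is.na(mM_t)
  padj <- rep(NA_real_, ng)
  padj[testable] <- bh_adjust(pval[testable])

  out <- data.frame(gene_id = rownames(pre),
                    mM_control = mM_c,
                    mM_treatment = mM_t,
                    roar = roar,
                    mean_expr = rowMeans(pre + post),
                    pval = pval,
                    padj = padj,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("dexbg_apa", "data.frame")
  out
}

#' @export
print.dexbg_apa <- function(x, ...) {
  cat(sprintf("Differential APA usage: %d genes (%d testable), %d with padj < 0.1\n",
              nrow(x), sum(!is.na(x$padj)), sum(x$padj < 0.1, na.rm = TRUE)))
  NextMethod()
}

#' Filter differential APA results
#'
#' Keeps genes with a two-sided ratio-of-ratios effect at least `roar_min`
#' (i.e. roar >= `roar_min` or <= 1/`roar_min`), mean PRE+POST expression
#' above the `expr_quantile` quantile, and adjusted combined p below
#' `padj_max`.  Untestable genes (`NA` roar or padj) are dropped.
#'
#' @param results a `"dexbg_apa"` result table.
#' @param roar_min minimum two-sided ratio-of-ratios.
#' @param expr_quantile expression-quantile cutoff.
#' @param padj_max adjusted-p cutoff (exclusive).
#' @return the filtered data frame.
#' @export
filter_apa <- function(results, roar_min = 1.5, expr_quantile = 0.5,
                       padj_max = 0.1) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  roar_ok <- !is.na(results$roar) &
    (results$roar >= roar_min | results$roar <= 1 / roar_min)
  expr_thr <- if (expr_quantile <= 0) -Inf else
    quantile(results$mean_expr, expr_quantile)
  keep <- roar_ok & results$mean_expr > expr_thr &
    !is.na(results$padj) & results$padj < padj_max
  results[keep, , drop = FALSE]
}
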