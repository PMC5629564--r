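test_that("m/M ratio implements the length-normalized isoform contrast", {
  expect_equal(mM_ratio(100, 100, 30, 10), 2)
  expect_equal(mM_ratio(200, 50, 40, 5), 1)
  expect_equal(mM_ratio(120, 60, 10, 5), 0)  # equal length-normalized coverage
  expect_true(is.na(mM_ratio(100, 100, 5, 0)))
  expect_error(mM_ratio(0, 100, 1, 1), "positive")
  # invariance under joint count scaling
  for (c in c(2, 10, 0.5))
    expect_equal(mM_ratio(100, 80, 30 * c, 12 * c), mM_ratio(100, 80, 30, 12))
})

test_that("ratio-of-ratios effect size and its sentinels", {
  expect_equal(roar_ratio(2, 1), 2)
  expect_equal(roar_ratio(1.5, 1.5), 1)
  expect_equal(roar_ratio(3, 1.5), 2)
  expect_true(is.na(roar_ratio(2, 0)))
  expect_true(is.na(roar_ratio(NA, 1)))
})

test_that("2x2 Fisher test equals hypergeometric enumeration", {
  tabs <- list(rbind(c(30, 10), c(10, 30)),
               rbind(c(20, 5), c(20, 5)),
               rbind(c(0, 0), c(0, 0)),
               rbind(c(7, 0), c(2, 9)),
               rbind(c(1, 40), c(12, 13)))
  for (tab in tabs)
    expect_equal(apa_fisher(tab[1, ], tab[2, ]), oracle_fisher_p(tab),
                 tolerance = 1e-12)
  # exhaustive small-table sweep
  for (a in 0:6) for (b in 0:6) for (c in 0:6) {
    tab <- rbind(c(a, b), c(c, 5))
    expect_equal(apa_fisher(tab[1, ], tab[2, ]), oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("Fisher's method combines p-values through the chi-square tail", {
  expect_equal(fisher_combine(0.05), 0.05)       # k = 1 identity
  expect_equal(fisher_combine(c(0.5, 0.5)),
               pchisq(-2 * log(0.25), df = 4, lower.tail = FALSE))
  expect_equal(round(fisher_combine(c(0.5, 0.5)), 4), 0.5966)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_gt(fisher_combine(c(0, 0.5)), 0)        # zero is clamped, not -Inf
  # monotone: decreasing any input cannot increase the combination
  p0 <- c(0.3, 0.6, 0.9)
  for (i in 1:3) {
    p1 <- p0; p1[i] <- p1[i] / 2
    expect_lte(fisher_combine(p1), fisher_combine(p0))
  }
})

test_that("the APA pipeline flags a 3'UTR-shortened gene and honors conventions", {
  # gene gA: treatment strongly PRE-enriched (shortened); gB, gC stable
  pre <- rbind(gA = c(30, 28, 80, 85), gB = c(20, 22, 21, 19),
               gC = c(50, 48, 52, 49))
  post <- rbind(gA = c(30, 31, 8, 7), gB = c(20, 18, 19, 21),
                gC = c(25, 26, 24, 25))
  geom <- data.frame(gene_id = c("gA", "gB", "gC"),
                     l_pre = c(100, 100, 200), l_post = c(100, 100, 100))
  groups <- c("ctl", "ctl", "trt", "trt")
  res <- apa_test(pre, post, geom, groups)
  expect_s3_class(res, "dexbg_apa")
  expect_equal(res$gene_id[which.min(res$pval)], "gA")
  # group-level ratios come from pooled counts
  expect_equal(res$mM_control[1], mM_ratio(100, 100, 30 + 28, 30 + 31))
  expect_equal(res$mM_treatment[1], mM_ratio(100, 100, 80 + 85, 8 + 7))
  expect_equal(res$roar[1], res$mM_treatment[1] / res$mM_control[1])

  # identical samples: every cross-group 2x2 is degenerate, combined p = 1
  pre2 <- rbind(gX = rep(10, 4)); post2 <- rbind(gX = rep(5, 4))
  res2 <- apa_test(pre2, post2,
                   data.frame(gene_id = "gX", l_pre = 50, l_post = 50),
                   groups)
  expect_equal(res2$pval, 1)

  # a 2v2 design feeds exactly 4 pairwise tests into the combination:
  # with all pairwise tables identical, the combination equals the
  # 4-fold Fisher combination of that single p-value
  pre3 <- rbind(gY = c(12, 12, 30, 30)); post3 <- rbind(gY = c(30, 30, 12, 12))
  res3 <- apa_test(pre3, post3,
                   data.frame(gene_id = "gY", l_pre = 50, l_post = 50),
                   groups)
  p1 <- apa_fisher(c(12, 30), c(30, 12))
  expect_equal(res3$pval, fisher_combine(rep(p1, 4)))
})

test_that("under a null APA model few genes reach nominal significance", {
  # identical PRE/POST multinomial in both groups; Fisher's method on
  # dependent pairs is anti-conservative, so we only bound the rate
  ng <- 150
  sim <- with_seed(29, {
    pre <- matrix(rpois(ng * 6, 40), ng)
    post <- matrix(rpois(ng * 6, 20), ng)
    rownames(pre) <- rownames(post) <- paste0("g", 1:ng)
    list(pre = pre, post = post)
  })
  geom <- data.frame(gene_id = paste0("g", 1:ng), l_pre = 100, l_post = 50)
  res <- apa_test(sim$pre, sim$post, geom, rep(c("a", "b"), each = 3))
  expect_lte(mean(res$pval < 0.05, na.rm = TRUE), 0.10)
})

test_that("APA filtering thresholds the ratio-of-ratios two-sidedly", {
  res <- data.frame(
    gene_id = paste0("g", 1:5),
    mM_control = c(1, 1, 1, 1, 1),
    mM_treatment = c(2, 0.5, 1.1, 2.5, 2.2),
    roar = c(2, 0.5, 1.1, 2.5, 2.2),
    mean_expr = c(100, 98, 80, 3, 95),
    pval = c(0.001, 0.002, 0.003, 0.001, 0.2),
    padj = c(0.01, 0.01, 0.01, 0.01, 0.4),
    stringsAsFactors = FALSE)
  class(res) <- c("dexbg_apa", "data.frame")
  # g1 (roar 2) and g2 (roar 0.5 <= 1/1.5) pass; g3 fails effect size;
  # g4 fails expression; g5 fails padj
  kept <- filter_apa(res, roar_min = 1.5, expr_quantile = 0.5, padj_max = 0.1)
  expect_setequal(kept$gene_id, c("g1", "g2"))
  expect_equal(nrow(filter_apa(res, 0, 0, 1.01)), 5)
  expect_equal(nrow(filter_apa(res, 0, 0, 0)), 0)
})
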