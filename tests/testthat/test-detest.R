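test_that("moderated exact test equals brute-force enumeration over the conditional support", {
  pp <- list(alpha = 2, beta = 2, lambda = 1)
  # identical symmetric null, balanced counts: every term is included
  expect_equal(delap_exact_test(10, 10, pp, pp), 1)
  expect_equal(delap_exact_test(0, 0, pp, pp), 1)
  expect_equal(delap_exact_test(15, 5, pp, pp),
               oracle_exact_p(15, 5, pp, pp), tolerance = 1e-12)

  # grid of asymmetric parameter pairs and sample sizes, all x + y <= 60
  grid <- expand.grid(aa = c(1, 3), ba = c(0.5, 2), la = c(0.5, 2),
                      ab = c(2), bb = c(1), lb = c(1),
                      n1 = c(1, 3), n2 = c(1, 2))
  set.seed(13)
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    pa <- list(alpha = g$aa, beta = g$ba, lambda = g$la)
    pb <- list(alpha = g$ab, beta = g$bb, lambda = g$lb)
    z <- sample(0:60, 1)
    x <- sample(0:z, 1); y <- z - x
    expect_equal(delap_exact_test(x, y, pa, pb, g$n1, g$n2),
                 oracle_exact_p(x, y, pa, pb, g$n1, g$n2),
                 tolerance = 1e-12)
  }
})

test_that("exact test is symmetric in the two groups", {
  pa <- list(alpha = 3, beta = 0.8, lambda = 2)
  pb <- list(alpha = 1.5, beta = 2.5, lambda = 0.5)
  for (xy in list(c(12, 30), c(0, 17), c(25, 25))) {
    expect_equal(delap_exact_test(xy[1], xy[2], pa, pb, 3, 2),
                 delap_exact_test(xy[2], xy[1], pb, pa, 2, 3),
                 tolerance = 1e-12)
  }
})

test_that("beta approximation reproduces the printed formulas with clamp and straddle rules", {
  # re-evaluation oracle over a grid
  for (case in list(c(60, 40, 3, 3), c(600, 400, 3, 3), c(35, 80, 2, 4),
                    c(1500, 900, 5, 5), c(3, 1, 1, 1))) {
    expect_equal(beta_approx_test(case[1], case[2], case[3], case[4]),
                 oracle_beta_p(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-10)
  }
  # symmetry forces the straddle branch: both corrected points bracket med
  expect_equal(beta_approx_test(50, 50, 3, 3), 1)
  expect_equal(beta_approx_test(0, 0, 3, 3), 1)
  # the printed statistic is a doubled density; when it exceeds 1 the
  # returned p is clamped at 1
  z <- 4; mu <- z / 2; a <- mu / (1 + 1 / mu)
  expect_gt(2 * dbeta(2.5 / 4, a, a), 1)
  expect_equal(beta_approx_test(3, 1, 1, 1), 1)
})

test_that("beta p-value decreases as imbalance grows at fixed totals", {
  for (z in c(50, 100, 500)) {
    xs <- seq(ceiling(z / 2), z)
    p <- beta_approx_test(xs, z - xs, 3, 3)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(p), oracle_bh(p))
  set.seed(2)
  q <- runif(50)
  expect_equal(bh_adjust(q), oracle_bh(q))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the pipeline ranks a strongly changed gene first on either routing", {
  toy <- toy_de_data()
  fit_exact <- dexbg(toy$X, toy$B, toy$groups, big_count = 1e9)
  res_e <- de_results(fit_exact)
  expect_equal(which.min(res_e$pval), 1L)
  expect_true(all(res_e$test[res_e$pval < 1] == "exact"))

  fit_beta <- dexbg(toy$X, toy$B, toy$groups, big_count = 0)
  res_b <- de_results(fit_beta)
  expect_equal(which.min(res_b$pval), 1L)
  expect_true(all(res_b$test == "beta"))
})

test_that("zero-signal data yield no discoveries across seeded runs", {
  hits <- vapply(1:20, function(s) {
    B <- with_seed(s, matrix(rpois(150 * 6, 25), 150))
    fit <- dexbg(B, B, rep(c("a", "b"), each = 3))
    any(de_results(fit)$padj < 0.1)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("near-Poisson null p-values are approximately calibrated on the exact path", {
  ng <- 400
  sim <- with_seed(31, {
    mu <- 60; disp <- 0.01; lam <- 3
    X <- matrix(rnbinom(ng * 6, size = 1 / disp, mu = mu), ng) +
      matrix(rpois(ng * 6, lam), ng)
    B <- matrix(rpois(ng * 6, lam), ng)
    list(X = X, B = B)
  })
  fit <- dexbg(sim$X, sim$B, rep(c("a", "b"), each = 3), big_count = 1e9)
  frac <- mean(de_results(fit)$pval < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})

test_that("untestable and malformed inputs are handled explicitly", {
  X <- rbind(g1 = c(5L, 6L, 4L, 9L), g2 = c(0L, 0L, 0L, 0L),
             g3 = c(7L, 8L, 9L, 10L))
  B <- matrix(1L, 3, 4, dimnames = list(rownames(X), NULL))
  fit <- dexbg(X, B, c("a", "a", "b", "b"))
  r <- de_results(fit)
  expect_equal(r$pval[2], 1)
  expect_equal(r$padj[2], 1)
  expect_equal(r$test[2], "none")
  # zero-count genes do not enter the BH denominator
  expect_equal(r$padj[c(1, 3)], bh_adjust(r$pval[c(1, 3)]))

  expect_error(dexbg(X, B[, 1:3], c("a", "a", "b")), "dimensions")
  expect_error(dexbg(X, B, c("a", "a", "a", "a")), "two group")
  expect_error(dexbg(X, B, c("a", "a", "a", "b")), "at least 2")
})

test_that("both routings agree on which genes are strongly separated", {
  sim <- simulate_experiment(sim_config(n_genes = 400, seed = 17))
  pe <- de_results(dexbg(sim$X, sim$B, sim$groups, big_count = 1e9))$pval
  pb <- de_results(dexbg(sim$X, sim$B, sim$groups, big_count = 0))$pval
  # genes the beta approximation calls strong are also small under the
  # exact enumeration, and clearly smaller than beta's null calls
  strong <- pb < 0.01
  expect_gt(sum(strong), 5)
  expect_lt(median(pe[strong]), 0.1)
  expect_lt(median(pe[strong]), median(pe[pb == 1]) / 5)
})

test_that("result filtering applies fold-change, expression and significance rules", {
  res <- data.frame(
    gene_id = paste0("g", 1:4),
    mean_A = c(100, 100, 2, 100),
    mean_B = c(300, 110, 8, 320),
    mean_expr = c(200, 105, 5, 210),
    log2fc = log2(c(3, 1.1, 4, 3.2)),
    pval = c(0.001, 0.5, 0.001, 0.2),
    padj = c(0.004, 0.6, 0.004, 0.3),
    test = "exact", stringsAsFactors = FALSE)
  # g1: passes all three; g2 fails FC; g3 fails expression; g4 fails padj
  kept <- filter_de(res, fc_min = 1.5, expr_quantile = 0.5, padj_max = 0.1)
  expect_equal(kept$gene_id, "g1")
  expect_equal(nrow(filter_de(res, 0, 0, 1.01)), 4)
  expect_equal(nrow(filter_de(res, 0, 0, 0)), 0)
})
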