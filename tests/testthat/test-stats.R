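test_that("rank-sum test: exact small-sample enumeration and degeneracy", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p_value, 1 / 20)
  expect_match(r$method, "exact")

  same <- wilcoxon_rank_sum(rep(2, 5), rep(2, 7))
  expect_equal(same$p_value, 1)
  expect_equal(same$effect_size, 0)

  ## shifting one sample beyond the other's range maximises U
  a <- c(1.2, 3.4, 2.2, 0.5)
  b <- a + 10
  expect_equal(wilcoxon_rank_sum(b, a)$statistic, length(a) * length(b))
})

test_that("signed-rank test: exact sign enumeration and direction", {
  pos <- c(0.4, 1.1, 2.3, 0.9, 1.7, 3.2)
  r <- wilcoxon_signed_rank(pos, alternative = "greater")
  expect_equal(r$p_value, 1 / 64)

  neg <- wilcoxon_signed_rank(-pos, alternative = "greater")
  expect_gte(neg$p_value, 0.5)

  sym <- wilcoxon_signed_rank(c(1.3, -1.1, 2.2, -2.4, 0.7, -0.6),
                              alternative = "greater")
  expect_gt(sym$p_value, 0.2)

  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  ## zeros dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(pos, 0, 0))$n, 6)
})

test_that("effect size is |Z|/sqrt(n) recovered from the p value", {
  expect_equal(effect_size_r(1, n = 50), 0)
  expect_equal(effect_size_r(0.05, n = 100), qnorm(0.975) / 10,
               tolerance = 1e-6)
  expect_equal(effect_size_r(0.05, n = 100, tails = "one"),
               qnorm(0.95) / 10, tolerance = 1e-6)
  ## quadrupling n halves r
  expect_equal(effect_size_r(0.01, n = 400), effect_size_r(0.01, n = 100) / 2)
  expect_error(effect_size_r(0, n = 10), "underflow")
})

test_that("Dunn's pooled-rank z matches independently computed values", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 4, 3, 5, 6, 8, 7, 9, 10, 12),
    group = rep(c("g1", "g2", "g3"), each = 4)
  )
  d <- dunn_holm(df, value, group)
  ## reference z values computed independently (pooled ranks, tie term)
  expect_equal(d$z[d$group_a == "g1" & d$group_b == "g2"], -1.375219,
               tolerance = 1e-5)
  expect_equal(d$z[d$group_a == "g1" & d$group_b == "g3"], -2.897783,
               tolerance = 1e-5)
  expect_equal(d$z[d$group_a == "g2" & d$group_b == "g3"], -1.522564,
               tolerance = 1e-5)
  ## Holm: monotone, never below raw, order preserved
  expect_true(all(d$p_adj >= d$p_value))
  expect_true(all(diff(d$p_adj[order(d$p_value)]) >= -1e-12))
  expect_equal(d$p_adj, p.adjust(d$p_value, "holm"))

  ident <- tibble::tibble(value = rep(c(5, 5, 5), 3),
                          group = rep(c("a", "b", "c"), each = 3))
  expect_true(all(dunn_holm(ident, value, group)$p_adj == 1))
  expect_error(dunn_holm(df[df$group != "g3", ], value, group), "3 groups")
})

test_that("Holm step-down reproduces the hand-adjusted example", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
})

test_that("Fisher's exact test with sample odds ratio and relative risk", {
  r <- fisher_exact_or(c(180, 90, 633, 538))
  expect_equal(r$odds_ratio, 1.70, tolerance = 0.005)
  expect_equal(r$prop_a, 2 / 3, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-3)
  ## the printed one-sided probability
  r1 <- fisher_exact_or(c(180, 90, 633, 538), alternative = "greater")
  expect_equal(r1$p_value, 9.5e-5, tolerance = 0.02)

  flat <- fisher_exact_or(c(10, 10, 10, 10))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  degen <- fisher_exact_or(c(5, 0, 0, 5))
  expect_equal(degen$p_value, 2 / 252, tolerance = 1e-9)
  expect_true(degen$degenerate)
  expect_true(is.infinite(degen$odds_ratio))
})

test_that("Jeffreys intervals use Beta(x+1/2, n-x+1/2) with boundary rules", {
  ci <- jeffreys_ci(50, 100)
  expect_equal(ci$lower, 0.4505, tolerance = 1e-3)
  expect_equal(ci$upper, 0.5495, tolerance = 1e-3)
  expect_equal(jeffreys_ci(0, 20)$lower, 0)
  expect_equal(jeffreys_ci(20, 20)$upper, 1)
  ## interval always contains the point estimate
  ci_v <- jeffreys_ci(c(0, 3, 17, 20), 20)
  expect_true(all(ci_v$lower <= ci_v$estimate))
  expect_true(all(ci_v$upper >= ci_v$estimate))
})

test_that("Spearman correlation handles ties with average ranks", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  ## hand example with one tie: brute-force rank formula
  y <- c(2, 2, 1, 4, 5)
  rho_hand <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_cor(x, y)$rho, rho_hand, tolerance = 1e-9)
  expect_error(spearman_cor(x, rep(1, 5)), "constant")
})

test_that("stratified bootstrap: correction floor, determinism, null", {
  up <- tibble::tibble(d = c(5, 6, 7, 8, 9), g = "all")
  b <- stratified_bootstrap(up, d, g, B = 1000, seed = 1)
  expect_equal(tidy(b)$p_value, 1 / 1001)  # all estimates positive

  b2 <- stratified_bootstrap(up, d, g, B = 1000, seed = 1)
  expect_identical(tidy(b)$p_value, tidy(b2)$p_value)
  expect_identical(b$estimates$estimate, b2$estimates$estimate)

  withr::with_seed(3, {
    null_df <- tibble::tibble(d = stats::rnorm(120),
                              g = rep(c("old", "new"), 60))
  })
  bn <- stratified_bootstrap(null_df, d, g, B = 2000, seed = 2)
  expect_true(all(tidy(bn)$p_value > 0.05))   # symmetric about zero
  expect_true(all(tidy(bn)$p_value >= 1 / 2001))
  expect_equal(sort(tidy(bn)$stratum), c("new", "old"))
  expect_error(stratified_bootstrap(up, d, g, B = 0), "at least 1")
})
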