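# Statistical toolbox: frozen hand computations, enumeration oracles, and
# cross-checks against independent implementations.

test_that("paired and one-sample t match hand computations", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))  # differences (1,2,3)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-sqrt(12), 2), tolerance = 1e-6)
  r1 <- one_sample_t(c(1, 2, 3))
  expect_equal(r1$statistic, sqrt(12), tolerance = 1e-6)
  # identical samples: defined as t = 0, p = 1, g = 0
  re <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(re$statistic, re$p, re$effect_size), c(0, 1, 0))
  expect_error(paired_t(c(1, 2), c(0, 1)), "zero variance")
  # agreement with stats::t.test
  set.seed(51)
  x <- rnorm(15); y <- rnorm(15)
  tt <- t.test(x, y, paired = TRUE)
  ours <- paired_t(x, y)
  expect_equal(ours$statistic, unname(tt$statistic))
  expect_equal(ours$p, tt$p.value)
})

test_that("paired t p-values are uniform under the null", {
  set.seed(52)
  ps <- replicate(400, paired_t(rnorm(12), rnorm(12))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Hedges g carries the small-sample correction", {
  # diffs (1,2,3): d = 2, J = 1 - 3/7, g = 8/7
  expect_equal(hedges_g(c(2, 4, 6), c(1, 2, 3)), 2 * (1 - 3 / 7))
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(hedges_g1(c(1, 2, 3), 2), 0)
  expect_equal(hedges_g1(c(1, 2, 3), 0), 2 * (1 - 3 / 7))
  # J -> 1 for large n
  set.seed(53)
  x <- rnorm(1e4, 1)
  expect_equal(hedges_g1(x), mean(x) / sd(x), tolerance = 1e-3)
  # the alternative paired standardizer uses the average condition SD
  x <- c(1, 2, 3, 5); y <- c(0, 1, 5, 2)
  expect_equal(hedges_g(x, y, method = "average"),
               (1 - 3 / 11) * mean(x - y) / ((sd(x) + sd(y)) / 2))
})

test_that("Wilcoxon signed-rank matches exact enumeration", {
  # all-positive diffs (1,2,3): V = 6, exact two-sided p = 0.25
  r <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p, 0.25)
  expect_true(r$exact)
  # center of the distribution: p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -2))$p, 1)
  # random draws against the 2^n enumeration oracle
  set.seed(54)
  for (i in 1:20) {
    d <- round(rnorm(sample(4:11, 1)) * 100)  # integers, ties unlikely
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_exact_enum(d))
  }
  # agreement with stats::wilcox.test on the exact path
  d <- c(3, -1, 4, -9, 2, 6, -5)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcox.test(d)$p.value)
  # large n: normal approximation close to the exact distribution
  set.seed(55)
  d <- rnorm(26)
  approx_p <- wilcoxon_signed_rank(d)$p
  exact_p <- wilcox.test(d, exact = TRUE, correct = TRUE)$p.value
  expect_false(wilcoxon_signed_rank(d)$exact)
  expect_equal(approx_p, exact_p, tolerance = 0.015)
})

test_that("repeated-measures ANOVA matches the multivariate-model oracle", {
  set.seed(56)
  n <- 16; k <- 4
  Y <- matrix(rnorm(n * k), n, k) %*% chol(0.4 * diag(k) + 0.6) +
    matrix(rnorm(n), n, k) * 0.5
  r <- rm_anova_1way(Y)
  fit <- lm(Y ~ 1)
  idata <- data.frame(cond = factor(seq_len(k)))
  mt <- mauchly.test(fit, M = ~cond, X = ~1, idata = idata)
  av <- anova(fit, M = ~cond, X = ~1, idata = idata, test = "Spherical")
  expect_equal(r$statistic, av$F[1])
  expect_equal(r$mauchly_w, unname(mt$statistic))
  expect_equal(r$mauchly_p, mt$p.value, tolerance = 5e-3)
  eps_oracle <- {
    C <- alphalat:::orthonormal_contrasts(k)
    Tm <- t(C) %*% cov(Y) %*% C
    sum(diag(Tm))^2 / ((k - 1) * sum(Tm^2))
  }
  expect_equal(r$epsilon, eps_oracle)
})

test_that("ANOVA edge cases: two levels, flat profiles, partial eta squared", {
  set.seed(57)
  Y2 <- matrix(rnorm(20), 10, 2)
  r2 <- rm_anova_1way(Y2)
  expect_equal(r2$epsilon, 1)           # sphericity trivial for k = 2
  expect_equal(r2$mauchly_p, 1)
  # F of k=2 equals squared paired t
  tt <- paired_t(Y2[, 1], Y2[, 2])
  expect_equal(r2$statistic, tt$statistic^2, tolerance = 1e-8)
  # flat per-subject profiles: F exactly 0
  Yf <- matrix(rep(rnorm(6), 3), 6, 3)
  rf <- rm_anova_1way(Yf)
  expect_equal(rf$statistic, 0)
  # etap2 = SS_effect / (SS_effect + SS_error) stays in [0, 1]
  Y3 <- matrix(rnorm(30), 10, 3) + rep(c(0, 1, 2), each = 10)
  r3 <- rm_anova_1way(Y3)
  expect_true(r3$effect_size > 0 && r3$effect_size < 1)
  expect_error(rm_anova_1way(matrix(c(1, 2, 3, NA, 5, 6), 3, 2)), "missing")
})

test_that("Greenhouse-Geisser epsilon approaches 1 under compound symmetry", {
  set.seed(58)
  k <- 4
  eps <- replicate(20, {
    subj <- rnorm(60)
    Y <- matrix(rnorm(60 * k), 60, k) + subj  # compound-symmetric covariance
    rm_anova_1way(Y)$epsilon
  })
  expect_gt(mean(eps), 0.9)
})

test_that("Friedman matches the worked example and the base implementation", {
  Y <- rbind(c(1, 2, 3), c(10, 20, 30), c(5, 6, 7))  # identical orderings
  expect_equal(friedman(Y)$statistic, 6)
  expect_equal(friedman(Y)$df, 2)
  set.seed(59)
  Z <- matrix(rnorm(40), 10, 4)
  expect_equal(friedman(Z)$statistic,
               unname(friedman.test(Z)$statistic))
})

test_that("uncapped FDR adjustment follows the step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_bh(0.73), 0.73)
  # reference step-up oracle, BH and BY, on random inputs
  set.seed(60)
  for (i in 1:20) {
    p <- runif(sample(2:9, 1))
    expect_equal(fdr_adjust(p), fdr_stepup_oracle(p))
    m <- length(p)
    expect_equal(fdr_adjust(p, method = "by"),
                 fdr_stepup_oracle(p, sum(1 / seq_len(m))))
    # capped values agree with stats::p.adjust
    expect_equal(pmin(1, fdr_adjust(p)), p.adjust(p, "BH"))
    expect_equal(pmin(1, fdr_adjust(p, method = "by")), p.adjust(p, "BY"))
  }
  # families are corrected independently
  p <- c(0.01, 0.04, 0.01, 0.04)
  fam <- c("a", "a", "b", "b")
  expect_equal(fdr_adjust(p, fam), rep(fdr_adjust(c(0.01, 0.04)), 2))
  # monotone: adjusted >= raw
  set.seed(61)
  p <- runif(30)
  expect_true(all(fdr_adjust(p, method = "by") >= p))
  expect_error(fdr_adjust(c(0, 0.5)), "0, 1")
})

test_that("the dependence-robust FDR variant can exceed 1", {
  # three post-hoc tests, two tiny and one large p: the large one adjusts
  # to p * 3 * (1 + 1/2 + 1/3) / 3 = p * 11/6 > 1
  adj <- fdr_adjust(c(1e-5, 1e-5, 0.871), method = "by")
  expect_equal(adj[3], 0.871 * 11 / 6)
  expect_gt(adj[3], 1)
})

test_that("JZS Bayes factors behave and match the quadrature oracle", {
  expect_lt(bf_ttest(0, 10), 1)
  expect_lt(bf_ttest(0, 3), 1)
  # strictly increasing in |t| at fixed n
  bfs <- vapply(seq(0, 6, by = 0.5), bf_ttest, numeric(1), n = 15)
  expect_true(all(diff(bfs) > 0))
  expect_equal(bf_ttest(2, 15), bf_ttest(-2, 15), tolerance = 1e-6)
})

test_that("Lilliefors statistic matches nortest and gates correctly", {
  skip_if_not_installed("nortest")
  set.seed(62)
  for (i in 1:5) {
    x <- rnorm(40 + i, sd = 1 + i)
    expect_equal(lilliefors(x)$statistic,
                 unname(nortest::lillie.test(x)$statistic))
  }
  # statistic is affine invariant
  x <- rnorm(50)
  expect_equal(lilliefors(3 * x + 7)$statistic, lilliefors(x)$statistic)
  # Gaussian samples pass the gate at roughly the nominal rate
  ps <- replicate(50, lilliefors(rnorm(60))$p)
  expect_gte(mean(ps > 0.05), 0.84)
  # a strongly bimodal sample fails it
  xb <- c(rnorm(50, -5, 0.3), rnorm(50, 5, 0.3))
  expect_lt(lilliefors(xb)$p, 0.05)
  expect_error(lilliefors(c(1, 2, 3)), "n >= 4")
})
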