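test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(31)
  for (rep_i in 1:10) {
    groups <- list(a = rnorm(13), b = rnorm(13, 0.3), c = rnorm(13, 0.6))
    got <- oneway_anova(groups)
    want <- oracle_anova(groups)
    expect_equal(got$statistic, want$F, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(got$effect_size, want$eta, tolerance = 1e-10)
    expect_equal(got$df, c(2, 36))
    # decomposition identity
    expect_equal(want$ssb + want$ssw, want$sst, tolerance = 1e-9)
    # effect size from its own F and dfs (algebraic identity)
    expect_equal(got$effect_size,
                 got$df[1] * got$statistic /
                   (got$df[1] * got$statistic + got$df[2]),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases are flagged", {
  ident <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  got <- oneway_anova(ident)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$effect_size, 0, tolerance = 1e-12)
  # zero within-group variance
  degen <- oneway_anova(list(a = c(0, 0), b = c(1, 1), c = c(2, 2)))
  expect_true(is.infinite(degen$statistic))
  expect_true(degen$degenerate)
  expect_equal(degen$effect_size, 1)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), "insufficient")
  expect_error(oneway_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(7)
  for (rep_i in 1:5) {
    g <- list(a = rnorm(10), b = rnorm(12, 0.5))
    f <- oneway_anova(g)$statistic
    t2 <- pairwise_ttests(g)$statistic^2
    expect_equal(f, t2, tolerance = 1e-10)
  }
})

test_that("pairwise t-tests cover all pairs with optional correction", {
  set.seed(9)
  g <- list(C1 = rnorm(8), C2 = rnorm(8, 1), C3 = rnorm(8, 2))
  tab <- pairwise_ttests(g)
  expect_equal(nrow(tab), 3)
  expect_setequal(paste(tab$group1, tab$group2),
                  c("C1 C2", "C1 C3", "C2 C3"))
  # identical groups: t = 0, p = 1
  same <- pairwise_ttests(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand formula on n = 3 per group (pooled variance)
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(pairwise_ttests(list(a = a, b = b))$statistic, t_hand,
               tolerance = 1e-12)
  # Holm never lowers a p-value
  tabh <- pairwise_ttests(g, p_adjust = "holm")
  expect_true(all(tabh$p_adjusted >= tabh$p_value - 1e-15))
})

test_that("Welch test matches the formula oracle and shrinks df", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- welch_ttest(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  # equal samples: t = 0
  expect_equal(welch_ttest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # 100:1 variance ratio pulls df far below the pooled value
  set.seed(13)
  x <- rnorm(10, sd = 10); y <- rnorm(10, sd = 1)
  expect_lt(welch_ttest(x, y)$df, 18)
  expect_error(welch_ttest(1, c(1, 2)), "insufficient")
})

test_that("correlation matches the product-moment formula and affine invariance", {
  x <- c(1, 3, 4, 7, 9)
  y <- c(2, 3, 7, 8, 12)
  got <- correlate(x, y)
  expect_equal(got$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$r, -1, tolerance = 1e-12)
  # affine transforms change nothing (up to sign)
  expect_equal(correlate(3 * x - 2, y)$r, got$r, tolerance = 1e-12)
  expect_equal(correlate(-x, y)$r, -got$r, tolerance = 1e-12)
  expect_error(correlate(c(1, 1, 1), y[1:3]), "zero-variance")
  expect_error(correlate(1:2, 1:3), "differ")
})

test_that("rate of descent is a signed central-difference derivative", {
  t <- seq(0, 60, 1)
  expect_equal(unname(rate_of_descent(t, rep(8000, 61))[2:60]), rep(0, 59))
  # linear descent of 6000 ft over 60 s -> -100 ft/s inside
  alt <- 14000 - 100 * t
  rod <- rate_of_descent(t, alt)
  expect_equal(unname(rod[2:60]), rep(-100, 59), tolerance = 1e-9)
  # dive-then-recover: single minimum, negative first half, positive second
  tt <- seq(0, 90, 0.1)
  u <- tt / 90
  alt2 <- 15000 - 3000 * (1 - cos(2 * pi * u))
  rod2 <- rate_of_descent(tt, alt2)
  interior <- rod2[2:(length(rod2) - 1)]
  expect_equal(which.min(interior), round(length(interior) / 4), tolerance = 2)
  expect_lt(min(interior), -200)
  expect_gt(max(interior), 200)
})

test_that("series alignment interpolates onto the overlapping grid", {
  t1 <- seq(0, 10, 0.5); x1 <- sin(t1)
  t2 <- seq(2, 12, 0.25); x2 <- cos(t2)
  al <- align_series(t1, x1, t2, x2, n = 50)
  expect_equal(range(al$t), c(2, 10))
  expect_equal(al$x1, sin(al$t), tolerance = 0.05)
  expect_equal(al$x2, cos(al$t), tolerance = 0.02)
  expect_error(align_series(1:5, 1:5, 10:15, (10:15) * 1.0), "overlap")
})
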