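test_that("Kruskal-Wallis + Dunn: fixtures and symmetry", {
  same <- kruskal_wallis_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                   c = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  kw <- kruskal_wallis_dunn(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(nrow(kw$pairwise), 3)
  expect_true(all(kw$pairwise$p_adjusted >= kw$pairwise$p_raw - 1e-15))
  expect_true(all(kw$pairwise$p_adjusted <= 1))

  perm <- kruskal_wallis_dunn(list(c = 7:9, a = 1:3, b = 4:6))
  expect_equal(perm$statistic, kw$statistic)
  expect_equal(perm$p_value, kw$p_value)
  z1 <- kw$pairwise$z[kw$pairwise$group_a == "a" & kw$pairwise$group_b == "b"]
  z2 <- perm$pairwise$z[perm$pairwise$group_a == "a" & perm$pairwise$group_b == "b"]
  expect_equal(abs(z1), abs(z2))

  expect_error(kruskal_wallis_dunn(list(a = 1:3, b = numeric(0))), "empty group")
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(71)
  for (i in 1:10) {
    g <- list(a = rnorm(7), b = rnorm(5, 1), c = rnorm(9, -0.5))
    h0 <- kruskal_wallis_dunn(g)$statistic
    h1 <- kruskal_wallis_dunn(lapply(g, function(x) exp(x)))$statistic
    h2 <- kruskal_wallis_dunn(lapply(g, function(x) x^3 + 5))$statistic
    expect_equal(h1, h0)
    expect_equal(h2, h0)
  }
})

test_that("chi-square contingency: fixtures and closed form", {
  flat <- chi_square_contingency(rbind(c(50, 50), c(50, 50)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag_tab <- chi_square_contingency(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag_tab$statistic, 20)
  expect_equal(diag_tab$df, 1)

  expect_error(chi_square_contingency(rbind(c(0, 0), c(3, 4))), "zero marginal")

  yates <- chi_square_contingency(rbind(c(12, 5), c(6, 9)), yates = TRUE)
  plain <- chi_square_contingency(rbind(c(12, 5), c(6, 9)))
  expect_lt(yates$statistic, plain$statistic)
})

test_that("chi-square equals the textbook closed form on small 2x2 tables", {
  for (a in 0:8) for (b in 0:8) for (cc in 0:8) for (d in 0:8) {
    tab <- rbind(c(a, b), c(cc, d))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- chi_square_contingency(tab)
    expect_equal(got$statistic, chisq_2x2_closed(a, b, cc, d),
                 tolerance = 1e-12)
  }
})

test_that("log-normal check accepts exp-normal samples at the test level", {
  set.seed(72)
  pvals <- replicate(100, lognormal_check(exp(rnorm(500)))$shapiro_p)
  expect_gte(mean(pvals > 0.05), 0.90)
  fit <- lognormal_check(exp(rnorm(500)))
  expect_true(is.finite(fit$mu) && fit$sigma > 0)
  # uniform sample: finite estimates, no crash
  u <- lognormal_check(runif(50, 1, 2))
  expect_true(is.finite(u$mu) && is.finite(u$shapiro_w))
  bad <- c(a = 1, b = 0, c = 2, d = 1, e = 1, f = 1, g = 1, h = 1)
  expect_error(lognormal_check(bad), "non-positive values for: b")
})

test_that("cluster summary: SEM arithmetic and group ordering", {
  f <- make_features(c("h1", "a1", "a2", "b1", "b2"),
                     c(19, 2, 4, 3, 3.5),
                     pcts = c(0, 0, 5, 30, 40))
  high <- f[1, ]
  assign <- structure(list(labels = c(b1 = 1L, b2 = 1L, a1 = 2L, a2 = 2L),
                           k = 2L), class = "vta_assignment")
  sm <- cluster_summary(f, assign, high)
  expect_equal(sm$label, c("high-firing", "non-high-firing 1",
                           "non-high-firing 2"))
  # ascending mean pct_sib after the high group
  expect_equal(sm$pct_sib_mean, c(0, 2.5, 35))
  expect_equal(sm$firing_rate_mean[2], 3.0)
  expect_equal(sm$firing_rate_sem[2], 1.0)  # two-point SEM = |diff|/2
  expect_equal(sm$n_bursting, c(0, 1, 2))

  # row order of the feature table does not matter
  sm2 <- cluster_summary(f[c(3, 5, 1, 4, 2), ], assign, high)
  expect_equal(as.data.frame(sm2), as.data.frame(sm))

  # SEM scales linearly
  f3 <- f; f3$firing_rate_hz <- f3$firing_rate_hz * 3
  sm3 <- cluster_summary(f3, assign, f3[1, ])
  expect_equal(sm3$firing_rate_sem, sm$firing_rate_sem * 3)

  bad <- structure(list(labels = c(a1 = 1L, a2 = 1L), k = 2L),
                   class = "vta_assignment")
  expect_error(cluster_summary(f, bad, high), "empty cluster")
})
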