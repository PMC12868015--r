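test_that("beta_mean matches the closed form and rejects other kinds", {
  expect_equal(beta_mean(dist_beta(2, 192)), 2 / 194)
  expect_equal(beta_mean(dist_beta(2, 192)), 0.01031, tolerance = 1e-3)
  expect_equal(beta_mean(dist_beta(1, 1)), 0.5)
  expect_equal(beta_mean(dist_beta(8, 186)), 0.041237, tolerance = 1e-5)
  expect_error(beta_mean(dist_gamma(100, 10)), "not a beta")
})

test_that("gamma moment matching reproduces published mean/SD pairs", {
  g1 <- gamma_from_mean_sd(2501, 500)
  expect_equal(g1$a, 25.0200, tolerance = 1e-5)
  expect_equal(g1$b, 99.960, tolerance = 1e-4)
  g2 <- gamma_from_mean_sd(817, 39)
  expect_equal(g2$a, 438.86, tolerance = 1e-4)
  expect_equal(g2$b, 1.8617, tolerance = 1e-4)
  # shape x scale recovers the mean to 1e-9 relative for arbitrary inputs
  for (m in c(0.5, 817, 36351, 153049)) {
    for (s in c(0.1, 39, 4401, 54514)) {
      g <- gamma_from_mean_sd(m, s)
      expect_equal(g$a * g$b, m, tolerance = 1e-9)
      expect_equal(sqrt(g$a) * g$b, s, tolerance = 1e-9)
    }
  }
  expect_error(gamma_from_mean_sd(0, 10), "positive")
  expect_error(gamma_from_mean_sd(10, -1), "positive")
})

test_that("cumulative-to-annual conversion follows both conventions", {
  expect_equal(cumulative_to_annual(0.043, 5), 0.0086)
  expect_equal(cumulative_to_annual(0.0103, 4.5), 0.00229, tolerance = 1e-3)
  expect_equal(cumulative_to_annual(0, 7), 0)
  expect_equal(cumulative_to_annual(0, 7, "exponential"), 0)
  expect_equal(cumulative_to_annual(0.5, 2, "exponential"), 1 - sqrt(0.5))
  expect_error(cumulative_to_annual(1.2, 5), "\\[0, 1\\]")
  expect_error(cumulative_to_annual(0.1, 0), "years")
})

test_that("the two annualization conventions are ordered and agree for small risks", {
  # for windows over a year the constant-hazard value dominates the
  # linear one (Bernoulli: 1 - (1-p)^(1/y) >= p/y for y >= 1)
  p <- seq(0.001, 0.999, by = 0.002)
  for (y in c(2, 4.5, 5)) {
    lin <- cumulative_to_annual(p, y)
    expo <- cumulative_to_annual(p, y, "exponential")
    expect_true(all(expo >= lin))
    small <- p <= 0.05
    expect_true(all(abs(lin[small] - expo[small]) / lin[small] < 0.10))
  }
})

test_that("analytic means agree with large-sample draw means", {
  specs <- list(
    dist_beta(8, 186, per_years = 5),
    dist_beta(235, 2707, per_years = 5, frac = 0.625),
    dist_gamma(2501, 500),
    dist_normal(0.779, 0.038),
    dist_sum(dist_beta(266, 17284), dist_beta(1592, 15958),
             dist_beta(418, 22583))
  )
  withr::with_seed(42, {
    for (spec in specs) {
      x <- dist_draw(spec, 1e6)
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - dist_mean(spec)), 3 * se)
    }
  })
})

test_that("quantiles are monotone and respect the annualization transform", {
  spec <- dist_beta(8, 186, per_years = 5, frac = 0.5)
  q <- dist_quantile(spec, c(0.025, 0.5, 0.975))
  expect_true(all(diff(q) > 0))
  expect_equal(dist_quantile(spec, 0.5),
               stats::qbeta(0.5, 8, 186) / 5 * 0.5)
  expect_equal(dist_quantile(dist_point(3), c(0.1, 0.9)), c(3, 3))
})

test_that("rescaling preserves Beta sample size and Gamma coefficient of variation", {
  # implied annualized mean 0.237% vs printed 0.2%: rescaled
  b <- rescale_dist(dist_beta(23, 9702), 0.002)
  expect_equal(b$a + b$b, 9725)
  expect_equal(dist_mean(b), 0.002)
  # implied mean within 10% of base: untouched
  b2 <- rescale_dist(dist_beta(8, 186, per_years = 5), 0.0086)
  expect_equal(b2$a, 8)
  g <- rescale_dist(dist_gamma(1000, 200), 1500)
  expect_equal(g$a, gamma_from_mean_sd(1000, 200)$a)  # cv kept
  expect_equal(dist_mean(g), 1500)
  # sum components rescale toward their own targets
  s <- rescale_dist(dist_sum(dist_beta(1592, 15958, target = 0.110),
                             dist_beta(266, 17284, target = 0.015)), 0.125)
  expect_equal(dist_mean(s$components[[1]]), 0.110)
  expect_equal(s$components[[1]]$a + s$components[[1]]$b, 17550)
  expect_equal(s$components[[2]]$a, 266)  # within 10%: untouched
})

test_that("draws honour distribution support", {
  withr::with_seed(7, {
    x <- dist_draw(dist_beta(5, 201), 1e5)
    expect_true(all(x >= 0 & x <= 1))
    y <- dist_draw(dist_gamma(817, 39), 1e4)
    expect_true(all(y > 0))
  })
  expect_equal(dist_draw(dist_point(2501), 5), rep(2501, 5))
})

test_that("invalid specifications are rejected", {
  expect_error(dist_beta(0, 5), "invalid")
  expect_error(dist_beta(5, -1), "invalid")
  expect_error(dist_normal(0.5, -0.1), "invalid")
})
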