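test_that("procedure-cost sweeps have slope -1 and reproduce base NMBs", {
  scn <- paper_scenarios()$low_risk
  base <- run_base_case(scn)
  sw <- one_way_sweep(scn, "bca.procedure_cost", 2501, 10000, steps = 5)
  expect_equal(sw$value[1], 2501)
  expect_equal(sw$nmb_bca[1], base$nmb_bca)
  expect_equal(sw$nmb_bcs[1], base$nmb_bcs)
  slopes <- diff(sw$nmb_bca) / diff(sw$value)
  expect_equal(slopes, rep(-1, 4), tolerance = 1e-12)
  expect_equal(diff(sw$nmb_bcs), rep(0, 4))
})

test_that("sweep ranges outside the parameter's validity are rejected", {
  scn <- paper_scenarios()$low_risk
  expect_error(one_way_sweep(scn, "bca.p_mortality_annual", -0.1, 0.5), "valid")
  expect_error(one_way_sweep(scn, "bca.p_mortality_annual", 0.5, 0.1), "lo < hi")
  expect_error(one_way_sweep(scn, "bca.procedure_cost", -10, 100), "negative")
})

test_that("bisection matches the analytic procedure-cost break-even point", {
  scn <- paper_scenarios()$low_risk
  base <- run_base_case(scn)
  analytic <- 2501 + (base$nmb_bca - base$nmb_bcs)  # exact, by cost linearity
  thr <- find_threshold(scn, "bca.procedure_cost", c(0, 60000))
  expect_identical(thr$status, "found")
  expect_equal(thr$value, analytic, tolerance = 1e-6)
  expect_lt(abs(thr$nmb_gap), 1)  # slope is 1 $/$: gap ~ x-tolerance
})

test_that("brackets without a crossing report no_crossing", {
  scn <- paper_scenarios()$low_risk
  thr <- find_threshold(scn, "bca.p_mortality_annual", c(0, 0.01))
  expect_identical(thr$status, "no_crossing")
  expect_true(is.na(thr$value))
})

test_that("the mortality sweep crosses break-even exactly once", {
  scn <- paper_scenarios()$low_risk
  sw <- one_way_sweep(scn, "bca.p_mortality_annual", 0, 0.10, steps = 101)
  signs <- sign(sw$nmb_diff)
  expect_equal(sum(diff(signs) != 0), 1)
  thr <- find_threshold(scn, "bca.p_mortality_annual", c(0, 0.10))
  expect_identical(thr$status, "found")
  expect_equal(thr$n_crossings, 1)
})

test_that("bisection agrees with a grid-search oracle on forced crossings", {
  # quick version of the acceptance-scale property: procedure-cost
  # thresholds on synthetic scenarios with a crossing forced inside the
  # bracket by the analytic solution
  n_grid <- 2000
  checked <- 0
  seed <- 0
  while (checked < 10 && seed < 200) {
    seed <- seed + 1
    scn <- generate_synthetic_scenario(seed)
    base <- run_base_case(scn)
    x_star <- scn$bca$procedure_cost$base_value + (base$nmb_bca - base$nmb_bcs)
    if (x_star <= 0) next
    checked <- checked + 1
    bracket <- c(0, 2 * x_star)
    thr <- find_threshold(scn, "bca.procedure_cost", bracket)
    ev <- cryocea:::.nmb_evaluator(scn)
    xs <- seq(bracket[1], bracket[2], length.out = n_grid)
    fs <- vapply(xs, function(x) {
      v <- ev(list(bca.procedure_cost = x))
      v[[1]] - v[[2]]
    }, numeric(1))
    flip <- which(diff(sign(fs)) != 0)[1]
    oracle <- (xs[flip] + xs[flip + 1]) / 2
    step <- diff(bracket) / (n_grid - 1)
    expect_lt(abs(thr$value - oracle), step)
    expect_equal(thr$value, x_star, tolerance = 1e-5)
  }
  expect_equal(checked, 10)
})

test_that("two-way maps classify preference pointwise", {
  scn <- paper_scenarios()$low_risk
  base <- run_base_case(scn)
  # 1x1 grid at base reproduces the base-case preference
  m0 <- two_way_map(scn, "bca.p_mortality_annual", "bcs.p_mortality_annual",
                    0.0073, 0.002)
  expect_equal(nrow(m0), 1)
  expect_identical(m0$preferred, base$preferred)
  m <- two_way_map(scn, "bca.p_mortality_annual", "bcs.p_mortality_annual",
                   c(0, 0.05), c(0, 0.05))
  expect_equal(nrow(m), 4)
  # high cryoablation mortality with zero surgical mortality flips the
  # preference; the mirrored corner keeps cryoablation
  expect_identical(m$preferred[m$value_a == 0.05 & m$value_b == 0], "bcs")
  expect_identical(m$preferred[m$value_a == 0 & m$value_b == 0.05], "bca")
})

test_that("the two-way boundary is consistent with the one-way threshold", {
  scn <- paper_scenarios()$low_risk
  thr <- find_threshold(scn, "bca.p_mortality_annual", c(0, 0.10))
  # at the surgery arm's base mortality, the boundary must sit at the
  # one-way threshold by definition
  bnd <- two_way_boundary(scn, "bcs.p_mortality_annual",
                          "bca.p_mortality_annual", 0.002, c(0, 0.10))
  expect_identical(bnd$status, "found")
  expect_equal(bnd$b_threshold, thr$value, tolerance = 1e-6)
})

test_that("tornado bars are sorted, overridable, and skip point parameters", {
  scn <- paper_scenarios()$low_risk
  tor <- tornado(scn)
  expect_true(all(diff(tor$width) <= 1e-9))
  expect_false("bca.treatment_disutility" %in% tor$param)
  expect_warning(
    tornado(scn, params = c("bca.procedure_cost", "bca.treatment_disutility")),
    "point distribution")
  # explicit override with low = high gives a zero-width bar
  tor2 <- tornado(scn, params = "bca.treatment_disutility",
                  overrides = list(bca.treatment_disutility = c(0.02, 0.02)))
  expect_equal(tor2$width, 0)
  # procedure-cost bar width equals its quantile spread exactly (slope -1)
  tor3 <- tornado(scn, params = "bca.procedure_cost")
  spread <- diff(dist_quantile(gamma_from_mean_sd(2501, 500), c(0.025, 0.975)))
  expect_equal(tor3$width, spread, tolerance = 1e-9)
})

test_that("complication-risk sweeps up to +50% never flip the preference", {
  for (scn in paper_scenarios()) {
    for (arm in c("bca", "bcs")) {
      pp <- paste0(arm, ".complication_prob")
      b <- get_param(scn, pp)$base_value
      sw <- one_way_sweep(scn, pp, b * 0.5, b * 1.5, steps = 11)
      expect_true(all(sw$preferred == "bca"))
    }
  }
})

test_that("lowering the willingness-to-pay to $50,000 leaves dominance intact", {
  for (scn in paper_scenarios()) {
    cmp100 <- run_base_case(scn)
    cmp50 <- run_base_case(scn, wtp = 5e4)
    expect_identical(cmp50$preferred, cmp100$preferred)
    expect_identical(cmp50$icer_case, "dominant")
  }
})
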