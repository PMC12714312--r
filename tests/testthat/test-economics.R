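test_that("single-cycle accrual composes state costs, utilities and discounting", {
  lt <- flat_life_table(0, 1)  # one live cycle, then terminal
  p_off <- base_params(discounting_enabled = FALSE)
  p_off$tox_p1[] <- 0
  tr <- run_cohort(p_off, "T7", lt, max_cycles = 1)
  out <- accumulate_outcomes(tr, p_off, "T7")
  expect_equal(out$annual_costs, 2914.90)
  expect_equal(out$lifetime_qalys, 0.90)
  expect_equal(out$treatment_cost, 20670.28)
  expect_equal(out$lifetime_cost, 20670.28 + 2914.90)

  p_on <- base_params()
  p_on$tox_p1[] <- 0
  tr2 <- run_cohort(p_on, "T7", lt, max_cycles = 1)
  out2 <- accumulate_outcomes(tr2, p_on, "T7")
  expect_equal(out2$annual_costs, 2914.90 / 1.03, tolerance = 1e-12)
  expect_equal(out2$lifetime_qalys, 0.90 / 1.03, tolerance = 1e-12)
})

test_that("discounting can only lower lifetime QALYs and costs", {
  lt <- default_life_table()
  for (tk in c("T4", "T9")) {
    on <- accumulate_outcomes(run_cohort(base_params(), tk, lt),
                              base_params(), tk)
    p_off <- base_params(discounting_enabled = FALSE)
    off <- accumulate_outcomes(run_cohort(p_off, tk, lt), p_off, tk)
    expect_gte(off$lifetime_qalys, on$lifetime_qalys)
    expect_gte(off$lifetime_cost, on$lifetime_cost)
  }
})

test_that("arm aggregation is a weight-linear combination plus the test cost", {
  lt <- flat_life_table(0.02, 12)
  p <- base_params()
  # single-track SOC arm equals the track outcome
  p1 <- base_params(soc_utilization = c(SBRT = 1, CFRT = 0, prostatectomy = 0))
  arm <- evaluate_arms(p1, lt)$SOC
  o7 <- accumulate_outcomes(run_cohort(p1, "T7", lt), p1, "T7")
  expect_equal(arm$lifetime_cost, o7$lifetime_cost)
  expect_equal(arm$lifetime_qalys, o7$lifetime_qalys)
  expect_equal(arm$annual_costs, o7$annual_costs)
  # linear interpolation between two tracks
  o8 <- accumulate_outcomes(run_cohort(p, "T8", lt), p, "T8")
  for (w in c(0.25, 0.5)) {
    pw <- base_params(soc_utilization = c(SBRT = w, CFRT = 1 - w,
                                          prostatectomy = 0))
    aw <- evaluate_arms(pw, lt)$SOC
    expect_equal(aw$lifetime_cost,
                 w * o7$lifetime_cost + (1 - w) * o8$lifetime_cost,
                 tolerance = 1e-9)
    expect_equal(aw$lifetime_qalys,
                 w * o7$lifetime_qalys + (1 - w) * o8$lifetime_qalys,
                 tolerance = 1e-9)
  }
  # assay-guided arm carries the test cost exactly once, at T0
  arms <- evaluate_arms(p, lt)
  pz <- base_params(c_test = 0)
  arms0 <- evaluate_arms(pz, lt)
  expect_equal(arms$PROSTOX$t0_cost - arms0$PROSTOX$t0_cost, 4000)
  expect_equal(arms$PROSTOX$lifetime_cost - arms0$PROSTOX$lifetime_cost, 4000)
  expect_equal(arms$SOC$lifetime_cost, arms0$SOC$lifetime_cost)
  # cumulative costs never decrease
  expect_true(all(diff(arms$PROSTOX$cumulative_costs) >= 0))
})

test_that("cost impact is antisymmetric and zero for identical arms", {
  lt <- flat_life_table(0.02, 12)
  arms <- evaluate_arms(base_params(), lt)
  ci <- cost_impact(arms$PROSTOX, arms$SOC, 5)
  rev <- cost_impact(arms$SOC, arms$PROSTOX, 5)
  expect_equal(ci$savings, -rev$savings)
  same <- cost_impact(arms$SOC, arms$SOC, 5)
  expect_equal(same$savings, rep(0, 6))
  expect_error(cost_impact(arms$PROSTOX, arms$SOC, 50), "horizon")
})

test_that("printed-table savings stay positive at every year, led by the T0 gap", {
  agg <- aggregate_printed_table(load_printed_table(), base_params())
  cum_p <- agg$PROSTOX$t0_cost + c(0, cumsum(agg$PROSTOX$annual_costs))
  cum_s <- agg$SOC$t0_cost + c(0, cumsum(agg$SOC$annual_costs))
  savings <- cum_s - cum_p
  expect_true(all(savings > 0))
  # the bulk of the saving is locked in at T0 by the treatment-cost gap
  expect_gt(savings[1], 0.9 * savings[6])
})

test_that("ICER classification follows the cost-effectiveness plane", {
  mk <- function(cost, qalys) {
    structure(list(arm = "X", t0_cost = cost, annual_costs = numeric(0),
                   cumulative_costs = cost, lifetime_cost = cost,
                   lifetime_qalys = qalys), class = "arm_outcome")
  }
  r <- icer(mk(300, 1.5), mk(200, 1.0))
  expect_equal(r$icer, 200)
  expect_equal(r$dominance, "tradeoff")
  expect_equal(icer(mk(100, 2), mk(200, 1))$dominance, "dominant")
  expect_equal(icer(mk(200, 1), mk(100, 2))$dominance, "dominated")
  same <- icer(mk(100, 1), mk(100, 1))
  expect_equal(same$dominance, "undefined")
  expect_true(is.na(same$icer))
})

test_that("per-track lifetime QALYs under the calibrated table approximate the published scale", {
  lt <- default_life_table()
  p <- base_params()
  published <- c(T2 = 11.28, T3 = 11.59, T4 = 11.68,
                 T7 = 11.15, T8 = 11.28, T9 = 11.59)
  for (tk in names(published)) {
    q <- accumulate_outcomes(run_cohort(p, tk, lt), p, tk)$lifetime_qalys
    # sanity gate, not an exact match: the mortality source is synthetic
    expect_lt(abs(q - published[[tk]]) / published[[tk]], 0.10)
  }
})
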