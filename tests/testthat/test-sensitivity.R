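test_that("moment matching recovers the stated distribution parameters", {
  g <- calibrate_distribution(list(name = "c", family = "gamma",
                                   mean = 100, se = 10))
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 1)
  b <- calibrate_distribution(list(name = "u", family = "beta",
                                   mean = 0.9, se = 0.05))
  expect_equal(b$alpha, 31.5)
  expect_equal(b$beta, 3.5)
  expect_error(calibrate_distribution(list(name = "u_bad", family = "beta",
                                           mean = 0.9, se = 0.5)),
               "u_bad")
  expect_error(calibrate_distribution(list(name = "x", family = "gamma",
                                           mean = 10, se = 0)), "SE")
  fx <- calibrate_distribution(list(name = "f", family = "fixed", mean = 3))
  expect_identical(prostoxcea:::draw_distribution(fx, 4), rep(3, 4))
})

test_that("calibrated draws match the stated mean and SE", {
  set.seed(2024)
  n <- 100000
  for (spec in list(list(name = "cost", family = "gamma", mean = 97782.37,
                         se = 9778.237),
                    list(name = "prob", family = "beta", mean = 0.1189,
                         se = 0.01189))) {
    x <- prostoxcea:::draw_distribution(spec, n)
    expect_equal(mean(x), spec$mean, tolerance = 2 * spec$se / sqrt(n) / spec$mean)
    expect_equal(sd(x), spec$se, tolerance = 2 * spec$se / sqrt(2 * n) / spec$se)
  }
})

test_that("zero-delta DSA reproduces the base case for every parameter", {
  lt <- flat_life_table(0.02, 12)
  p <- base_params()
  dsa <- run_dsa(p, delta = 0, life_table = lt)
  base <- attr(dsa, "base_outcome")
  expect_equal(dsa$outcome_low, rep(base, nrow(dsa)))
  expect_equal(dsa$outcome_high, rep(base, nrow(dsa)))
})

test_that("the test price enters the DSA as an exact affine term", {
  lt <- flat_life_table(0.02, 12)
  dsa <- suppressWarnings(run_dsa(base_params(), life_table = lt))
  row <- dsa[dsa$parameter == "c_test", ]
  expect_equal(row$range, 2 * 0.20 * 4000, tolerance = 1e-9)
  base <- attr(dsa, "base_outcome")
  # affine dependence makes low/high equidistant from base
  expect_equal(row$outcome_low - base, base - row$outcome_high,
               tolerance = 1e-9)
  # base case lies inside every parameter's outcome range
  expect_true(all(pmin(dsa$outcome_low, dsa$outcome_high) <= base + 1e-9))
  expect_true(all(pmax(dsa$outcome_low, dsa$outcome_high) >= base - 1e-9))
})

test_that("PSA with all-fixed distributions collapses to the base case", {
  lt <- flat_life_table(0.02, 12)
  p <- base_params()
  specs <- lapply(psa_default_specs(p), function(s) {
    s$family <- "fixed"
    s
  })
  psa <- run_psa(p, specs = specs, n = 5, seed = 1, life_table = lt)
  arms <- evaluate_arms(p, lt)
  base <- icer(arms$PROSTOX, arms$SOC)
  expect_equal(psa$results$delta_cost, rep(base$delta_cost, 5),
               tolerance = 1e-9)
  expect_equal(psa$results$delta_qaly, rep(base$delta_qalys, 5),
               tolerance = 1e-9)
  # degenerate PSA of a dominant base case: CEAC is identically 1
  cc <- ceac(psa, seq(0, 150000, 50000))
  expect_equal(cc$probability, rep(1, 4))
})

test_that("PSA is seed-reproducible and labels quadrants consistently", {
  lt <- flat_life_table(0.02, 12)
  p <- base_params()
  a <- run_psa(p, n = 300, seed = 42, life_table = lt)
  b <- run_psa(p, n = 300, seed = 42, life_table = lt)
  expect_identical(a$results, b$results)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$results), 300)
  r <- a$results
  expect_true(all((r$quadrant == "SE") == (r$delta_cost < 0 & r$delta_qaly > 0)))
  # drawn parameter means stay near their inputs (law of large numbers)
  big <- run_psa(p, n = 10000, seed = 1, life_table = lt)
  for (spec in psa_default_specs(p)) {
    if (spec$family == "fixed") next
    expect_equal(mean(big$draws[[spec$name]]), spec$mean,
                 tolerance = 0.01)
  }
})

test_that("CEAC is monotone when every iteration gains QALYs", {
  lt <- flat_life_table(0.02, 12)
  psa <- run_psa(base_params(), n = 2000, seed = 5, life_table = lt)
  keep <- psa$results$delta_qaly > 0
  psa$results <- psa$results[keep, ]
  cc <- ceac(psa, seq(0, 150000, 10000))
  expect_true(all(diff(cc$probability) >= 0))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
})

test_that("quadrant classification covers the plane with favorable boundaries", {
  expect_equal(classify_quadrant(-1, 0.1), "SE")
  expect_equal(classify_quadrant(1, -0.1), "NW")
  expect_equal(classify_quadrant(1, 0.1), "NE")
  expect_equal(classify_quadrant(-1, -0.1), "SW")
  expect_equal(classify_quadrant(0, 0), "SE")
  expect_equal(classify_quadrant(c(-1, 1), c(0.1, -0.1)), c("SE", "NW"))
})
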