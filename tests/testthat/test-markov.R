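test_that("toxicity transition probabilities follow the taper schedule", {
  p <- base_params()
  expect_equal(toxicity_probability(p, "T7", 3), 0.0499)
  expect_equal(toxicity_probability(p, "T9", 2), 0)
  expect_equal(toxicity_probability(p, "T9", 1), 0.1189)
  # taper applies geometrically from cycle 5
  expect_equal(toxicity_probability(p, "T7", 6), 0.0499 * 0.7013^2,
               tolerance = 1e-15)
  expect_equal(toxicity_probability(p, "T2", 1:4), rep(0.0396, 4))
  expect_equal(toxicity_probability(p, "T2", 5), 0.0396 * 0.7013)
  expect_error(toxicity_probability(p, "T10", 1), "unknown track")
  # cycle-1 inflow ordering across tracks follows the inputs
  p1 <- vapply(c("T4", "T8", "T7", "T9", "T1"),
               function(tk) toxicity_probability(p, tk, 1), numeric(1))
  expect_true(all(diff(p1) > 0))
})

test_that("one-cycle cohort recursion matches the hand computation", {
  p <- base_params()
  lt <- flat_life_table(0.05, 1)
  p$tox_p1[] <- 0.1
  tr <- run_cohort(p, "T7", lt, max_cycles = 1)
  # death applied first, then toxicity among survivors
  expect_equal(unlist(tr[2, c("s_notox", "s_tox", "s_dead")]),
               c(s_notox = 0.855, s_tox = 0.095, s_dead = 0.05))
})

test_that("degenerate inputs give degenerate traces", {
  p <- base_params()
  p$tox_p1[] <- 0
  tr <- run_cohort(p, "T7", zero_mortality_table(20))
  expect_true(all(tr$s_notox[-nrow(tr)] == 1))
  expect_true(all(tr$s_tox == 0))
  # all-dead after cycle 1 accrues nothing further
  dead <- run_cohort(base_params(), "T7", flat_life_table(1, 5))
  expect_equal(dead$s_dead[-1], rep(1, nrow(dead) - 1))
  expect_equal(sum(dead$cost_disc[-1]), 0)
  expect_equal(sum(dead$qaly_disc[-1]), 0)
})

test_that("constant hazard with zero mortality matches the closed form", {
  p <- base_params()
  lt <- zero_mortality_table(10)
  tr <- run_cohort(p, "T8", lt, max_cycles = 4)
  expect_equal(tr$cum_tox[5], 1 - (1 - 0.0396)^4, tolerance = 1e-12)
  # property over random constant hazards (cycles 1-4, before the taper)
  for (seed in 1:10) {
    set.seed(seed)
    q1 <- runif(1, 0, 0.5)
    pr <- p
    pr$tox_p1["T7"] <- q1
    trr <- run_cohort(pr, "T7", lt, max_cycles = 4)
    expect_equal(trr$cum_tox[5], 1 - (1 - q1)^4, tolerance = 1e-12)
  }
})

test_that("occupancies conserve mass and absorbing states never shrink", {
  lt <- default_life_table()
  for (seed in 1:10) {
    p <- random_parameter_set(seed, jitter = 0.4)
    for (tk in c("T1", "T4", "T7", "T9")) {
      tr <- run_cohort(p, tk, lt)
      expect_equal(tr$s_notox + tr$s_tox + tr$s_dead, rep(1, nrow(tr)),
                   tolerance = 1e-12)
      expect_true(all(diff(tr$s_dead) >= -1e-15))
      expect_true(all(diff(tr$cum_tox) >= -1e-15))
      expect_equal(unlist(tr[1, c("s_notox", "s_tox", "s_dead")]),
                   c(s_notox = 1, s_tox = 0, s_dead = 0))
      # full absorption by the end of the life table
      expect_equal(tr$s_dead[nrow(tr)], 1, tolerance = 1e-12)
    }
  }
})

test_that("prostatectomy tracks admit toxicity inflow only in cycle 1", {
  tr <- run_cohort(base_params(), "T9", zero_mortality_table(15))
  expect_equal(tr$cum_tox[-1], rep(0.1189, nrow(tr) - 1))
})

test_that("microsimulation agrees with the cohort recursion and is reproducible", {
  p <- base_params()
  lt <- default_life_table()
  # zero hazards: everyone stays in no-toxicity (until the terminal q = 1)
  p0 <- p; p0$tox_p1[] <- 0
  ms0 <- microsimulate(p0, "T7", zero_mortality_table(10), n = 50, seed = 1)
  expect_true(all(ms0$s_tox == 0))
  expect_true(all(ms0$s_notox[-nrow(ms0)] == 1))
  # a single patient gives indicator occupancies
  ms1 <- microsimulate(p, "T7", lt, n = 1, seed = 3)
  expect_true(all(unlist(ms1[, c("s_notox", "s_tox", "s_dead")]) %in% c(0, 1)))
  # reproducibility
  a <- microsimulate(p, "T8", lt, n = 500, seed = 11)
  b <- microsimulate(p, "T8", lt, n = 500, seed = 11)
  expect_identical(a$s_tox, b$s_tox)
  # Monte-Carlo agreement with the deterministic recursion, 3 binomial SEs
  n <- 20000L
  ms <- microsimulate(p, "T7", lt, n = n, seed = 7)
  tr <- run_cohort(p, "T7", lt)
  for (col in c("s_notox", "s_tox", "s_dead")) {
    se3 <- 3 * sqrt(pmax(tr[[col]] * (1 - tr[[col]]), 0) / n)
    expect_true(all(abs(ms[[col]] - tr[[col]]) <= se3 + 1e-12))
  }
})
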