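test_that("default parameters carry the published base-case inputs and validate", {
  p <- model_parameters()
  expect_true(validate_parameters(p))
  expect_equal(p$p_high, 0.1872)
  expect_equal(p$taper, 0.7013)
  expect_equal(p$c_test, 4000)
  expect_equal(p$u_notox - p$u_tox, 0.20)
  expect_equal(unname(p$soc_utilization),
               c(0.3830, 0.1235, 0.4935),
               ignore_attr = TRUE)
  expect_equal(sum(p$soc_utilization), 1, tolerance = 1e-12)
  expect_equal(unname(p$tox_p1[c("T1", "T2", "T3", "T4", "T7")]),
               c(0.2778, 0.0396, 0.1189, 0.0124, 0.0499))
  expect_equal(unname(p$c_treat),
               c(20670.28, 42642.68, 97782.37))
  expect_true(p$discounting_enabled)
  expect_equal(p$d_cost, 0.03)
})

test_that("parameter validation rejects out-of-range fields by name", {
  expect_error(model_parameters(p_high = 1.5), "p_high")
  expect_error(model_parameters(tox_p1 = c(T7 = 1.5)), "tox_p1")
  expect_error(model_parameters(c_tox = -1), "c_tox")
  expect_error(model_parameters(taper = 0), "taper")
  expect_error(model_parameters(soc_utilization = c(SBRT = 0.5)),
               "sum to 1")
  expect_error(model_parameters(nonsense = 1), "unknown parameter")
})

test_that("JSON config round-trips bit-identically and supports partial override", {
  p <- model_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  save_config(p, path)
  expect_identical(unclass(load_config(path, quiet = TRUE)), unclass(p))

  bundled <- system.file("extdata", "default_config.json",
                         package = "prostoxcea")
  expect_identical(unclass(load_config(bundled, quiet = TRUE)), unclass(p))

  jsonlite::write_json(list(c_test = 10000), path, auto_unbox = TRUE)
  p2 <- load_config(path, quiet = TRUE)
  expect_equal(p2$c_test, 10000)
  same <- setdiff(names(unclass(p)), "c_test")
  expect_identical(unclass(p2)[same], unclass(p)[same])

  jsonlite::write_json(list(tox_p1 = list(T7 = 1.5)), path, auto_unbox = TRUE)
  expect_error(load_config(path, quiet = TRUE), "tox_p1")
  expect_error(load_config(file.path(tempdir(), "nope.json")), "not found")
})

test_that("the bundled printed per-track table matches the published cells", {
  tab <- load_printed_table()
  expect_s3_class(tab, "printed_track_table")
  expect_equal(nrow(tab), 9)
  expect_equal(tab$weight_pct[tab$track == "T4"], 73.26)
  expect_equal(tab$cost_t0[tab$track == "T4"], 20670)
  expect_equal(tab$lifetime_qalys[tab$track == "T9"], 11.59)
  expect_equal(tab$cost_y5[tab$track == "T7"], 1085)
  # arm weights sum to 100 within table rounding
  expect_equal(sum(tab$weight_pct[1:6]), 100, tolerance = 0.1)
  expect_equal(sum(tab$weight_pct[7:9]), 100, tolerance = 0.1)
})

test_that("printed-table loader rejects malformed files", {
  tab <- read.csv(system.file("extdata", "table_tracks_printed.csv",
                              package = "prostoxcea"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[1:8, ], path, row.names = FALSE)
  expect_error(load_printed_table(path), "nine")
  bad <- tab
  bad$cost_y1[1] <- -5
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_printed_table(path), "non-negative")
})
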