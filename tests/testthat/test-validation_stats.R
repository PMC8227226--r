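test_that("calibration detection limits follow the 3.3/10 sigma convention", {
  conc <- c(2, 10, 25, 40, 55, 70, 75)
  cal <- fit_calibration(conc, 0.2 * conc + 0.05, blank_sd = 0.01)
  expect_equal(cal$slope, 0.2, tolerance = 1e-10)
  expect_equal(cal$lod, 3.3 * 0.01 / 0.2, tolerance = 1e-12)  # 0.165 uM
  expect_equal(cal$loq, 10 * 0.01 / 0.2, tolerance = 1e-12)   # 0.5 uM
  expect_identical(cal$sigma_source, "blank_replicates")
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$linear_range[2], 75)

  # LOD/LOQ scale linearly in sigma and inversely in slope
  for (sig in c(0.005, 0.02, 0.1)) {
    for (S in c(0.05, 0.2, 1.3)) {
      m <- fit_calibration(conc, S * conc + 0.01, blank_sd = sig)
      expect_equal(m$lod, 3.3 * sig / m$slope, tolerance = 1e-10)
      expect_equal(m$loq / m$lod, 10 / 3.3, tolerance = 1e-12)
    }
  }

  # residual fallback recorded when no blank replicates are supplied
  set.seed(3)
  m2 <- fit_calibration(conc, 0.2 * conc + rnorm(7, 0, 0.01))
  expect_identical(m2$sigma_source, "fit_residuals")
  expect_gt(m2$sigma_blank, 0)
  expect_equal(m2$loq / m2$lod, 10 / 3.3, tolerance = 1e-12)

  expect_warning(bad <- fit_calibration(conc, 10 - 0.1 * conc + 11),
                 "unusable")
  expect_false(bad$usable)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("recovery arithmetic is exact and unit-scale invariant", {
  expect_equal(recovery(38.98, 40)$recovery_pct, 97.45, tolerance = 1e-10)
  expect_equal(recovery(23.71, 25)$recovery_pct, 94.84, tolerance = 1e-10)

  r <- recovery(c(40, 40, 40), 40)
  expect_equal(r$recovery_pct, 100, tolerance = 0)
  expect_equal(r$rsd_pct, 0, tolerance = 0)

  set.seed(9)
  meas <- rnorm(5, 24, 1)
  a <- recovery(meas, 25)
  b <- recovery(meas * 1000, 25 * 1000)  # e.g. uM -> nM
  expect_equal(a$recovery_pct, b$recovery_pct, tolerance = 1e-12)
  expect_equal(a$rsd_pct, b$rsd_pct, tolerance = 1e-12)

  expect_true(is.na(recovery(24.2, 25)$rsd_pct))
  expect_error(recovery(c(24, 25), 0), "positive")
})

test_that("precision computes per-level %RSD, its median, and skips singletons", {
  res <- precision(rep(1, 3), c(10, 10, 10))
  expect_equal(res$per_level$rsd_pct, 0)

  # sd(9,10,11) = 1, mean 10 -> exactly 10%
  res2 <- precision(rep(1, 3), c(9, 10, 11))
  expect_equal(res2$per_level$rsd_pct, 10, tolerance = 1e-12)

  lv <- rep(c(2, 10, 25), each = 3)
  x <- c(2.1, 1.9, 2.0, 10.2, 9.9, 10.1, 25.5, 24.3, 25.0)
  res3 <- precision(lv, x, mode = "inter_day")
  expect_identical(nrow(res3$per_level), 3L)
  expect_equal(res3$median_rsd_pct, sort(res3$per_level$rsd_pct)[2])
  # scale invariance
  res3b <- precision(lv, 5 * x)
  expect_equal(res3b$per_level$rsd_pct, res3$per_level$rsd_pct,
               tolerance = 1e-12)

  expect_warning(res4 <- precision(c(1, 1, 2), c(9, 11, 5)), "skipping")
  expect_identical(nrow(res4$per_level), 1L)
  expect_error(suppressWarnings(precision(1:3, c(1, 2, 3))), "2 or more")
})

test_that("interference percent change matches the published-table convention", {
  res <- interference_change(0.2311, 0.2311 - 0.039, "DSX", 100)
  expect_equal(res$delta_i, -0.039, tolerance = 1e-12)
  expect_equal(res$pct_change, 100 * 0.039 / 0.2311, tolerance = 1e-12)
  expect_equal(res$pct_change, 16.88, tolerance = 0.01)

  same <- interference_change(0.2311, 0.2311)
  expect_equal(same$pct_change, 0, tolerance = 0)
  expect_error(interference_change(0, 0.1), "positive")

  tab <- data.frame(interferent = c("none", "A", "A"),
                    conc_uM = c(0, 10, 100),
                    current_uA = c(0.2, 0.21, 0.15))
  out <- interference_table(tab)
  expect_identical(nrow(out), 2L)
  expect_equal(out$pct_change, c(5, 25), tolerance = 1e-12)
  expect_equal(attr(out, "reference_current"), 0.2)
  expect_error(interference_table(tab[-1, ]), "none")
})

test_that("published interference rows imply one common reference current", {
  tab <- utils::read.csv(system.file("extdata", "table2_interference.csv",
                                     package = "voltmip"))
  res <- derive_interference_reference(tab)
  expect_equal(res$reference_uA, 0.2311, tolerance = 0.001)
  expect_lt(res$max_rel_deviation, 0.05)
  flagged <- res$per_row[res$per_row$flagged, ]
  expect_identical(nrow(flagged), 1L)
  expect_identical(flagged$interferent, "PPX")
  expect_equal(flagged$conc_uM, 50)
})

test_that("method comparison flags agreement correctly", {
  x <- c(25, 40, 55, 70, 85)
  idn <- compare_methods(x, x)
  expect_equal(idn$fit$slope, 1, tolerance = 1e-12)
  expect_equal(idn$fit$intercept, 0, tolerance = 1e-10)
  expect_equal(idn$fit$r_squared, 1, tolerance = 1e-12)
  expect_true(idn$agreement)

  gc <- compare_methods(x, 0.9972 * x + 1.6067)
  expect_equal(gc$fit$slope, 0.9972, tolerance = 1e-12)
  expect_equal(gc$fit$intercept, 1.6067, tolerance = 1e-10)
  expect_true(gc$agreement)

  off <- compare_methods(x, 2 * x)
  expect_equal(off$fit$slope, 2, tolerance = 1e-12)
  expect_false(off$agreement)

  expect_error(compare_methods(x, x[-1]), "equal length")
})
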