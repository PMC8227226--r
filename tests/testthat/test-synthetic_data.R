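test_that("generator output is deterministic for a fixed seed", {
  cfg <- synthetic_config()
  a <- generate_voltammogram(cfg, 7, 0.1, 50, seed = 5, seed_offset = 3)
  b <- generate_voltammogram(cfg, 7, 0.1, 50, seed = 5, seed_offset = 3)
  expect_identical(a, b)
  # different stream offsets decorrelate traces
  c <- generate_voltammogram(cfg, 7, 0.1, 50, seed = 5, seed_offset = 4)
  expect_false(identical(a$voltammogram$current, c$voltammogram$current))

  # written studies are byte-identical across regenerations
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_mechanism_study(generate_mechanism_study(cfg, seed = 2), d1)
  write_mechanism_study(generate_mechanism_study(cfg, seed = 2), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("noiseless generator and analyzer agree exactly on every peak", {
  cfg <- synthetic_config(noise = c(0, 0))
  for (cond in list(list(ph = 3, v = 0.05, c = 2),
                    list(ph = 7, v = 0.1, c = 50),
                    list(ph = 9, v = 1.0, c = 75))) {
    out <- generate_voltammogram(cfg, cond$ph, cond$v, cond$c)
    pk <- detect_peak(out$voltammogram)
    gt <- out$ground_truth
    expect_equal(pk$ep, gt$ep, tolerance = 1e-12)
    expect_equal(pk$ip, gt$ip, tolerance = 1e-9)
    expect_equal(pk$ep_half, gt$ep_half, tolerance = 1e-9)
  }
})

test_that("doubling the scan rate shifts log peak current by the exponent", {
  cfg <- synthetic_config(noise = c(0, 0))
  p1 <- detect_peak(generate_voltammogram(cfg, 7, 0.1, 50)$voltammogram)
  p2 <- detect_peak(generate_voltammogram(cfg, 7, 0.2, 50)$voltammogram)
  expect_equal(log10(p2$ip) - log10(p1$ip), 0.7677 * log10(2),
               tolerance = 1e-9)
})

test_that("mechanism study grids match the experimental design", {
  st <- generate_mechanism_study(synthetic_config(noise = c(0, 0)))
  expect_identical(length(st$ph_series$values), 7L)
  expect_equal(st$ph_series$values, 3:9)
  expect_gte(length(st$scan_series$values), 5L)
  expect_equal(range(st$scan_series$values), c(0.05, 1.0), tolerance = 1e-12)
  # every trace carries its context
  expect_equal(vapply(st$ph_series$voltammograms, `[[`, numeric(1), "ph"), 3:9)
})

test_that("study CSVs round-trip through the file layer", {
  cfg <- synthetic_config()
  dir <- file.path(tempdir(), "roundtrip_study")
  write_mechanism_study(generate_mechanism_study(cfg, seed = 4), dir)
  back <- read_mechanism_study(dir, config = cfg)
  direct <- analyze_mechanism_study(generate_mechanism_study(cfg, seed = 4))
  from_files <- analyze_mechanism_study(back)
  expect_equal(from_files$alpha_n, direct$alpha_n, tolerance = 1e-12)
  expect_equal(from_files$fits$ph$slope, direct$fits$ph$slope,
               tolerance = 1e-12)

  vdir <- file.path(tempdir(), "roundtrip_validation")
  vs <- generate_validation_study(cfg, seed = 4)
  write_validation_study(vs, vdir)
  vback <- read_validation_study(vdir, config = cfg)
  expect_equal(vback$recovery$measured_uM, vs$recovery$measured_uM,
               tolerance = 1e-12)
  a1 <- analyze_validation_study(vs)
  a2 <- analyze_validation_study(vback)
  expect_equal(a2$recovery$recovery_pct, a1$recovery$recovery_pct,
               tolerance = 1e-12)
})

test_that("noiseless validation tables close exactly on their ground truth", {
  cfg <- synthetic_config(noise = c(0, 0))
  av <- analyze_validation_study(generate_validation_study(cfg))
  expect_equal(av$calibration$r_squared, 1, tolerance = 1e-12)
  expect_equal(av$calibration$slope, cfg$calibration_sensitivity,
               tolerance = 1e-12)
  # all recoveries equal 100 * matrix_effect exactly
  for (m in names(cfg$matrix_effect)) {
    rows <- av$recovery[av$recovery$matrix == m, ]
    expect_equal(rows$recovery_pct,
                 rep(100 * unname(cfg$matrix_effect[m]), nrow(rows)),
                 tolerance = 1e-12)
  }
})

test_that("seeded noisy recoveries fall inside the validated spike-recovery band", {
  av <- analyze_validation_study(generate_validation_study(synthetic_config(),
                                                           seed = 1))
  expect_true(all(av$recovery$recovery_pct >= 91.61))
  expect_true(all(av$recovery$recovery_pct <= 98.19))
})

test_that("interference table reproduces the calibrated selectivity profile", {
  av <- analyze_validation_study(generate_validation_study(synthetic_config()))
  expect_lt(av$max_interference_pct, 16.9)
  # worst interferent at tenfold excess is disulfoton-sulfoxide
  worst <- av$interference[which.max(av$interference$pct_change), ]
  expect_identical(worst$interferent, "DSX")
  expect_equal(worst$conc_uM, 100)
})

test_that("estimator scatter shrinks roughly as 1/sqrt(n) in replicates", {
  cfg <- synthetic_config()
  rec_scatter <- function(n_rep) {
    vals <- vapply(1:60, function(s) {
      vs <- generate_validation_study(cfg, seed = 300 + s, n_replicates = n_rep)
      av <- analyze_validation_study(vs)
      av$recovery$recovery_pct[av$recovery$matrix == "plasma" &
                               av$recovery$spiked_uM == 25]
    }, numeric(1))
    stats::sd(vals)
  }
  ratio <- rec_scatter(3L) / rec_scatter(12L)
  expect_gt(ratio, 1.4)  # ideal value 2
  expect_lt(ratio, 2.9)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(noise = c(-1, 0)), "noise")
  expect_error(synthetic_config(grid_step = 0), "positive")
  expect_error(synthetic_config(baseline_frac = 1.2), "baseline_frac")
  # a peak too wide for the sweep is caught at construction
  expect_error(synthetic_config(half_width_mv = 200), "baseline window")
  expect_error(generate_voltammogram(synthetic_config(), 7, -0.1, 50),
               "positive")
})
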