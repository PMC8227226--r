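test_that("fit_linear matches a brute-force OLS oracle and handles edge cases", {
  expect_equal(fit_linear(1:3, c(2, 4, 6))$slope, 2, tolerance = 1e-12)
  expect_equal(fit_linear(1:3, c(2, 4, 6))$intercept, 0, tolerance = 1e-12)
  expect_equal(fit_linear(1:3, c(2, 4, 6))$r_squared, 1, tolerance = 1e-12)

  cst <- fit_linear(1:5, rep(3, 5))
  expect_equal(cst$slope, 0, tolerance = 1e-12)
  expect_equal(cst$r_squared, 0)

  set.seed(42)
  for (k in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- rnorm(n, mean = 2 * x, sd = runif(1, 0.1, 3))
    got <- fit_linear(x, y)
    want <- ols_oracle(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  }

  expect_error(fit_linear(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("pH dependence recovers the configured slope and flags protonation", {
  ph <- 3:9
  res <- ph_dependence(ph, 0.736 + 0.0567 * (ph - 7))
  expect_equal(res$fit$slope, 0.0567, tolerance = 1e-12)
  expect_true(res$proton_coupled)

  flat <- ph_dependence(ph, rep(0.736, 7))
  expect_equal(flat$fit$slope, 0, tolerance = 1e-12)
  expect_false(flat$proton_coupled)

  # noisy series with known ground truth: the truth lies inside the 95% CI
  set.seed(7)
  noisy <- ph_dependence(ph, 0.736 + 0.0567 * (ph - 7) + rnorm(7, 0, 0.002))
  expect_gte(0.0567, noisy$fit$slope_ci95[1])
  expect_lte(0.0567, noisy$fit$slope_ci95[2])
})

test_that("scan-rate analysis recovers exact power laws", {
  v <- c(0.05, 0.1, 0.2, 0.5, 1)
  ep <- 0.736 + 0.1016 * log10(v / 0.1)

  pure_ads <- scan_rate_analysis(v, ip = 3 * v, ep = ep)
  expect_equal(pure_ads$loglog$slope, 1, tolerance = 1e-12)

  pure_diff <- scan_rate_analysis(v, ip = 3 * sqrt(v), ep = ep)
  expect_equal(pure_diff$loglog$slope, 0.5, tolerance = 1e-12)
  expect_equal(pure_diff$ip_sqrtv$r_squared, 1, tolerance = 1e-12)

  mixed <- scan_rate_analysis(v, ip = 10^(1.5706 + 0.7677 * log10(v)), ep = ep)
  expect_equal(mixed$loglog$slope, 0.7677, tolerance = 1e-12)
  expect_equal(mixed$ep_logv$slope, 0.1016, tolerance = 1e-12)

  expect_error(scan_rate_analysis(v, ip = c(-1, 1, 1, 1, 1), ep = ep),
               "positive")
  expect_error(scan_rate_analysis(-v, ip = 3 * v, ep = ep), "positive")
})

test_that("control-regime classification is correct, inclusive and monotone", {
  expect_identical(classify_control(0.7677), "mixed")
  expect_identical(classify_control(0.5), "diffusion")
  expect_identical(classify_control(1.0), "adsorption")
  # boundaries inclusive toward the pure regimes
  expect_identical(classify_control(0.55), "diffusion")
  expect_identical(classify_control(0.95), "adsorption")
  expect_identical(classify_control(0.551), "mixed")

  # monotone: increasing slope never moves toward the diffusive class
  order_of <- c(diffusion = 1L, mixed = 2L, adsorption = 3L)
  slopes <- seq(0, 1.4, by = 0.01)
  classes <- order_of[vapply(slopes, classify_control, character(1))]
  expect_true(all(diff(classes) >= 0))
})

test_that("Laviron transfer-coefficient product obeys its algebraic identities", {
  cst <- voltammetry_constants()
  k <- 2.303 * cst$R * cst$T / cst$F
  # slope equal to 2.303RT/F gives exactly alpha*n = 1
  expect_equal(laviron_alpha_n(k), 1, tolerance = 1e-12)
  # exact inverse proportionality: halving the slope doubles alpha*n
  for (s in c(0.03, 0.1016, 0.2)) {
    expect_equal(laviron_alpha_n(s / 2), 2 * laviron_alpha_n(s),
                 tolerance = 1e-12)
    # product slope * alpha_n is the constant 2.303RT/F
    expect_equal(laviron_alpha_n(s) * s, k, tolerance = 1e-12)
  }
  expect_error(laviron_alpha_n(0), "positive")
  expect_error(laviron_alpha_n(-0.1), "positive")
})

test_that("half-peak-width transfer coefficient matches hand evaluation", {
  expect_equal(bard_faulkner_alpha(0.7, 0.7 - 0.0477), 1, tolerance = 1e-12)
  expect_equal(bard_faulkner_alpha(0.736, 0.736 - 0.090), 47.7 / 90,
               tolerance = 1e-12)
  expect_equal(bard_faulkner_alpha(0.736, 0.736 - 0.0954), 0.5,
               tolerance = 1e-12)
  expect_error(bard_faulkner_alpha(0.6, 0.7), "exceed")
})

test_that("electron count is the alpha ratio with ties away from zero", {
  res <- electron_count(0.57, 0.53)
  expect_equal(res$n_float, 0.57 / 0.53, tolerance = 1e-12)
  expect_identical(res$n_int, 1L)

  expect_equal(electron_count(0.53, 0.53)$n_float, 1, tolerance = 1e-12)
  expect_identical(electron_count(1.06, 0.53)$n_int, 2L)
  # scaling property: alpha_n = k * alpha recovers k
  for (k in c(0.5, 1, 1.5, 1.8)) {
    expect_equal(electron_count(k * 0.5, 0.5)$n_float, k, tolerance = 1e-12)
  }
  # half-integer rounds away from zero
  expect_identical(electron_count(0.75, 0.5)$n_int, 2L)
  expect_error(electron_count(-1, 0.5), "positive")
  expect_error(electron_count(0.5, 1.2), "\\(0, 1\\)")
})

test_that("end-to-end mechanism report reproduces a noiseless study exactly", {
  cfg <- synthetic_config(noise = c(0, 0))
  rep <- analyze_mechanism_study(generate_mechanism_study(cfg))
  expect_equal(rep$fits$ph$slope, 0.0567, tolerance = 1e-12)
  expect_equal(rep$fits$loglog$slope, 0.7677, tolerance = 1e-12)
  expect_equal(rep$fits$ep_logv$slope, 0.1016, tolerance = 1e-12)
  expect_identical(rep$control_regime, "mixed")
  expect_true(rep$proton_coupled)
  expect_equal(rep$alpha, 0.53, tolerance = 1e-12)
  expect_identical(rep$n_electrons_int, 1L)
  expect_equal(rep$n_electrons, rep$alpha_n / rep$alpha, tolerance = 0)
})

test_that("a pure-diffusion study classifies as diffusion controlled", {
  cfg <- synthetic_config(ip_loglog = c(0.5, 1.5706), noise = c(0, 0))
  rep <- analyze_mechanism_study(generate_mechanism_study(cfg))
  expect_identical(rep$control_regime, "diffusion")
  expect_equal(rep$fits$loglog$slope, 0.5, tolerance = 1e-9)
})

test_that("seeded noisy studies still conclude a one-electron oxidation", {
  cfg <- synthetic_config()
  for (s in 1:5) {
    rep <- analyze_mechanism_study(generate_mechanism_study(cfg, seed = s))
    expect_identical(rep$n_electrons_int, 1L)
    expect_identical(rep$control_regime, "mixed")
  }
})
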