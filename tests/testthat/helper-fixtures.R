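# shared in-code fixtures and independent oracles

# a plain (untruncated) Gaussian peak trace on the usual CV window
gaussian_trace <- function(center = 0.736, amplitude = 2, width = 0.05,
                           bg_intercept = 0, bg_slope = 0,
                           from = 0.3, to = 1.3, step = 0.002) {
  e <- seq(from, to, by = step)
  i <- amplitude * exp(-(e - center)^2 / (2 * width^2)) +
    bg_intercept + bg_slope * e
  voltammogram(e, i, technique = "CV", scan_rate = 0.1, ph = 7)
}

# brute-force two-pass OLS oracle, independent of fit_linear's lm route
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

table1_path <- function() {
  system.file("extdata", "table1_energies.csv", package = "voltmip")
}

# printed binding-energy column of the packaged DFT table
table1_expected <- c(MBT = -0.00708, ETOP = -0.011916, Py = -0.012061,
                     "H-A" = -0.005138, OPD = -0.004755, IPA = -0.010974,
                     A = -0.008635, OAP = -0.010432)
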