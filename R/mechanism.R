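#' Peak-potential dependence on pH
#'
#' Regresses the anodic peak potential on the pH of the medium. A slope whose
#' magnitude reaches `threshold_mv_per_ph` (default 20 mV per pH unit) flags
#' the electrode reaction as proton-coupled; a Nernstian one-proton,
#' one-electron process gives about 59 mV/pH at 25 degC, so the permissive
#' default flags any meaningful pH dependence.
#'
#' @param ph numeric vector of pH values (at least 3 distinct).
#' @param ep peak potentials in volts, either a numeric vector or a list of
#'   [detect_peak()] results.
#' @param threshold_mv_per_ph proton-coupling decision threshold, mV/pH.
#' @return list with `fit` (a `regression_fit` of Ep on pH, slope in V/pH)
#'   and `proton_coupled` (logical).
#' @examples
#' ph <- 3:9
#' ph_dependence(ph, 0.736 + 0.0567 * (ph - 7))
#' @export
ph_dependence <- function(ph, ep, threshold_mv_per_ph = 20) {
  if (is.list(ep)) ep <- peak_field(ep, "ep")
  if (length(unique(ph)) < 3L) stop("need at least 3 distinct pH values")
  fit <- fit_linear(ph, ep, x_label = "pH", y_label = "Ep")
  list(fit = fit,
       proton_coupled = abs(fit$slope) * 1000 >= threshold_mv_per_ph)
}

#' Scan-rate dependence of the anodic peak
#'
#' Runs the two scan-rate regressions that drive the mechanistic inference,
#' plus one auxiliary diagnostic:
#' \describe{
#'   \item{`loglog`}{log10(Ip) on log10(v) — the power-law exponent that
#'     classifies the current as diffusion- (0.5) or adsorption- (1.0)
#'     controlled.}
#'   \item{`ep_logv`}{Ep (untransformed, volts) on log10(v) — the slope that
#'     enters the Laviron relation for an irreversible electrode reaction.}
#'   \item{`ip_sqrtv`}{Ip on sqrt(v) — the classical diffusion-control
#'     linearity check, reported as a diagnostic only.}
#' }
#' Scan rates are taken in V/s; the unit choice shifts intercepts only,
#' never slopes.
#'
#' @param scan_rate numeric vector of scan rates in V/s, all positive, at
#'   least 3 distinct.
#' @param peaks list of [detect_peak()] results, or `NULL` if `ip` and `ep`
#'   are given directly.
#' @param ip,ep numeric vectors of peak currents (uA, all positive) and peak
#'   potentials (V); ignored when `peaks` is supplied.
#' @return list of three `regression_fit` objects: `loglog`, `ep_logv`,
#'   `ip_sqrtv`.
#' @examples
#' v <- c(0.05, 0.1, 0.2, 0.5, 1)
#' scan_rate_analysis(v, ip = 10^(1.57 + 0.7677 * log10(v)),
#'                    ep = 0.736 + 0.1016 * log10(v / 0.1))
#' @export
scan_rate_analysis <- function(scan_rate, peaks = NULL, ip = NULL, ep = NULL) {
  if (!is.null(peaks)) {
    ip <- peak_field(peaks, "ip")
    ep <- peak_field(peaks, "ep")
  }
  if (is.null(ip) || is.null(ep)) stop("supply `peaks` or both `ip` and `ep`")
  if (length(unique(scan_rate)) < 3L) stop("need at least 3 distinct scan rates")
  if (any(scan_rate <= 0)) stop("all scan rates must be positive")
  if (any(ip <= 0)) stop("all peak currents must be positive")
  list(
    loglog = fit_linear(log10(scan_rate), log10(ip),
                        x_label = "log10 v", y_label = "log10 Ip"),
    ep_logv = fit_linear(log10(scan_rate), ep,
                         x_label = "log10 v", y_label = "Ep"),
    ip_sqrtv = fit_linear(sqrt(scan_rate), ip,
                          x_label = "sqrt v", y_label = "Ip")
  )
}

#' Classify the electrode control regime from the log-log slope
#'
#' The slope of log10(Ip) vs log10(scan rate) is 0.5 for a purely
#' diffusion-controlled current and 1.0 for a surface-adsorbed reactant;
#' intermediate slopes indicate mixed control. Slopes within `tol` of an
#' anchor are assigned to the pure regime (boundaries inclusive toward the
#' pure regimes).
#'
#' @param loglog_slope finite numeric slope.
#' @param tol tolerance band around the 0.5 and 1.0 anchors; default 0.05.
#' @return `"diffusion"`, `"mixed"` or `"adsorption"`.
#' @examples
#' classify_control(0.7677)
#' @export
classify_control <- function(loglog_slope, tol = 0.05) {
  if (!is.numeric(loglog_slope) || length(loglog_slope) != 1L ||
      !is.finite(loglog_slope)) {
    stop("`loglog_slope` must be a single finite number")
  }
  if (loglog_slope <= 0.5 + tol) "diffusion"
  else if (loglog_slope >= 1.0 - tol) "adsorption"
  else "mixed"
}

#' Transfer-coefficient product from the Laviron slope
#'
#' For an irreversible electrode reaction, the peak potential is linear in
#' log10 of the scan rate with slope 2.303 R T / (alpha n F); inverting gives
#' the transfer-coefficient times electron-number product
#' `alpha_n = 2.303 R T / (F * slope)`.
#'
#' @param ep_logv_slope slope of Ep vs log10(scan rate), volts per decade,
#'   strictly positive.
#' @param constants a [voltammetry_constants()] list.
#' @return the dimensionless product alpha * n.
#' @examples
#' laviron_alpha_n(0.1016)  # ~0.582 at 298 K
#' @export
laviron_alpha_n <- function(ep_logv_slope, constants = voltammetry_constants()) {
  check_constants(constants)
  if (!is.numeric(ep_logv_slope) || length(ep_logv_slope) != 1L ||
      !is.finite(ep_logv_slope) || ep_logv_slope <= 0) {
    stop("`ep_logv_slope` must be a single positive number (V/decade)")
  }
  2.303 * constants$R * constants$T / (constants$F * ep_logv_slope)
}

#' Transfer coefficient from the half-peak width
#'
#' For an irreversible wave at 25 degC, the transfer coefficient follows
#' `alpha = 47.7 mV / (Ep - Ep1/2)`, with the peak-to-half-peak separation
#' expressed in millivolts.
#'
#' @param ep,ep_half peak and half-peak potentials in volts; `ep > ep_half`.
#' @param constants a [voltammetry_constants()] list (supplies the 47.7 mV
#'   numerator).
#' @return the dimensionless transfer coefficient alpha.
#' @examples
#' bard_faulkner_alpha(0.736, 0.646)  # 90 mV separation -> 0.53
#' @export
bard_faulkner_alpha <- function(ep, ep_half, constants = voltammetry_constants()) {
  check_constants(constants)
  if (!is.numeric(ep) || !is.numeric(ep_half) ||
      length(ep) != 1L || length(ep_half) != 1L) {
    stop("`ep` and `ep_half` must be single numbers (volts)")
  }
  if (ep <= ep_half) stop("`ep` must exceed `ep_half` for an anodic peak")
  constants$bard_faulkner_mv / (1000 * (ep - ep_half))
}

#' Number of electrons transferred
#'
#' Divides the transfer-coefficient product alpha*n by the transfer
#' coefficient alpha to estimate the electron count, and rounds to the
#' nearest integer (ties away from zero).
#'
#' @param alpha_n transfer-coefficient product, positive.
#' @param alpha transfer coefficient in (0, 1).
#' @return list with `n_float` (= `alpha_n / alpha`) and `n_int`.
#' @examples
#' electron_count(0.57, 0.53)  # ~1.07 -> 1 electron
#' @export
electron_count <- function(alpha_n, alpha) {
  if (!is.numeric(alpha_n) || length(alpha_n) != 1L || !is.finite(alpha_n) ||
      alpha_n <= 0) {
    stop("`alpha_n` must be a single positive number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly in (0, 1)")
  }
  n_float <- alpha_n / alpha
  list(n_float = n_float,
       n_int = as.integer(sign(n_float) * floor(abs(n_float) + 0.5)))
}

#' Full electron-transfer mechanism inference
#'
#' Composes the whole mechanistic chain from a pH series and a scan-rate
#' series of extracted peaks: the Ep-vs-pH regression (proton coupling), the
#' two scan-rate regressions, the control-regime classification from the
#' log-log exponent, the Laviron transfer-coefficient product from the
#' Ep-vs-log10(v) slope, the half-peak-width transfer coefficient from the
#' peak measured nearest the reference scan rate, and the resulting electron
#' count.
#'
#' @param ph numeric vector of pH values of the pH series.
#' @param ph_peaks list of [detect_peak()] results matching `ph`.
#' @param scan_rate numeric vector of scan rates (V/s) of the scan-rate
#'   series.
#' @param scan_peaks list of [detect_peak()] results matching `scan_rate`.
#' @param constants a [voltammetry_constants()] list.
#' @param reference_scan_rate the scan rate (V/s) whose peak supplies the
#'   half-peak width for the transfer coefficient; the series member closest
#'   to it is used. Default 0.1 V/s, the usual working condition.
#' @param tol classification tolerance passed to [classify_control()].
#' @return An object of class `mechanism_report`: `alpha_n`, `alpha`,
#'   `n_electrons` (float), `n_electrons_int`, `control_regime`,
#'   `proton_coupled`, `reference_scan_rate`, and `fits` (the
#'   `ph`, `loglog`, `ep_logv` and `ip_sqrtv` regression fits).
#' @export
mechanism_report <- function(ph, ph_peaks, scan_rate, scan_peaks,
                             constants = voltammetry_constants(),
                             reference_scan_rate = 0.1, tol = 0.05) {
  phdep <- ph_dependence(ph, ph_peaks)
  sra <- scan_rate_analysis(scan_rate, peaks = scan_peaks)
  alpha_n <- laviron_alpha_n(sra$ep_logv$slope, constants)

  iref <- which.min(abs(scan_rate - reference_scan_rate))
  ref_peak <- scan_peaks[[iref]]
  alpha <- bard_faulkner_alpha(ref_peak$ep, ref_peak$ep_half, constants)
  ne <- electron_count(alpha_n, alpha)

  structure(
    list(alpha_n = alpha_n, alpha = alpha,
         n_electrons = ne$n_float, n_electrons_int = ne$n_int,
         control_regime = classify_control(sra$loglog$slope, tol = tol),
         proton_coupled = phdep$proton_coupled,
         reference_scan_rate = scan_rate[iref],
         fits = list(ph = phdep$fit, loglog = sra$loglog,
                     ep_logv = sra$ep_logv, ip_sqrtv = sra$ip_sqrtv)),
    class = "mechanism_report"
  )
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("Electron-transfer mechanism report\n")
  cat(sprintf("  Ep vs pH slope:        %.4g V/pH (proton-coupled: %s)\n",
              x$fits$ph$slope, x$proton_coupled))
  cat(sprintf("  log Ip vs log v slope: %.4g  -> %s control\n",
              x$fits$loglog$slope, x$control_regime))
  cat(sprintf("  Ep vs log v slope:     %.4g V/decade\n", x$fits$ep_logv$slope))
  cat(sprintf("  alpha*n = %.3f, alpha = %.3f (at %g V/s), n = %.3f ~ %d\n",
              x$alpha_n, x$alpha, x$reference_scan_rate,
              x$n_electrons, x$n_electrons_int))
  invisible(x)
}
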