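#' Configuration for the synthetic voltammogram generator
#'
#' The generator emulates the empirical behaviour of an anodic,
#' proton-coupled, irreversible oxidation on a MIP-modified electrode:
#' peak potential linear in pH and in log10 of the scan rate, peak current
#' following a power law of the scan rate and proportional to analyte
#' concentration, a fixed rising-flank half-peak width, an additive linear
#' background, multiplicative matrix effects on recovery, additive
#' interferent perturbations, and a linear inter-method relation against a
#' reference technique. The two empirical laws for the peak position are
#' composed additively around a reference condition (`ph_ref`,
#' `scan_rate_ref`, `ep_ref`).
#'
#' The peak shape is a truncated asymmetric Gaussian: each flank is a
#' Gaussian rescaled to vanish exactly at `cutoff_sigmas` standard
#' deviations, so the peak has compact support and the pre-peak baseline
#' region is exactly background. The rising-flank width parameter is solved
#' so that the half-height crossing sits exactly `half_width_mv` below the
#' peak center, which pins the half-peak-width transfer coefficient at
#' `47.7 / half_width_mv`.
#'
#' When `calibration_sensitivity` is supplied it overrides the sensitivity
#' implied by `ip_loglog` and `conc_ref`, and the log-log intercept is
#' recomputed to stay consistent.
#'
#' @param ph_slope peak-potential shift per pH unit, V/pH. Default 0.0567.
#' @param ep_logv_slope peak-potential shift per decade of scan rate,
#'   V/decade. Default 0.1016.
#' @param ip_loglog c(exponent, intercept) of log10(Ip/uA) vs log10(v / (V/s))
#'   at the reference concentration. Default c(0.7677, 1.5706).
#' @param ep_ref peak potential (V) at the reference condition.
#'   Default 0.736 V at pH 7 and 0.1 V/s.
#' @param ph_ref,scan_rate_ref,conc_ref reference pH, scan rate (V/s) and
#'   concentration (uM). Defaults 7, 0.1, 50.
#' @param half_width_mv rising-flank half-peak width Ep - Ep1/2 in mV;
#'   default 90 (transfer coefficient 0.53).
#' @param falling_width_factor falling-flank width as a fraction of the
#'   rising-flank width (asymmetric anodic peak). Default 0.6.
#' @param cutoff_sigmas compact-support cutoff per flank, in flank standard
#'   deviations. Default 4.
#' @param calibration_sensitivity sensitivity S in uA/uM at the reference
#'   scan rate, or `NULL` to derive it from `ip_loglog` and `conc_ref`.
#' @param background c(intercept_uA, slope_uA_per_V) of the additive linear
#'   background. Default c(0.5, 0.1).
#' @param matrix_effect named multiplicative recovery factors per sample
#'   matrix. Default c(plasma = 0.95, urine = 0.96).
#' @param interference named interferent response coefficients, uA per uM of
#'   interferent (signed). Defaults fitted to reproduce the printed
#'   interference magnitudes of the chlorferron MIP study; synthetic values,
#'   not instrument constants.
#' @param interference_reference_uA analyte-only peak current of the
#'   interference study, uA. Default 0.2311 (back-derived, see
#'   [derive_interference_reference()]).
#' @param comparison c(slope, intercept) of the reference-method relation
#'   `ref = slope * sensor + intercept`. Default c(0.9972, 1.6067).
#' @param noise c(sigma_e, sigma_i): potential jitter of the peak center (V)
#'   and band-limited additive current noise level (uA) at the reference
#'   signal scale. The realized noise level scales with the signal
#'   amplitude of each measurement (instrument auto-ranging), floored at a
#'   tenth of the reference range. Default c(0.002, 0.02); set both to 0
#'   for noiseless ground-truth data.
#' @param grid_step potential grid step, V. Default 0.002. For exact
#'   noiseless closure `half_width_mv / 1000` should be a multiple of it.
#' @param window c(pre, post): sweep extent below and above the peak center,
#'   V. Default c(0.5, 0.3) (a 0.8 V sweep, e.g. 0.236-1.036 V at the
#'   reference condition).
#' @param baseline_frac fraction of the sweep used as the default pre-peak
#'   baseline window. Default 0.2.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(ph_slope = 0.0567,
                             ep_logv_slope = 0.1016,
                             ip_loglog = c(0.7677, 1.5706),
                             ep_ref = 0.736,
                             ph_ref = 7,
                             scan_rate_ref = 0.1,
                             conc_ref = 50,
                             half_width_mv = 90,
                             falling_width_factor = 0.6,
                             cutoff_sigmas = 4,
                             calibration_sensitivity = NULL,
                             background = c(0.5, 0.1),
                             matrix_effect = c(plasma = 0.95, urine = 0.96),
                             interference = c("4-MU" = 3.7e-4,
                                              "CMP" = -2.5e-4,
                                              "DSX" = -3.9e-4,
                                              "PPX" = -2.4e-4),
                             interference_reference_uA = 0.2311,
                             comparison = c(0.9972, 1.6067),
                             noise = c(sigma_e = 0.002, sigma_i = 0.02),
                             grid_step = 0.002,
                             window = c(pre = 0.5, post = 0.3),
                             baseline_frac = 0.2) {
  exponent <- ip_loglog[1L]
  intercept <- ip_loglog[2L]
  if (is.null(calibration_sensitivity)) {
    # Ip(v_ref, conc_ref) from the power law, spread over conc_ref
    calibration_sensitivity <-
      10^(intercept + exponent * log10(scan_rate_ref)) / conc_ref
  } else {
    intercept <- log10(calibration_sensitivity * conc_ref) -
      exponent * log10(scan_rate_ref)
  }
  cfg <- list(
    ph_slope = ph_slope, ep_logv_slope = ep_logv_slope,
    ip_exponent = exponent, ip_intercept = intercept,
    ep_ref = ep_ref, ph_ref = ph_ref, scan_rate_ref = scan_rate_ref,
    conc_ref = conc_ref, half_width_mv = half_width_mv,
    falling_width_factor = falling_width_factor,
    cutoff_sigmas = cutoff_sigmas,
    calibration_sensitivity = calibration_sensitivity,
    background = unname(background),
    matrix_effect = matrix_effect,
    interference = interference,
    interference_reference_uA = interference_reference_uA,
    comparison = unname(comparison),
    noise = c(sigma_e = unname(noise[1L]), sigma_i = unname(noise[2L])),
    grid_step = grid_step,
    window = c(pre = unname(window[1L]), post = unname(window[2L])),
    baseline_frac = baseline_frac
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  num_fields <- c("ph_slope", "ep_logv_slope", "ip_exponent", "ip_intercept",
                  "ep_ref", "ph_ref", "scan_rate_ref", "conc_ref",
                  "half_width_mv", "falling_width_factor", "cutoff_sigmas",
                  "calibration_sensitivity", "grid_step", "baseline_frac")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("invalid config: `", f, "` must be a single finite number")
    }
  }
  if (cfg$scan_rate_ref <= 0 || cfg$conc_ref <= 0 || cfg$grid_step <= 0 ||
      cfg$half_width_mv <= 0 || cfg$falling_width_factor <= 0 ||
      cfg$cutoff_sigmas <= 1 || cfg$calibration_sensitivity <= 0) {
    stop("invalid config: scale parameters must be strictly positive")
  }
  if (any(cfg$noise < 0)) stop("invalid config: noise sigmas must be >= 0")
  if (any(cfg$window <= 0)) stop("invalid config: window extents must be > 0")
  if (cfg$baseline_frac <= 0 || cfg$baseline_frac >= 1) {
    stop("invalid config: `baseline_frac` must lie in (0, 1)")
  }
  hw <- cfg$half_width_mv / 1000
  sig <- peak_sigmas(cfg)
  if (cfg$cutoff_sigmas * sig$rising + cfg$baseline_frac *
        sum(cfg$window) > cfg$window[["pre"]]) {
    stop("invalid config: rising flank reaches into the baseline window; ",
         "widen `window[\"pre\"]` or narrow the peak")
  }
  if (cfg$cutoff_sigmas * sig$falling >= cfg$window[["post"]]) {
    stop("invalid config: falling flank reaches the sweep end")
  }
  if (hw >= cfg$cutoff_sigmas * sig$rising) {
    stop("invalid config: half width outside the truncated flank")
  }
  invisible(cfg)
}

# flank standard deviations of the truncated Gaussian peak shape.
# Each flank is (exp(-d^2/(2 s^2)) - eps) / (1 - eps) with eps the Gaussian
# value at the cutoff, so the shape is exactly 0 beyond cutoff_sigmas * s.
# The rising s is solved so the half-height crossing is exactly at the
# configured half width: g(hw) = 1/2  <=>  exp(-hw^2/(2 s^2)) = (1 + eps)/2.
peak_sigmas <- function(cfg) {
  eps <- exp(-cfg$cutoff_sigmas^2 / 2)
  hw <- cfg$half_width_mv / 1000
  s_rise <- hw / sqrt(2 * log(2 / (1 + eps)))
  list(rising = s_rise, falling = cfg$falling_width_factor * s_rise, eps = eps)
}

peak_shape <- function(d, sigma, eps, cutoff_sigmas) {
  # d: distance from the center, >= 0 on the given flank
  out <- numeric(length(d))
  inside <- d < cutoff_sigmas * sigma
  out[inside] <- (exp(-d[inside]^2 / (2 * sigma^2)) - eps) / (1 - eps)
  out
}

# law for the peak center, composing pH and scan-rate dependence around the
# reference condition
ep_law <- function(cfg, ph, scan_rate) {
  cfg$ep_ref + cfg$ph_slope * (ph - cfg$ph_ref) +
    cfg$ep_logv_slope * (log10(scan_rate) - log10(cfg$scan_rate_ref))
}

# law for the peak current: power law in scan rate, linear in concentration
ip_law <- function(cfg, scan_rate, conc) {
  cfg$calibration_sensitivity * conc *
    (scan_rate / cfg$scan_rate_ref)^cfg$ip_exponent
}

# derive a per-trace RNG stream seed from the root seed and an offset,
# kept inside 32-bit integer range
stream_seed <- function(seed, seed_offset) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * (as.double(seed_offset) %% 100000)) %%
               2147483647)
}

# instrument current-noise level for a measurement whose signal scale is
# `signal` microamperes: the configured sigma_i applies at the reference
# signal scale and scales with the selected current range (auto-ranging),
# floored at a tenth of the reference range for near-blank signals
noise_level <- function(sigma_i, signal, reference_signal) {
  sigma_i * max(abs(signal) / reference_signal, 0.1)
}

# band-limited instrument noise: white noise on knots every `corr_pts`
# samples, cubic-spline interpolated to the full grid. Models the heavily
# low-pass-filtered current channel of a pulse-voltammetry acquisition;
# white noise at the raw grid scale would be unphysical for ~0.4 s steps.
smooth_noise <- function(n, sigma, corr_pts = 25L) {
  knots <- seq.int(-corr_pts, n + 2L * corr_pts, by = corr_pts)
  z <- stats::rnorm(length(knots), 0, sigma)
  stats::spline(knots, z, xout = seq_len(n))$y
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic voltammogram with ground truth
#'
#' Builds a single anodic sweep under the configured empirical laws: the
#' peak center follows the pH and scan-rate laws (plus a seeded Gaussian
#' potential jitter `sigma_e`), the amplitude follows the scan-rate power
#' law scaled linearly by concentration, the shape is the truncated
#' asymmetric Gaussian described in [synthetic_config()], a linear
#' background is added, and band-limited Gaussian current noise of level
#' `sigma_i` (correlation length about 25 grid steps, emulating the
#' low-pass-filtered current channel) is applied. The potential grid runs through the (jittered) peak center,
#' `window["pre"]` volts below to `window["post"]` volts above, in
#' `grid_step` steps.
#'
#' Output is fully determined by `(seed, seed_offset)`; with both noise
#' sigmas zero no random numbers are drawn at all.
#'
#' @param config a [synthetic_config()].
#' @param ph medium pH.
#' @param scan_rate scan rate, V/s, positive.
#' @param conc analyte concentration, uM, non-negative.
#' @param seed root seed (integer); ignored when the config is noiseless.
#' @param seed_offset per-trace stream offset decorrelating traces that
#'   share a root seed.
#' @param technique stored technique tag.
#' @return list with `voltammogram` and `ground_truth` (true `ep`, `ip`,
#'   `ep_half`, `alpha`, the law value `ep_law` before jitter, the
#'   background coefficients, and the peak-free `baseline_window`).
#' @examples
#' cfg <- synthetic_config(noise = c(0, 0))
#' out <- generate_voltammogram(cfg, ph = 7, scan_rate = 0.1, conc = 50)
#' detect_peak(out$voltammogram)$ep == out$ground_truth$ep
#' @export
generate_voltammogram <- function(config, ph, scan_rate, conc,
                                  seed = 1L, seed_offset = 0L,
                                  technique = "CV") {
  stopifnot(inherits(config, "synthetic_config"))
  if (scan_rate <= 0) stop("`scan_rate` must be positive")
  if (conc < 0) stop("`conc` must be non-negative")
  sig <- peak_sigmas(config)
  noisy <- any(config$noise > 0)

  ep_true_law <- ep_law(config, ph, scan_rate)
  ip_true <- ip_law(config, scan_rate, conc)

  jitter <- 0
  cur_noise <- NULL
  npre <- round(config$window[["pre"]] / config$grid_step)
  npost <- round(config$window[["post"]] / config$grid_step)
  npts <- npre + npost + 1L
  if (noisy) {
    sigma_trace <- noise_level(config$noise[["sigma_i"]], ip_true,
                               config$calibration_sensitivity * config$conc_ref)
    out <- with_seed(stream_seed(seed, seed_offset), {
      list(jitter = stats::rnorm(1, 0, config$noise[["sigma_e"]]),
           cur = smooth_noise(npts, sigma_trace))
    })
    jitter <- out$jitter
    cur_noise <- out$cur
  }
  center <- ep_true_law + jitter

  pot <- center + seq.int(-npre, npost) * config$grid_step
  d <- pot - center
  shape <- numeric(npts)
  rise <- d <= 0
  shape[rise] <- peak_shape(-d[rise], sig$rising, sig$eps, config$cutoff_sigmas)
  shape[!rise] <- peak_shape(d[!rise], sig$falling, sig$eps,
                             config$cutoff_sigmas)
  cur <- ip_true * shape + config$background[1L] + config$background[2L] * pot
  if (noisy) cur <- cur + cur_noise

  vg <- voltammogram(pot, cur, technique = technique, scan_rate = scan_rate,
                     ph = ph, concentration = conc,
                     label = sprintf("synthetic pH %g, %g V/s, %g uM",
                                     ph, scan_rate, conc))
  hw <- config$half_width_mv / 1000
  gt <- list(
    ep = center, ip = ip_true, ep_half = center - hw,
    ep_law = ep_true_law,
    alpha = 47.7 / config$half_width_mv,
    background = config$background,
    baseline_window = c(pot[1L], center - config$cutoff_sigmas * sig$rising)
  )
  list(voltammogram = vg, ground_truth = gt)
}

#' Generate a mechanism study (pH series + scan-rate series)
#'
#' Produces the two trace bundles the mechanistic analysis consumes: a pH
#' series (pH 3 to 9 in unit steps, fixed reference scan rate) and a
#' scan-rate series (log-spaced over 0.05 to 1.0 V/s, fixed reference pH),
#' both at the reference concentration, with per-trace ground truth
#' attached.
#'
#' @param config a [synthetic_config()].
#' @param seed root seed for the noise streams.
#' @param ph_grid pH values of the pH series; default `3:9`.
#' @param scan_grid scan rates of the scan-rate series, V/s; default 7
#'   log-spaced points over 0.05-1.0.
#' @return An object of class `mechanism_study`: `ph_series` and
#'   `scan_series`, each a list of `values`, `voltammograms` and
#'   `ground_truth` (data.frame of true `ep`, `ip`, `ep_half` per trace),
#'   plus `config`, `seed` and `truth` (the law parameters: `ph_slope`,
#'   `ip_exponent`, `ep_logv_slope`, `alpha`, `alpha_n`, `n_electrons`).
#' @export
generate_mechanism_study <- function(config = synthetic_config(), seed = 1L,
                                     ph_grid = 3:9,
                                     scan_grid = 10^seq(log10(0.05), 0,
                                                        length.out = 7)) {
  stopifnot(inherits(config, "synthetic_config"))
  gen_series <- function(values, vary, offset0) {
    traces <- vector("list", length(values))
    gts <- vector("list", length(values))
    for (k in seq_along(values)) {
      ph <- if (vary == "ph") values[k] else config$ph_ref
      v <- if (vary == "scan_rate") values[k] else config$scan_rate_ref
      out <- generate_voltammogram(config, ph = ph, scan_rate = v,
                                   conc = config$conc_ref, seed = seed,
                                   seed_offset = offset0 + k)
      traces[[k]] <- out$voltammogram
      gts[[k]] <- data.frame(value = values[k], ep = out$ground_truth$ep,
                             ip = out$ground_truth$ip,
                             ep_half = out$ground_truth$ep_half)
    }
    list(values = values, voltammograms = traces,
         ground_truth = do.call(rbind, gts))
  }
  constants <- voltammetry_constants()
  alpha <- 47.7 / config$half_width_mv
  alpha_n <- laviron_alpha_n(config$ep_logv_slope, constants)
  structure(
    list(ph_series = gen_series(ph_grid, "ph", 0L),
         scan_series = gen_series(scan_grid, "scan_rate", 100L),
         config = config, seed = seed,
         truth = list(ph_slope = config$ph_slope,
                      ip_exponent = config$ip_exponent,
                      ep_logv_slope = config$ep_logv_slope,
                      alpha = alpha, alpha_n = alpha_n,
                      n_electrons = alpha_n / alpha)),
    class = "mechanism_study"
  )
}

#' Analyze a mechanism study end to end
#'
#' Runs [detect_peak()] on every trace of a [generate_mechanism_study()]
#' bundle (or an equivalent structure assembled from files) and assembles
#' the [mechanism_report()].
#'
#' @param study a `mechanism_study`.
#' @param constants a [voltammetry_constants()] list.
#' @param ... passed to [mechanism_report()].
#' @return A `mechanism_report`.
#' @export
analyze_mechanism_study <- function(study, constants = voltammetry_constants(),
                                    ...) {
  stopifnot(inherits(study, "mechanism_study"))
  ph_peaks <- lapply(study$ph_series$voltammograms, detect_peak)
  scan_peaks <- lapply(study$scan_series$voltammograms, detect_peak)
  mechanism_report(study$ph_series$values, ph_peaks,
                   study$scan_series$values, scan_peaks,
                   constants = constants,
                   reference_scan_rate = study$config$scan_rate_ref, ...)
}

#' Generate a validation study (calibration, recovery, interference,
#' comparison)
#'
#' Emits the four tables the validation analysis consumes, with ground truth
#' attached:
#' \describe{
#'   \item{calibration}{`n_replicates` currents per level at the seven-level
#'     design 2, 10, 25, 40, 55, 70, 75 uM; current = sensitivity * conc
#'     plus Gaussian `sigma_i` noise.}
#'   \item{recovery}{`n_replicates` measured concentrations per spike (25
#'     and 40 uM) per matrix; measured = spike * matrix_effect plus
#'     `sigma_i / sensitivity` concentration noise (the current noise
#'     propagated through the calibration slope).}
#'   \item{interference}{the 10/50/100 uM interferent design against the
#'     fixed analyte reference current, deterministic by construction:
#'     current = reference + coefficient * conc, plus an analyte-only
#'     `"none"` row.}
#'   \item{comparison}{sensor levels 25, 40, 55, 70, 85 uM mapped through
#'     the configured reference-method relation, deterministic.}
#' }
#'
#' @param config a [synthetic_config()].
#' @param seed root seed.
#' @param calibration_levels concentration levels, uM.
#' @param spike_levels spiked concentrations for recovery, uM.
#' @param comparison_levels sensor concentrations for the method
#'   comparison, uM.
#' @param n_replicates replicates per calibration level and per spike.
#' @return An object of class `validation_study`: data.frames
#'   `calibration` (`level_uM`, `replicate`, `current_uA`), `recovery`
#'   (`matrix`, `spiked_uM`, `measured_uM`), `interference` (`interferent`,
#'   `conc_uM`, `current_uA`), `comparison` (`sample`, `test_uM`, `ref_uM`),
#'   plus `config`, `seed` and `truth`.
#' @export
generate_validation_study <- function(config = synthetic_config(), seed = 1L,
                                      calibration_levels = c(2, 10, 25, 40,
                                                             55, 70, 75),
                                      spike_levels = c(25, 40),
                                      comparison_levels = c(25, 40, 55, 70, 85),
                                      n_replicates = 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  S <- config$calibration_sensitivity
  sigma_i <- config$noise[["sigma_i"]]
  noisy <- sigma_i > 0

  # calibration replicates
  levels_rep <- rep(calibration_levels, each = n_replicates)
  cal_sd <- vapply(levels_rep, function(l) {
    noise_level(sigma_i, S * l, S * config$conc_ref)
  }, numeric(1))
  cal_noise <- if (noisy) {
    with_seed(stream_seed(seed, 201L),
              stats::rnorm(length(levels_rep), 0, cal_sd))
  } else 0
  calibration <- data.frame(
    level_uM = levels_rep,
    replicate = rep(seq_len(n_replicates), times = length(calibration_levels)),
    current_uA = S * levels_rep + cal_noise
  )

  # spike recovery per matrix; current noise propagated to concentration
  matrices <- names(config$matrix_effect)
  rec_rows <- expand.grid(matrix = matrices, spiked_uM = spike_levels,
                          replicate = seq_len(n_replicates),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec_rows <- rec_rows[order(rec_rows$matrix, rec_rows$spiked_uM,
                             rec_rows$replicate), ]
  rec_sd <- vapply(seq_len(nrow(rec_rows)), function(k) {
    true_i <- S * rec_rows$spiked_uM[k] *
      unname(config$matrix_effect[rec_rows$matrix[k]])
    noise_level(sigma_i, true_i, S * config$conc_ref) / S
  }, numeric(1))
  rec_noise <- if (noisy) {
    with_seed(stream_seed(seed, 202L),
              stats::rnorm(nrow(rec_rows), 0, rec_sd))
  } else 0
  recovery <- data.frame(
    matrix = rec_rows$matrix,
    spiked_uM = rec_rows$spiked_uM,
    measured_uM = rec_rows$spiked_uM *
      unname(config$matrix_effect[rec_rows$matrix]) + rec_noise
  )

  # interference design: deterministic, coefficients are per-uM responses
  interferents <- names(config$interference)
  int_rows <- expand.grid(interferent = interferents,
                          conc_uM = c(10, 50, 100),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  int_rows <- int_rows[order(match(int_rows$interferent, interferents),
                             int_rows$conc_uM), ]
  ref_i <- config$interference_reference_uA
  interference <- rbind(
    data.frame(interferent = "none", conc_uM = 0, current_uA = ref_i),
    data.frame(interferent = int_rows$interferent,
               conc_uM = int_rows$conc_uM,
               current_uA = ref_i +
                 unname(config$interference[int_rows$interferent]) *
                 int_rows$conc_uM)
  )
  row.names(interference) <- NULL

  # method comparison: configured linear relation, deterministic
  comparison <- data.frame(
    sample = paste0("S", seq_along(comparison_levels)),
    test_uM = comparison_levels,
    ref_uM = config$comparison[1L] * comparison_levels + config$comparison[2L]
  )

  structure(
    list(calibration = calibration, recovery = recovery,
         interference = interference, comparison = comparison,
         config = config, seed = seed,
         truth = list(sensitivity = S,
                      matrix_effect = config$matrix_effect,
                      interference_reference_uA = ref_i,
                      interference_coefficients = config$interference,
                      comparison_slope = config$comparison[1L],
                      comparison_intercept = config$comparison[2L],
                      sigma_i = sigma_i)),
    class = "validation_study"
  )
}

#' Analyze a validation study end to end
#'
#' Runs the full validation battery on a [generate_validation_study()]
#' bundle: calibration fit with detection limits, per-level precision,
#' per-matrix-and-spike recovery, interference percent changes against the
#' analyte-only row, and the reference-method comparison.
#'
#' @param study a `validation_study`.
#' @param blank_sd optional blank standard deviation for the calibration
#'   (uA); defaults to the fit residuals.
#' @return list with `calibration` (a `calibration_model`), `precision`,
#'   `recovery` (data.frame `matrix`, `spiked_uM`, `mean_uM`,
#'   `recovery_pct`, `rsd_pct`, `n`), `interference` (see
#'   [interference_table()]), `max_interference_pct`, and `comparison` (a
#'   `method_comparison`).
#' @export
analyze_validation_study <- function(study, blank_sd = NULL) {
  stopifnot(inherits(study, "validation_study"))
  cal <- fit_calibration(study$calibration$level_uM,
                         study$calibration$current_uA, blank_sd = blank_sd)
  prec <- precision(study$calibration$level_uM, study$calibration$current_uA,
                    mode = "intra_day")
  groups <- split(study$recovery,
                  list(study$recovery$matrix, study$recovery$spiked_uM),
                  drop = TRUE)
  rec <- do.call(rbind, lapply(groups, function(g) {
    r <- recovery(g$measured_uM, g$spiked_uM[1L])
    data.frame(matrix = g$matrix[1L], spiked_uM = r$spiked,
               mean_uM = r$mean_measured, recovery_pct = r$recovery_pct,
               rsd_pct = r$rsd_pct, n = r$n_replicates,
               stringsAsFactors = FALSE)
  }))
  rec <- rec[order(rec$matrix, rec$spiked_uM), ]
  row.names(rec) <- NULL
  intf <- interference_table(study$interference)
  cmp <- compare_methods(study$comparison$test_uM, study$comparison$ref_uM)
  list(calibration = cal, precision = prec, recovery = rec,
       interference = intf, max_interference_pct = max(intf$pct_change),
       comparison = cmp)
}

#' Write a mechanism study to disk
#'
#' Writes every trace as a two-column CSV plus a `manifest.csv` indexing
#' them (`file`, `series`, `technique`, `scan_rate_V_s`, `ph`, `conc_uM`)
#' and a `ground_truth.json`. Output is byte-reproducible for a fixed
#' `(config, seed)`.
#'
#' @param study a `mechanism_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mechanism_study <- function(study, dir) {
  stopifnot(inherits(study, "mechanism_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  dump_series <- function(series, tag) {
    for (k in seq_along(series$values)) {
      vg <- series$voltammograms[[k]]
      fname <- sprintf("%s_%02d.csv", tag, k)
      write_voltammogram(vg, file.path(dir, fname))
      rows[[length(rows) + 1L]] <<- data.frame(
        file = fname, series = tag, technique = vg$technique,
        scan_rate_V_s = vg$scan_rate, ph = vg$ph, conc_uM = vg$concentration,
        stringsAsFactors = FALSE)
    }
  }
  dump_series(study$ph_series, "ph")
  dump_series(study$scan_series, "scan_rate")
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- list(truth = study$truth, seed = study$seed,
             ph_ground_truth = study$ph_series$ground_truth,
             scan_ground_truth = study$scan_series$ground_truth)
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", pretty = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a mechanism study written by [write_mechanism_study()]
#'
#' @param dir directory containing `manifest.csv` and the trace CSVs.
#' @param config the [synthetic_config()] the study was generated with (its
#'   reference scan rate is needed by the analysis); defaults to the
#'   package defaults.
#' @return a `mechanism_study` (without per-trace ground truth).
#' @export
read_mechanism_study <- function(dir, config = synthetic_config()) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  need <- c("file", "series", "technique", "scan_rate_V_s", "ph", "conc_uM")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  load_series <- function(tag, values_from) {
    sub <- man[man$series == tag, , drop = FALSE]
    if (nrow(sub) == 0L) stop("manifest has no '", tag, "' series")
    traces <- lapply(seq_len(nrow(sub)), function(k) {
      read_voltammogram(file.path(dir, sub$file[k]),
                        technique = sub$technique[k],
                        scan_rate = sub$scan_rate_V_s[k],
                        ph = sub$ph[k], concentration = sub$conc_uM[k])
    })
    list(values = sub[[values_from]], voltammograms = traces,
         ground_truth = NULL)
  }
  structure(
    list(ph_series = load_series("ph", "ph"),
         scan_series = load_series("scan_rate", "scan_rate_V_s"),
         config = config, seed = NA_integer_, truth = NULL),
    class = "mechanism_study"
  )
}

#' Write a validation study to disk
#'
#' Writes `calibration.csv`, `recovery.csv`, `interference.csv`,
#' `comparison.csv` in the schemas consumed by the validation functions,
#' plus `ground_truth.json`.
#'
#' @param study a `validation_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_study <- function(study, dir) {
  stopifnot(inherits(study, "validation_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wr(study$calibration, "calibration.csv")
  wr(study$recovery, "recovery.csv")
  wr(study$interference, "interference.csv")
  wr(study$comparison, "comparison.csv")
  writeLines(jsonlite::toJSON(study$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a validation study written by [write_validation_study()]
#'
#' @param dir directory containing the four CSV tables.
#' @param config a [synthetic_config()] carried along for provenance.
#' @return a `validation_study` (without ground truth).
#' @export
read_validation_study <- function(dir, config = synthetic_config()) {
  rd <- function(name, need) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing ", name, " in ", dir)
    df <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(need %in% names(df))) {
      stop("'", p, "': expected columns ", paste(need, collapse = ", "))
    }
    df
  }
  structure(
    list(calibration = rd("calibration.csv",
                          c("level_uM", "replicate", "current_uA")),
         recovery = rd("recovery.csv",
                       c("matrix", "spiked_uM", "measured_uM")),
         interference = rd("interference.csv",
                           c("interferent", "conc_uM", "current_uA")),
         comparison = rd("comparison.csv",
                         c("sample", "test_uM", "ref_uM")),
         config = config, seed = NA_integer_, truth = NULL),
    class = "validation_study"
  )
}
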