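#' Fit a calibration line with detection and quantitation limits
#'
#' Ordinary least-squares fit of peak current on analyte concentration. The
#' blank noise `sigma_blank` is the supplied standard deviation of blank
#' replicates when available, otherwise the residual standard deviation of
#' the fit (the source is recorded in the result). Detection limits follow
#' the 3.3/10 convention: `lod = 3.3 * sigma_blank / slope`,
#' `loq = 10 * sigma_blank / slope`, so `loq / lod` is 10/3.3 by
#' construction. The linear range is reported as `(lod, max(conc))`.
#'
#' @param conc analyte concentrations in micromolar; at least 3 distinct.
#' @param current peak currents in microamperes, all positive.
#' @param blank_sd optional standard deviation of blank measurements (uA).
#' @return An object of class `calibration_model`: `fit` (a
#'   `regression_fit`), `slope` (sensitivity, uA/uM), `intercept`,
#'   `r_squared`, `sigma_blank`, `sigma_source` (`"blank_replicates"` or
#'   `"fit_residuals"`), `lod`, `loq`, `linear_range`, `usable` (FALSE, with
#'   a warning, when the slope is not positive).
#' @examples
#' conc <- c(2, 10, 25, 40, 55, 70, 75)
#' fit_calibration(conc, 0.127 * conc, blank_sd = 0.01)
#' @export
fit_calibration <- function(conc, current, blank_sd = NULL) {
  if (length(unique(conc)) < 3L) stop("need at least 3 distinct concentrations")
  if (any(current <= 0)) stop("all currents must be positive")
  fit <- fit_linear(conc, current, x_label = "conc_uM", y_label = "Ip_uA")
  usable <- fit$slope > 0
  if (!usable) warning("calibration slope is not positive; model flagged unusable")
  if (!is.null(blank_sd)) {
    if (!is.numeric(blank_sd) || length(blank_sd) != 1L || blank_sd < 0) {
      stop("`blank_sd` must be a single non-negative number")
    }
    sigma <- blank_sd
    src <- "blank_replicates"
  } else {
    sigma <- fit$residual_sd
    src <- "fit_residuals"
  }
  lod <- if (usable) 3.3 * sigma / fit$slope else NA_real_
  loq <- if (usable) 10 * sigma / fit$slope else NA_real_
  structure(
    list(fit = fit, slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, sigma_blank = sigma, sigma_source = src,
         lod = lod, loq = loq,
         linear_range = c(lod, max(conc)), usable = usable),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: Ip = %.4g * conc + %.4g uA (r2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  sigma_blank = %.3g uA (%s)\n", x$sigma_blank, x$sigma_source))
  if (x$usable) {
    cat(sprintf("  LOD = %.3g uM, LOQ = %.3g uM, linear range %.3g-%.3g uM\n",
                x$lod, x$loq, x$linear_range[1L], x$linear_range[2L]))
  } else {
    cat("  model flagged unusable (non-positive slope)\n")
  }
  invisible(x)
}

#' Spike recovery
#'
#' Recovery percentage and precision for one spiked level:
#' `recovery_pct = 100 * mean(measured) / spiked` and
#' `rsd_pct = 100 * sd(measured) / mean(measured)` (sample standard
#' deviation, n - 1 denominator). Both are invariant under a common unit
#' rescaling of `measured` and `spiked`.
#'
#' @param measured replicate measured concentrations (uM), at least 1.
#' @param spiked the spiked (true) concentration, uM, positive.
#' @return list with `spiked`, `mean_measured`, `recovery_pct`, `rsd_pct`
#'   (`NA` for a single replicate), `n_replicates`.
#' @examples
#' recovery(c(38.5, 39.2, 39.2), spiked = 40)
#' @export
recovery <- function(measured, spiked) {
  if (!is.numeric(spiked) || length(spiked) != 1L || !is.finite(spiked) ||
      spiked <= 0) {
    stop("`spiked` must be a single positive concentration")
  }
  if (length(measured) < 1L || anyNA(measured)) {
    stop("`measured` must contain at least one non-missing replicate")
  }
  m <- mean(measured)
  list(spiked = spiked,
       mean_measured = m,
       recovery_pct = 100 * m / spiked,
       rsd_pct = if (length(measured) >= 2L) 100 * stats::sd(measured) / m
                 else NA_real_,
       n_replicates = length(measured))
}

#' Per-level precision (%RSD)
#'
#' Computes the percent relative standard deviation at each concentration
#' level and the median across levels — the usual summary statistic for
#' intra- or inter-day precision. Levels with fewer than 2 replicates are
#' skipped with a warning.
#'
#' @param level grouping vector (concentration level per replicate).
#' @param value replicate responses (uA or uM).
#' @param mode `"intra_day"` or `"inter_day"`, recorded in the result.
#' @return list with `per_level` (data.frame `level`, `n`, `mean`,
#'   `rsd_pct`), `median_rsd_pct`, `mode`.
#' @examples
#' precision(rep(c(2, 10, 25), each = 3),
#'           c(2.1, 1.9, 2.0, 10.2, 9.9, 10.1, 25.5, 24.3, 25.0))
#' @export
precision <- function(level, value, mode = c("intra_day", "inter_day")) {
  mode <- match.arg(mode)
  if (length(level) != length(value)) {
    stop("`level` and `value` must have equal length")
  }
  groups <- split(value, level)
  short <- vapply(groups, length, integer(1)) < 2L
  if (any(short)) {
    warning("skipping levels with fewer than 2 replicates: ",
            paste(names(groups)[short], collapse = ", "))
    groups <- groups[!short]
  }
  if (length(groups) == 0L) stop("no level has 2 or more replicates")
  per_level <- data.frame(
    level = suppressWarnings(
      if (all(!is.na(as.numeric(names(groups))))) as.numeric(names(groups))
      else names(groups)),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    rsd_pct = vapply(groups, function(g) 100 * stats::sd(g) / mean(g),
                     numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_level = per_level,
       median_rsd_pct = stats::median(per_level$rsd_pct),
       mode = mode)
}

#' Interferent-induced signal change
#'
#' Signed current change and unsigned percent change of the analyte peak
#' when an interferent is present:
#' `delta_i = perturbed - reference` and
#' `pct_change = 100 * |delta_i| / reference`.
#'
#' @param reference_current analyte-only peak current, uA, positive.
#' @param perturbed_current peak current with the interferent present, uA.
#' @param interferent interferent identifier.
#' @param conc interferent concentration, uM.
#' @return list with `interferent`, `conc`, `delta_i` (signed) and
#'   `pct_change` (unsigned percent).
#' @examples
#' interference_change(0.2311, 0.1921, "DSX", 100)
#' @export
interference_change <- function(reference_current, perturbed_current,
                                interferent = NA_character_, conc = NA_real_) {
  if (!is.numeric(reference_current) || length(reference_current) != 1L ||
      !is.finite(reference_current) || reference_current <= 0) {
    stop("`reference_current` must be a single positive current")
  }
  delta <- perturbed_current - reference_current
  list(interferent = as.character(interferent), conc = conc,
       delta_i = delta,
       pct_change = 100 * abs(delta) / reference_current)
}

#' Interference table analysis
#'
#' Applies [interference_change()] to every row of an interference study
#' table. The analyte-only reference current is taken from `reference`, or,
#' when `reference` is `NULL`, from the table row whose `interferent` equals
#' `"none"`.
#'
#' @param df data.frame with columns `interferent`, `conc_uM`, `current_uA`.
#' @param reference analyte-only peak current (uA), or `NULL` to use the
#'   `"none"` row.
#' @return data.frame `interferent`, `conc_uM`, `delta_i_uA`,
#'   `pct_change`, with the reference current as attribute
#'   `reference_current`.
#' @export
interference_table <- function(df, reference = NULL) {
  need <- c("interferent", "conc_uM", "current_uA")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("`df` must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(reference)) {
    ref_rows <- df$interferent == "none"
    if (!any(ref_rows)) {
      stop("no `reference` given and no 'none' row in the table")
    }
    reference <- mean(df$current_uA[ref_rows])
    df <- df[!ref_rows, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(k) {
    res <- interference_change(reference, df$current_uA[k],
                               df$interferent[k], df$conc_uM[k])
    data.frame(interferent = res$interferent, conc_uM = res$conc,
               delta_i_uA = res$delta_i, pct_change = res$pct_change,
               stringsAsFactors = FALSE)
  }))
  attr(out, "reference_current") <- reference
  out
}

#' Back-derive the common reference current of an interference summary
#'
#' A published interference table that prints the signed current change and
#' the unsigned percent change for each row implies, row by row, the
#' analyte-only reference current `|delta_i| / (pct / 100)`. This function
#' computes the per-row implied references, their consensus (median), each
#' row's relative deviation from the consensus, and flags rows deviating by
#' more than `flag_tol` — a consistency check on the published numbers.
#'
#' @param df data.frame with columns `interferent`, `conc_uM`, `delta_i_uA`,
#'   `pct_change`.
#' @param flag_tol relative deviation above which a row is flagged;
#'   default 0.02.
#' @return list with `per_row` (data.frame adding `implied_reference_uA`,
#'   `rel_deviation`, `flagged`), `reference_uA` (consensus median) and
#'   `max_rel_deviation`.
#' @export
derive_interference_reference <- function(df, flag_tol = 0.02) {
  need <- c("interferent", "conc_uM", "delta_i_uA", "pct_change")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("`df` must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$pct_change <= 0)) stop("percent changes must be positive")
  implied <- abs(df$delta_i_uA) / (df$pct_change / 100)
  consensus <- stats::median(implied)
  rel_dev <- abs(implied - consensus) / consensus
  per_row <- df[need]
  per_row$implied_reference_uA <- implied
  per_row$rel_deviation <- rel_dev
  per_row$flagged <- rel_dev > flag_tol
  list(per_row = per_row, reference_uA = consensus,
       max_rel_deviation = max(rel_dev))
}

#' Compare the sensor against a reference method
#'
#' Ordinary least-squares regression of the reference-method concentrations
#' (e.g. GC-MS) on the sensor concentrations, mirroring the usual
#' reference-vs-test orientation. The methods are flagged as agreeing when
#' the slope lies in \[0.9, 1.1\] and r-squared is at least 0.99.
#'
#' @param test_conc sensor concentrations, uM.
#' @param ref_conc paired reference-method concentrations, uM; same length,
#'   at least 3 points.
#' @return An object of class `method_comparison`: `fit` (a
#'   `regression_fit` of reference on test) and `agreement` (logical).
#' @examples
#' x <- c(25, 40, 55, 70, 85)
#' compare_methods(x, 0.9972 * x + 1.6067)
#' @export
compare_methods <- function(test_conc, ref_conc) {
  if (length(test_conc) != length(ref_conc)) {
    stop("`test_conc` and `ref_conc` must be paired series of equal length")
  }
  fit <- fit_linear(test_conc, ref_conc,
                    x_label = "sensor_uM", y_label = "reference_uM")
  structure(
    list(fit = fit,
         agreement = fit$slope >= 0.9 && fit$slope <= 1.1 &&
                     fit$r_squared >= 0.99),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison: reference = %.4f * sensor + %.4f (r2 = %.4f)\n",
              x$fit$slope, x$fit$intercept, x$fit$r_squared))
  cat(sprintf("  agreement (slope in [0.9, 1.1], r2 >= 0.99): %s\n", x$agreement))
  invisible(x)
}
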