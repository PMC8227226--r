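#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning the quantities the mechanism
#' and validation analyses need: slope, intercept, coefficient of
#' determination, residual standard deviation, and a 95% confidence interval
#' for the slope. When the response is constant the fit is the horizontal
#' line and `r_squared` is defined as 0 by convention.
#'
#' @param x,y numeric vectors of equal length, at least 3 points; `x` must
#'   not be constant.
#' @param x_label,y_label axis labels recording any transformation applied
#'   upstream (e.g. `"log10 v"`), carried into reports.
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`, `residual_sd`, `slope_se`,
#'   `slope_ci95` (length 2), `x_label`, `y_label`.
#' @examples
#' fit_linear(1:5, c(2.1, 3.9, 6.2, 8.0, 9.9))
#' @export
fit_linear <- function(x, y, x_label = "x", y_label = "y") {
  if (!is.numeric(x) || !is.numeric(y)) stop("`x` and `y` must be numeric")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for a line fit, got ", n)
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    stop("`x` and `y` must be finite")
  }
  if (stats::sd(x) == 0) stop("degenerate design: `x` is constant")

  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x = x), y)
  coefs <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  # guard tiny negative / >1 from floating point
  r2 <- min(max(r2, 0), 1)
  sigma2 <- rss / (n - 2L)
  sxx <- sum((x - mean(x))^2)
  slope_se <- sqrt(sigma2 / sxx)
  tcrit <- stats::qt(0.975, df = n - 2L)
  slope <- unname(coefs["x"])
  structure(
    list(slope = slope, intercept = unname(coefs["(Intercept)"]),
         r_squared = r2, n_points = n, residual_sd = sqrt(sigma2),
         slope_se = slope_se,
         slope_ci95 = c(slope - tcrit * slope_se, slope + tcrit * slope_se),
         x_label = x_label, y_label = y_label),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<fit> %s = %.6g * %s + %.6g  (r2 = %.4f, n = %d)\n",
              x$y_label, x$slope, x$x_label, x$intercept,
              x$r_squared, x$n_points))
  invisible(x)
}
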