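#' Construct a voltammogram
#'
#' A voltammogram is a single potential sweep: an ordered potential series
#' (volts vs Ag/AgCl) with the matching current series (microamperes), plus
#' the experimental context it was recorded under. Traces supplied with
#' strictly decreasing potential are reversed so that the stored sweep is
#' always anodic (increasing potential).
#'
#' @param potential numeric vector, electrode potential in volts; strictly
#'   monotone.
#' @param current numeric vector of the same length, current in microamperes.
#' @param technique `"CV"` (cyclic voltammetry) or `"DPV"` (differential
#'   pulse voltammetry).
#' @param scan_rate potential sweep rate in V/s, or `NULL` if not recorded.
#' @param ph pH of the measurement medium in \[0, 14\], or `NULL`.
#' @param concentration analyte concentration in micromolar; `NULL` or `NA`
#'   for blanks.
#' @param label free-text metadata.
#' @return An object of class `voltammogram`.
#' @seealso [read_voltammogram()], [detect_peak()]
#' @examples
#' e <- seq(0.3, 1.3, by = 0.002)
#' i <- 2 * exp(-(e - 0.736)^2 / (2 * 0.05^2))
#' vg <- voltammogram(e, i, technique = "CV", scan_rate = 0.1, ph = 7)
#' vg
#' @export
voltammogram <- function(potential, current, technique = c("CV", "DPV"),
                         scan_rate = NULL, ph = NULL, concentration = NULL,
                         label = "") {
  technique <- match.arg(technique)
  if (!is.numeric(potential) || !is.numeric(current)) {
    stop("`potential` and `current` must be numeric vectors")
  }
  if (length(potential) != length(current)) {
    stop("`potential` and `current` must have equal length")
  }
  if (length(potential) < 8L) {
    stop("a voltammogram needs at least 8 samples, got ", length(potential))
  }
  if (anyNA(potential) || anyNA(current) ||
      !all(is.finite(potential)) || !all(is.finite(current))) {
    stop("`potential` and `current` must be finite and free of NA")
  }
  dE <- diff(potential)
  if (all(dE < 0)) {          # cathodic ordering: normalize to anodic
    potential <- rev(potential)
    current <- rev(current)
  } else if (!all(dE > 0)) {
    stop("`potential` must be strictly monotone")
  }
  if (!is.null(scan_rate)) {
    if (!is.numeric(scan_rate) || length(scan_rate) != 1L ||
        !is.finite(scan_rate) || scan_rate <= 0) {
      stop("`scan_rate` must be a single positive number (V/s)")
    }
  }
  if (!is.null(ph) && !is.na(ph)) {
    if (!is.numeric(ph) || length(ph) != 1L || ph < 0 || ph > 14) {
      stop("`ph` must be a single value in [0, 14]")
    }
  }
  if (!is.null(concentration) && !is.na(concentration)) {
    if (!is.numeric(concentration) || length(concentration) != 1L ||
        concentration < 0) {
      stop("`concentration` must be a single non-negative value (uM)")
    }
  }
  structure(
    list(potential = as.numeric(potential), current = as.numeric(current),
         technique = technique, scan_rate = scan_rate, ph = ph,
         concentration = concentration, label = as.character(label)[1L]),
    class = "voltammogram"
  )
}

#' @export
print.voltammogram <- function(x, ...) {
  ctx <- c(
    if (!is.null(x$scan_rate)) sprintf("%g V/s", x$scan_rate),
    if (!is.null(x$ph)) sprintf("pH %g", x$ph),
    if (!is.null(x$concentration) && !is.na(x$concentration))
      sprintf("%g uM", x$concentration)
  )
  cat(sprintf("<voltammogram> %s, %d points, %.3f to %.3f V%s%s\n",
              x$technique, length(x$potential),
              min(x$potential), max(x$potential),
              if (length(ctx)) paste0(" [", paste(ctx, collapse = ", "), "]") else "",
              if (nzchar(x$label)) paste0(" ", dQuote(x$label)) else ""))
  invisible(x)
}

vg_header <- "potential_V,current_uA"

#' Read a voltammogram from a two-column CSV file
#'
#' The file format is a mandatory header line `potential_V,current_uA`
#' followed by comma-separated numeric rows (dot decimal separator, UTF-8).
#' Experimental context is not stored in the CSV; it is supplied through the
#' metadata arguments. Traces recorded with decreasing potential are
#' normalized to increasing order.
#'
#' @param path path to the CSV file.
#' @inheritParams voltammogram
#' @return A [voltammogram()] object.
#' @examples
#' e <- seq(0.3, 1.3, by = 0.01)
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("potential_V,current_uA", paste(e, 1, sep = ",")), tmp)
#' read_voltammogram(tmp, technique = "CV", scan_rate = 0.1)
#' @export
read_voltammogram <- function(path, technique = c("CV", "DPV"),
                              scan_rate = NULL, ph = NULL,
                              concentration = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || lines[1L] != vg_header) {
    stop("'", path, "': expected header line '", vg_header, "'")
  }
  body <- lines[-1L]
  if (length(body) < 8L) {
    stop("'", path, "': fewer than 8 data rows")
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- which(nfield != 2L)[1L]
    stop(sprintf("'%s': expected 2 fields at line %d", path, bad + 1L))
  }
  mat <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  pot <- suppressWarnings(as.numeric(mat[, 1L]))
  cur <- suppressWarnings(as.numeric(mat[, 2L]))
  bad <- which(is.na(pot) | is.na(cur))
  if (length(bad)) {
    stop(sprintf("'%s': non-numeric value at line %d", path, bad[1L] + 1L))
  }
  voltammogram(pot, cur, technique = technique, scan_rate = scan_rate,
               ph = ph, concentration = concentration, label = label)
}

#' Write a voltammogram to CSV
#'
#' Writes the two-column format read by [read_voltammogram()], at full double
#' precision so that a write-read-write cycle is byte-identical.
#'
#' @param vg a [voltammogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(vg, path) {
  stopifnot(inherits(vg, "voltammogram"))
  lines <- c(vg_header,
             sprintf("%.17g,%.17g", vg$potential, vg$current))
  writeLines(lines, path)
  invisible(path)
}
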