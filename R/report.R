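REPORT_SCHEMA_VERSION <- "1.0.0"

# strip classes / attributes recursively so jsonlite serializes plain lists
as_plain <- function(x) {
  if (is.data.frame(x)) {
    lapply(as.list(x), as_plain)
  } else if (is.list(x)) {
    lapply(unclass(x), as_plain)
  } else if (is.numeric(x) || is.logical(x) || is.character(x)) {
    out <- unname(x)
    attributes(out) <- NULL
    out
  } else {
    x
  }
}

#' Assemble a pipeline report
#'
#' Aggregates any subset of stage outputs into the single schema-versioned
#' report structure the CLI serializes. Raw double-precision values are
#' stored; display rounding happens only in `print` methods, never here.
#'
#' @param mechanism a [mechanism_report()], or `NULL`.
#' @param screening a [screen_monomers()] result, optionally with a `ratio`
#'   element from [select_ratio()], or `NULL`.
#' @param calibration a [fit_calibration()] model, or `NULL`.
#' @param validation an [analyze_validation_study()] result, or `NULL`.
#' @param config resolved run configuration echoed into the report, or
#'   `NULL`.
#' @return list of class `voltmip_report` with a `meta` block
#'   (schema/package versions) plus the supplied blocks.
#' @export
build_report <- function(mechanism = NULL, screening = NULL,
                         calibration = NULL, validation = NULL,
                         config = NULL) {
  blocks <- list(mechanism = mechanism, screening = screening,
                 calibration = calibration, validation = validation)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) stop("a report needs at least one stage block")
  rep <- c(
    list(meta = list(
      schema_version = REPORT_SCHEMA_VERSION,
      package = "voltmip",
      package_version = as.character(utils::packageVersion("voltmip")))),
    if (!is.null(config)) list(config = as_plain(config)),
    lapply(blocks, as_plain)
  )
  structure(rep, class = "voltmip_report")
}

#' Serialize a report to JSON text
#'
#' Numbers are written at full double precision; scalars are unboxed.
#'
#' @param report a `voltmip_report` (or any nested list).
#' @return a JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(as_plain(report), auto_unbox = TRUE, digits = I(17),
                   null = "null", pretty = TRUE)
}

#' Write a report to a JSON file
#'
#' @param report a `voltmip_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open report path for writing: ", path)
  })
  on.exit(close(con))
  writeLines(report_json(report), con)
  invisible(path)
}

#' Read a report back from JSON
#'
#' @param path path to a report written by [write_report()].
#' @return the parsed report (nested lists, class `voltmip_report`).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE),
            class = "voltmip_report")
}

#' Validate a report against the shipped schema
#'
#' Checks the structural contract mirrored in
#' `inst/schema/report.schema.json`: a `meta` block with the schema version,
#' only known top-level blocks, and the required fields of each present
#' block. Stops with a descriptive error on violation.
#'
#' @param report a report structure.
#' @return `TRUE`, invisibly, on success.
#' @export
validate_report <- function(report) {
  if (!is.list(report)) stop("report must be a list")
  known <- c("meta", "config", "mechanism", "screening", "calibration",
             "validation")
  extra <- setdiff(names(report), known)
  if (length(extra)) {
    stop("unknown report block(s): ", paste(extra, collapse = ", "))
  }
  if (is.null(report$meta) || is.null(report$meta$schema_version)) {
    stop("report is missing meta$schema_version")
  }
  if (!any(names(report) %in% c("mechanism", "screening", "calibration",
                                "validation"))) {
    stop("report has no stage block")
  }
  required <- list(
    mechanism = c("alpha_n", "alpha", "n_electrons", "control_regime",
                  "proton_coupled", "fits"),
    screening = c("table", "selected_monomer"),
    calibration = c("slope", "sigma_blank", "lod", "loq"),
    validation = c("calibration", "recovery")
  )
  for (blk in names(required)) {
    if (!is.null(report[[blk]])) {
      missing <- setdiff(required[[blk]], names(report[[blk]]))
      if (length(missing)) {
        stop("report block '", blk, "' is missing field(s): ",
             paste(missing, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}
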