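#' Template-monomer binding energy
#'
#' The stabilization energy of the pre-polymerization complex:
#' `delta_e = e_complex - e_template - e_monomer`, where `e_monomer` is the
#' energy of the free monomer (or the sum over monomers for higher
#' stoichiometries). More negative values mean a more stable complex and
#' hence a better imprinting monomer. The arithmetic is unit-agnostic: the
#' difference is returned in the same units as the inputs, at full input
#' precision.
#'
#' @param e_complex,e_template,e_monomer numeric vectors (recycled to common
#'   length) of quantum-chemistry total energies.
#' @return numeric vector of binding-energy differences.
#' @examples
#' binding_energy(-1281.328453, -1071.15051, -210.165882)  # pyrrole row
#' @export
binding_energy <- function(e_complex, e_template, e_monomer) {
  vals <- c(e_complex, e_template, e_monomer)
  if (!is.numeric(vals) || anyNA(vals) || !all(is.finite(vals))) {
    stop("all energies must be finite numbers")
  }
  e_complex - e_template - e_monomer
}

#' Read a monomer energy table
#'
#' Expects a CSV with header `monomer,e_complex,e_template,e_monomer` and an
#' optional `units` column whose label is passed through untouched (never
#' converted). Multiple free-monomer columns named `e_monomer1`,
#' `e_monomer2`, ... are summed into a single `e_monomer`.
#'
#' @param path path to the CSV file.
#' @return A data.frame with columns `monomer`, `e_complex`, `e_template`,
#'   `e_monomer`, and a `units` attribute.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("monomer", "e_complex", "e_template")
  if (!all(need %in% names(df))) {
    stop("'", path, "': expected columns ", paste(need, collapse = ", "),
         " and e_monomer (or e_monomer1, e_monomer2, ...)")
  }
  mono_cols <- grep("^e_monomer", names(df), value = TRUE)
  if (length(mono_cols) == 0L) {
    stop("'", path, "': no e_monomer column(s) found")
  }
  mono <- as.data.frame(lapply(df[mono_cols], function(col) {
    suppressWarnings(as.numeric(col))
  }))
  e_monomer <- rowSums(mono)
  out <- data.frame(monomer = as.character(df$monomer),
                    e_complex = as.numeric(df$e_complex),
                    e_template = as.numeric(df$e_template),
                    e_monomer = as.numeric(e_monomer),
                    stringsAsFactors = FALSE)
  if (anyNA(out[-1L]) || !all(is.finite(as.matrix(out[-1L])))) {
    stop("'", path, "': non-numeric or non-finite energy values")
  }
  if (anyDuplicated(out$monomer)) {
    stop("'", path, "': duplicate monomer ids: ",
         paste(unique(out$monomer[duplicated(out$monomer)]), collapse = ", "))
  }
  attr(out, "units") <- if ("units" %in% names(df)) as.character(df$units[1L]) else NA_character_
  out
}

#' Screen candidate functional monomers by binding energy
#'
#' Computes the binding-energy difference for every candidate, ranks them
#' ascending (most negative, i.e. most stable complex, first) and selects the
#' minimum. The ranking is deterministic and permutation-invariant; exact
#' ties — which have no physical basis — are broken lexicographically by
#' monomer id with a warning.
#'
#' @param energies a data.frame as returned by [read_energy_table()], or any
#'   data.frame with columns `monomer`, `e_complex`, `e_template`,
#'   `e_monomer`.
#' @return An object of class `screening_result`: `table` (ranked data.frame
#'   with `rank`, `monomer`, `delta_e` and the input energies),
#'   `selected_monomer`, `runner_up` (or `NA` for a single candidate), and
#'   `units` (pass-through label).
#' @examples
#' tbl <- read_energy_table(system.file("extdata", "table1_energies.csv",
#'                                      package = "voltmip"))
#' screen_monomers(tbl)
#' @export
screen_monomers <- function(energies) {
  need <- c("monomer", "e_complex", "e_template", "e_monomer")
  if (!is.data.frame(energies) || !all(need %in% names(energies))) {
    stop("`energies` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(energies) < 1L) stop("`energies` must have at least one row")
  if (anyDuplicated(energies$monomer)) stop("duplicate monomer ids")
  delta_e <- binding_energy(energies$e_complex, energies$e_template,
                            energies$e_monomer)
  if (anyDuplicated(delta_e)) {
    warning("tied binding energies broken lexicographically by monomer id")
  }
  ord <- order(delta_e, energies$monomer)
  tab <- data.frame(rank = seq_along(ord),
                    monomer = energies$monomer[ord],
                    delta_e = delta_e[ord],
                    e_complex = energies$e_complex[ord],
                    e_template = energies$e_template[ord],
                    e_monomer = energies$e_monomer[ord],
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         selected_monomer = tab$monomer[1L],
         runner_up = if (nrow(tab) > 1L) tab$monomer[2L] else NA_character_,
         units = attr(energies, "units") %||% NA_character_),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Monomer screening by template-monomer binding energy\n")
  print(x$table[c("rank", "monomer", "delta_e")], row.names = FALSE)
  cat(sprintf("selected: %s", x$selected_monomer))
  if (!is.na(x$runner_up)) cat(sprintf(" (runner-up: %s)", x$runner_up))
  cat("\n")
  invisible(x)
}

#' Read a template:monomer ratio scan
#'
#' CSV with header `t_count,m_count,score`: one row per candidate
#' stoichiometry, `score` being the complex energy computed externally (e.g.
#' by a semi-empirical method); this package ingests scores, it does not run
#' quantum chemistry.
#'
#' @param path path to the CSV file.
#' @return data.frame with integer `t_count`, `m_count` and numeric `score`.
#' @export
read_ratio_scan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_count", "m_count", "score")
  if (!all(need %in% names(df))) {
    stop("'", path, "': expected columns ", paste(need, collapse = ", "))
  }
  df
}

#' Select the optimal template:monomer ratio
#'
#' Returns the stoichiometry with the minimal (most stable) complex energy
#' score. Ties are broken by the lexicographically smallest `(t_count,
#' m_count)` pair, with a warning.
#'
#' @param candidates data.frame with columns `t_count`, `m_count`
#'   (integers >= 1) and `score` (finite numeric).
#' @return list with `t_count`, `m_count` and `score` of the winner.
#' @examples
#' select_ratio(data.frame(t_count = 1, m_count = 1:4,
#'                         score = c(-1, -2, -3, -4)))
#' @export
select_ratio <- function(candidates) {
  need <- c("t_count", "m_count", "score")
  if (!is.data.frame(candidates) || !all(need %in% names(candidates))) {
    stop("`candidates` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(candidates) < 1L) stop("`candidates` must have at least one row")
  if (any(candidates$t_count < 1) || any(candidates$m_count < 1) ||
      any(candidates$t_count %% 1 != 0) || any(candidates$m_count %% 1 != 0)) {
    stop("ratio components must be integers >= 1")
  }
  if (!all(is.finite(candidates$score))) stop("scores must be finite")
  if (sum(candidates$score == min(candidates$score)) > 1L) {
    warning("tied ratio scores broken by smallest (t_count, m_count)")
  }
  ord <- order(candidates$score, candidates$t_count, candidates$m_count)
  best <- candidates[ord[1L], ]
  list(t_count = as.integer(best$t_count),
       m_count = as.integer(best$m_count),
       score = best$score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
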