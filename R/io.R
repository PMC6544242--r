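measurement_roles <- c("blank", "calibration", "validation", "qc",
                       "setA", "setB", "setC", "stability", "clinical")

measurement_columns <- c("sample_id", "role", "analyte", "transition",
                         "day", "replicate", "nominal_conc",
                         "peak_area", "istd_area")

#' Validate a long-format measurement table
#'
#' Checks the schema and the basic physical invariants of the measurement
#' interchange format: required columns, known roles, non-negative peak
#' areas and nominal concentrations, strictly positive nominal
#' concentrations for calibration/validation records and strictly positive
#' ISTD areas for processed samples. Violations are reported with the
#' offending row numbers.
#'
#' @param measurements a data frame in long measurement format.
#' @return The table (as tibble) invisibly; errors on violation.
#' @export
validate_measurements <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  missing <- setdiff(measurement_columns, names(m))
  if (length(missing) > 0L) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      stop(sprintf("%s (row%s %s)", what,
                   if (length(rows) > 1) "s" else "",
                   paste(utils::head(rows, 10), collapse = ", ")))
    }
  }
  bad(!m$role %in% measurement_roles, "unknown sample role")
  bad(!is.finite(m$peak_area) | m$peak_area < 0, "negative peak area")
  bad(!is.finite(m$nominal_conc) | m$nominal_conc < 0,
      "negative nominal concentration")
  bad(m$role %in% c("calibration", "validation") & m$nominal_conc <= 0,
      "calibration/validation record with non-positive nominal concentration")
  bad(m$role != "blank" & (!is.finite(m$istd_area) | m$istd_area <= 0),
      "non-positive ISTD area in processed sample")
  invisible(m)
}

#' Read or write measurement tables as delimited text
#'
#' The single interchange format of the package: comma-separated, header
#' row, UTF-8, `"."` decimal mark; concentrations in ng/mL, times in
#' seconds, m/z in Da. The written table round-trips losslessly.
#'
#' @param measurements measurement tibble.
#' @param path file path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns a validated tibble.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  m <- tibble::as_tibble(
    utils::read.csv(path, check.names = TRUE, fileEncoding = "UTF-8"))
  for (col in c("sample_id", "role", "analyte", "transition", "donor",
                "matrix")) {
    if (col %in% names(m)) m[[col]] <- as.character(m[[col]])
  }
  validate_measurements(m)
  m
}

#' Collapse a per-transition measurement table to quantification responses
#'
#' Sums the configured quantifier transition areas per injection (see
#' [combine_quantifier_transitions()]) and forms the analyte/ISTD area
#' ratio used for quantification.
#'
#' @param measurements validated measurement tibble (per-transition rows).
#' @param design an [assay_design()] naming the quantifier transitions.
#' @return Tibble with one row per injection and analyte: identifiers,
#'   `combined_area`, `istd_area` and `ratio`.
#' @export
quantification_responses <- function(measurements, design) {
  m <- validate_measurements(measurements)
  if (!"donor" %in% names(m)) m$donor <- NA_character_
  if (!"matrix" %in% names(m)) m$matrix <- NA_character_
  m <- dplyr::filter(m, .data$analyte %in% design$analytes)
  combined <- dplyr::summarise(
    dplyr::group_by(m, .data$sample_id, .data$role, .data$analyte, .data$day,
                    .data$replicate, .data$donor, .data$matrix,
                    .data$nominal_conc),
    combined_area = {
      if (all(.data$transition == "combined")) sum(.data$peak_area)
      else {
        rule <- design$transitions
        rule <- rule[rule$analyte == .data$analyte[1] & rule$quantifier, ]
        areas <- stats::setNames(.data$peak_area, format(.data$product_mz))
        combine_quantifier_transitions(areas, format(rule$product_mz))
      }
    },
    istd_area = .data$istd_area[1],
    .groups = "drop")
  combined$ratio <- combined$combined_area / combined$istd_area
  combined
}
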