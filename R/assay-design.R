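#' Assay design: analytes, transitions, level grids and acceptance constants
#'
#' An `assay_design` bundles everything the validation pipeline needs to know
#' about an MRM assay that is not a measurement: the analyte panel with its
#' quantifier/qualifier transitions and reference ion ratios, the internal
#' standard (ISTD) assigned to each analyte, the calibration and validation
#' concentration grids, the replication scheme (p validation days, n
#' replicates per level and day), and the acceptance constants used by the
#' decision rules.
#'
#' @param transitions data frame with one row per MRM transition and columns
#'   `analyte`, `istd`, `precursor_mz`, `product_mz`, `ion_ratio`
#'   (area ratio to the most intense product, which has ratio 1),
#'   `quantifier` (logical: summed into the quantification signal) and
#'   `retention_time_min`.
#' @param calibration_levels strictly increasing calibration concentrations
#'   (ng/mL).
#' @param validation_levels strictly increasing validation-standard
#'   concentrations (ng/mL).
#' @param days number of validation days p.
#' @param replicates replicates n per level and day.
#' @param beta coverage proportion of the beta-expectation tolerance
#'   intervals, in (0, 1).
#' @param lambda acceptance limit of the accuracy profile, in percent.
#' @param lloq optional named numeric: per-analyte lower end of the retained
#'   range (ng/mL). Analytes not named keep the full grid.
#' @param limits named list of decision thresholds in percent:
#'   `matrix_effect`, `stability`, `stability_lloq`, `ion_ratio`,
#'   `carryover`, `bias`, `bias_lloq`.
#' @param blood_ratio length-2 numeric `c(blood, anticoagulant)` volume parts
#'   used for the whole-blood dilution correction.
#' @param seed integer seed propagated to every random operation run from
#'   this design.
#'
#' @return An object of class `assay_design`.
#' @seealso [pbtz169_design()] for the ready-made benzothiazinone panel.
#' @export
assay_design <- function(transitions,
                         calibration_levels,
                         validation_levels,
                         days = 3L,
                         replicates = 3L,
                         beta = 0.90,
                         lambda = 30,
                         lloq = NULL,
                         limits = list(),
                         blood_ratio = c(blood = 10, anticoagulant = 1),
                         seed = 42L) {
  transitions <- tibble::as_tibble(transitions)
  needed <- c("analyte", "istd", "precursor_mz", "product_mz",
              "ion_ratio", "quantifier", "retention_time_min")
  missing <- setdiff(needed, names(transitions))
  if (length(missing) > 0L) {
    stop("transitions table lacks column(s): ", paste(missing, collapse = ", "))
  }
  istd_map <- unique(transitions[, c("analyte", "istd")])
  if (anyDuplicated(istd_map$analyte)) {
    stop("each analyte must be assigned exactly one internal standard")
  }
  check_grid <- function(x, what) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop(what, " levels must be positive and finite")
    }
    if (is.unsorted(x, strictly = TRUE)) {
      stop(what, " levels must be strictly increasing")
    }
  }
  check_grid(calibration_levels, "calibration")
  check_grid(validation_levels, "validation")
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (!(lambda > 0)) stop("lambda must be positive")
  if (days < 1L || replicates < 1L) stop("days and replicates must be >= 1")

  default_limits <- list(matrix_effect = 15, stability = 15,
                         stability_lloq = 20, ion_ratio = 20,
                         carryover = 20, bias = 15, bias_lloq = 20)
  limits <- utils::modifyList(default_limits, limits)

  if (!is.null(lloq)) {
    unknown <- setdiff(names(lloq), istd_map$analyte)
    if (length(unknown) > 0L) {
      stop("lloq names not in analyte panel: ", paste(unknown, collapse = ", "))
    }
  }

  structure(
    list(
      transitions = transitions,
      analytes = unique(transitions$analyte),
      istd = stats::setNames(istd_map$istd, istd_map$analyte),
      calibration_levels = as.numeric(calibration_levels),
      validation_levels = as.numeric(validation_levels),
      days = as.integer(days),
      replicates = as.integer(replicates),
      beta = beta,
      lambda = lambda,
      lloq = lloq,
      limits = limits,
      blood_ratio = blood_ratio,
      seed = as.integer(seed)
    ),
    class = "assay_design"
  )
}

#' Benzothiazinone (PBTZ169) panel design
#'
#' The assay design of the six-analyte benzothiazinone panel: PBTZ169 and its
#' five active metabolites (Met 1-OH, 2-OH, 3-OH, 3-oxo and oxo), each with
#' its MRM transitions, reference ion ratios and ISTD assignment, a
#' nine-level calibration grid 0.1--2000 ng/mL, an eight-level validation
#' grid 0.1--1500 ng/mL, and the 3 days x 3 replicates scheme. The retained
#' lower range end differs per analyte (0.1 for PBTZ169, 0.2 for Met 3-OH and
#' 3-oxo, 0.5 for the others).
#'
#' @inheritParams assay_design
#' @param ... passed on to [assay_design()] to override defaults.
#' @return An `assay_design`.
#' @export
pbtz169_design <- function(seed = 42L, ...) {
  path <- system.file("extdata", "pbtz169_transitions.csv", package = "msval",
                      mustWork = TRUE)
  transitions <- utils::read.csv(path, check.names = TRUE)
  assay_design(
    transitions = transitions,
    calibration_levels = c(0.1, 0.2, 0.5, 1, 2, 50, 500, 1000, 2000),
    validation_levels = c(0.1, 0.2, 0.5, 1, 2, 150, 750, 1500),
    lloq = c("PBTZ169" = 0.1, "Met 3-OH" = 0.2, "Met 3-oxo" = 0.2,
             "Met 1-OH" = 0.5, "Met 2-OH" = 0.5, "Met oxo" = 0.5),
    seed = seed,
    ...
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat("<assay_design>\n")
  cat("  analytes:   ", paste(x$analytes, collapse = ", "), "\n")
  cat("  calibration:", length(x$calibration_levels), "levels,",
      min(x$calibration_levels), "-", max(x$calibration_levels), "ng/mL\n")
  cat("  validation: ", length(x$validation_levels), "levels,",
      min(x$validation_levels), "-", max(x$validation_levels), "ng/mL\n")
  cat("  scheme:     ", x$days, "days x", x$replicates, "replicates\n")
  cat("  beta:", x$beta, " lambda:", x$lambda, "%  seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write an assay design as a YAML configuration file
#'
#' The design (including the transition table) round-trips through a single
#' structured key-value file so that a validation run is fully described by
#' one configuration artifact.
#'
#' @param design an `assay_design`.
#' @param path file path.
#' @return `write_assay_design()` returns `path` invisibly;
#'   `read_assay_design()` returns an `assay_design`.
#' @export
write_assay_design <- function(design, path) {
  stopifnot(inherits(design, "assay_design"))
  x <- unclass(design)
  x$transitions <- lapply(seq_len(nrow(design$transitions)), function(i) {
    as.list(design$transitions[i, ])
  })
  x$istd <- as.list(x$istd)
  x$lloq <- if (is.null(x$lloq)) NULL else as.list(x$lloq)
  x$blood_ratio <- as.list(stats::setNames(as.numeric(design$blood_ratio),
                                           c("blood", "anticoagulant")))
  x$analytes <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_assay_design
#' @export
read_assay_design <- function(path) {
  x <- yaml::read_yaml(path)
  transitions <- dplyr::bind_rows(lapply(x$transitions, tibble::as_tibble))
  assay_design(
    transitions = transitions,
    calibration_levels = unlist(x$calibration_levels),
    validation_levels = unlist(x$validation_levels),
    days = x$days,
    replicates = x$replicates,
    beta = x$beta,
    lambda = x$lambda,
    lloq = if (is.null(x$lloq)) NULL else unlist(x$lloq),
    limits = x$limits,
    blood_ratio = c(blood = x$blood_ratio$blood,
                    anticoagulant = x$blood_ratio$anticoagulant),
    seed = x$seed
  )
}
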