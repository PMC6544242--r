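#' Carryover as percent of the LLOQ signal
#'
#' The area found in a blank injected after a high-concentration sample,
#' expressed as a percentage of the mean LLOQ-standard area. The flag uses a
#' configurable threshold (default 20% of the LLOQ signal, the usual
#' regulatory cut-off).
#'
#' @param blank_area area in the blank after the high standard.
#' @param lloq_area_mean mean peak area of LLOQ-level standards, > 0.
#' @param threshold flagging threshold in percent.
#' @return List with `percent` and logical `flagged`.
#' @export
carryover_percent <- function(blank_area, lloq_area_mean, threshold = 20) {
  stopifnot(lloq_area_mean > 0, blank_area >= 0)
  pct <- blank_area / lloq_area_mean * 100
  list(percent = pct, flagged = pct > threshold)
}

#' Reference ion ratios from calibration standards
#'
#' The reference ratio of each product ion is the mean over calibration
#' standards of its area relative to the most intense (base) product.
#'
#' @param calib tibble of calibration records with columns `sample_id`,
#'   `product_mz`, `peak_area` (one analyte).
#' @param base_product m/z of the base product ion.
#' @return Named numeric vector of mean ratios (base product = 1).
#' @export
reference_ion_ratios <- function(calib, base_product) {
  calib <- tibble::as_tibble(calib)
  base <- dplyr::filter(calib, .data$product_mz == base_product)
  if (nrow(base) == 0L) stop("base product ", base_product, " not found")
  base <- dplyr::select(dplyr::rename(base, base_area = "peak_area"),
                        "sample_id", "base_area")
  joined <- dplyr::inner_join(calib, base, by = "sample_id")
  ratios <- dplyr::summarise(
    dplyr::group_by(joined, .data$product_mz),
    ratio = mean(.data$peak_area / .data$base_area), .groups = "drop")
  stats::setNames(ratios$ratio, format(ratios$product_mz))
}

#' Ion-ratio confirmation of peak identity
#'
#' Compares observed qualifier/base product-ion area ratios in a sample
#' against the reference ratios (mean over calibration standards). Identity
#' is confirmed for a product when the observed ratio is within the relative
#' tolerance (default +/-20%) of its reference ratio.
#'
#' @param observed_areas named numeric vector of product-ion areas; names
#'   are product m/z values.
#' @param reference_ratios named numeric vector of reference ratios (the
#'   base product has ratio 1).
#' @param base_product name of the base (most intense) product; defaults to
#'   the reference entry with ratio 1.
#' @param tolerance relative tolerance as a fraction (0.20 = +/-20%).
#' @return Tibble with one row per non-base product: observed ratio,
#'   reference ratio, relative deviation in percent, and `confirmed`.
#' @export
ion_ratio_confirm <- function(observed_areas, reference_ratios,
                              base_product = NULL, tolerance = 0.20) {
  if (is.null(base_product)) {
    base_product <- names(reference_ratios)[which(reference_ratios == 1)][1]
  }
  if (is.na(base_product) || !base_product %in% names(observed_areas)) {
    stop("base product ", base_product, " missing from observed areas")
  }
  base_area <- observed_areas[[base_product]]
  if (base_area <= 0) stop("base product area must be positive")
  products <- setdiff(intersect(names(observed_areas),
                                names(reference_ratios)), base_product)
  obs <- observed_areas[products] / base_area
  ref <- reference_ratios[products]
  dev <- (obs / ref - 1) * 100
  tibble::tibble(
    product = products,
    observed_ratio = unname(obs),
    reference_ratio = unname(ref),
    deviation = unname(dev),
    confirmed = abs(unname(dev)) <= tolerance * 100
  )
}

#' Stability verdicts from a concentration (or response-ratio) series
#'
#' Deviation of the mean measurement at each time point / condition from a
#' reference -- either the t0 mean of freshly prepared samples or the nominal
#' concentration -- with pass/fail at +/-15% (widened to +/-20% for LLOQ-level
#' samples). The same computation applies to analyte/ISTD peak-area ratios
#' monitored over time in processed samples (ratio mode); only the units of
#' `value` change.
#'
#' @param series tibble with columns `condition` (label), `value` (measured
#'   concentration ng/mL, or area ratio), and optionally `level` (ng/mL).
#' @param reference reference value (t0 mean or nominal), > 0; either a
#'   single number or a named vector by condition.
#' @param lloq logical (or vector by condition): the sample is at LLOQ level,
#'   so the widened limit applies.
#' @param limit,limit_lloq acceptance limits in percent.
#' @return Tibble with one row per condition: n, mean, deviation %, limit,
#'   pass.
#' @export
stability_deviation <- function(series, reference, lloq = FALSE,
                                limit = 15, limit_lloq = 20) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("condition", "value") %in% names(series)),
            all(reference > 0))
  out <- dplyr::summarise(
    dplyr::group_by(series, .data$condition),
    n = dplyr::n(), mean_value = mean(.data$value), .groups = "drop")
  ref <- if (length(reference) == 1L && is.null(names(reference))) {
    rep(reference, nrow(out))
  } else {
    unname(reference[out$condition])
  }
  if (any(is.na(ref))) stop("missing reference for some condition(s)")
  is_lloq <- if (length(lloq) == 1L) rep(lloq, nrow(out)) else
    unname(lloq[out$condition])
  out$reference <- ref
  out$deviation <- (out$mean_value - ref) / ref * 100
  out$limit <- ifelse(is_lloq, limit_lloq, limit)
  out$pass <- abs(out$deviation) <= out$limit
  out
}

#' Bias and precision of alternate-matrix QCs on the validated calibration
#'
#' Quantifies QC samples prepared in an alternate matrix (EDTA or heparin
#' plasma, serum) against the calibration validated in citrated plasma, and
#' reports per-level bias and RSD with the +/-15% acceptance (widened to 20%
#' at LLOQ).
#'
#' @param qc tibble with columns `matrix`, `level` (nominal ng/mL) and
#'   `conc` (measured ng/mL).
#' @param lloq_level nominal concentration treated as LLOQ (widened limit);
#'   NA for none.
#' @param limit,limit_lloq acceptance limits in percent.
#' @return Tibble per matrix x level: n, bias %, rsd %, limit, pass.
#' @export
anticoagulant_bias <- function(qc, lloq_level = NA, limit = 15,
                               limit_lloq = 20) {
  qc <- tibble::as_tibble(qc)
  stopifnot(all(c("matrix", "level", "conc") %in% names(qc)),
            all(qc$level > 0))
  out <- dplyr::summarise(
    dplyr::group_by(qc, .data$matrix, .data$level),
    n = dplyr::n(),
    bias = (mean(.data$conc) - .data$level[1]) / .data$level[1] * 100,
    rsd = if (dplyr::n() > 1) stats::sd(.data$conc) / mean(.data$conc) * 100
          else 0,
    .groups = "drop")
  out$limit <- ifelse(!is.na(lloq_level) & out$level == lloq_level,
                      limit_lloq, limit)
  out$pass <- abs(out$bias) <= out$limit
  out
}

#' Whole-blood dilution correction for anticoagulated samples
#'
#' Plasma concentrations measured in blood collected on a liquid
#' anticoagulant are multiplied by (blood + anticoagulant) / blood to
#' recover the blood-equivalent concentration (factor 1.1 for a 10:1
#' blood:citrate collection).
#'
#' @param conc measured plasma concentration(s).
#' @param blood,anticoagulant volume parts, > 0 (anticoagulant may be 0).
#' @return Corrected concentration(s).
#' @export
blood_dilution_correct <- function(conc, blood = 10, anticoagulant = 1) {
  stopifnot(blood > 0, anticoagulant >= 0)
  conc * (blood + anticoagulant) / blood
}
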