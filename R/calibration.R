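#' Combine quantifier transition areas into the quantification signal
#'
#' Multi-transition analytes are quantified on the sum of their configured
#' quantifier product-ion areas (summing independent SRM signals raises S/N);
#' single-transition analytes pass through unchanged.
#'
#' @param areas named numeric vector of peak areas, names are product m/z
#'   values (as printed, e.g. `"344.1"`).
#' @param rule character vector naming the product m/z values to sum.
#' @return The combined area (numeric scalar).
#' @export
combine_quantifier_transitions <- function(areas, rule) {
  rule <- as.character(rule)
  missing <- setdiff(rule, names(areas))
  if (length(missing) > 0L) {
    stop("configured quantifier transition(s) missing from areas: ",
         paste(missing, collapse = ", "))
  }
  sum(areas[rule])
}

response_families <- c("quad_weighted_1_over_x", "linear_log", "quad_log")

#' Fit a candidate response model to calibration points
#'
#' Three model families describe the analyte/ISTD area-ratio response over a
#' wide (four-decade) concentration range:
#' * `quad_weighted_1_over_x` — quadratic `y = a + b x + c x^2` on raw
#'   scales, weighted least squares with weights `1/x` (nominal
#'   concentration);
#' * `linear_log` — ordinary least squares of `log10(y)` on `log10(x)`;
#' * `quad_log` — quadratic in `log10(x)`.
#'
#' @param conc nominal concentrations x (ng/mL), > 0.
#' @param ratio response y: analyte/ISTD peak-area ratio, > 0 for the log
#'   families.
#' @param family one of `"quad_weighted_1_over_x"`, `"linear_log"`,
#'   `"quad_log"`.
#' @param analyte,day optional labels carried on the fit.
#' @return An object of class `calibration_fit`: coefficients `(a, b, c)`
#'   (with `c = 0` for `linear_log`), the fitted `domain`
#'   (lowest--highest calibration level), the number of distinct levels `k`,
#'   and the labels.
#' @export
fit_response <- function(conc, ratio,
                         family = c("quad_weighted_1_over_x", "linear_log",
                                    "quad_log"),
                         analyte = NULL, day = NULL) {
  family <- match.arg(family)
  stopifnot(length(conc) == length(ratio), all(is.finite(conc)),
            all(is.finite(ratio)), all(conc > 0))
  k <- length(unique(conc))
  npar <- if (family == "linear_log") 2L else 3L
  if (k < npar + 1L) {
    stop(sprintf("need at least %d distinct levels for %s, got %d",
                 npar + 1L, family, k))
  }
  if (family == "quad_weighted_1_over_x") {
    fit <- stats::lm(ratio ~ conc + I(conc^2), weights = 1 / conc)
    co <- stats::coef(fit)
  } else {
    if (any(ratio <= 0)) stop("log-scale families need strictly positive ratios")
    lx <- log10(conc)
    ly <- log10(ratio)
    fit <- if (family == "linear_log") stats::lm(ly ~ lx)
           else stats::lm(ly ~ lx + I(lx^2))
    co <- stats::coef(fit)
  }
  if (any(!is.finite(co))) {
    stop("singular design: calibration levels do not identify the model")
  }
  coefficients <- c(a = unname(co[1]), b = unname(co[2]),
                    c = if (length(co) > 2) unname(co[3]) else 0)
  structure(
    list(family = family, coefficients = coefficients,
         domain = range(conc), k = k, analyte = analyte, day = day),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", x$family,
      if (!is.null(x$analyte)) paste0("[", x$analyte, "]") else "", "\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g\n",
              x$coefficients["a"], x$coefficients["b"], x$coefficients["c"]))
  cat(sprintf("  domain %g - %g ng/mL (k = %d)\n",
              x$domain[1], x$domain[2], x$k))
  invisible(x)
}

#' Predicted response at given concentrations
#'
#' @param object a `calibration_fit`.
#' @param conc concentrations (ng/mL), > 0.
#' @param ... unused.
#' @return Predicted area ratios.
#' @export
predict.calibration_fit <- function(object, conc, ...) {
  co <- object$coefficients
  switch(object$family,
    quad_weighted_1_over_x = co["a"] + co["b"] * conc + co["c"] * conc^2,
    linear_log = 10^(co["a"] + co["b"] * log10(conc)),
    quad_log = 10^(co["a"] + co["b"] * log10(conc) + co["c"] * log10(conc)^2)
  ) |> unname()
}

# headroom multiplier for the admissible inverse-prediction domain: supports
# above-ULOQ extrapolation (e.g. 5000 ng/mL on a 2000 ng/mL curve) while
# still failing loudly on quadratic fold-back
INVERSE_HEADROOM <- 2.5

inversion_error <- function(fit, ratio, roots, n_admissible = 0L) {
  stop(structure(
    class = c("msval_inversion_error", "error", "condition"),
    list(message = sprintf(
           paste0("response %.6g is not invertible for %s fit on domain ",
                  "%g-%g ng/mL: %d admissible root(s) [candidates: %s]"),
           ratio, fit$family, fit$domain[1], fit$domain[2], n_admissible,
           if (length(roots)) paste(signif(roots, 6), collapse = ", ")
           else "none"),
         call = sys.call(-1), roots = roots)
  ))
}

solve_quadratic <- function(cc, bb, aa) {
  # roots of cc u^2 + bb u + aa = 0 (possibly degenerate to linear)
  if (abs(cc) < 1e-14 * max(abs(bb), 1)) {
    if (bb == 0) return(numeric(0))
    return(-aa / bb)
  }
  disc <- bb^2 - 4 * cc * aa
  if (disc < 0) return(numeric(0))
  sq <- sqrt(disc)
  c((-bb + sq) / (2 * cc), (-bb - sq) / (2 * cc))
}

#' Inverse prediction (back-calculation) of concentration from response
#'
#' Inverts the fitted response model at each observed area ratio. For the
#' linear log model the inverse is in closed form. For the quadratic families
#' both roots are examined and exactly one must fall inside the fit domain
#' extended by the dilution headroom (/2.5 below, x2.5 above); anything else
#' raises a condition of class `msval_inversion_error` carrying the candidate
#' roots. Concentrations outside the fitted domain proper (but inside the
#' headroom) are returned with an `out_of_range` attribute flag, supporting
#' above-ULOQ extrapolation checks.
#'
#' @param fit a `calibration_fit`.
#' @param ratio observed area ratio(s), > 0.
#' @return Numeric vector of concentrations (ng/mL) with logical attribute
#'   `out_of_range` marking values outside the fitted domain.
#' @export
back_calculate <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"), all(is.finite(ratio)))
  co <- fit$coefficients
  lo <- fit$domain[1] / INVERSE_HEADROOM
  hi <- fit$domain[2] * INVERSE_HEADROOM
  one <- function(y) {
    if (fit$family == "linear_log") {
      if (y <= 0) inversion_error(fit, y, numeric(0))
      return(10^((log10(y) - co["a"]) / co["b"]))
    }
    if (fit$family == "quad_weighted_1_over_x") {
      roots <- solve_quadratic(co["c"], co["b"], co["a"] - y)
    } else { # quad_log, roots in u = log10(x)
      if (y <= 0) inversion_error(fit, y, numeric(0))
      roots <- 10^solve_quadratic(co["c"], co["b"], co["a"] - log10(y))
    }
    roots <- roots[is.finite(roots) & roots > 0]
    # small relative slack so responses at exactly the headroom edge invert
    admissible <- roots[roots >= lo * (1 - 1e-9) & roots <= hi * (1 + 1e-9)]
    if (length(admissible) != 1L) {
      inversion_error(fit, y, roots, length(admissible))
    }
    admissible
  }
  conc <- unname(vapply(ratio, one, numeric(1)))
  attr(conc, "out_of_range") <- conc < fit$domain[1] | conc > fit$domain[2]
  conc
}

#' Trim a calibration level grid to a retained range
#'
#' @param levels candidate calibration levels (ng/mL).
#' @param lloq,uloq retained range bounds; both must be members of `levels`.
#' @return Sorted retained levels; the retained count is their length `k`.
#' @export
trim_range <- function(levels, lloq, uloq = max(levels)) {
  stopifnot(lloq <= uloq)
  if (!lloq %in% levels || !uloq %in% levels) {
    stop("lloq and uloq must be members of the level grid")
  }
  kept <- sort(unique(levels[levels >= lloq & levels <= uloq]))
  if (length(kept) == 0L) stop("no calibration level inside the range")
  kept
}

#' Linearity of trueness: experimental versus nominal concentration
#'
#' Ordinary least squares of back-calculated (experimental) concentrations on
#' nominal concentrations, pooled over validation days. A truthful method
#' gives slope 1, intercept 0 and R^2 near 1.
#'
#' @param nominal nominal concentrations (ng/mL).
#' @param measured back-calculated concentrations (ng/mL).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linearity_of_trueness <- function(nominal, measured) {
  stopifnot(length(nominal) == length(measured))
  if (length(unique(nominal)) < 3L) {
    stop("need at least 3 distinct nominal levels")
  }
  fit <- stats::lm(measured ~ nominal)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((measured - mean(measured))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (sst > 0) 1 - sse / sst else NA_real_)
}

#' Integrity to dilution
#'
#' Checks that samples above the calibration range can be diluted into it:
#' measured concentrations are multiplied back by the dilution factor and
#' compared with the nominal pre-dilution concentration.
#'
#' @param measured measured (post-dilution) concentrations (ng/mL).
#' @param factor dilution factor, > 1 (e.g. 10 for a 10-fold dilution).
#' @param nominal nominal pre-dilution concentration (ng/mL).
#' @return List with `bias` (% of nominal), `rsd` (% across replicates) and
#'   the corrected concentrations.
#' @export
dilution_integrity <- function(measured, factor, nominal) {
  stopifnot(factor > 1, nominal > 0, length(measured) >= 1)
  corrected <- measured * factor
  list(bias = (mean(corrected) - nominal) / nominal * 100,
       rsd = stats::sd(corrected) / mean(corrected) * 100,
       corrected = corrected)
}

#' Solution-preparation dilution arithmetic
#'
#' Concentration of a working solution after an f-fold dilution (e.g. an
#' ISTD working solution at 2000 ng/mL diluted 50-fold gives 40 ng/mL).
#'
#' @param conc starting concentration.
#' @param factor fold dilution, >= 1.
#' @return Diluted concentration, same units.
#' @export
dilute_concentration <- function(conc, factor) {
  stopifnot(factor >= 1, all(conc >= 0))
  conc / factor
}

#' Serialize a calibration fit to a structured text file
#'
#' @param fit a `calibration_fit`.
#' @param path file path (YAML).
#' @return `write_calibration_fit()` returns `path` invisibly;
#'   `read_calibration_fit()` returns the fit.
#' @export
write_calibration_fit <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  yaml::write_yaml(list(
    family = fit$family,
    coefficients = as.list(fit$coefficients),
    domain = as.numeric(fit$domain),
    k = fit$k, analyte = fit$analyte, day = fit$day
  ), path)
  invisible(path)
}

#' @rdname write_calibration_fit
#' @export
read_calibration_fit <- function(path) {
  x <- yaml::read_yaml(path)
  structure(
    list(family = x$family,
         coefficients = c(a = x$coefficients$a, b = x$coefficients$b,
                          c = x$coefficients$c),
         domain = unlist(x$domain), k = x$k,
         analyte = x$analyte, day = x$day),
    class = "calibration_fit"
  )
}
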