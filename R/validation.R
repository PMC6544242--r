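#' Repeatability and between-day variance components
#'
#' One-way random-effects ANOVA with day as the random factor, on the
#' back-calculated concentrations of one validation level measured over p
#' days with n replicates per day (balanced design):
#' `MSW = sum_j sum_r (z_jr - mean_j)^2 / (p (n - 1))`,
#' `MSB = n sum_j (mean_j - grand_mean)^2 / (p - 1)`,
#' repeatability variance `s_r^2 = MSW` and between-day variance
#' `s_B^2 = max(0, (MSB - MSW) / n)` (negative estimates truncate to zero).
#' Intermediate-precision variance is their sum.
#'
#' @param z back-calculated concentrations (ng/mL), one value per injection.
#' @param day parallel vector of day indices.
#' @return List with `grand_mean`, `s_r2`, `s_B2`, `s_IT2`, the raw
#'   (untruncated) `s_B2_raw`, the mean squares `msw` and `msb`, and the
#'   design sizes `p`, `n`.
#' @export
variance_components <- function(z, day) {
  stopifnot(length(z) == length(day), all(is.finite(z)))
  day <- as.factor(day)
  counts <- table(day)
  p <- length(counts)
  if (p < 2L) stop("between-day variance needs at least 2 days (p >= 2)")
  if (length(unique(as.integer(counts))) != 1L) {
    stop("unbalanced design: replicate counts per day differ (",
         paste(counts, collapse = ", "), ")")
  }
  n <- as.integer(counts[1])
  if (n < 2L) stop("repeatability needs at least 2 replicates per day (n >= 2)")
  day_means <- tapply(z, day, mean)
  grand_mean <- mean(z)
  msw <- sum((z - day_means[day])^2) / (p * (n - 1))
  msb <- n * sum((day_means - grand_mean)^2) / (p - 1)
  s_r2 <- msw
  s_B2_raw <- (msb - msw) / n
  s_B2 <- max(0, s_B2_raw)
  list(grand_mean = grand_mean, s_r2 = s_r2, s_B2 = s_B2,
       s_IT2 = s_r2 + s_B2, s_B2_raw = s_B2_raw,
       msw = msw, msb = msb, p = p, n = n)
}

#' Trueness as percent of nominal
#'
#' @param grand_mean mean measured concentration (ng/mL).
#' @param nominal reference nominal concentration (ng/mL), > 0.
#' @return Trueness in percent (100 = unbiased).
#' @export
trueness <- function(grand_mean, nominal) {
  stopifnot(all(nominal > 0))
  grand_mean / nominal * 100
}

#' Precision as RSD of the nominal concentration
#'
#' Precision components are reported as relative standard deviations with
#' the reference nominal concentration in the denominator (not the observed
#' mean).
#'
#' @param s2 variance (ng/mL)^2, >= 0.
#' @param nominal reference nominal concentration (ng/mL), > 0.
#' @return RSD in percent.
#' @export
precision_rsd <- function(s2, nominal) {
  stopifnot(all(s2 >= 0), all(nominal > 0))
  100 * sqrt(s2) / nominal
}

#' Beta-expectation tolerance interval (Mee, Satterthwaite d.f.)
#'
#' The interval expected to contain a proportion beta of future single
#' measurements, from the two variance components of a balanced p x n
#' design. With `R = s_B^2 / s_r^2`:
#' `B^2 = (R + 1) / (n R + 1)`,
#' Satterthwaite degrees of freedom
#' `nu = (R + 1)^2 / [ (R + 1/n)^2 / (p - 1) + (1 - 1/n) / (p n) ]`,
#' and half-width
#' `t(nu; (1 + beta)/2) * s_IT * sqrt(1 + 1/(p n B^2))`
#' around the grand mean. When `s_r^2 = 0` with `s_B^2 > 0` the R -> Inf
#' limit is used (`B^2 = 1/n`, `nu = p - 1`); when both components are zero
#' the interval degenerates to the point.
#'
#' @param grand_mean grand mean (ng/mL).
#' @param s_r2 repeatability variance.
#' @param s_B2 between-day variance.
#' @param p number of days (>= 2).
#' @param n replicates per day (>= 2).
#' @param beta expectation proportion in (0, 1), default 0.90.
#' @return Numeric `c(low, high)`.
#' @export
beta_eti <- function(grand_mean, s_r2, s_B2, p, n, beta = 0.90) {
  stopifnot(beta > 0, beta < 1, p >= 2, n >= 2, s_r2 >= 0, s_B2 >= 0)
  s_IT2 <- s_r2 + s_B2
  if (s_IT2 == 0) return(c(low = grand_mean, high = grand_mean))
  if (s_r2 == 0) {
    B2 <- 1 / n
    nu <- p - 1
  } else {
    R <- s_B2 / s_r2
    B2 <- (R + 1) / (n * R + 1)
    nu <- (R + 1)^2 / ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  }
  half <- stats::qt((1 + beta) / 2, df = nu) * sqrt(s_IT2) *
    sqrt(1 + 1 / (p * n * B2))
  c(low = grand_mean - half, high = grand_mean + half)
}

#' Validation summary for one concentration level
#'
#' Combines [variance_components()], [trueness()], [precision_rsd()] and
#' [beta_eti()] for the p x n back-calculated concentrations of one
#' validation level.
#'
#' @inheritParams variance_components
#' @param nominal nominal level concentration (ng/mL).
#' @param beta expectation proportion of the tolerance interval.
#' @return One-row tibble with nominal, p, n, grand mean, trueness %,
#'   variance components, RSDs and ETI bounds (absolute ng/mL and relative
#'   % of nominal).
#' @export
level_validation <- function(z, day, nominal, beta = 0.90) {
  vc <- variance_components(z, day)
  eti <- beta_eti(vc$grand_mean, vc$s_r2, vc$s_B2, vc$p, vc$n, beta)
  tibble::tibble(
    nominal = nominal, p = vc$p, n = vc$n,
    grand_mean = vc$grand_mean,
    trueness = trueness(vc$grand_mean, nominal),
    s_r2 = vc$s_r2, s_B2 = vc$s_B2, s_IT2 = vc$s_IT2,
    rsd_repeat = precision_rsd(vc$s_r2, nominal),
    rsd_intermediate = precision_rsd(vc$s_IT2, nominal),
    eti_low = eti[["low"]], eti_high = eti[["high"]],
    rel_eti_low = (eti[["low"]] - nominal) / nominal * 100,
    rel_eti_high = (eti[["high"]] - nominal) / nominal * 100
  )
}

#' Accuracy (total-error) profile over the validation levels
#'
#' Assembles per-level validation results into the accuracy profile: relative
#' bias and relative tolerance-interval bounds per level (in % of nominal),
#' the per-level total error `max(|rel_low|, |rel_high|)`, the compliance of
#' each level with the acceptance limits +/- lambda, and the interpolated
#' LLOQ/ULOQ (see [determine_limits()]).
#'
#' @param levels tibble of [level_validation()] rows (any order).
#' @param beta expectation proportion used for the intervals (metadata).
#' @param lambda acceptance limit in percent.
#' @param mode `"relative"` (limits as % of nominal; interpolation on
#'   log10 concentration) or `"absolute"` (limits in concentration units;
#'   interpolation on concentration).
#' @param analyte optional label.
#' @return An object of class `accuracy_profile`: the ordered level table
#'   (with `total_error` and `within` flags), `lloq`, `uloq`, `valid`
#'   (TRUE when the whole designed range is compliant) and the parameters.
#' @export
accuracy_profile <- function(levels, beta = 0.90, lambda = 30,
                             mode = c("relative", "absolute"),
                             analyte = NULL) {
  mode <- match.arg(mode)
  levels <- dplyr::arrange(tibble::as_tibble(levels), .data$nominal)
  if (nrow(levels) < 2L) stop("an accuracy profile needs at least 2 levels")
  levels$total_error <- pmax(abs(levels$rel_eti_low), abs(levels$rel_eti_high))
  levels$within <- levels$rel_eti_low >= -lambda & levels$rel_eti_high <= lambda
  lim <- determine_limits(levels, lambda = lambda, mode = mode)
  structure(
    list(analyte = analyte, beta = beta, lambda = lambda, mode = mode,
         levels = levels, lloq = lim$lloq, uloq = lim$uloq,
         valid = all(levels$within)),
    class = "accuracy_profile"
  )
}

#' @export
print.accuracy_profile <- function(x, ...) {
  cat("<accuracy_profile>",
      if (!is.null(x$analyte)) paste0("[", x$analyte, "] ") else "",
      sprintf("beta = %g, lambda = %g%%, mode = %s\n", x$beta, x$lambda,
              x$mode))
  print(as.data.frame(x$levels[, c("nominal", "trueness", "rsd_repeat",
                                   "rsd_intermediate", "rel_eti_low",
                                   "rel_eti_high", "total_error", "within")]),
        digits = 4, row.names = FALSE)
  cat(sprintf("  LLOQ = %.4g ng/mL, ULOQ = %.4g ng/mL, range %s\n",
              x$lloq, x$uloq,
              if (x$valid) "fully validated" else "partially validated"))
  invisible(x)
}

# abscissa where a linearly interpolated bound crosses its acceptance limit,
# between levels i (non-compliant) and j (compliant)
interpolate_crossing <- function(levels, i, j, lambda, mode) {
  xi <- levels$nominal[i]; xj <- levels$nominal[j]
  cross_one <- function(vi, vj, li, lj, ui, uj) {
    # solve (v - l)(t) = 0 with linear interpolation in t on the chosen axis
    gi <- vi - li; gj <- vj - lj
    if (gi == gj) return(NA_real_)
    t <- gi / (gi - gj)
    ui + t * (uj - ui)
  }
  if (mode == "relative") {
    ui <- log10(xi); uj <- log10(xj)
    cand <- c(
      if (levels$rel_eti_low[i] < -lambda)
        cross_one(levels$rel_eti_low[i], levels$rel_eti_low[j],
                  -lambda, -lambda, ui, uj),
      if (levels$rel_eti_high[i] > lambda)
        cross_one(levels$rel_eti_high[i], levels$rel_eti_high[j],
                  lambda, lambda, ui, uj)
    )
    10^cand
  } else {
    cand <- c(
      if (levels$eti_low[i] < xi * (1 - lambda / 100))
        cross_one(levels$eti_low[i], levels$eti_low[j],
                  xi * (1 - lambda / 100), xj * (1 - lambda / 100), xi, xj),
      if (levels$eti_high[i] > xi * (1 + lambda / 100))
        cross_one(levels$eti_high[i], levels$eti_high[j],
                  xi * (1 + lambda / 100), xj * (1 + lambda / 100), xi, xj)
    )
    cand
  }
}

#' Quantification limits from an accuracy profile
#'
#' The LLOQ (ULOQ) is the lowest (highest) concentration at which both
#' tolerance-interval bounds stay inside the acceptance limits. When the
#' crossing falls between two adjacent levels, the violating bound is
#' interpolated linearly -- against log10 concentration in relative mode,
#' against concentration (with the +/- lambda limits as straight lines in
#' concentration units) in absolute mode -- and the limit is placed at the
#' crossing abscissa. When several bounds violate, the crossing closest to
#' the compliant region wins (both bounds must comply at the limit).
#'
#' @param levels ordered level table with `nominal`, `rel_eti_low`,
#'   `rel_eti_high`, `eti_low`, `eti_high` columns.
#' @param lambda acceptance limit in percent.
#' @param mode `"relative"` or `"absolute"` (see [accuracy_profile()]).
#' @return List with `lloq` and `uloq` (ng/mL).
#' @export
determine_limits <- function(levels, lambda, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  levels <- dplyr::arrange(tibble::as_tibble(levels), .data$nominal)
  ok <- levels$rel_eti_low >= -lambda & levels$rel_eti_high <= lambda
  if (!any(ok)) {
    cond <- structure(
      class = c("msval_no_valid_level", "error", "condition"),
      list(message = paste0("no level complies with the +/-", lambda,
                            "% acceptance limits"),
           call = sys.call(-1), profile = levels))
    stop(cond)
  }
  # widest contiguous compliant run; ties resolved toward lower concentrations
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  okruns <- which(runs$values)
  best <- okruns[which.max(runs$lengths[okruns])]
  i0 <- starts[best]; i1 <- ends[best]

  lloq <- levels$nominal[i0]
  if (i0 > 1L) {
    cand <- interpolate_crossing(levels, i0 - 1L, i0, lambda, mode)
    cand <- cand[is.finite(cand)]
    if (length(cand) > 0L) lloq <- max(cand)
  }
  uloq <- levels$nominal[i1]
  if (i1 < nrow(levels)) {
    cand <- interpolate_crossing(levels, i1 + 1L, i1, lambda, mode)
    cand <- cand[is.finite(cand)]
    if (length(cand) > 0L) uloq <- min(cand)
  }
  list(lloq = lloq, uloq = uloq)
}

#' Monte-Carlo coverage of the beta-expectation tolerance interval
#'
#' Replays the validation experiment under the two-component lognormal noise
#' model: for each replay, p days x n replicates are drawn with multiplicative
#' day effects (CV `cv_between`) and residuals (CV `cv_repeat`), the interval
#' is computed via [variance_components()] and [beta_eti()], one independent
#' future observation is drawn from the same model, and its inclusion is
#' recorded. The mean inclusion rate estimates the interval's expectation
#' coverage and should match beta.
#'
#' @param p,n design sizes.
#' @param cv_repeat,cv_between noise CVs (fractions).
#' @param beta expectation proportion.
#' @param n_replays number of Monte-Carlo replays.
#' @param nominal nominal concentration of the simulated level.
#' @param seed integer seed.
#' @return Empirical coverage (fraction in [0, 1]).
#' @export
eti_coverage <- function(p = 3, n = 3, cv_repeat = 0.05, cv_between = 0.05,
                         beta = 0.90, n_replays = 10000, nominal = 100,
                         seed = 1L) {
  sig_r <- lognorm_sigma(cv_repeat)
  sig_b <- lognorm_sigma(cv_between)
  set.seed(seed)
  day_idx <- rep(seq_len(p), each = n)
  inside <- logical(n_replays)
  for (b in seq_len(n_replays)) {
    d <- stats::rnorm(p, 0, sig_b)
    z <- nominal * exp(d[day_idx] + stats::rnorm(p * n, 0, sig_r))
    vc <- variance_components(z, day_idx)
    eti <- beta_eti(vc$grand_mean, vc$s_r2, vc$s_B2, p, n, beta)
    future <- nominal * exp(stats::rnorm(1, 0, sig_b) +
                              stats::rnorm(1, 0, sig_r))
    inside[b] <- future >= eti[["low"]] && future <= eti[["high"]]
  }
  mean(inside)
}
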