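#' Chromatographic signal-to-noise with peak-to-peak noise
#'
#' Estimates S/N for a peak in a chromatogram following the peak-to-peak
#' convention: the noise is the max-minus-min intensity excursion in a
#' baseline window of at least 30 s immediately before or after the peak --
#' both sides are evaluated where available and the more intense (larger)
#' noise is selected, which is the conservative choice. The peak height is
#' the maximum intensity inside the peak window minus the local baseline,
#' taken as the median of the selected noise window.
#'
#' @param chrom a `chromatogram` (see [simulate_chromatogram()]) or a list
#'   with numeric `times` (s) and `intensities`.
#' @param peak_window numeric `c(start, end)` in seconds bracketing the peak.
#' @param noise_window length of the baseline window in seconds (>= 30 by
#'   convention).
#' @return List of class `sn_estimate`: `peak_height`, `noise_pp`,
#'   `sn_ratio`, and the chosen `window` (start, end, side).
#' @export
signal_to_noise <- function(chrom, peak_window, noise_window = 30) {
  stopifnot(length(peak_window) == 2L, peak_window[1] < peak_window[2],
            noise_window >= 30)
  t <- chrom$times; y <- chrom$intensities
  in_peak <- t >= peak_window[1] & t <= peak_window[2]
  if (!any(in_peak)) stop("peak window contains no data points")
  windows <- list(
    before = c(peak_window[1] - noise_window, peak_window[1]),
    after = c(peak_window[2], peak_window[2] + noise_window)
  )
  est <- lapply(names(windows), function(side) {
    w <- windows[[side]]
    if (w[1] < min(t) || w[2] > max(t)) return(NULL)
    sel <- t >= w[1] & t <= w[2]
    list(side = side, window = w, noise_pp = max(y[sel]) - min(y[sel]),
         baseline = stats::median(y[sel]))
  })
  est <- Filter(Negate(is.null), est)
  if (length(est) == 0L) {
    stop("no ", noise_window, " s baseline window available on either side ",
         "of the peak")
  }
  pick <- est[[which.max(vapply(est, `[[`, numeric(1), "noise_pp"))]]
  if (pick$noise_pp <= 0) {
    stop("peak-to-peak noise is zero: signal-to-noise is undefined on a ",
         "noise-free trace")
  }
  height <- max(y[in_peak]) - pick$baseline
  structure(
    list(peak_height = height, noise_pp = pick$noise_pp,
         sn_ratio = height / pick$noise_pp,
         window = list(start = pick$window[1], end = pick$window[2],
                       side = pick$side)),
    class = "sn_estimate"
  )
}

#' @export
print.sn_estimate <- function(x, ...) {
  cat(sprintf("<sn_estimate> height %.3g / noise(p-p) %.3g = S/N %.3g (%s)\n",
              x$peak_height, x$noise_pp, x$sn_ratio, x$window$side))
  invisible(x)
}

#' Limit of detection from a signal-to-noise scan
#'
#' The LOD in a given matrix is the lowest tested concentration whose peak
#' reaches S/N >= 3 (or another threshold).
#'
#' @param scan tibble with columns `matrix`, `level` (ng/mL) and `sn_ratio`.
#' @param threshold minimal S/N, default 3.
#' @return Tibble with one row per matrix: `lod` (NA when no level reaches
#'   the threshold) and the threshold used.
#' @export
lod_from_scan <- function(scan, threshold = 3) {
  scan <- tibble::as_tibble(scan)
  stopifnot(all(c("matrix", "level", "sn_ratio") %in% names(scan)))
  dplyr::summarise(
    dplyr::group_by(scan, .data$matrix),
    lod = if (any(.data$sn_ratio >= threshold))
            min(.data$level[.data$sn_ratio >= threshold]) else NA_real_,
    threshold = threshold, .groups = "drop")
}

#' One-sided Student t confidence factor
#'
#' The t quantile used by the instrument-detection-limit formula: the
#' one-sided Student t value at the given confidence level with n - 1
#' degrees of freedom (2.821 for n = 10 replicates at 99%).
#'
#' @param n_replicates number of replicate injections (>= 2).
#' @param confidence one-sided confidence level in (0, 1), default 0.99.
#' @return The t factor.
#' @export
t_confidence_factor <- function(n_replicates, confidence = 0.99) {
  stopifnot(n_replicates >= 2, confidence > 0, confidence < 1)
  stats::qt(confidence, df = n_replicates - 1)
}

#' Instrument detection limit from replicate-injection precision
#'
#' `IDL = t_factor x (RSD / 100) x injected amount`, where the RSD is the
#' peak-area precision over the replicate injections of a standard at 2--5
#' times the expected detection limit, and the t factor is
#' [t_confidence_factor()] (2.821 for 10 replicates at 99% confidence).
#'
#' @param rsd_percent peak-area RSD over the replicate injections, in
#'   percent, > 0.
#' @param injected_amount injected amount; the result has the same units.
#' @param n_replicates number of replicate injections.
#' @param confidence one-sided confidence level.
#' @return The detection limit in the units of `injected_amount`.
#' @export
idl <- function(rsd_percent, injected_amount, n_replicates = 10,
                confidence = 0.99) {
  if (any(rsd_percent <= 0)) {
    stop("rsd_percent must be positive (a zero-RSD series carries no ",
         "precision information)")
  }
  t_confidence_factor(n_replicates, confidence) * rsd_percent / 100 *
    injected_amount
}

#' IDL from raw replicate peak areas
#'
#' Convenience wrapper computing the RSD of the replicate areas and applying
#' [idl()].
#'
#' @param areas replicate peak areas (>= 2 values).
#' @param injected_amount injected amount.
#' @param confidence one-sided confidence level.
#' @return List with `rsd_percent`, `n` and `idl`.
#' @export
idl_from_areas <- function(areas, injected_amount, confidence = 0.99) {
  stopifnot(length(areas) >= 2)
  rsd <- stats::sd(areas) / mean(areas) * 100
  list(rsd_percent = rsd, n = length(areas),
       idl = idl(rsd, injected_amount, length(areas), confidence))
}
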