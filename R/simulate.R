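#' Ground truth for the synthetic MRM data generator
#'
#' A `ground_truth` holds the generative parameters of the synthetic assay:
#' the true response curve of each analyte, the two precision components, the
#' per-donor matrix-effect and extraction-recovery factors, and the carryover
#' memory. Every generator in the package draws from these parameters, and
#' they are retained so that estimator output can be compared with the values
#' that produced the data.
#'
#' The noise model is multiplicative (lognormal): a measured response carries
#' a day effect with coefficient of variation `cv_between` and a residual
#' with coefficient of variation `cv_repeat`, both applied as
#' `exp(N(0, sigma))` with `sigma = sqrt(log(1 + cv^2))` so the lognormal CV
#' equals the stated value. The ISTD log-noise term is shared into the
#' analyte area (the two signals come from the same processed sample), so the
#' analyte/ISTD area ratio carries exactly the `cv_repeat`/`cv_between`
#' noise while raw areas are positively correlated.
#'
#' @param analytes character vector of analyte names.
#' @param response_coefficients numeric matrix with one row per analyte and
#'   columns `a`, `b`, `c`: the true response curve
#'   `ratio = a + b x + c x^2` in signal-ratio units versus ng/mL. A single
#'   row is recycled to all analytes.
#' @param cv_repeat intra-day (repeatability) coefficient of variation, as a
#'   fraction: either a single number (constant CV) or a data frame with
#'   columns `conc` and `cv` describing a concentration-dependent profile
#'   (interpolated linearly on log10 concentration, held constant beyond the
#'   stated range) -- real assays show much larger relative noise at the
#'   LLOQ than at mid-range.
#' @param cv_between inter-day coefficient of variation, same forms as
#'   `cv_repeat`.
#' @param istd_cv coefficient of variation of the ISTD area noise shared
#'   between analyte and ISTD signals.
#' @param donors data frame with columns `donor`, `matrix_class`
#'   (`"regular"` or `"lipemic"`), `matrix_factor` (multiplicative
#'   ionization factor, ~1) and `recovery_factor` (extraction recovery
#'   fraction, > 0).
#' @param istd_matrix_power exponent applied to the donor matrix and recovery
#'   factors for the ISTD signal: 1 means the ISTD tracks the analyte's
#'   suppression exactly (IS-normalization cancels it), 0 means the ISTD is
#'   unaffected. Default 0.8.
#' @param carryover_fraction fraction of the previous injection's area that
#'   appears in a following blank, in [0, 1).
#' @param istd_base_area nominal ISTD peak area (arbitrary units).
#' @param day_effects `"shared"` (one random day effect per analyte and day,
#'   common to all levels of that day) or `"per_level"` (independent day
#'   effects per level).
#' @param seed integer randomness seed.
#'
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(analytes,
                         response_coefficients = c(a = 5e-4, b = 0.025, c = -1.25e-6),
                         cv_repeat = 0.025,
                         cv_between = 0.02,
                         istd_cv = 0.02,
                         donors = default_donors(),
                         istd_matrix_power = 0.8,
                         carryover_fraction = 0,
                         istd_base_area = 2e5,
                         day_effects = c("shared", "per_level"),
                         seed = 42L) {
  day_effects <- match.arg(day_effects)
  if (is.null(dim(response_coefficients))) {
    response_coefficients <- matrix(response_coefficients, nrow = 1,
                                    dimnames = list(NULL, c("a", "b", "c")))
  }
  check_cv <- function(cv, what) {
    if (is.data.frame(cv)) {
      if (!all(c("conc", "cv") %in% names(cv)) || any(cv$cv < 0) ||
          any(cv$conc <= 0)) {
        stop(what, " profile needs positive conc and non-negative cv columns")
      }
    } else if (!(is.numeric(cv) && length(cv) == 1L && cv >= 0)) {
      stop(what, " must be a non-negative scalar or a conc/cv profile")
    }
    cv
  }
  cv_repeat <- check_cv(cv_repeat, "cv_repeat")
  cv_between <- check_cv(cv_between, "cv_between")
  response_coefficients <- as.matrix(response_coefficients)
  if (ncol(response_coefficients) != 3L) {
    stop("response_coefficients needs columns a, b, c")
  }
  if (nrow(response_coefficients) == 1L) {
    response_coefficients <-
      response_coefficients[rep(1L, length(analytes)), , drop = FALSE]
  }
  if (nrow(response_coefficients) != length(analytes)) {
    stop("one coefficient row per analyte required")
  }
  rownames(response_coefficients) <- analytes
  colnames(response_coefficients) <- c("a", "b", "c")
  stopifnot(istd_cv >= 0,
            carryover_fraction >= 0, carryover_fraction < 1,
            istd_base_area > 0)
  donors <- tibble::as_tibble(donors)
  stopifnot(all(c("donor", "matrix_class", "matrix_factor",
                  "recovery_factor") %in% names(donors)),
            all(donors$recovery_factor > 0),
            all(donors$matrix_factor > 0))
  structure(
    list(analytes = analytes,
         response_coefficients = response_coefficients,
         cv_repeat = cv_repeat, cv_between = cv_between, istd_cv = istd_cv,
         donors = donors, istd_matrix_power = istd_matrix_power,
         carryover_fraction = carryover_fraction,
         istd_base_area = istd_base_area,
         day_effects = day_effects, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @rdname ground_truth
#' @details `default_donors()` returns the seven-donor panel used throughout:
#'   five regular plasma donors and two pooled lipemic plasmas, with fixed
#'   matrix factors spread around 1 (the lipemic donors suppressed more) and
#'   recoveries between 0.85 and 1.05.
#' @export
default_donors <- function() {
  tibble::tibble(
    donor = c("D1", "D2", "D3", "D4", "D5", "L1", "L2"),
    matrix_class = c(rep("regular", 5), rep("lipemic", 2)),
    matrix_factor = c(1.04, 0.97, 1.02, 0.95, 1.00, 0.88, 0.92),
    recovery_factor = c(0.98, 1.02, 0.95, 1.00, 0.97, 0.90, 0.93)
  )
}

#' Level-dependent precision profiles of the benzothiazinone panel
#'
#' Concentration-dependent CV profiles emulating the precision the validated
#' multiplex assay achieves: repeatability around 17% at the 0.1 ng/mL LLOQ,
#' falling steeply through the low calibrators and settling near 1.5--2% over
#' the mid and high range, with a small between-day component. Pass the two
#' elements as `cv_repeat` and `cv_between` to [ground_truth()].
#'
#' @return List with data frames `cv_repeat` and `cv_between` (columns
#'   `conc` ng/mL and `cv` fraction).
#' @export
pbtz169_cv_profiles <- function() {
  list(
    cv_repeat = data.frame(
      conc = c(0.1, 0.2, 0.5, 2, 150, 750, 1500),
      cv = c(0.17, 0.07, 0.035, 0.03, 0.02, 0.013, 0.016)),
    cv_between = data.frame(
      conc = c(0.1, 1, 150, 1500),
      cv = c(0.01, 0.022, 0.013, 0.01))
  )
}

cv_label <- function(cv) {
  if (is.data.frame(cv)) {
    sprintf("profile(%.3g-%.3g)", min(cv$cv), max(cv$cv))
  } else format(cv)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", length(x$analytes), "analyte(s)\n")
  cat("  cv_repeat:", cv_label(x$cv_repeat),
      " cv_between:", cv_label(x$cv_between),
      " istd_cv:", x$istd_cv, "\n")
  cat("  donors:", nrow(x$donors),
      sprintf("(%d regular, %d lipemic)",
              sum(x$donors$matrix_class == "regular"),
              sum(x$donors$matrix_class == "lipemic")), "\n")
  cat("  carryover_fraction:", x$carryover_fraction,
      " day_effects:", x$day_effects, " seed:", x$seed, "\n")
  invisible(x)
}

# lognormal sigma for a target coefficient of variation
lognorm_sigma <- function(cv) sqrt(log1p(cv^2))

# evaluate a CV specification (scalar or conc/cv profile) at concentrations x
cv_at <- function(cv, x) {
  if (!is.data.frame(cv)) return(rep(cv, length(x)))
  ord <- order(cv$conc)
  stats::approx(log10(cv$conc[ord]), cv$cv[ord], xout = log10(x),
                rule = 2)$y
}

# true response-curve value (area ratio) at concentration x
true_ratio <- function(truth, analyte, x) {
  co <- truth$response_coefficients[analyte, ]
  co[["a"]] + co[["b"]] * x + co[["c"]] * x^2
}

# split a combined quantifier area into per-transition rows according to the
# configured ion ratios; qualifier areas follow from the base product area
split_transition_areas <- function(design, analyte, combined_area) {
  tr <- design$transitions[design$transitions$analyte == analyte, ]
  qr <- tr$ion_ratio[tr$quantifier]
  base_area <- combined_area / sum(qr)
  area <- base_area * tr$ion_ratio
  tibble::tibble(
    transition = sprintf("%.1f>%.1f", tr$precursor_mz, tr$product_mz),
    product_mz = tr$product_mz,
    quantifier = tr$quantifier,
    peak_area = area
  )
}

#' Generate the calibration/validation design dataset
#'
#' Emits the full p-days x n-replicates x k-levels measurement table for
#' every analyte in the design, for both the calibration and the validation
#' level grids. Areas follow the multiplicative noise model of
#' [ground_truth()]: `area = curve(x) * exp(day effect) * exp(residual)`
#' (times the shared ISTD noise), with one day effect per analyte and day
#' (`day_effects = "shared"`) or one per level and day (`"per_level"`).
#'
#' @param design an [assay_design()].
#' @param truth a [ground_truth()].
#' @return A tibble in long measurement format, one row per MRM transition
#'   and injection, with columns `sample_id`, `role`, `analyte`,
#'   `transition`, `product_mz`, `quantifier`, `day`, `replicate`, `donor`,
#'   `matrix`, `nominal_conc`, `peak_area`, `istd_area`.
#' @export
generate_design_dataset <- function(design, truth) {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "ground_truth"))
  levels_by_role <- list(calibration = design$calibration_levels,
                         validation = design$validation_levels)
  if (any(unlist(levels_by_role) <= 0)) {
    stop("calibration/validation levels must be strictly positive")
  }
  p <- design$days; n <- design$replicates
  sig_i <- lognorm_sigma(truth$istd_cv)

  set.seed(truth$seed)
  out <- vector("list", 0L)
  for (analyte in intersect(design$analytes, truth$analytes)) {
    for (role in names(levels_by_role)) {
      levels <- levels_by_role[[role]]
      k <- length(levels)
      sig_b_lvl <- lognorm_sigma(cv_at(truth$cv_between, levels))
      # day effects: either one per day (scaled per level), or independent
      # per day x level
      if (truth$day_effects == "shared") {
        de <- outer(sig_b_lvl, stats::rnorm(p))
      } else {
        de <- matrix(stats::rnorm(p * k), nrow = k) * sig_b_lvl
      }
      grid <- expand.grid(replicate = seq_len(n), day = seq_len(p),
                          level_idx = seq_len(k))
      x <- levels[grid$level_idx]
      eps <- stats::rnorm(nrow(grid)) *
        lognorm_sigma(cv_at(truth$cv_repeat, x))
      eta <- stats::rnorm(nrow(grid), 0, sig_i)
      day_eff <- de[cbind(grid$level_idx, grid$day)]
      ratio <- true_ratio(truth, analyte, x) * exp(day_eff + eps)
      istd_area <- truth$istd_base_area * exp(eta)
      combined <- ratio * istd_area
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        tr <- split_transition_areas(design, analyte, combined[i])
        tibble::tibble(
          sample_id = sprintf("%s_%s_L%02d_d%d_r%d", substr(role, 1, 3),
                              gsub("[^A-Za-z0-9]", "", analyte),
                              grid$level_idx[i], grid$day[i], grid$replicate[i]),
          role = role, analyte = analyte,
          transition = tr$transition, product_mz = tr$product_mz,
          quantifier = tr$quantifier,
          day = grid$day[i], replicate = grid$replicate[i],
          donor = NA_character_, matrix = "citrate",
          nominal_conc = x[i], peak_area = tr$peak_area,
          istd_area = istd_area[i]
        )
      })
      out[[length(out) + 1L]] <- dplyr::bind_rows(rows)
    }
  }
  dplyr::bind_rows(out)
}

#' Generate Matuszewski matrix-effect sets A, B and C
#'
#' Set A holds neat (matrix-free) standards: the pure response at each level.
#' Set B holds post-extraction spiked plasma: set A response times the
#' donor's matrix factor. Set C holds pre-extraction spiked plasma: set B
#' times the donor's recovery factor. B and C are prepared in duplicate per
#' donor; the ISTD signal carries the donor factors raised to
#' `istd_matrix_power`.
#'
#' @inheritParams generate_design_dataset
#' @param levels concentrations of the three sets (ng/mL).
#' @param set_a_replicates replicates of the neat standards (reference mean).
#' @param duplicates replicate extractions per donor in sets B and C.
#' @return A measurement tibble with roles `setA`, `setB`, `setC` (combined
#'   quantifier areas; one row per injection and analyte).
#' @export
generate_matrix_sets <- function(design, truth, levels = c(10, 100, 1000),
                                 set_a_replicates = 3L, duplicates = 2L) {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "ground_truth"))
  sig_i <- lognorm_sigma(truth$istd_cv)
  donors <- truth$donors
  gpow <- truth$istd_matrix_power
  set.seed(truth$seed + 1L)
  out <- list()
  emit <- function(role, analyte, level, donor, matrix_class, replicate,
                   analyte_factor, istd_factor) {
    eps <- stats::rnorm(1, 0, lognorm_sigma(cv_at(truth$cv_repeat, level)))
    eta <- stats::rnorm(1, 0, sig_i)
    istd_area <- truth$istd_base_area * istd_factor * exp(eta)
    area <- true_ratio(truth, analyte, level) * truth$istd_base_area *
      analyte_factor * exp(eps + eta)
    tibble::tibble(
      sample_id = sprintf("%s_%s_%g_%s_r%d", role,
                          gsub("[^A-Za-z0-9]", "", analyte), level,
                          ifelse(is.na(donor), "neat", donor), replicate),
      role = role, analyte = analyte,
      transition = "combined", product_mz = NA_real_, quantifier = TRUE,
      day = 1L, replicate = replicate,
      donor = donor, matrix = matrix_class,
      nominal_conc = level, peak_area = area, istd_area = istd_area
    )
  }
  for (analyte in intersect(design$analytes, truth$analytes)) {
    for (level in levels) {
      for (r in seq_len(set_a_replicates)) {
        out[[length(out) + 1L]] <-
          emit("setA", analyte, level, NA_character_, "neat", r, 1, 1)
      }
      for (d in seq_len(nrow(donors))) {
        mf <- donors$matrix_factor[d]; rf <- donors$recovery_factor[d]
        for (r in seq_len(duplicates)) {
          out[[length(out) + 1L]] <-
            emit("setB", analyte, level, donors$donor[d],
                 donors$matrix_class[d], r, mf, mf^gpow)
          out[[length(out) + 1L]] <-
            emit("setC", analyte, level, donors$donor[d],
                 donors$matrix_class[d], r, mf * rf, (mf * rf)^gpow)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate an injection sequence with carryover memory
#'
#' Walks an ordered injection list. Non-blank injections produce their own
#' response area (with the usual repeatability noise); each blank inherits
#' `carryover_fraction` times the effective area of the immediately preceding
#' injection, so successive blanks decay multiplicatively
#' (second blank = fraction^2 of the source area).
#'
#' @inheritParams generate_design_dataset
#' @param injections data frame with columns `role` (`"blank"` or any
#'   non-blank role) and `nominal_conc` (ng/mL; 0 for blanks), in injection
#'   order; an optional `sample_id` column is preserved.
#' @param analyte analyte name (single).
#' @return A measurement tibble, one row per injection, with combined
#'   quantifier `peak_area` including carryover.
#' @export
generate_sequence_with_carryover <- function(design, truth, injections,
                                             analyte = design$analytes[[1]]) {
  stopifnot(inherits(design, "assay_design"), inherits(truth, "ground_truth"))
  injections <- tibble::as_tibble(injections)
  stopifnot(all(c("role", "nominal_conc") %in% names(injections)))
  set.seed(truth$seed + 2L)
  m <- nrow(injections)
  area <- numeric(m)
  memory <- 0
  for (i in seq_len(m)) {
    if (injections$role[i] == "blank") {
      area[i] <- truth$carryover_fraction * memory
    } else {
      xi <- injections$nominal_conc[i]
      area[i] <- true_ratio(truth, analyte, xi) * truth$istd_base_area *
        exp(stats::rnorm(1, 0, lognorm_sigma(cv_at(truth$cv_repeat, xi))))
    }
    memory <- area[i]
  }
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(injections)) injections$sample_id
                else sprintf("inj%03d", seq_len(m)),
    role = injections$role, analyte = analyte,
    transition = "combined", product_mz = NA_real_, quantifier = TRUE,
    day = 1L, replicate = seq_len(m),
    donor = NA_character_, matrix = "citrate",
    nominal_conc = injections$nominal_conc,
    peak_area = area, istd_area = truth$istd_base_area
  )
}

#' Simulate a chromatogram of Gaussian peaks over noisy baseline
#'
#' Builds an intensity trace on a fixed 0.2 s sampling grid: a constant
#' baseline, bounded uniform noise of stated peak-to-peak amplitude, and one
#' Gaussian per peak. Every peak must leave at least `noise_window` seconds
#' of peak-free trace on at least one side, since the downstream
#' signal-to-noise estimator needs such a window.
#'
#' @param peaks data frame with columns `rt` (apex, s), `height` (counts)
#'   and `sigma` (Gaussian SD, s).
#' @param noise_amplitude peak-to-peak amplitude of the uniform baseline
#'   noise (counts); 0 gives a noise-free trace.
#' @param baseline constant baseline level (counts).
#' @param duration trace length (s).
#' @param dt sampling interval (s); fixed default 0.2 s cycle time.
#' @param noise_window minimum clear window required next to each peak (s).
#' @param seed optional seed for the noise draw.
#' @return An object of class `chromatogram`: list with `times`,
#'   `intensities` and the `peaks` table.
#' @export
simulate_chromatogram <- function(peaks, noise_amplitude = 0, baseline = 0,
                                  duration = 240, dt = 0.2,
                                  noise_window = 30, seed = NULL) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("rt", "height", "sigma") %in% names(peaks)),
            all(peaks$sigma > 0), duration > 0, noise_amplitude >= 0)
  # peak-free intervals: outside rt +/- 4 sigma of every peak
  lo <- peaks$rt - 4 * peaks$sigma
  hi <- peaks$rt + 4 * peaks$sigma
  clear <- function(a, b) {
    if (a < 0 || b > duration || b - a < noise_window) return(FALSE)
    !any(pmax(a, lo) < pmin(b, hi))
  }
  for (i in seq_len(nrow(peaks))) {
    before <- clear(lo[i] - noise_window, lo[i])
    after <- clear(hi[i], hi[i] + noise_window)
    if (!before && !after) {
      stop(sprintf(paste0("peak at %.1f s has no %g s noise window on either",
                          " side within the %g s trace"),
                   peaks$rt[i], noise_window, duration))
    }
  }
  times <- seq(0, duration, by = dt)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_amplitude > 0) {
    stats::runif(length(times), -noise_amplitude / 2, noise_amplitude / 2)
  } else 0
  intensities <- baseline + noise
  for (i in seq_len(nrow(peaks))) {
    intensities <- intensities +
      peaks$height[i] * exp(-(times - peaks$rt[i])^2 / (2 * peaks$sigma[i]^2))
  }
  intensities <- pmax(intensities, 0)
  structure(list(times = times, intensities = intensities, peaks = peaks),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram>", length(x$times), "points,",
      max(x$times), "s,", nrow(x$peaks), "peak(s)\n")
  invisible(x)
}
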