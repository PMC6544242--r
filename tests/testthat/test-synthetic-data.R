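test_that("noise-free generation back-calculates to nominal at every level", {
  d <- mini_design()
  m <- generate_design_dataset(d, noise_free_truth(d))
  resp <- quantification_responses(m, d)
  for (an in d$analytes) {
    ra <- dplyr::filter(resp, analyte == an)
    calib <- dplyr::filter(ra, role == "calibration", day == 1)
    fit <- fit_response(calib$nominal_conc, calib$ratio,
                        "quad_weighted_1_over_x")
    val <- dplyr::filter(ra, role == "validation", day == 1)
    expect_equal(back_calculate(fit, val$ratio), val$nominal_conc,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("design dataset emits p x n x k calibration records per analyte", {
  d <- mini_design()
  m <- generate_design_dataset(d, mini_truth(d))
  injections <- dplyr::distinct(
    dplyr::filter(m, role == "calibration", analyte == "A1"),
    sample_id, day, replicate, nominal_conc)
  expect_identical(nrow(injections), 81L)  # 9 levels x 3 days x 3 replicates
  expect_error(
    generate_design_dataset(
      assay_design(mini_transitions(), calibration_levels = c(1, 10),
                   validation_levels = c(1, 10)) |>
        (\(x) { x$calibration_levels <- c(-1, 10); x })(),
      mini_truth()),
    "positive")
})

test_that("per-level empirical precision recovers the generative CVs", {
  d <- mini_design(days = 50, replicates = 10)
  gt <- mini_truth(d, cv_repeat = 0.05, cv_between = 0.05,
                   day_effects = "per_level")
  m <- generate_design_dataset(d, gt)
  resp <- dplyr::filter(quantification_responses(m, d),
                        analyte == "A1", role == "calibration")
  est <- dplyr::bind_rows(lapply(split(resp, resp$nominal_conc), function(g) {
    vc <- variance_components(g$ratio / mean(g$ratio), g$day)
    tibble::tibble(cv_r = sqrt(vc$s_r2), cv_b = sqrt(vc$s_B2))
  }))
  # repeatability is tightly determined per level (p(n-1) = 450 df)
  expect_true(all(abs(est$cv_r / 0.05 - 1) < 0.10))
  # the between-day component has ~11% Monte-Carlo spread per level at
  # p = 50; the mean over 9 independent levels is the per-run estimate
  expect_lt(abs(mean(est$cv_b) / 0.05 - 1), 0.10)
})

test_that("identical seeds give bit-identical tables", {
  d <- mini_design()
  m1 <- generate_design_dataset(d, mini_truth(d))
  m2 <- generate_design_dataset(d, mini_truth(d))
  expect_identical(m1, m2)
  s1 <- generate_matrix_sets(d, mini_truth(d))
  s2 <- generate_matrix_sets(d, mini_truth(d))
  expect_identical(s1, s2)
})

test_that("matrix sets honour donor factors and replication counts", {
  d <- mini_design()
  # unity factors, no noise: ME deviation 0, ER = PE = 100 downstream
  donors1 <- default_donors()
  donors1$matrix_factor <- 1
  donors1$recovery_factor <- 1
  gt1 <- mini_truth(d, cv_repeat = 0, istd_cv = 0, donors = donors1)
  me <- compute_me_er_pe(generate_matrix_sets(d, gt1))
  expect_equal(me$me_mean_deviation, rep(0, nrow(me)), tolerance = 1e-10)
  expect_equal(me$er_mean, rep(100, nrow(me)), tolerance = 1e-10)
  expect_equal(me$pe_mean, rep(100, nrow(me)), tolerance = 1e-10)
  expect_equal(me$me_rsd, rep(0, nrow(me)), tolerance = 1e-10)

  # 5 regular donors x 2 duplicates = 10 measures, 2 lipemic x 2 = 4
  sets <- generate_matrix_sets(d, mini_truth(d))
  b <- dplyr::filter(sets, role == "setB", analyte == "A1",
                     nominal_conc == 10)
  expect_identical(sum(b$matrix == "regular"), 10L)
  expect_identical(sum(b$matrix == "lipemic"), 4L)

  # a single donor at matrix_factor 0.8 shows a -20% ME deviation
  donors2 <- donors1
  donors2$matrix_factor[donors2$donor == "D1"] <- 0.8
  gt2 <- mini_truth(d, cv_repeat = 0, istd_cv = 0, donors = donors2)
  sets2 <- generate_matrix_sets(d, gt2)
  a_mean <- mean(dplyr::filter(sets2, role == "setA", analyte == "A1",
                               nominal_conc == 100)$peak_area)
  d1 <- dplyr::filter(sets2, role == "setB", analyte == "A1",
                      nominal_conc == 100, donor == "D1")
  expect_equal(mean(d1$peak_area) / a_mean * 100 - 100, -20,
               tolerance = 1e-10)
})

test_that("carryover memory decays multiplicatively over blanks", {
  d <- mini_design()
  inj <- data.frame(
    role = c("calibration", "blank", "blank"),
    nominal_conc = c(2000, 0, 0))
  gt0 <- mini_truth(d, cv_repeat = 0, carryover_fraction = 0)
  m0 <- generate_sequence_with_carryover(d, gt0, inj)
  expect_equal(m0$peak_area[2:3], c(0, 0))

  gt <- mini_truth(d, cv_repeat = 0, carryover_fraction = 0.02)
  m <- generate_sequence_with_carryover(d, gt, inj)
  src <- m$peak_area[1]
  expect_equal(m$peak_area[2], 0.02 * src, tolerance = 1e-12)
  expect_equal(m$peak_area[3], 0.02^2 * src, tolerance = 1e-12)
})

test_that("simulated chromatograms respect sampling and noise-window rules", {
  # a 0.06 min-wide peak sampled at 0.2 s shows >= 18 points across it
  sigma <- 0.06 * 60 / (2 * sqrt(2 * log(2)))  # FWHM 3.6 s
  ch <- simulate_chromatogram(
    data.frame(rt = 180, height = 100, sigma = sigma),
    noise_amplitude = 0, duration = 240)
  fwhm <- ch$times[ch$intensities >= 50 * (1 - 1e-6)]
  expect_gte(length(fwhm), 18L)
  expect_equal(diff(ch$times)[1], 0.2)
  expect_true(all(ch$intensities >= 0))

  expect_error(
    simulate_chromatogram(data.frame(rt = 15, height = 10, sigma = 2),
                          duration = 30),
    "noise window")
})
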