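test_that("carryover percent of the LLOQ signal flags above threshold", {
  clean <- carryover_percent(0, 1000)
  expect_equal(clean$percent, 0)
  expect_false(clean$flagged)

  seen <- carryover_percent(350, 1000)
  expect_equal(seen$percent, 35)
  expect_true(seen$flagged)
  expect_true(seen$percent >= 20 && seen$percent <= 50)

  # interference below 30% of the LLOQ signal, same computation
  interf <- carryover_percent(280, 1000, threshold = 30)
  expect_lt(interf$percent, 30)
  expect_false(interf$flagged)
})

test_that("carryover flows from the generator through the percent rule", {
  d <- mini_design()
  gt <- mini_truth(d, cv_repeat = 0, carryover_fraction = 0)
  # fraction chosen so the blank lands at 35% of the LLOQ-level area
  inj <- data.frame(role = c("calibration", "blank"),
                    nominal_conc = c(2000, 0))
  seq0 <- generate_sequence_with_carryover(d, gt, inj, analyte = "A1")
  lloq_inj <- data.frame(role = "calibration", nominal_conc = 0.5)
  lloq_area <- generate_sequence_with_carryover(d, gt, lloq_inj,
                                                analyte = "A1")$peak_area
  frac <- 0.35 * lloq_area / seq0$peak_area[1]
  gt2 <- mini_truth(d, cv_repeat = 0, carryover_fraction = frac)
  seq2 <- generate_sequence_with_carryover(d, gt2, inj, analyte = "A1")
  res <- carryover_percent(seq2$peak_area[2], lloq_area)
  expect_equal(res$percent, 35, tolerance = 1e-9)
  expect_true(res$flagged)
})

test_that("ion ratios confirm within a relative 20% window", {
  ref <- c("344.1" = 1, "298.1" = 0.68)
  ok <- ion_ratio_confirm(c("344.1" = 1000, "298.1" = 680), ref)
  expect_equal(ok$deviation, 0)
  expect_true(ok$confirmed)

  off <- ion_ratio_confirm(c("344.1" = 1000, "298.1" = 680 * 1.25), ref)
  expect_false(off$confirmed)
  edge <- ion_ratio_confirm(c("344.1" = 1000, "298.1" = 680 * 1.19), ref)
  expect_true(edge$confirmed)

  expect_error(ion_ratio_confirm(c("344.1" = 0, "298.1" = 680), ref),
               "positive")
})

test_that("reference ion ratios equal the brute-force calibration mean", {
  set.seed(13)
  k <- 9
  calib <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
    base <- 1000 * i * exp(rnorm(1, 0, 0.05))
    qual_ratio <- 0.68 * exp(rnorm(1, 0, 0.03))
    tibble::tibble(sample_id = paste0("cal", i),
                   product_mz = c(344.1, 298.1),
                   peak_area = c(base, base * qual_ratio))
  }))
  ref <- reference_ion_ratios(calib, base_product = 344.1)
  manual <- vapply(seq_len(k), function(i) {
    a <- calib[calib$sample_id == paste0("cal", i), ]
    a$peak_area[a$product_mz == 298.1] / a$peak_area[a$product_mz == 344.1]
  }, numeric(1))
  expect_equal(unname(ref[["298.1"]]), mean(manual), tolerance = 1e-12)
  expect_equal(unname(ref[["344.1"]]), 1)
})

test_that("stability verdicts apply the 15/20 percent rules to both modes", {
  same <- stability_deviation(
    data.frame(condition = "bench 24h", value = c(99, 100, 101)),
    reference = 100)
  expect_equal(same$deviation, 0)
  expect_true(same$pass)

  degraded <- stability_deviation(
    data.frame(condition = "RT 24h", value = rep(70, 3)),
    reference = 100)
  expect_equal(degraded$deviation, -30)
  expect_false(degraded$pass)

  # the LLOQ widening rescues a -18% deviation
  lloq_ok <- stability_deviation(
    data.frame(condition = "FT x3", value = rep(0.082, 3)),
    reference = 0.1, lloq = TRUE)
  expect_false(abs(lloq_ok$deviation) <= 15)
  expect_true(lloq_ok$pass)

  # ratio mode: analyte/ISTD response ratios over time, same computation
  ratios <- data.frame(condition = rep(c("t0", "t24", "t48"), each = 3),
                       value = c(1.00, 1.02, 0.98, 0.93, 0.95, 0.94,
                                 0.80, 0.82, 0.81))
  t0_mean <- mean(ratios$value[ratios$condition == "t0"])
  verd <- stability_deviation(ratios, reference = t0_mean)
  manual <- vapply(split(ratios$value, ratios$condition), function(v) {
    (mean(v) - t0_mean) / t0_mean * 100
  }, numeric(1))
  expect_equal(sort(verd$deviation), sort(unname(manual)), tolerance = 1e-12)
  expect_identical(verd$pass[verd$condition == "t48"],
                   abs(manual[["t48"]]) <= 15)
})

test_that("alternate-matrix bias matches the trueness computation", {
  identical_qc <- anticoagulant_bias(
    data.frame(matrix = "EDTA", level = rep(c(10, 150), each = 3),
               conc = rep(c(10, 150), each = 3)))
  expect_equal(identical_qc$bias, c(0, 0))
  expect_true(all(identical_qc$pass))

  low_bias <- anticoagulant_bias(
    data.frame(matrix = "serum", level = rep(10, 3),
               conc = rep(8.1, 3)))
  expect_equal(low_bias$bias, -19)
  expect_false(low_bias$pass)

  set.seed(19)
  conc <- 150 * exp(rnorm(3, 0, 0.04))
  res <- anticoagulant_bias(data.frame(matrix = "heparin", level = 150,
                                       conc = conc))
  expect_equal(res$bias, trueness(mean(conc), 150) - 100, tolerance = 1e-12)
})

test_that("blood dilution correction reduces to the volume-ratio factor", {
  expect_equal(blood_dilution_correct(100, 10, 1), 110)
  expect_equal(blood_dilution_correct(1, 10, 1), 1.1)
  expect_equal(blood_dilution_correct(100, 10, 0), 100)
  expect_equal(blood_dilution_correct(c(464, 147, 13), 10, 1),
               c(464, 147, 13) * 1.1)
})

test_that("verdict rules are scale invariant and reproducible", {
  series <- data.frame(condition = rep(c("a", "b"), each = 3),
                       value = c(95, 97, 99, 70, 72, 71))
  v1 <- stability_deviation(series, reference = 100)
  series_scaled <- transform(series, value = value * 1e3)
  v2 <- stability_deviation(series_scaled, reference = 1e5)
  expect_identical(v1$pass, v2$pass)
  expect_equal(v1$deviation, v2$deviation, tolerance = 1e-12)
  v3 <- stability_deviation(series, reference = 100)
  expect_identical(v1, v3)

  c1 <- carryover_percent(350, 1000)
  c2 <- carryover_percent(3.5, 10)
  expect_identical(c1$flagged, c2$flagged)
  expect_equal(c1$percent, c2$percent)
})
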