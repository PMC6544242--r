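test_that("quantifier transitions combine additively with explicit errors", {
  areas <- c("344.1" = 700, "298.1" = 300)
  expect_equal(combine_quantifier_transitions(areas, c("344.1", "298.1")),
               1000)
  expect_equal(combine_quantifier_transitions(c("361.1" = 123.4), "361.1"),
               123.4)
  expect_error(combine_quantifier_transitions(areas, c("344.1", "318.0")),
               "318.0")
})

test_that("log-family fits recover exact coefficients on exact data", {
  x <- c(0.1, 0.5, 1, 5, 10, 100, 1000)
  y_lin <- 10^(0.1 + 1.0 * log10(x))
  f_lin <- fit_response(x, y_lin, "linear_log")
  expect_equal(unname(f_lin$coefficients), c(0.1, 1.0, 0), tolerance = 1e-12)

  y_quad <- 10^(0.2 + 0.9 * log10(x) - 0.015 * log10(x)^2)
  f_quad <- fit_response(x, y_quad, "quad_log")
  expect_equal(unname(f_quad$coefficients), c(0.2, 0.9, -0.015),
               tolerance = 1e-10)
  expect_identical(f_quad$k, 7L)

  expect_error(fit_response(rep(2, 8), rep(1.5, 8), "linear_log"),
               "distinct levels")
})

test_that("weighted quadratic fit matches a brute-force weighted-SSE search", {
  set.seed(11)
  x <- c(0.1, 0.2, 0.5, 1, 2, 50, 500, 1000, 2000)
  y <- (5e-4 + 0.025 * x - 1.25e-6 * x^2) * exp(rnorm(9, 0, 0.05))
  fit <- fit_response(x, y, "quad_weighted_1_over_x")
  wsse <- function(co) sum((1 / x) * (y - co[1] - co[2] * x - co[3] * x^2)^2)
  # refine a local grid around an independent optim start
  oracle <- optim(c(0, 0.02, 0), wsse, method = "BFGS",
                  control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(wsse(fit$coefficients) / wsse(oracle$par), 1 + 1e-6)
  expect_equal(unname(fit$coefficients), oracle$par, tolerance = 1e-4)
  # weighted normal equations hold at the solution
  r <- y - fit$coefficients[1] - fit$coefficients[2] * x -
    fit$coefficients[3] * x^2
  for (basis in list(rep(1, 9), x, x^2)) {
    expect_lt(abs(sum((1 / x) * r * basis)), 1e-8 * sum(abs(y)))
  }
})

test_that("predict and back_calculate are mutual inverses on the domain", {
  x <- c(0.1, 0.2, 0.5, 1, 2, 50, 500, 1000, 2000)
  y <- 5e-4 + 0.025 * x - 1.25e-6 * x^2
  grid <- 10^seq(log10(0.1), log10(2000), length.out = 60)
  for (fam in c("quad_weighted_1_over_x", "linear_log", "quad_log")) {
    fit <- fit_response(x, y, fam)
    tol <- if (fam == "linear_log") 1e-9 else 1e-6
    bc <- back_calculate(fit, predict(fit, grid))
    expect_equal(bc, grid, tolerance = tol, ignore_attr = TRUE)
  }
})

test_that("inverse prediction agrees with dense grid search to 0.1%", {
  x <- c(0.1, 0.2, 0.5, 1, 2, 50, 500, 1000, 2000)
  y <- 5e-4 + 0.025 * x - 1.25e-6 * x^2
  targets <- 10^seq(log10(0.15), log10(1800), length.out = 25)
  conc_grid <- 10^seq(log10(0.1 / 2.5), log10(2000 * 2.5),
                      length.out = 200001)
  for (fam in c("quad_weighted_1_over_x", "linear_log", "quad_log")) {
    fit <- fit_response(x, y, fam)
    ratios <- predict(fit, targets)
    pred_grid <- predict(fit, conc_grid)
    oracle <- vapply(ratios, function(r) {
      conc_grid[which.min(abs(pred_grid - r))]
    }, numeric(1))
    bc <- back_calculate(fit, ratios)
    expect_true(all(abs(bc / oracle - 1) < 1e-3))
  }
})

test_that("above-range responses extrapolate with a flag, fold-back errors", {
  x <- c(0.5, 1, 2, 50, 500, 1000, 2000)
  y <- 10^(-1.6 + 1.0 * log10(x) - 0.02 * log10(x)^2)  # monotone over range
  fit <- fit_response(x, y, "quad_log")
  ratio_5000 <- predict(fit, 5000)
  bc <- back_calculate(fit, ratio_5000)
  expect_equal(as.numeric(bc), 5000, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(attr(bc, "out_of_range"))
  in_range <- back_calculate(fit, predict(fit, 100))
  expect_false(attr(in_range, "out_of_range"))

  # response above the curve maximum of a folding quadratic: no real root
  yq <- 1 + 0.01 * x - 5e-6 * x^2
  fitq <- fit_response(x, yq, "quad_weighted_1_over_x")
  err <- tryCatch(back_calculate(fitq, 10), condition = identity)
  expect_s3_class(err, "msval_inversion_error")
  expect_true(!is.null(err$roots))
})

test_that("range trimming is idempotent, order-independent and counted", {
  levels <- c(0.1, 0.2, 0.5, 1, 2, 50, 500, 1000, 2000)
  k7 <- trim_range(levels, 0.5)
  expect_length(k7, 7L)
  expect_equal(k7[1], 0.5)
  expect_length(trim_range(levels, 0.1), 9L)
  expect_identical(trim_range(k7, 0.5), k7)
  expect_identical(trim_range(sample(levels), 0.5), k7)
  k1 <- trim_range(levels, 2000, 2000)
  expect_length(k1, 1L)
  expect_error(fit_response(k1, 50, "linear_log"), "distinct levels")
  expect_error(trim_range(levels, 0.3), "member")
})

test_that("linearity of trueness matches a direct covariance-ratio oracle", {
  nominal <- rep(c(0.5, 1, 2, 150, 750, 1500), each = 9)
  exact <- linearity_of_trueness(nominal, nominal)
  expect_equal(exact$slope, 1, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  set.seed(5)
  measured <- nominal * exp(rnorm(length(nominal), 0, 0.03))
  fit <- linearity_of_trueness(nominal, measured)
  slope_oracle <- sum((nominal - mean(nominal)) * (measured - mean(measured))) /
    sum((nominal - mean(nominal))^2)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(measured) - slope_oracle * mean(nominal),
               tolerance = 1e-9)
})

test_that("dilution integrity corrects tenfold dilutions within limits", {
  exact <- dilution_integrity(rep(500, 6), 10, 5000)
  expect_equal(exact$bias, 0)
  expect_equal(exact$rsd, 0)

  set.seed(9)
  measured <- 500 * exp(rnorm(6, 0, 0.02))
  res <- dilution_integrity(measured, 10, 5000)
  expect_lt(abs(res$bias), 15)
  expect_lt(res$rsd, 4)
  expect_equal(res$corrected, measured * 10)

  # the whole-blood correction is the same operation with factor 1.1
  expect_equal(blood_dilution_correct(100, 10, 1), 110)
})

test_that("calibration fits serialize losslessly to text", {
  x <- c(0.5, 1, 2, 50, 500, 1000, 2000)
  fit <- fit_response(x, 10^(0.1 + log10(x)), "quad_log", analyte = "A1",
                      day = 2L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_calibration_fit(fit, path)
  fit2 <- read_calibration_fit(path)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_identical(fit2$family, fit$family)
  expect_equal(fit2$domain, fit$domain)
  expect_identical(fit2$analyte, "A1")
})
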