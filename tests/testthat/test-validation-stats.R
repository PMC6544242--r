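test_that("variance components handle degenerate and truncated cases", {
  z <- rep(100, 9)
  day <- rep(1:3, each = 3)
  vc <- variance_components(z, day)
  expect_equal(vc$s_r2, 0)
  expect_equal(vc$s_B2, 0)

  # identical day means, spread only within days: truncation to exactly 0
  z2 <- rep(c(-1, 0, 1), times = 3) + 100
  vc2 <- variance_components(z2, day)
  expect_gt(vc2$s_r2, 0)
  expect_identical(vc2$s_B2, 0)
  expect_lt(vc2$s_B2_raw, 0)

  expect_error(variance_components(z[1:8], day[1:8]), "unbalanced")
  expect_error(variance_components(z[1:3], rep(1, 3)), "p >= 2")
})

test_that("mean squares agree with independent ANOVA and REML oracles", {
  set.seed(21)
  for (i in 1:5) {
    sim <- simulate_level(100, p = 4, n = 3, cv_repeat = 0.06,
                          cv_between = 0.08)
    vc <- variance_components(sim$z, sim$day)
    aov_tab <- anova(aov(z ~ factor(day), data = data.frame(z = sim$z,
                                                            day = sim$day)))
    expect_equal(vc$msb, aov_tab$`Mean Sq`[1], tolerance = 1e-8)
    expect_equal(vc$msw, aov_tab$`Mean Sq`[2], tolerance = 1e-8)
    if (vc$s_B2 > 0) {
      fit <- lme4::lmer(z ~ 1 + (1 | day),
                        data = data.frame(z = sim$z, day = sim$day),
                        REML = TRUE)
      vcs <- as.data.frame(lme4::VarCorr(fit))
      expect_equal(vc$s_B2, vcs$vcov[vcs$grp == "day"], tolerance = 1e-5)
      expect_equal(vc$s_r2, vcs$vcov[vcs$grp == "Residual"], tolerance = 1e-5)
    }
  }
})

test_that("between-day estimator is unbiased before truncation", {
  set.seed(31)
  p <- 3; n <- 3
  sigma_b2 <- 4; sigma_r2 <- 9
  raw <- replicate(20000, {
    d <- rnorm(p, 0, sqrt(sigma_b2))
    z <- 100 + rep(d, each = n) + rnorm(p * n, 0, sqrt(sigma_r2))
    variance_components(z, rep(1:p, each = n))$s_B2_raw
  })
  mc_se <- sd(raw) / sqrt(length(raw))
  expect_lt(abs(mean(raw) - sigma_b2), 4 * mc_se)
})

test_that("trueness and precision follow the nominal-denominator convention", {
  expect_equal(trueness(150, 150), 100)
  expect_equal(trueness(156.9, 150), 104.6)
  x <- 7.3
  expect_equal(trueness(105.0 * x / 100, x), 105.0)

  expect_equal(precision_rsd(0, 10), 0)
  expect_equal(precision_rsd((0.0172 * 0.1)^2, 0.1), 1.72)
  # denominator is nominal, not the observed mean
  expect_equal(precision_rsd(4, 200), 1)
  s_r2 <- 2.5; s_B2 <- 1.5
  expect_gte(precision_rsd(s_r2 + s_B2, 50), precision_rsd(s_r2, 50))
})

test_that("beta-ETI degenerates, widens monotonically and covers", {
  expect_equal(beta_eti(100, 0, 0, 3, 3), c(low = 100, high = 100))

  widths <- vapply(c(0.80, 0.90, 0.95), function(b) {
    e <- beta_eti(100, 4, 2, 3, 3, beta = b); e[["high"]] - e[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  w1 <- beta_eti(100, 4, 2, 3, 3)
  w2 <- beta_eti(100, 8, 4, 3, 3)  # larger s_IT, same R
  expect_gt(w2[["high"]] - w2[["low"]], w1[["high"]] - w1[["low"]])

  # s_r2 = 0 limit: B^2 -> 1/n, nu -> p - 1
  e0 <- beta_eti(100, 0, 4, 4, 3)
  half0 <- qt(0.95, 3) * 2 * sqrt(1 + 1 / (4 * 3 * (1 / 3)))
  expect_equal(e0[["high"]] - 100, half0, tolerance = 1e-12)
})

test_that("empirical expectation coverage matches beta across designs", {
  cases <- expand.grid(beta = c(0.80, 0.90, 0.95),
                       design = c("3x3", "5x4"))
  for (i in seq_len(nrow(cases))) {
    p <- if (cases$design[i] == "3x3") 3 else 5
    n <- if (cases$design[i] == "3x3") 3 else 4
    cov <- eti_coverage(p = p, n = n, cv_repeat = 0.05, cv_between = 0.05,
                        beta = cases$beta[i], n_replays = 10000,
                        seed = 100 + i)
    expect_lt(abs(cov - cases$beta[i]), 0.015,
              label = sprintf("coverage %g at beta %g (p=%d,n=%d)",
                              cov, cases$beta[i], p, n))
  }
})

profile_from_bounds <- function(nominal, rel_low, rel_high, trueness = 100) {
  tibble::tibble(
    nominal = nominal, p = 3, n = 3,
    grand_mean = trueness / 100 * nominal, trueness = trueness,
    s_r2 = 1, s_B2 = 0, s_IT2 = 1,
    rsd_repeat = 1, rsd_intermediate = 1,
    rel_eti_low = rel_low, rel_eti_high = rel_high,
    eti_low = nominal * (1 + rel_low / 100),
    eti_high = nominal * (1 + rel_high / 100)
  )
}

test_that("accuracy profiles flag non-compliant levels and dominate bias", {
  flat <- profile_from_bounds(c(1, 10, 100), rep(0, 3), rep(0, 3))
  prof <- accuracy_profile(flat, lambda = 30)
  expect_true(prof$valid)
  expect_equal(prof$levels$total_error, rep(0, 3))
  expect_equal(prof$lloq, 1)
  expect_equal(prof$uloq, 100)

  # a level with 33.5% total error lies outside the +/-30% allowance
  one_out <- profile_from_bounds(c(0.1, 0.2, 0.5), c(-33.5, -10, -5),
                                 c(20, 10, 5))
  prof2 <- accuracy_profile(one_out, lambda = 30)
  expect_false(prof2$levels$within[1])
  expect_true(all(prof2$levels$within[-1]))
  expect_equal(prof2$levels$total_error[1], 33.5)
  expect_false(prof2$valid)
  expect_true(all(prof2$levels$total_error >=
                    abs(prof2$levels$trueness - 100)))
})

test_that("limit interpolation places the LLOQ at the crossing abscissa", {
  # lower bound violates at 0.1 and complies at 0.2; build it so the
  # log-linear crossing of -lambda lands at 1.1 x the lowest level
  lambda <- 30
  x <- c(0.1, 0.2, 0.5)
  u <- log10(x)
  target <- log10(0.11)
  t_frac <- (target - u[1]) / (u[2] - u[1])
  v1 <- -35  # violation at 0.1
  v2 <- (-lambda - v1 * (1 - t_frac)) / t_frac  # compliant bound at 0.2
  lv <- profile_from_bounds(x, c(v1, v2, -5), c(10, 10, 5))
  lim <- determine_limits(lv, lambda = lambda, mode = "relative")
  expect_equal(lim$lloq, 0.11, tolerance = 1e-10)
  expect_equal(lim$uloq, 0.5)

  # all-compliant profile keeps the designed endpoints
  lim2 <- determine_limits(profile_from_bounds(x, rep(-5, 3), rep(5, 3)),
                           lambda = lambda)
  expect_equal(lim2$lloq, 0.1)
  expect_equal(lim2$uloq, 0.5)

  expect_error(
    determine_limits(profile_from_bounds(x, rep(-40, 3), rep(0, 3)),
                     lambda = lambda),
    class = "msval_no_valid_level")
})

test_that("shrinking the acceptance limit never lowers the LLOQ", {
  set.seed(77)
  for (rep in 1:20) {
    k <- 6
    x <- 10^seq(-1, 2, length.out = k)
    rel_low <- -sort(runif(k, 0, 45), decreasing = TRUE)
    rel_high <- sort(runif(k, 0, 45), decreasing = TRUE)
    lv <- profile_from_bounds(x, rel_low, rel_high)
    lloqs <- vapply(c(40, 35, 30, 25), function(lam) {
      tryCatch(determine_limits(lv, lambda = lam)$lloq,
               msval_no_valid_level = function(e) Inf)
    }, numeric(1))
    expect_true(all(diff(lloqs) >= -1e-9))
  }
})

test_that("absolute-mode interpolation works on concentration-unit bounds", {
  x <- c(0.1, 0.2, 0.5)
  lv <- profile_from_bounds(x, c(-40, -10, -5), c(35, 10, 5))
  lim_rel <- determine_limits(lv, lambda = 30, mode = "relative")
  lim_abs <- determine_limits(lv, lambda = 30, mode = "absolute")
  expect_gt(lim_abs$lloq, 0.1)
  expect_lte(lim_abs$lloq, 0.2)
  # both modes agree that the crossing sits between the first two levels
  expect_gt(lim_rel$lloq, 0.1)
  expect_lte(lim_rel$lloq, 0.2)
})
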