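# Small two-analyte design used where the full six-analyte panel is overkill.
mini_transitions <- function() {
  data.frame(
    analyte = c("A1", "A1", "A2"),
    istd = c("IS1", "IS1", "IS2"),
    precursor_mz = c(457.5, 457.5, 471.3),
    product_mz = c(344.1, 298.1, 361.1),
    ion_ratio = c(1, 0.68, 1),
    quantifier = c(TRUE, TRUE, TRUE),
    retention_time_min = c(3.0, 3.0, 3.5)
  )
}

mini_design <- function(...) {
  assay_design(
    transitions = mini_transitions(),
    calibration_levels = c(0.1, 0.2, 0.5, 1, 2, 50, 500, 1000, 2000),
    validation_levels = c(0.1, 0.2, 0.5, 1, 2, 150, 750, 1500),
    seed = 42L,
    ...
  )
}

mini_truth <- function(design = mini_design(), ...) {
  ground_truth(design$analytes, seed = design$seed, ...)
}

noise_free_truth <- function(design = mini_design()) {
  mini_truth(design, cv_repeat = 0, cv_between = 0, istd_cv = 0)
}

# p x n lognormal level replay used by variance-component tests
simulate_level <- function(nominal, p, n, cv_repeat, cv_between) {
  sig_r <- sqrt(log1p(cv_repeat^2))
  sig_b <- sqrt(log1p(cv_between^2))
  d <- rnorm(p, 0, sig_b)
  z <- nominal * exp(rep(d, each = n) + rnorm(p * n, 0, sig_r))
  list(z = z, day = rep(seq_len(p), each = n))
}
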