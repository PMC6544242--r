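#!/usr/bin/env Rscript
# Detection limits: signal-to-noise LOD scan over a simulated dilution
# series in three plasma backgrounds, and the instrument detection limit
# from replicate-injection precision.

suppressPackageStartupMessages({
  library(msval)
  library(dplyr)
})

design <- read_assay_design("results/assay_design.yaml")
set.seed(design$seed + 20L)

# S/N LOD scan: peaks shrink with concentration over a fixed noise floor
levels <- c(0.01, 0.02, 0.05, 0.1, 0.2)
matrices <- c("plasma_1", "plasma_2", "plasma_3")
scan <- tidyr::expand_grid(matrix = matrices, level = levels)
scan$sn_ratio <- vapply(seq_len(nrow(scan)), function(i) {
  ch <- simulate_chromatogram(
    data.frame(rt = 180, height = 600 * scan$level[i], sigma = 1.5),
    noise_amplitude = 10, duration = 300,
    seed = design$seed + i)
  signal_to_noise(ch, peak_window = c(174, 186))$sn_ratio
}, numeric(1))
lods <- lod_from_scan(scan, threshold = 3)
write.csv(lods, "results/lod_scan.csv", row.names = FALSE)
message("S/N >= 3 LOD per matrix -> results/lod_scan.csv")
print(as.data.frame(lods))

# IDL: ten replicate injections at 0.05 ng/mL (12.5 uL injected = 250 fg
# on column at 2x the expected detection limit), 99% one-sided confidence
idl_tbl <- bind_rows(lapply(design$analytes, function(an) {
  areas <- 5e3 * exp(rnorm(10, 0, 0.08))
  res <- idl_from_areas(areas, injected_amount = 250)
  tibble::tibble(analyte = an, rsd_percent = res$rsd_percent,
                 n = res$n, idl_fg = res$idl)
}))
write.csv(idl_tbl, "results/idl.csv", row.names = FALSE)
message(sprintf("IDL range %.1f-%.1f fg (t-factor %.3f) -> results/idl.csv",
                min(idl_tbl$idl_fg), max(idl_tbl$idl_fg),
                t_confidence_factor(10, 0.99)))
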