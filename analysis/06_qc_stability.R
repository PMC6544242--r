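#!/usr/bin/env Rscript
# QC decision rules: carryover after the highest calibrator, ion-ratio
# confirmation against calibration-standard references, stability series
# (bench-top, whole blood, freeze-thaw, long-term), anticoagulant/serum
# comparison, and the whole-blood dilution correction.

suppressPackageStartupMessages({
  library(msval)
  library(dplyr)
})

design <- read_assay_design("results/assay_design.yaml")
set.seed(design$seed + 30L)

# carryover: blank after 2000 ng/mL vs mean LLOQ-calibrator area
carry <- read_measurements("results/measurements_carryover.csv")
main <- read_measurements("results/measurements_design.csv")
resp <- quantification_responses(main, design)
carry_tbl <- bind_rows(lapply(design$analytes, function(an) {
  bl <- filter(carry, analyte == an, role == "blank")[1, ]
  lloq_level <- design$lloq[[an]]
  cal <- filter(resp, analyte == an, role == "calibration",
                nominal_conc == lloq_level)
  res <- carryover_percent(bl$peak_area,
                           mean(cal$combined_area),
                           threshold = design$limits$carryover)
  tibble::tibble(analyte = an, carryover_percent = res$percent,
                 flagged = res$flagged)
}))
write.csv(carry_tbl, "results/carryover.csv", row.names = FALSE)
message(sprintf("carryover: %.1f-%.1f%% of LLOQ signal -> results/carryover.csv",
                min(carry_tbl$carryover_percent),
                max(carry_tbl$carryover_percent)))

# ion-ratio confirmation on a mid-level sample of each analyte
ir_tbl <- bind_rows(lapply(design$analytes, function(an) {
  tr <- filter(design$transitions, analyte == an)
  base <- tr$product_mz[tr$ion_ratio == 1][1]
  sample_areas <- setNames(1000 * tr$ion_ratio * exp(rnorm(nrow(tr), 0, 0.05)),
                           format(tr$product_mz))
  ref <- setNames(tr$ion_ratio, format(tr$product_mz))
  out <- ion_ratio_confirm(sample_areas, ref,
                           base_product = format(base),
                           tolerance = design$limits$ion_ratio / 100)
  out$analyte <- an
  out
}))
write.csv(ir_tbl, "results/ion_ratios.csv", row.names = FALSE)
message(sprintf("ion ratios: %d/%d confirmed -> results/ion_ratios.csv",
                sum(ir_tbl$confirmed), nrow(ir_tbl)))

# stability: three QC levels, several storage conditions; one condition is
# generated degraded (-30%) to exercise the failure path
stab_tbl <- bind_rows(lapply(c(2, 150, 1500), function(lv) {
  make <- function(cond, factor) {
    data.frame(condition = cond, value = lv * factor * exp(rnorm(3, 0, 0.02)))
  }
  series <- bind_rows(
    make("bench-top 24 h +4C", 0.99),
    make("freeze-thaw x3 -80C", 0.97),
    make("whole blood 4 h RT", if (lv == 150) 0.70 else 0.96),
    make("long-term 12 mo -80C", 0.95))
  out <- stability_deviation(series, reference = lv,
                             lloq = FALSE,
                             limit = design$limits$stability,
                             limit_lloq = design$limits$stability_lloq)
  out$level <- lv
  out
}))
write.csv(stab_tbl, "results/stability.csv", row.names = FALSE)
message(sprintf("stability: %d/%d conditions pass -> results/stability.csv",
                sum(stab_tbl$pass), nrow(stab_tbl)))

# anticoagulant / serum comparison on citrate-validated calibration
anti_tbl <- bind_rows(lapply(c("EDTA", "heparin", "serum"), function(mx) {
  bias_true <- c(EDTA = 0.98, heparin = 1.01, serum = 0.97)[[mx]]
  qc <- tidyr::expand_grid(level = c(10, 150, 1500), rep = 1:3)
  qc$matrix <- mx
  qc$conc <- qc$level * bias_true * exp(rnorm(nrow(qc), 0, 0.03))
  anticoagulant_bias(qc, limit = design$limits$bias,
                     limit_lloq = design$limits$bias_lloq)
}))
write.csv(anti_tbl, "results/anticoagulant_bias.csv", row.names = FALSE)
message(sprintf("anticoagulant bias: %d/%d pass -> results/anticoagulant_bias.csv",
                sum(anti_tbl$pass), nrow(anti_tbl)))

# whole-blood dilution correction of measured clinical concentrations
clin <- tibble::tibble(
  analyte = c("PBTZ169", "Met 3-OH", "Met 3-oxo", "Met 1-OH"),
  plasma_conc = c(464, 147, 13, 2))
clin$blood_equivalent <- blood_dilution_correct(
  clin$plasma_conc,
  blood = design$blood_ratio[["blood"]],
  anticoagulant = design$blood_ratio[["anticoagulant"]])
write.csv(clin, "results/blood_corrected.csv", row.names = FALSE)
message("blood-dilution corrected concentrations (x1.1) -> ",
        "results/blood_corrected.csv")
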