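#!/usr/bin/env Rscript
# Dose-response and synergy analysis: 4PL monotherapy fits from each
# matrix's monotherapy axes, Loewe-additivity expectation per dose pair,
# and overall synergy classification per the >10 / -10..10 / <-10 bands.

suppressPackageStartupMessages(library(modscreen))
dir.create("results/synergy", showWarnings = FALSE, recursive = TRUE)

for (path in list.files("results/data", pattern = "^dose_matrix_.*\\.csv$",
                        full.names = TRUE)) {
  dm <- read_dose_matrix(path)
  label <- sub("^dose_matrix_", "", sub("\\.csv$", "", basename(path)))

  fit_a <- fit_dose_response(data.frame(dose = dm$dose_a,
                                        viability = dm$values[, 1] / 100))
  fit_b <- fit_dose_response(data.frame(dose = dm$dose_b,
                                        viability = dm$values[1, ] / 100))
  message(sprintf("%s: drug A ED50 %.0f nM (hill %.2f), drug B ED50 %.0f nM (hill %.2f)",
                  label, fit_a$ed50, fit_a$hill, fit_b$ed50, fit_b$hill))

  sm <- synergy_map(dm, fit_a, fit_b)
  message(sprintf("  overall Loewe score %.2f -> %s",
                  sm$overall, sm$classification))
  write_synergy_map(sm, sprintf("results/synergy/%s.json", label))
  write.csv(round(sm$scores, 2), sprintf("results/synergy/%s_grid.csv", label))
}
message("wrote results/synergy/")
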