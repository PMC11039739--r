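#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume: a pooled
# CRISPR screen with planted resistance genes, mimic-vs-control expression
# for two neuroblastoma cell lines, drug-combination dose matrices, and a
# survival cohort with a bimodal expression covariate. All outputs are
# plain-text tables under results/data/.

suppressPackageStartupMessages(library(modscreen))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Pooled screen: 1000 genes x 3 guides, 20 resistance genes, two ALK TKIs
## at two doses each plus DMSO vehicle, duplicate replicates
screen <- simulate_screen(screen_sim_config(seed = 11))
write_guide_counts(screen$counts, file.path(out, "screen_counts.tsv"))
write_screen_design(screen$design, file.path(out, "screen_design.tsv"))
writeLines(screen$truth, file.path(out, "screen_truth_genes.txt"))
message(sprintf("screen: %d guides x %d samples, %d planted resistance genes",
                nrow(screen$counts$counts), ncol(screen$counts$counts),
                length(screen$truth)))

## Expression: two cell lines, 50 planted mimic targets downregulated 30%
expr <- simulate_expression(expression_sim_config(seed = 12))
for (cl in names(expr$matrices)) {
  stem <- file.path(out, paste0("expr_", gsub("[^A-Za-z0-9]", "", cl)))
  write_gct_cls(expr$matrices[[cl]], paste0(stem, ".gct"),
                paste0(stem, ".cls"))
}
writeLines(expr$truth, file.path(out, "expr_truth_targets.txt"))
# synthetic prediction table: planted targets score well, decoys do not
set.seed(12)
decoys <- setdiff(expr$matrices[[1]]$gene_ids, expr$truth)[1:100]
preds <- data.frame(gene = c(expr$truth, decoys),
                    score = c(runif(length(expr$truth), -0.6, -0.05),
                              runif(100, -0.005, 0.2)))
write.table(preds, file.path(out, "target_predictions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("expression: %d genes, %d planted targets, 2 cell lines",
                nrow(expr$matrices[[1]]$values), length(expr$truth)))

## Dose matrices: additive, synergistic (+15) and antagonistic (-15)
for (cond in list(c("additive", 0), c("synergistic", 15),
                  c("antagonistic", -15))) {
  cfg <- dose_matrix_sim_config(interaction_offset = as.numeric(cond[2]),
                                noise_sd = 2, seed = 13)
  write_dose_matrix(simulate_dose_matrix(cfg),
                    file.path(out, paste0("dose_matrix_", cond[1], ".csv")))
}
message("dose matrices: 7x7 grids, offsets 0 / +15 / -15")

## Survival cohort: 143 patients, bimodal expression, hazard ratio 3
cohort <- simulate_survival(survival_sim_config(seed = 14))
write_survival_cohort(cohort, file.path(out, "survival_cohort.tsv"))
message(sprintf("survival: %d patients, %.0f%% censored",
                nrow(cohort), 100 * mean(!cohort$event)))
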