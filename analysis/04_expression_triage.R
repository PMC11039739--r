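#!/usr/bin/env Rscript
# Mimic-vs-control expression analysis and target triage: quantile
# normalization, differential expression per cell line, GSEA against a
# small hallmark-style collection, and the prediction/downregulation/
# pathway funnel evaluated against the planted target set.

suppressPackageStartupMessages(library(modscreen))
stems <- list.files("results/data", pattern = "^expr_.*\\.gct$",
                    full.names = TRUE)
truth <- readLines("results/data/expr_truth_targets.txt")
preds <- read_target_predictions("results/data/target_predictions.tsv")

de <- list()
for (gct in stems) {
  cls <- sub("\\.gct$", ".cls", gct)
  em <- quantile_normalize(read_gct_cls(gct, cls))
  line <- sub("^expr_", "", sub("\\.gct$", "", basename(gct)))
  de[[line]] <- differential_expression(em)
  message(sprintf("%s: %d genes altered (|change| > 20%%), %d downregulated",
                  line, sum(de[[line]]$altered),
                  sum(de[[line]]$altered & de[[line]]$direction == "down")))
}

# GSEA on the first cell line: planted targets act as the gene set expected
# to crowd the bottom of the log2-ratio ranking
rl <- make_ranked_list(de[[1]])
set.seed(16)
coll <- list(planted_targets = truth,
             random_control = sample(setdiff(rl$gene_id, truth), 50))
res <- gsea_collection(rl, coll, n_perm = 1000, seed = 16)
print(res)

# triage funnel
predicted <- filter_predictions(preds, cutoff = -0.01)
both <- intersect_downregulated(de[[1]], de[[2]], predicted)
message(sprintf("funnel: %d predicted -> %d down in both lines; recall %.3f",
                length(predicted), length(both), mean(truth %in% both)))

dir.create("results/triage", showWarnings = FALSE, recursive = TRUE)
for (line in names(de))
  write.table(de[[line]], sprintf("results/triage/de_%s.tsv", line),
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res, "results/triage/gsea.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tr <- triage_funnel(preds, de[[1]], de[[2]])
write_triage_result(tr, "results/triage/funnel.json")
message("wrote results/triage/")
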