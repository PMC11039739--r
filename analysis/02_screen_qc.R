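#!/usr/bin/env Rscript
# Sample-level QC of the pooled screen: median-ratio normalization, count
# distribution summaries, PCA and pairwise Pearson correlation on
# log-transformed normalized counts.

suppressPackageStartupMessages(library(modscreen))
counts <- read_guide_counts("results/data/screen_counts.tsv")
design <- read_screen_design("results/data/screen_design.tsv")

norm <- normalize_counts(counts, method = "median-ratio")
message("size factors: ",
        paste(sprintf("%s=%.3f", norm$sample_ids, norm$size_factors),
              collapse = " "))

qc <- qc_report(norm, design)
print(qc)
off <- qc$pearson[lower.tri(qc$pearson)]
message(sprintf("pairwise Pearson r on log2 counts: min %.3f, median %.3f",
                min(off), median(off)))
# drug and vehicle samples should not separate grossly on PC1 before
# selection effects dominate a handful of guides
message(sprintf("PC1 explains %.1f%% of sample variance",
                100 * qc$pca$var_explained[1]))

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_qc_report(qc, "results/qc/qc_report.json")
write.csv(data.frame(sample = rownames(qc$summaries), qc$summaries),
          "results/qc/sample_summaries.csv", row.names = FALSE)
message("wrote results/qc/")
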