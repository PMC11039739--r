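# modscreen

Analysis pipeline for pooled CRISPR knockout **drug-modifier screens** and
their downstream follow-up, as used to find genes whose loss lets
ALK-driven neuroblastoma cells survive ALK tyrosine-kinase inhibitors, and
to work a miRNA hit through to drug-combination and survival analysis. It
is aimed at computational biologists who want the whole chain — screen QC,
hit calling, expression triage, synergy scoring, survival testing — as
tested, seedable functions that run end-to-end on synthetic data with
planted ground truth.

## What it computes

**Fold-difference hit calling.** Per guide *g* and screen (drug × dose),

    FD_g = (mean normalized abundance under drug + c) / (mean under vehicle + c)

with pseudocount *c* = 1 after median-ratio normalization. A gene is
*enriched* in a screen when ≥ 2 of its guides have FD > 1.8 (strict), a
*hit* when enriched under **both** drugs at **either** dose, and a *top*
hit when enriched in ≥ 3 of the 4 screens. k-means (k-means++ seeding,
Lloyd iterations) clusters enrichment profiles across screens.

**Expression triage.** Quantile normalization, mimic-vs-control percent
change, ΔΔCt fold changes (2^−ΔΔCt), a from-scratch GSEA engine (weighted
running-sum ES, gene-set permutation NES and nominal p), and the target
funnel: context++ score ≤ −0.01 → downregulated > 20% in both cell lines →
designated-pathway membership → validated fold < 0.8.

**Loewe synergy.** Four-parameter logistic monotherapy fits
(f(d) = bottom + (top − bottom)/(1 + (d/ED50)^hill)); the Loewe expected
response solves d_A/D_A(y) + d_B/D_B(y) = 1; per-cell score =
100 × (expected − observed viability); overall score classified
synergistic (> 10), additive (−10..10) or antagonistic (< −10).

**Survival.** Expression-cutoff dichotomization (cohort z-score or absolute
cutoff), Kaplan–Meier curves, log-rank test, and the modified-ellipsoid
tumour volume V = a·b²/2.

Seeded generators (`simulate_screen`, `simulate_expression`,
`simulate_dose_matrix`, `simulate_survival`) produce every input with
planted truth: negative-binomial guide counts with selection effects,
dual-cell-line expression with planted targets, exact-Loewe dose matrices
with an interaction offset, and survival times driven by a bimodal
expression covariate.

## Worked example

```r
library(modscreen)

sim  <- simulate_screen(screen_sim_config(seed = 11))   # 1000 genes x 3 guides
norm <- normalize_counts(sim$counts)
enr  <- guide_fold_differences(norm, sim$design)
hits <- intersect_screens(call_gene_hits(enr))
head(hits[hits$is_hit, ], 4)
#>     gene_id                                                   screens n_screens is_hit is_top
#> 34 gene0034 brigatinib@300,brigatinib@750,ceritinib@300,ceritinib@750         4   TRUE   TRUE
#> 39 gene0039 brigatinib@300,brigatinib@750,ceritinib@300,ceritinib@750         4   TRUE   TRUE
#> 62 gene0062 brigatinib@300,brigatinib@750,ceritinib@300,ceritinib@750         4   TRUE   TRUE
#> 93 gene0093 brigatinib@300,brigatinib@750,ceritinib@300,ceritinib@750         4   TRUE   TRUE
```

20 genes pass the both-drug/either-dose rule; against the 20 planted
resistance genes this run scores precision 1.000 and recall 1.000. Each row
shows which screens a gene was enriched in, whether it met the hit rule,
and whether it recurred in ≥ 3 screens.

```r
cfg <- dose_matrix_sim_config(interaction_offset = 15, noise_sd = 2, seed = 13)
synergy_map(simulate_dose_matrix(cfg), cfg$fit_a, cfg$fit_b)
#> Loewe synergy: overall 15.46 (synergistic)
```

The planted 15-point excess killing is recovered and lands in the > 10
synergistic band.

The numbered scripts under `analysis/` run the full chain as a narrative —
`01_simulate.R` writes all synthetic inputs to `results/data/`, then
QC (`02`), hit calling (`03`), expression + triage (`04`), synergy (`05`)
and survival (`06`) read them back and write tables under `results/`.
The methods vignette (`vignettes/drug-modifier-pipeline.Rmd`) documents the
models, defaults and limitations.

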