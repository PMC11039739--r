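---
title: "Methods: pooled-screen hit calling, expression triage, Loewe synergy and survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-screen hit calling, expression triage, Loewe synergy and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

`modscreen` implements the computational chain of a drug-modifier study in
ALK-driven neuroblastoma: a genome-wide CRISPR knockout screen identifies
genes whose loss confers resistance to ALK tyrosine-kinase inhibitors, a
miRNA hit is followed up by expression profiling and target triage, candidate
drug combinations are scored for Loewe synergy, and an expression cutoff is
related to patient survival. Every stage runs on synthetic data with planted
ground truth, so the whole chain is testable without any external download.
This vignette is the package's account of the models, the defaults, and what
the synthetic experiments do and do not demonstrate.

## Pooled-screen model and hit calling

A knockout library of `n_genes × guides_per_gene` sgRNAs (3 guides/gene by
default, as in common genome-scale libraries) is sequenced under four drug
conditions — two ALK inhibitors at two doses each — and a DMSO vehicle.
Counts are modeled negative-binomially with mean `μ` and dispersion `α`
(variance `μ + αμ²`), the standard pooled-screen count model. Library
abundances are log-normal (sdlog 0.5) to mimic the uneven guide
representation real libraries show; this matters because it is what
normalization has to cope with. In drug samples the expected abundance of
guides targeting a planted resistance gene is multiplied by
`resistance_effect` and the composition renormalized to the sample's depth,
emulating outgrowth of resistant knockout clones under selection.

Normalization defaults to median-ratio scaling against the geometric-mean
pseudo-reference over guides detected in all samples. The alternative
(`total-count`) is exposed because the upstream convention in screen
pipelines varies; median-ratio is the default because it is robust to the
composition shift that strong selection induces. Size factors are rescaled
to geometric mean 1, which makes normalization idempotent. QC follows the
usual battery: count quartiles and zero fractions, CDF curves, PCA of
samples over per-guide-centered log2 counts, and pairwise Pearson
correlation of log2(normalized + 1) counts.

Hit calling is deliberately simple, mirroring the fold-difference procedure
rather than a regression framework: per guide and screen,

FD = (mean normalized abundance under drug + c) / (mean under vehicle + c)

with pseudocount `c = 1`. A gene is *enriched* in a screen when at least 2
of its guides have FD strictly above 1.8 (the threshold comparison is
strict; guides at exactly 1.8 do not pass). A gene is a *hit* when enriched
under both drugs at either dose, and a *top* hit when enriched in at least
3 of the 4 screens. "At least 2" is the minimal reading of "multiple
guides" for a 3-guide library and is configurable. FD is computed on
replicate means against the same batch's vehicle; a Day-0 reference is not
used because the comparison of interest is drug versus vehicle.

Two behaviors of this estimator are worth knowing. First, the ratio of
noisy means carries an `O(CV²)` Jensen skew, so even with no selection the
mean FD sits slightly above 1 at high dispersion. Second, all screens share
the vehicle denominator, so a gene whose guides happen to be undersampled
in the vehicle inflates its FD in *every* screen at once; the both-drug
intersection therefore removes less multiplicity than independence would
suggest. At the default study conditions (effect 4, dispersion 0.1, depth
500, duplicate replicates) precision and recall against planted truth are
both above 0.9, with the residual false positives coming from exactly this
shared-vehicle mechanism.

Profile clustering uses Lloyd's k-means with k-means++ seeding, 10 restarts
under one seed, default `k = 4` (one per screen condition; the choice of k
is the user's — nothing in the FD procedure pins it).

## Expression, GSEA and the triage funnel

The expression generator draws per-gene baselines log-normal
(meanlog log 100, sdlog 1) per cell line, multiplies planted targets in the
mimic arm by `1 − downregulation_fraction` (default 0.3), and applies
multiplicative log-normal noise with unit mean and the configured CV, so
the zero-noise case reproduces the planted fold exactly. Three replicates
per arm reflect the usual design of transfection experiments.

Quantile normalization equalizes each sample's empirical distribution to
the cross-sample mean of order statistics (ties receive the mean of the
reference values they span); it is idempotent. Differential expression is
intentionally a mean-ratio method: per gene, group means, ratio, percent
change, and an "altered" flag at |percent change| > 20%. No variance
moderation is applied because the downstream funnel consumes only the
direction and magnitude of change, and 20% is the one magnitude criterion
the workflow states anywhere (at the qPCR validation stage); the microarray
stage reuses it as the default, configurable.

The GSEA engine is written from scratch. Over a ranked list of N genes with
a set of Nh members, the running sum increments by |score|^p (normalized
over the set's members) at hits and decrements by 1/(N − Nh) at misses; the
enrichment score ES is the running-sum value of largest magnitude, with the
positive extreme winning exact ties (a 1e−12 tolerance guards float noise
in the comparison). Defaults: weighting exponent p = 1, 1000 permutations.
Significance uses *gene-set* permutation — random same-size sets under a
seed — rather than phenotype permutation, because three replicates per arm
cannot support phenotype permutation. NES is ES divided by the mean
magnitude of same-sign permutation ESs, and the nominal p is the same-sign
tail fraction; FDR q-values are out of scope. Ranking defaults to
log2(treated/control); genes with zero control mean are excluded and
counted.

ΔΔCt relative quantification follows the textbook form: ΔCt = Ct(target) −
Ct(reference) per sample, ΔΔCt = mean ΔCt(treated) − mean ΔCt(control),
fold = 2^(−ΔΔCt). Per-sample plate offsets cancel by construction.

The triage funnel chains four set operations: context++ score ≤ −0.01
(inclusive, as that cutoff is conventionally printed), downregulation
strictly beyond the threshold in *both* cell lines (genes missing from a
differential result count as not downregulated), membership in at least one
designated cancer-associated pathway (the designation is user input — which
pathway categories count as cancer-associated is a curation decision, not a
computation), and measured fold change strictly below 0.8. Counts are
monotone non-increasing along the funnel, and loosening any threshold can
only grow downstream stages; both properties are tested.

## Dose-response and Loewe synergy

Viability is normalized to the vehicle-mean signal. Monotherapies are fit
with a four-parameter logistic,
f(d) = bottom + (top − bottom)/(1 + (d/ED50)^hill),
the standard viability model behind "non-linear regression" ED50 estimates,
by Levenberg–Marquardt least squares with a multi-start grid over ED50
(log-spaced across the observed doses) and hill (0.5–4). Replicates are
averaged before fitting. Responses whose total range is below 0.05 are
flagged non-determined rather than fit. ED50 is by construction the dose at
the midpoint of the fitted asymptotes.

The Loewe expectation for a dose pair (dA, dB) is the unique response y
solving dA/DA(y) + dB/DB(y) = 1, with D(y) the inverse 4PL; the root is
bracketed inside the overlap of the two response ranges (ε = 1e−6 from the
asymptotes keeps D finite) and found to 1e−9. When one dose is zero the
expectation reduces to the other monotherapy, and a drug combined with
itself satisfies the sham-combination identity f(dA + dB) — both fall out
of the equation rather than being special-cased approximations. Per cell,
the synergy score is 100 × (expected − observed viability fraction),
positive when the combination kills more than additivity predicts; the
overall score is the mean over combination cells, classified synergistic
(> 10), additive (−10 to 10) or antagonistic (< −10). This is the Loewe
definition applied directly; version-specific baseline corrections and
smoothing of interactive synergy software are intentionally not replicated.

Synergy scoring takes the monotherapy fits as input, as ED50s are normally
estimated from dedicated monotherapy series; when absent they are refit
from the matrix's own monotherapy row and column. The refit route is
noisier — at plate noise of 2 percentage points the overall-score error is
roughly ±1.4 points via refit versus ±0.3 with given fits — which is why
the recovery experiments score against the fits.

The matrix generator needs monotherapy plateaus high enough that a planted
±15-point offset stays inside the [0, 110]% clipping range; the defaults
(bottoms 0.30 and 0.35) reflect partially effective single agents, the
regime in which combination questions are interesting in the first place.
With plateaus near zero, clipping truncates planted synergy at high doses
and the offset is no longer recoverable — a generator artifact, not a
property of the scorer.

## Survival

The cohort generator draws expression from a two-component Gaussian
mixture (defaults: means 0 and 2, sd 0.5, equal weights — a clearly bimodal
population, as motivates choosing an expression cutoff by eye), event times
exponential with the hazard multiplied by `hazard_ratio` for the
high-expression component, and independent exponential censoring whose rate
targets the requested censored fraction at the average hazard (the
realized fraction is approximate when the two components' hazards differ).
The default cohort size of 143 matches the scale of the RNA-seq patient
cohort this analysis pattern is applied to.

Dichotomization supports both a cohort-wide z-score cutoff (default z ≥ 1)
and an absolute cutoff for the manual, distribution-guided choice; with a
bimodal covariate the absolute cutoff at the antimode separates the risk
groups far better than the z-score, which lands in the upper mode's flank.
Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (events before censorings at tied times); tests verify
them against hand-computed product-limit and
observed/expected/hypergeometric-variance tabulations. Median survival is
read off the step function as the smallest observed time with S(t) ≤ 0.5.
Tumour volumes use the modified ellipsoid formula V = a·b²/2 with a ≥ b
enforced (swapped with a warning if given in the wrong order).

## What the synthetic experiments show — and what they do not

The generators emulate the *structure* of the study's data: overdispersed
guide counts under selection, mimic-induced downregulation across two cell
lines, additivity-plus-offset dose grids, and a bimodal-expression survival
cohort. They do not emulate guide-efficiency heterogeneity, off-target
effects, probe-level microarray artifacts, batch effects, plate-position
effects, or cohort heterogeneity beyond the two-component mixture. Passing
the truth-recovery experiments therefore shows the *procedures* are
implemented correctly and are well calibrated under their stated noise
models — not that the thresholds (FD > 1.8, 20% downregulation, ±10 synergy
bands) are optimal on real data, where they are inherited conventions.

Problem sizes used throughout the tests and the reproduction script —
1000-gene screens at depth 500, 2000-gene expression matrices, 7×7 dose
grids, cohorts of 143–200 with 500-replicate calibration loops, 1000
permutation sets of 200 permutations — were chosen as the smallest scales
at which the calibration claims (binomial false-call consistency,
KS-uniformity of null p-values, ≥90% power) are statistically meaningful.

Known limitations: the FD caller inherits the shared-vehicle correlation
discussed above and reports no per-gene significance (by design — the
procedure is a thresholding rule, not a test); the differential-expression
step is unmoderated and so is only appropriate for the magnitude-threshold
use it serves here; Loewe scoring assumes monotone 4PL monotherapies and
will clamp, with a flag, when a combination response falls outside both
curves' ranges; and the survival generator's censoring fraction is a
target, not an exact quantile.
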