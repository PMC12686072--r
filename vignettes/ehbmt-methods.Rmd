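---
title: "EMT-heterogeneity-based molecular typing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMT-heterogeneity-based molecular typing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epithelial–mesenchymal transition (EMT) is not a binary switch: bulk tumor
transcriptomes occupy a continuum from strongly epithelial, through hybrid
(partial-EMT) states that co-express epithelial and mesenchymal markers,
to strongly mesenchymal. **ehbmt** types a cohort of bulk expression
profiles into three phenotype clusters along this axis — EPC (epithelial),
HPC (hybrid) and MPC (mesenchymal) — and provides the downstream
statistics such a typing feeds: clinical covariate association,
normal-to-tumor subtype traceability in paired designs, survival
comparison, and marker correlation-block analysis.

The method is cohort-wise by construction: clustering is unsupervised
within each dataset, so subtype labels are relative to the cohort being
analyzed. There is deliberately no projection of new samples onto an
existing clustering.

## The classifier

`ehbmt()` composes five stages, each exported on its own.

**Normalization** (`normalize_expression`). In `auto` mode, `log2(x + 1)`
is applied when the matrix maximum exceeds 50 — z-scored or log-scale data
never reaches 50, while FPKM/TPM/count matrices essentially always do —
followed by a per-gene z-score across samples. The z-score divides by the
*population* standard deviation (denominator n). Either sd convention is
defensible; one has to be fixed for bit-reproducibility, and the
population form makes the "z-scores of (0, 2, 4) are (−1, 0, 1)" identity
exact. Zero-variance genes are dropped with a warning since their z-score
is undefined.

**Panel extraction** (`select_panel`). The default panel holds 22
epithelial markers (keratins KRT18/KRT19, junctional genes CDH1, EPCAM,
F11R, claudins, the splicing regulators ESRP1/ESRP2, and epithelial
transcription factors ELF3, HNF4A, OVOL1/2, among others) and 16
mesenchymal markers (the EMT transcription factors ZEB1/2, SNAI1/2,
TWIST1/2, plus VIM, the TGF-beta ligands, and matrix genes FN1, SPARC,
COL1A1/2, MMP2, TCF4). Gene symbols are canonicalized (uppercase, small
alias map — e.g. the occasionally-seen misprint EARP1 maps to ESRP1).
Each sub-panel must be covered at `min_coverage` (default 0.6): the
method is a panel consensus, and below roughly 60% coverage the
epithelial and mesenchymal axes are under-determined.

**Clustering** (`cluster_samples`). Samples are clustered by
agglomerative hierarchical clustering with **complete linkage** on the
distance d(i, j) = 1 − Pearson r between the samples' panel z-score
vectors, and the dendrogram is cut into exactly k = 3 clusters. k is
fixed: the typing is defined as a three-state axis, so no data-driven k
selection (silhouette, gap statistic) is performed. Correlation distance
is the standard choice for expression-heatmap clustering: it compares
profile *shape* and ignores per-sample location and scale.

**Labeling** (`label_clusters`). Each sample gets an epithelial score
(mean z over epithelial panel genes), a mesenchymal score, and their
difference delta. Clusters are ranked by mean delta: highest = EPC
(epi-high), middle = HPC (epi-medium), lowest = MPC (epi-low). Exact ties
are broken by the larger mean epithelial score, then by the smaller
cluster index, so the cluster-to-subtype map is always a bijection.

**Verification** (`enrichment_score`, `verify_assignments`). As an
independent check, every sample is scored with a rank-based single-sample
enrichment statistic: with all G measured genes ranked ascending within
the sample (ties = midranks), the score is
(mean rank of set members − (G+1)/2) / ((G−1)/2), which lies in [−1, 1]
and is invariant under any strictly monotone transform of the sample's
expression. The epithelial panel and the mesenchymal (stromal) panel give
two scores per sample; cohort tertiles (count-based thirds, ties to the
lower tertile) label each sample high/medium/low. Concordance expects
EPC = epithelial-high and stromal-low, MPC the reverse, HPC neither
extreme. Verification is a *check, not a gate*: discordant samples keep
their cluster label and are flagged. This plays the role that
deconvolution-based epithelial/stromal scoring plays in validating such
typings, with a deliberately simple, transform-invariant statistic.

## Downstream statistics

**Association tests.** `chi_square_test` computes the Pearson statistic
with no continuity correction for any table size; the upper-tail p-value
comes from the chi-square distribution (evaluated via the regularized
upper incomplete gamma function, as `pchisq(..., lower.tail = FALSE)`).
Zero-margin rows/columns are dropped with a warning and expected counts
below 5 set a flag. `association_test` includes explicit
"Missing"/"Uncertain" categories as ordinary rows by default — published
clinical tables count them, and their statistics are only reproduced with
those rows in.

**Percentages and rounding.** All printed percentages (proportions,
conversion rates) are rounded to 1 decimal place with round-half-even
(base R `round`). This reproduces published figures exactly — e.g. a
26/32 conversion fraction is 81.25%, printed as 81.2 — where half-up
rounding would not.

**Traceability.** `build_pairs` pairs strictly by patient id (exactly one
normal and one tumor sample; replicates make a patient ambiguous and
excluded with a warning — no expression-similarity matching).
Classification for a paired cohort is run on the combined normal+tumor
matrix, so both tissues share one clustering; `transition_table` then
counts pairs by (normal subtype → tumor subtype) and `conversion_rate`
turns rows into percentages. The Sankey JSON export is renderer-agnostic.

**Survival.** `km_curve` and `logrank_test` wrap the survival package's
product-limit estimator and k-group log-rank chi-square (df = k−1,
hypergeometric expected events). Conventions: censored observations at an
event time remain at risk for that time (deaths before censorings at
ties). Greenwood bands are omitted; they play no role in the quantities
the package reports. Five-year survival rates for real cohorts require
the external accessions and are out of the validation surface; the
survival module is validated against hand-worked product-limit fixtures,
an independent O−E/variance oracle, a seeded type-I-error simulation
(about 1000 null replicates of 90 samples) and a power check (hazard
ratio 2, 200 per group).

**Mann–Whitney.** `mann_whitney` reports U oriented as the number of
(a, b) pairs with a < b (plus half-ties). For groups of at most 8 the
two-sided p-value is exact by enumeration over all rank splits — valid
under ties, which is why this is implemented here rather than delegated
to `wilcox.test` (whose exact path refuses ties); larger groups use the
tie-corrected normal approximation with continuity correction, which
matches `wilcox.test` to numerical precision.

**Correlation blocks.** `correlation_blocks` summarizes pairwise Pearson
correlations among panel genes as within-epithelial (E&E),
within-mesenchymal (M&M) and between-panel (E&M) means, diagonal
excluded. In normal tissue the two programmes are tightly anti-coupled
(E&M strongly negative); hybrid-rich tumor cohorts decouple them.

## The synthetic-cohort generator

`simulate_cohort`, `simulate_paired_cohort` and `simulate_cell_counts`
generate data with the statistical structure the method exploits, so the
whole pipeline is testable without any external download. All generators
are pure functions of (parameters, seed).

**Latent-state model.** Each sample draws one of three states. On a
latent z-like scale, the polar states sit on an anti-coupled EMT axis:
EPC has epithelial panel means +a and mesenchymal means −a; MPC the
mirror image. The hybrid state deploys both programmes *partially and
differentially*: the first half of each sub-panel sits at +0.75a, the
remainder at −0.75a. This reflects what partial-EMT means at the marker
level — some epithelial genes retained above baseline while others are
lost, some mesenchymal genes induced while others are not — and it is a
modelling necessity, not a flourish: Pearson-correlation distance removes
each sample's mean, so a hybrid state defined as a *uniform* intermediate
offset has a flat, noise-only profile and cannot form a cluster at any
prevalence. A generator whose hybrid state is unclusterable would fail to
emulate the phenomenon the method exists to detect, namely that the
hybrid cluster is recoverable in every cohort. Gene-level noise is
Gaussian with sd sigma; background genes are pure N(0, sigma) noise.

**Tumor vs normal.** Tumor samples add a joint upregulation offset
b = 0.5 to every panel gene and use a hybrid-enriched prevalence
(defaults: normal 0.60/0.10/0.30, tumor 0.35/0.43/0.22 for
EPC/HPC/MPC). Two mechanisms then decouple the E&M anticorrelation in
tumors exactly as observed in the correlation-block contrast: the polar
(anti-coupled) states lose prevalence mass, and the hybrid state's
mixed-sign programme contributes correlation structure orthogonal to the
EMT axis.

**Defaults and why.** Separation a = 1.0 with sigma = 0.5 (signal 2 sd —
clearly separated states, as marker panels on curated cohorts are, while
leaving visible within-cluster spread); hybrid level 0.75a ("moderate"
co-expression, between baseline and full activation) on half of each
sub-panel; 200 background genes; transition matrix rows
EPC (0.20, 0.50, 0.30), HPC (0.10, 0.60, 0.30), MPC (0.05, 0.25, 0.70) —
normal epithelial tissue mostly progresses toward hybrid/mesenchymal
tumors, established hybrid or mesenchymal tissue rarely reverts; monthly
hazards 0.008/0.012/0.020 for EPC/HPC/MPC (five-year survival near
0.62/0.49/0.30, echoing the worsening prognosis along the axis) with
uniform censoring over 120 months; single-cell mixtures with epithelial
fraction 0.6 (normal) vs 0.2 (tumor) over 2000 cells per sample.

**What the generator does not emulate.** Count-level (negative binomial)
noise — the classifier consumes normalized expression, so simulation at
the normalized level keeps expectations closed-form; batch effects and
cross-cohort merging (the method clusters cohorts individually);
realistic gene–gene covariance beyond the panel block structure; any
association between expression state and censoring. Passing tests
therefore demonstrate correctness of the algorithms under a clean
generative model, not robustness to real-data artefacts such as batch
structure, low purity or platform noise.

## Numerical choices and degenerate inputs

- Duplicate gene rows after canonicalization collapse by mean
  (deterministic and order-independent; how published matrices collapsed
  duplicate probes is generally unstated, so this is a package decision).
- Orientation of expression files is never auto-detected; silent
  transposition is a classic corruption source.
- A sample whose panel vector has zero variance has no defined
  correlation and is a hard error naming the sample.
- Tertile boundaries use sample counts (lower third / middle / upper
  third) with ties resolved by first-occurrence rank toward the lower
  tertile — deterministic and scale-free; with fewer than 3 samples
  tertiles are undefined and concordance is NA.
- IHC ratio boundaries are inclusive (CDH1/VIM = 3 is EPC, = 0.5 is MPC);
  VIM = 0 with CDH1 > 0 is EPC (the ratio's limit) and 0/0 is flagged
  indeterminate rather than guessed.
- E/M ratios with an empty epithelial+fibroblast+endothelial denominator
  are NA, never 0.

## Validation problem sizes

The test suite validates clustering against a brute-force complete-linkage
oracle on cohorts of up to 8 samples (exhaustive recomputation of the
linkage maximum at every merge), label recovery and correlation-block
contrasts on 300-sample cohorts, transition recovery on 500 pairs,
log-rank calibration on 1000 null replicates of 90 samples, and power on
100 replicates of 2×200. These sizes give the binomial/3-SE margins used
in the assertions comfortable resolution while keeping the full suite in
the tens of seconds.

## Known limitations

- Subtype labels are cohort-relative; two cohorts' EPC clusters need not
  sit at the same absolute expression level.
- k = 3 is fixed by definition of the axis; cohorts genuinely lacking one
  state will still be partitioned into three clusters, with the labeling
  driven by relative delta ordering.
- Whether a published typing cut its dendrogram at k = 3 or delineated
  clusters on the heatmap by eye is generally unstated; this
  implementation always cuts at k = 3, and clusters on z-scored values.
- The enrichment verification is a rank statistic, not a calibrated
  deconvolution; it checks ordering consistency, not cell fractions.
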