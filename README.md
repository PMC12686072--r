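# ehbmt — EMT-heterogeneity-based molecular typing of bulk transcriptomes

Epithelial–mesenchymal transition (EMT) in carcinomas is a spectrum, not a
switch: tumors range from strongly epithelial, through hybrid
(partial-EMT) states co-expressing both programmes, to strongly
mesenchymal. **ehbmt** types a cohort of bulk expression profiles into
three phenotype clusters along this axis — **EPC** (epithelial phenotype
cluster), **HPC** (hybrid) and **MPC** (mesenchymal) — and supplies the
downstream statistics such a typing feeds. It is aimed at computational
biologists analyzing bulk RNA-seq or array cohorts (e.g. gastric cancer
series with paired adjacent-normal tissue), entirely from R or from a
small command-line front end.

## The method

Given a gene × sample expression matrix:

1. **Normalize**: `log2(x + 1)` when the data are on a raw FPKM/count
   scale, then per-gene z-score across samples (population sd).
2. **Panel**: restrict to a fixed EMT marker panel — 22 epithelial genes
   (KRT18, KRT19, CDH1, EPCAM, ESRP1/2, claudins, …) and 16 mesenchymal
   genes (ZEB1/2, SNAI1/2, TWIST1/2, VIM, TGFB1–3, FN1, COL1A1/2, …).
3. **Cluster**: agglomerative clustering of samples with complete linkage
   on the correlation distance *d*(*i*, *j*) = 1 − *r*(*xᵢ*, *xⱼ*), cut at
   *k* = 3.
4. **Label**: per sample, epithelial score *E* = mean panel z-score,
   mesenchymal score *M*, Δ = *E* − *M*; clusters ranked by mean Δ give
   EPC (epi-high) > HPC (epi-medium) > MPC (epi-low).
5. **Verify**: a rank-based single-sample enrichment score
   (score = (mean rank of set − (G+1)/2) / ((G−1)/2) ∈ [−1, 1]) for the
   epithelial and stromal sets; cohort tertiles flag discordant samples
   without changing their labels.

Downstream: Pearson chi-square association against clinical covariates
(no continuity correction, "Missing"/"Uncertain" rows included),
normal→tumor subtype **traceability** on paired cohorts (transition
tables, conversion rates, Sankey export), Kaplan–Meier / log-rank
survival comparison, Mann–Whitney two-group tests, single-cell E/M
ratios, IHC CDH1/VIM subtyping, and epithelial/mesenchymal correlation
blocks. A synthetic-cohort simulator with three latent EMT states,
paired designs with a configurable transition matrix, subtype-dependent
survival and single-cell mixtures makes every stage testable offline.

## Worked example

```r
library(ehbmt)

## a synthetic 120-sample tumor cohort with planted states
sim <- simulate_cohort(n_samples = 120, seed = 7)
fit <- ehbmt(sim$expression)
fit
#> EHBMT typing of 120 samples (panel 'ehbmt-default' v1.0)
#>   EPC:  44 (36.7%)
#>   HPC:  51 (42.5%)
#>   MPC:  25 (20.8%)
#> Label/enrichment concordance: 0.91
```

The cohort splits into the three phenotype clusters (here ~37/43/21%,
matching the planted tumor prevalences), and 91% of samples have
enrichment tertiles concordant with their cluster label.

```r
## association with a clinical covariate, counts from a published table
lauren <- matrix(c(74, 51, 21,  26, 60, 48,  10, 6, 4),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("Intestinal", "Diffuse", "Mixed"),
                                 c("EPC", "HPC", "MPC")))
chi_square_test(lauren)
#> Pearson chi-square: X2 = 35.229, df = 4, p = 4.169e-07
#>   note: some expected counts < 5
```

The histological type is strongly associated with subtype: intestinal
tumors concentrate in EPC, diffuse tumors in HPC/MPC.

```r
## traceability on a paired normal/tumor cohort
paired <- simulate_paired_cohort(n_pairs = 80, seed = 7)
pfit   <- ehbmt(paired$expression)       # one clustering spans both tissues
tab    <- transition_table(build_pairs(paired$meta)$pairs, pfit$assignments)
tab
#>       tumor
#> normal EPC HPC MPC
#>    EPC   8  25  14
#>    HPC   0   3   7
#>    MPC   2   7  14
conversion_rate(tab, "EPC", c("HPC", "MPC"))
#> [1] 83
```

Of 47 patients whose adjacent-normal tissue typed EPC, 83% converted to a
hybrid or mesenchymal tumor — the prevalence shift that makes the hybrid
cluster the dominant tumor subtype.

A command-line front end mirrors the R API:

```sh
exec/ehbmt simulate --n 300 --seed 42 --out sim/
exec/ehbmt classify --expr sim/expression.tsv --out typed/
exec/ehbmt transitions --assignments typed/assignments.tsv --meta sim/meta.tsv --out flows/
```

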