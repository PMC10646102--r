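---
title: "Methods: immunogenomic profiling of a three-group melanoma cohort"
author: "tmeprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunogenomic profiling of a three-group melanoma cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeprofiler)
```

## Scope and model

`tmeprofiler` characterizes the tumor microenvironment (TME) of a melanoma
cohort split into three anatomic groups — primary cutaneous melanoma (PCM),
melanoma brain metastases (MBM), and extracranial metastases (ECM) — from
bulk RNA-seq TPM matrices and targeted-panel mutation tables. The pipeline
computes, per sample: composite z-score expression signatures, immune-cell
fractions by constrained least-squares deconvolution, gene-set enrichment
(preranked GSEA and single-sample GSEA), tumor mutational burden (TMB), HLA
homozygosity, and neoantigen affinity bins; and, per cohort: nonparametric
group comparisons with false-discovery-rate control, mutation frequencies,
correlation structure, and differential expression.

Because the patient-level data this kind of analysis targets is typically
protected, the package ships a synthetic cohort generator whose defaults
emulate the published three-group cohort structure (350 PCM / 94 MBM / 870
ECM) with planted group effects, so every stage is exercised end-to-end by
tests without any external data.

## Composite z-score signatures

All signature scores are built on the cohort z-score primitive: each gene
is standardized across samples, `z = (x - mean) / sd`, using the
**population** SD (divide by `n`). The choice matters only as a constant
factor per gene; it is configurable to the `n - 1` convention
(`sd_type = "sample"`). Zero-variance genes map to all-zero z-rows with a
warning rather than NaN.

The individual scores:

* **T cell dysfunction** — the sum of z-scores of *HAVCR2* (TIM3), *LAG3*,
  and *PDCD1* (PD-1) raw TPM. All three genes are required.
* **STING pathway** — the sum of z-scores of *TMEM173* (STING), *CGAS*,
  *CCL5*, *CXCL10*, and *IRF3*, aggregated in parallel to the dysfunction
  score; a mean-z variant is available.
* **Interferon-gamma (IFNγ) score** — the *mean* of per-gene z-scores of
  `log2(TPM + 1)` over the signature genes. The mean (rather than the sum)
  makes the score robust to partial signature membership, which is logged.
  The default 6-gene membership, and the default 18-gene T cell-inflamed
  set, follow the anti-PD-1 response signature literature (Ayers et al.,
  *J Clin Invest* 2017); both ship as editable defaults
  (`builtin_genesets()`, or any GMT file), not hard-coded constants.
* **T cell-inflamed (TIS) classification** — three-way: score below the low
  threshold is TIS(−), above the high threshold TIS(+), in between
  (strictly) undetermined. Published analyses of this kind do not print
  their thresholds; the default is the cohort score tertiles, overridable.
  If ties collapse the tertiles, the strict comparisons classify the tied
  mass as undetermined.
* **Non-functional CD8** — flagged when the dysfunction score is strictly
  greater than 1.0 *and* *FGFBP2* TPM is strictly below the whole-cohort
  median; samples with zero inferred CD8 fraction are excluded from any
  reported percentage denominator, since the rule is defined among tumors
  with non-zero CD8 infiltration. The strict inequalities follow the
  printed bracketed definitions.

Z-scores are computed over the whole cohort, not within group; the
non-functional rule's "median TPM for the whole cohort" anchors that
reading.

## Immune-cell deconvolution

Bulk expression is modeled as a non-negative combination of cell-type
reference profiles over marker genes (the quanTIseq-style "absolute
fraction" formulation). Per sample: the expression vector is renormalized
to TPM over the supplied genes (making fractions invariant to overall
library scaling), restricted to the signature's marker genes, and solved by
Lawson–Hanson non-negative least squares (`pracma::lsqnonneg`). Weights are
divided by a per-type mRNA-content scale — default 1 for every type, since
published mRNA scaling factors are not reproducible from method
descriptions alone and a unit scale preserves the ranking and correlation
structure the downstream comparisons use. The remainder
`other = max(0, 1 - sum(w))` absorbs unexplained (tumor/stromal) signal and
rows are renormalized onto the simplex. Markers absent from the mixture are
dropped from both sides, with an error when more than half are missing.

The packaged default signature is the generator's reference restricted to
the **ten** immune types (B cells, M1 and M2 macrophages, monocytes,
neutrophils, NK cells, CD4 and CD8 T cells, Tregs, myeloid dendritic
cells); the output then has ten immune columns plus `other`. A published
matrix such as TIL10 drops in as a TSV.

## Enrichment

* **Enrichment score (ES)**: the weighted Kolmogorov–Smirnov running sum —
  hits increment by `|metric|^alpha` (normalized over the set), misses
  decrement by `1/(N - N_set)`; ES is the signed maximum deviation. At
  `alpha = 0` it is rank-only and bounded in `[-1, 1]`. On the measure-zero
  event of an exact magnitude tie between the extreme positive and negative
  deviations, the positive one is reported.
* **Preranked GSEA**: the null is gene-label permutation preserving set
  size (the pipeline consumes precomputed rankings, so phenotype
  permutation is not applicable). NES divides ES by the mean |null ES| of
  matching sign. The p-value is the sign-stratified empirical tail
  probability with +1 smoothing — the classic GSEA convention; it is
  calibrated (near-uniform under the null), which the test suite checks
  directly. Two FDR columns are reported: Benjamini–Hochberg over the
  empirical p-values (the default, simpler and conservative) and the
  classic sign-stratified NES null-ratio estimate.
* **ssGSEA**: per sample, genes are ranked by expression descending (ties
  broken by symbol for determinism) and position `j` of `N` carries rank
  weight `(N - j + 1)^alpha` with `alpha = 0.25` by the usual ssGSEA
  convention. The score is the sum over all positions of (weighted hit ECDF
  − miss ECDF). Rank-position weighting (rather than expression-value
  weighting) makes scores exactly invariant to monotone transforms of a
  sample's expression. A range-normalized variant divides by the global
  max − min of the score matrix.

## Genomic features

* **TMB** counts non-synonymous **missense** mutations not flagged as
  known germline variants, divided by the sequenced footprint (default
  1.4 MB, a 592-gene panel); "non-synonymous missense" is read literally,
  so nonsense/frameshift are excluded by default but the qualifying classes
  are configurable. TMB-high is `>= 10` mutations/MB — the boundary itself
  is high.
* **Mutation frequencies** count distinct samples with at least one
  *pathogenic or likely pathogenic* record for the gene (benign, likely
  benign, and VUS excluded), over the assessed samples in the group.
  Because panel coverage differs by gene, the assessed denominator is an
  explicit optional input (defaulting to all group samples). Percentages
  round half-up to one decimal, matching printed conventions.
* **HLA homozygosity** is allele string equality at a locus, over seven
  loci (class I: A, B, C; class II: DPA1, DPB1, DQB1, DRB1); samples
  missing a locus leave that locus's denominator. Parental homozygosity and
  loss of heterozygosity are not distinguished (they are not
  distinguishable from genotype calls alone).
* **Neoantigen bins**: IC50 intervals high `[0, 50)`, intermediate
  `[50, 500)`, low `[500, 5000)`, none `[5000, ∞)` nmol/L. The published
  interval wording leaves the boundary points 50/500/5000 unassigned;
  lower-closed half-open intervals are this package's convention.

## Cohort statistics

Continuous group comparisons use the tie-corrected Kruskal–Wallis test with
Benjamini–Hochberg correction applied across exactly the family of
variables passed in one call — families from different analyses are never
pooled. Two-group contrasts use the two-sided Mann–Whitney test (exact when
the combined n ≤ 20 without ties, otherwise normal approximation with tie
and continuity correction). Binary prevalences use Fisher's exact test for
2×2 tables with any expected cell at or below 5, otherwise Pearson
chi-square without continuity correction. Correlation heat maps use
Spearman (or Pearson) on pairwise-complete observations with a
non-significance mask at `p > 0.05` and an NA for pairs with fewer than 4
complete observations.

Differential expression is deliberately simple, matching a log2
fold-change-of-means formulation:
`log2fc = log2(mean_a + 1) - log2(mean_b + 1)` with a per-gene Mann–Whitney
p-value and BH adjustment across genes. The underlying test statistic is
not dictated by the fold-change definition; Mann–Whitney was chosen for
consistency with the rest of the comparison layer and a Welch t on
`log2(TPM + 1)` is available. The significance default is adjusted
`p < 0.05` (some figure-level analyses use 0.01; `alpha` is a parameter).

## The synthetic cohort generator

The generator is first-class, tested code. It emulates:

* **Group sizes** 350 PCM / 94 MBM / 870 ECM (1,314 samples) by default.
* **Cell mixing**: per-sample fractions over ten immune types plus a tumor
  compartment, drawn from group-specific Dirichlet priors; the tumor
  fraction is clamped to ≥ 0.3, consistent with microdissected specimens
  of at least 10% tumor content with margin. The MBM prior plants depleted
  B cells, M2 macrophages, NK cells, Tregs and dendritic cells, and
  enriched M1 macrophages.
* **Reference profiles**: each cell type owns a disjoint block of 20 marker
  genes. Each marker gene has one log-normal baseline (location 3, scale
  1.2 on the log2 scale), multiplied by 2^3 in the owning type and 2^-2
  elsewhere; the shared baseline makes the owner's dominance deterministic,
  which independent per-column draws would occasionally violate. Columns
  are TPM-normalized so convex mixtures are valid TPM profiles — this is
  what makes noiseless deconvolution recovery exact (machine precision),
  a property the tests assert at `< 1e-6`.
* **Expression noise** is multiplicative log-normal (default sdlog 0.5),
  the standard bulk RNA-seq variance structure; it keeps TPM non-negative.
* **Planted signature shifts** are additive log2 effects on built-in
  gene-set members for a designated group. Defaults (MBM: IFNγ −1.0, TIS
  −0.8, STING −0.5, exhaustion +0.3, OXPHOS +1.0, TCA +0.6, glycolysis
  +0.5, plus an up/down DEG block) reproduce the qualitative directions of
  the published findings; published work reports directions and
  significance but not effect sizes, so the magnitudes are free parameters
  of the generator, chosen once as plausible moderate effects.
* **Mutations**: pathogenic driver mutations are Bernoulli per assessed
  sample at per-group rates whose defaults mirror printed group rates
  (BRAF 47.8%, NRAS 22.0%, NF1 68.3% in MBM among assessed; PTEN
  16.3/8.1/6.0% across MBM/PCM/ECM). Per-gene assessment coverage
  (`assessed_prob`) models the differing published per-gene denominators
  (e.g. 92, 91, and 41 of 94 MBM); unprinted PCM/ECM rates for BRAF, NRAS,
  and NF1 are free parameters. TMB is realized as VUS missense filler
  records drawn negative-binomial (mean = group rate × footprint), so TMB
  counting and pathogenic frequency analysis remain independent; a few
  germline-flagged records exercise the germline exclusion. An additive
  log2 shift on angiogenesis genes in PTEN-mutant MBM plants the
  mutation-conditional enrichment the pipeline's PTEN/angiogenesis table
  tests.
* **HLA / neoantigens**: per-locus homozygosity at configurable rates
  (default 15%); neoantigen counts scale with TMB and IC50 is log10-uniform
  over `[1, 1e5]` nmol/L, spanning all four bins.

A single master seed derives independent child seeds per table, so adding
one artifact never perturbs another; the same config and seed reproduce
byte-identical files.

What the generator does **not** emulate: read-level noise, batch and
platform effects, gene–gene correlation beyond cell-type mixing,
eQTL-style mutation–expression linkage (besides the planted PTEN effect),
matched multi-site samples, and real marker-gene biology. Passing tests
therefore demonstrate the correctness and statistical behavior of the
machinery under a controlled model, not the biological validity of any
particular real-data finding.

## Numerical choices and degenerate inputs

* Duplicate gene rows collapse by per-cell maximum TPM with a warning
  (deterministic and conservative for signature scoring); gene symbols are
  matched case-sensitively after trimming, with no alias resolution.
* Tie-breaks in every ranking are stable by gene symbol; ES magnitude ties
  resolve positive; tertile ties classify as undetermined.
* Problem sizes in the tests are chosen to keep the default suite around a
  minute: module tests use cohorts of tens of samples and a 400-gene
  universe; the power property uses 100 generator seeds at 50 samples per
  group; the qualitative direction checks run one full-size default cohort
  (1,314 samples, 1,000 genes).
* The "1-SD planted shift" power condition is realized by setting the
  noise sdlog to `ln 2` — making the per-gene log2 noise SD exactly 1 — and
  planting a −1.0 log2 IFNγ shift in MBM.

## Known limitations

* The deconvolution omits mRNA-content scaling by default, so fractions are
  expression-share estimates; rankings and correlations are unaffected, but
  absolute fraction comparisons against scaled published outputs are not
  bit-reproducible.
* The empirical GSEA p-values have resolution `1/(nperm + 1)`; FDR at small
  set counts is coarse.
* The per-gene assessed-coverage model treats coverage as missing
  completely at random; real panel coverage is not random.
* Real IFNγ / TIS signature memberships are citation-sourced defaults, not
  assertions about any specific published cohort.
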