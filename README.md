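# tmeprofiler

Immunogenomic characterization of the melanoma tumor microenvironment
(TME) from bulk transcriptomic and targeted-panel mutation data, for
cohorts split into three anatomic groups: primary cutaneous melanoma
(PCM), melanoma brain metastases (MBM), and extracranial metastases (ECM).

Brain metastases are the common failure mode of advanced melanoma, and
whether a given tumor will respond to immune checkpoint blockade depends
on features of its microenvironment that can be read out of routine bulk
sequencing. `tmeprofiler` implements that readout as a tested, reusable
pipeline:

* **Composite z-score signatures** — the interferon-gamma (IFNγ) score
  (mean of per-gene cohort z-scores of log2(TPM+1) over the signature
  genes), three-way T cell-inflamed (TIS) classification, the T cell
  dysfunction score *z*(HAVCR2) + *z*(LAG3) + *z*(PDCD1), the STING
  pathway score over TMEM173/CGAS/CCL5/CXCL10/IRF3, and the
  non-functional CD8 rule (dysfunction > 1.0 and FGFBP2 below the cohort
  median, among tumors with non-zero CD8 infiltration).
* **Immune-cell deconvolution** — absolute fractions of ten immune cell
  types plus an uncharacterized remainder by non-negative least squares
  on a marker-gene signature matrix (the quanTIseq formulation).
* **Enrichment** — preranked GSEA (weighted Kolmogorov–Smirnov running
  sum, gene-permutation null, NES, empirical p, BH and NES-ratio FDR) and
  single-sample GSEA with rank-position weighting.
* **Genomic features** — tumor mutational burden (non-germline missense
  per 1.4 MB footprint, high at ≥ 10 mut/MB), pathogenic mutation
  frequencies with per-gene assessed denominators, HLA homozygosity at
  seven loci, and neoantigen IC50 affinity bins (50 / 500 / 5000 nmol/L).
* **Cohort statistics** — Kruskal–Wallis with Benjamini–Hochberg
  correction per variable family, two-sided Mann–Whitney, Fisher /
  chi-square proportion tests, Spearman correlation matrices with
  significance masks, and log2 fold-change differential expression.
* **A synthetic cohort generator** — a fully labeled three-group cohort
  (default 350 PCM / 94 MBM / 870 ECM) with planted signature shifts,
  immune mixing differences, mutation rates, and TMB distributions, so
  the entire pipeline is testable without protected patient data.

See `vignettes/tme-profiling.Rmd` for the methods, parameter defaults, and
the generator's scope and limitations.

## Worked example

```r
library(tmeprofiler)

cfg <- generator_config(n_per_group = c(PCM = 40, MBM = 30, ECM = 40),
                        n_genes = 400, seed = 7)
cohort <- generate_cohort(cfg)

scores <- data.frame(group = cohort$manifest$group,
                     ifng = ifng_score(cohort$expression),
                     dysfunction = dysfunction_score(cohort$expression))
aggregate(cbind(ifng, dysfunction) ~ group, scores, median)
#>   group   ifng dysfunction
#> 1   ECM  0.375      -0.371
#> 2   MBM -1.052       0.028
#> 3   PCM  0.405      -0.206
```

The planted brain-metastasis effect is visible: the MBM median IFNγ score
sits well below PCM and ECM (lower immunogenicity), and the dysfunction
score trends higher. A Kruskal–Wallis test across groups confirms it:

```r
kruskal_bh(rbind(ifng_score = scores$ifng), cohort$manifest$group)
#>     variable statistic    raw_p    adj_p median_ECM median_MBM median_PCM
#> 1 ifng_score      65.4 6.36e-15 6.36e-15      0.375      -1.05      0.405
```

Deconvolution returns per-sample fractions on the simplex (ten immune
types plus `other`, the tumor/stromal remainder):

```r
fr <- deconvolve(cohort$expression, default_signature_matrix(cohort$reference))
round(fr[c("PCM_001", "MBM_001"), c("B_cells", "T_cells_CD8", "other")], 3)
#>         B_cells T_cells_CD8 other
#> PCM_001   0.104       0.017 0.191
#> MBM_001   0.043       0.152 0.344
```

Pathogenic mutation frequency with per-gene assessed denominators:

```r
path <- filter_pathogenic(cohort$mutations)
rbind(mutation_frequency(path, cohort$manifest, "PTEN", "MBM",
                         assessed = cohort$truth$assessed$PTEN),
      mutation_frequency(path, cohort$manifest, "PTEN", "PCM",
                         assessed = cohort$truth$assessed$PTEN))
#>   group gene k  n  pct
#> 1   MBM PTEN 4 28 14.3
#> 2   PCM PTEN 1 37  2.7
```

The full analysis — all scores, fractions, genomic features, group tests,
the PTEN/angiogenesis comparison, metabolic-pathway correlations, and DEG
tables — runs in one call and writes a TSV report bundle:

```r
run_pipeline(pipeline_config(simulate = cfg, out_dir = "report", seed = 7))
```

A thin command-line front end over the same functions is installed at
`system.file("cli/tme_profiler.R", package = "tmeprofiler")` with
`simulate`, `score`, `deconvolve`, `genomics`, `gsea`, `ssgsea`, and `run`
subcommands.

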