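# meningiomics

Integrated transcriptome / methylation / copy-number analysis for
discovering prognostic molecular subgroups in anaplastic meningioma —
the rare, aggressive WHO grade III meningioma whose histological grade
predicts outcome poorly. The package implements the full discovery
pipeline as reusable, tested components, together with a multi-omic
synthetic cohort generator (the real cohorts behind such studies are
controlled-access), so every stage runs and is verified end to end on data
with known ground truth.

## What it computes

* **Expression subgrouping** — median-of-ratios size factors, a
  variance-stabilizing log transform, Poisson deviance distance
  d(a,b) = sqrt( Σ_g [dev(x_ga; μ_ga) + dev(x_gb; μ_gb)] ) with
  μ_ga = s_a (x_ga + x_gb)/(s_a + s_b) over the top-250 variable
  transcripts, hierarchical clustering, and silhouette-based selection of
  the cluster number k.
* **Differential expression** — per-gene negative-binomial Wald regression
  (Var = μ + αμ², IRLS, trend-shrunk method-of-moments dispersion) with a
  control-gene unwanted-variation factor plus hidden factors orthogonal to
  it, Benjamini–Hochberg adjustment.
* **Minimal marker panel** — intersect top-50 |PC1| loadings with
  stringent DE hits (|log2FC| > 4, adjusted p < 1e-4), then greedily reduce
  to the smallest panel whose re-clustering still reproduces the C1/C2
  partition exactly (adjusted Rand index 1).
* **Survival** — Kaplan–Meier curves, log-rank (Mantel-Cox) test, and the
  Mantel–Haenszel hazard ratio HR = exp((O−E)/V) with 95% CI
  exp((O−E)/V ± 1.96/√V).
* **Methylation** — EPIC-style probe filtering (detection p, SNPs, X/Y,
  promoter∩island), per-probe ANOVA with FDR < 0.01 and Δβ > 0.2,
  Manhattan/Ward clustering.
* **Copy number** — ploidy-adjusted aggregate profile in 10-kb bins
  (median and quartiles of total_cn − ploidy) and rule-based driver calls
  (focal < 1 Mb homozygous deletions over tumor suppressors; oncogene
  amplifications > 5 copies diploid / > 9 tetraploid).
* **Mutational signatures** — multi-restart KL-NMF over 96-channel
  trinucleotide catalogues with cosine-matched stability, plus
  non-negative least-squares exposure attribution.
* **Enrichment** — hypergeometric overlap tests and permutation-based
  functional class scoring with hallmark-level aggregation.

## Worked example

```r
library(meningiomics)

# a synthetic 12 + 13 cohort: 2000 genes, six C1 markers at log2FC 5,
# true hazard ratio 17
report <- run_pipeline(load_config(list(
  seed = 7,
  simulate = list(n_genes = 2000),
  stages = list(enrichment = TRUE))))
print(report)
#> <pipeline_report>
#>   subtype: k*=2, ARI vs truth=1
#>   de: 6/2000 significant at padj<0.01 & |lfc|>2
#>   markers: panel of 1 (g0005)
#>   survival: HR 23.47 (6.88-80.07), log-rank p=4.64e-07
#>   methylation: 645 retained, 50 selected
#>   cnv: 41 driver calls over 24000 bins
#>   signatures: k=2, min stability 1.000
```

Reading the output: silhouette selection picks two expression subgroups
and they match the planted labels exactly (ARI 1); exactly the six planted
markers pass the DE thresholds; greedy reduction finds that a single
marker transcript already recapitulates the split on this cohort; the
hazard-ratio interval (6.9–80.1) covers the simulated truth of 17; all 50
planted differential probes are selected after filtering; and both planted
mutational signatures are recovered with perfect restart stability.

Individual stages are plain functions on data frames / matrices and
compose with the pipe; results are tibbles with `tidy()`/`glance()`
methods and `autoplot()` plots (KM curves, volcano, aggregate CN profile,
signature spectra):

```r
cohort <- simulate_cohort(cohort_config(seed = 7))
sub    <- discover_subgroups(cohort$counts)
surv   <- compare_survival(cohort$survival)
tidy(surv$hazard_ratio)
autoplot(surv$km)
```

A thin command-line wrapper lives at `inst/scripts/run_pipeline.R`
(`--config cohort.yaml --outdir out --seed 1 --stages subtype,de,survival`).

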