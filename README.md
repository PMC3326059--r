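# clinetile

Detecting latitudinal (clinal) differential gene expression from genome
tiling arrays.

Populations of *Drosophila melanogaster* at the tropical and temperate ends
of a latitudinal gradient differ in adaptive quantitative traits such as
body size. One route to the genes involved is to compare transcription
between the cline ends during larval development using whole-genome tiling
arrays — arrays whose probes cover the genome at fixed spacing regardless of
annotation. `clinetile` implements the complete analysis chain for such an
experiment, for analysts who want each stage as a tested, reusable R
function rather than a one-off script:

* **Probe annotation** — map probe sequences to the genome allowing one
  substitution on either strand, keep uniquely mapping probes, and label
  each as exonic, intronic or intergenic.
* **Preprocessing** — per array and chromosome, subtract a local background
  (nearest-rank 5th percentile of the 1001-probe window centred on each
  probe, smoothed by first-degree loess), then calibrate arrays with a
  generalized-log (arsinh) variance-stabilizing transform.
* **Probe-wise statistics** — empirical-Bayes moderated t-tests of the
  North − South contrast per larval stage:
  `s̃² = (d₀s₀² + ds²)/(d₀+d)`, `t̃ = effect / √(s̃²(1/n_N + 1/n_S))`,
  with (d₀, s₀²) estimated by moment matching on log s².
* **Region calling** — a probe is differentially expressed if its p-value
  is below 1e-5 (*short*), the geometric mean with its two flanking probes
  is below 0.01 (*medium*), or the Gaussian-weighted (variance 5) geometric
  mean of the 21-probe window is below 0.1 (*long*); calls are summarized
  into gene and intergenic-region lists, and between-stage overlap is
  tested with the hypergeometric upper tail.
* **Enrichment** — Wilcoxon rank-sum scoring of gene categories on the
  moderated-t-ranked gene list, with a gene-category permutation FDR.
* **Clinal statistics** — OLS regression of expression or allele frequency
  on latitude, externally Studentized residual outlier screening with
  Bonferroni adjustment, and ΔΔCt relative expression for qPCR tables.
* **Synthetic data** — a generator that plants known clinal effects in a
  tiled genome (5 + 5 replicate arrays at two larval stages by default), so
  the whole pipeline is testable without array data.

See `vignettes/clinetile-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

Simulate the default fixture (2 × 200 kb chromosomes, 80 genes, 8 planted
with |log2FC| = 2) and run the full pipeline:

```r
library(clinetile)

mf <- run_pipeline(pipeline_config(outdir = "demo_run", seed = 1))

mf$results$stages$L2$summary$counts
#>     n_probes      n_genes n_intergenic
#>          472            9           35

g2 <- mf$results$stages$L2$summary$genes
head(g2[order(g2$best_p), ], 4)
#>      gene_id direction n_probes       best_p
#> 3 gene_1_017     North       25 3.148130e-22
#> 6 gene_2_001     South       23 1.961528e-21
#> 7 gene_2_010     South       59 2.377971e-21
#> 8 gene_2_030     South       42 4.503237e-21
```

At stage L2 the caller flags 472 probes covering 9 genes and 35 intergenic
regions; all 8 planted genes are recovered with their planted directions
(`mf$results$truth`), plus one unplanted gene — single-probe and intergenic
calls are dominated by the long-scenario false-call rate, mirroring the
observation that intergenic calls reproduce poorly between stages. The
between-stage gene-list overlap (8 of the 9 and 10 called genes shared, in
an 80-gene universe) is far beyond chance:

```r
mf$results$overlap$k   # 8
mf$results$overlap$p   # 1.362655e-08
```

and the planted expression cline is recovered with its displaced
population flagged:

```r
mf$results$cline$fit$r_squared       # 0.34 with the outlier in
mf$results$cline$outliers$outlier    # population 8 flagged
mf$results$cline$refit$r_squared     # 0.91 after exclusion
```

The same functions work stand-alone on real tables: `annotate_probes()`,
`preprocess_intensities()`, `probe_stats()`, `call_probes()`,
`summarize_calls()`, `overlap_test()`, `enrich_categories()`,
`latitude_regression()`, `relative_expression_ddct()`.

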