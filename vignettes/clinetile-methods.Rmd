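---
title: "Methods: clinal tiling-array differential expression with clinetile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinal tiling-array differential expression with clinetile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinetile)
```

## The problem

Populations of *Drosophila melanogaster* along a latitudinal gradient show
clinal variation in quantitative traits such as body size. One route to the
genes behind such variation is to compare transcription between the two ends
of the cline ("North" and "South") during development, using genome tiling
arrays — arrays whose short probes cover the genome at a fixed spacing
regardless of annotation, so that differential transcription can be detected
in exons, introns and intergenic regions alike. clinetile implements the
complete analysis chain for such an experiment, together with a synthetic
data generator that plants known clinal effects, so every stage can be
validated end to end without array data.

## Pipeline and models

### Probe mapping and labelling

Probe sequences are aligned to the genome allowing at most one alignment
error on either strand. "One error" is read as one substitution (Hamming
distance), not an indel: a tiling probe hybridizes at its full length, and an
indel would change the probe-length semantics. Matching is exhaustive: for
the one-mismatch case each probe is split into two halves, one of which must
match exactly (pigeonhole), exact half-matches are located with a
Biostrings dictionary scan, and every candidate is verified base by base.
Only probes mapping to a single genomic location are retained; the rest are
labelled `multi` or `unmapped` and excluded from all statistics. Probes
containing ambiguous bases are rejected loudly rather than wildcard-matched —
silent label drift is worse than an error.

Each retained probe gets exactly one label with the precedence
exon > gene body > intergenic: *exonic* if its interval overlaps at least
one base of any exon, else *intronic* if it overlaps any gene body, else
*intergenic*. A probe straddling a gene boundary that touches no exon is
therefore intronic. Intergenic regions are enumerated as the maximal
per-chromosome complement of the union of gene spans, so that intergenic
calls can be counted as discrete regions.

### Local background and normalization

Tiling arrays carry a smooth, position-dependent stray signal that is
additive on the raw intensity scale. Per array and per chromosome, the local
background at each probe is the nearest-rank 5th percentile of the window
holding the probe and the 500 probes on each side (up to 1001 values;
windows truncate at chromosome ends, where the rank is recomputed as
`ceiling(0.05 * m)` for the m values available). The nearest-rank convention
was chosen because it is exactly reproducible and trivially oracle-checkable
by a per-window sort. The raw background profile is then smoothed by
first-degree local regression (tricube-weighted linear fits, one gaussian
pass, default span 0.3 of the chromosome's probes) and subtracted. Negative
background-subtracted values are preserved — the downstream transform is
defined on all reals.

Between-array normalization uses the generalized-log (arsinh) transform
`h_j(x) = asinh((x - a_j) / b_j)` per array. The reference transform's
offset and scale are estimated from the across-array mean–sd relationship
(a robust line through decile medians of per-probe means and sds: with
noise sd ≈ s₀ + k·mean, the transform `asinh((x + s₀/k)/s₀)` has
approximately constant spread, behaving as a shifted log above the noise
floor while staying linear through zero). Every other array is then
calibrated to match the reference in median and MAD: the offset follows
from the scale in closed form because medians commute with monotone
transforms, and the scale is found by one-dimensional root finding on the
MAD. This preserves the two properties
downstream statistics rely on — variance stabilization across the intensity
range and between-array calibration — with a deterministic, dependency-free
calibration in place of a full maximum-likelihood fit. A degenerate array
(zero MAD) is an error, not a silent pass-through.

### Probe-wise moderated statistics

Within each larval stage, each probe is tested for a North-minus-South mean
difference with an empirical-Bayes moderated t. The per-probe sample
variance s² (pooled within groups, d residual df) is shrunk toward a prior
variance s₀² with prior df d₀:

s̃² = (d₀·s₀² + d·s²) / (d₀ + d),  t̃ = effect / √(s̃²·(1/n_N + 1/n_S)),

with p-values from Student's t on d₀ + d df (standard normal when d₀ is
infinite). The hyperparameters are estimated by moment matching on
z = log s²: `trigamma(d0/2) = var(z) − trigamma(d/2)` (numeric trigamma
inversion), with the mean of z fixing s₀². If var(z) does not exceed the
chi-squared sampling contribution, d₀ = ∞ and s̃² is the common variance.
Moment matching was chosen over marginal likelihood because it is
closed-form-checkable; the test suite cross-checks it against an independent
empirical-Bayes implementation and verifies both limits (d₀→0 gives the
ordinary pooled t; d₀=∞ gives the known-variance z). Stages are analysed
separately as independent two-group contrasts; no intensity-trend
moderation is applied.

### Three-scenario probe calling

A probe is called differentially expressed when any of three window
scenarios fires on the position-ordered p-values:

* **short** — its own p < 1e-5;
* **medium** — the geometric mean of its p and its two immediate
  neighbours (3-probe window) < 0.01;
* **long** — the Gaussian-weighted geometric mean of the 21-probe window
  (10 each side; weights `exp(-i²/(2·5))` on probe-index distance, variance
  5 in index² units) < 0.1.

Weighted geometric means are `exp(Σ w·log p / Σ w)` and always lie between
the window's extreme p-values. Windows never cross chromosome boundaries
and truncate at ends with weights renormalized. The medium scenario is read
as a 3-probe window ("the probe and the two probes up- and downstream",
i.e. one each side); the alternative 5-probe reading is available via
`medium_flank = 2` but not endorsed. Called probes are summarized into
genes (any gene overlapped by a called exonic or intronic probe; an
exonic-only mode is available) with a direction given by the sign of the
mean effect of the gene's called probes, and into intergenic regions
containing called intergenic probes. Between-stage reproducibility of the
gene lists is tested with the hypergeometric upper tail on the observed
intersection; the universe defaults to the number of genes with at least
one retained probe.

### Rank-based category enrichment

Genes are ranked by their strongest probe statistic (max-|t| by default;
the mean is available — the choice of per-gene summary is genuinely open,
and max-|t| favours genes with at least one strongly responding probe run).
Rankings are built separately for the up-in-North and up-in-South
directions. A category of m genes is scored by the Wilcoxon rank sum W of
its members; the one-sided p-value is P(W′ ≤ W) under uniformly random
rank assignment — exact via the rank-sum null distribution when
m·(N−m) ≤ 2000, otherwise a normal approximation with continuity correction
(mean m(N+1)/2, variance m(N−m)(N+1)/12). The false discovery rate is
estimated by gene-category permutation: each permutation shuffles the
gene-to-rank assignment and recomputes all category p-values; FDR(c) is the
mean number of null categories per permutation at or below p(c), divided by
the observed number, capped at 1. Chromosomal-window categories (genes
overlapping a genomic interval by ≥1 bp, the same overlap rule used for
probe labels) can be generated from the annotation and scored alongside
functional categories read from GMT files.

### Clinal regression and ΔΔCt

Population-level values (relative expression, allele frequency) are
regressed on latitude by ordinary least squares; latitudes are stored as
signed degrees (southern hemisphere negative), with an absolute-latitude
option since published clines are often reported either way. Outliers are
screened with externally Studentized residuals — each point standardized by
a leave-one-out variance estimate, referred to t with n−3 df, two-sided,
Bonferroni-multiplied by n and capped at 1; flagged points (adjusted
p < 0.05) trigger a side-by-side refit excluding them. External (not
internal) studentization is required for this standard single-outlier test.
qPCR tables are converted to relative expression by the conventional ΔΔCt
method with amplification efficiency exactly 2:
`2^-((Ct_target−Ct_ref)_sample − mean(Ct_target−Ct_ref)_calibrator)`.

## The synthetic-data generator

The generator emulates the study design: two cline ends × two larval
stages × five biological replicates, 25-mer probes tiling every chromosome
at a 40 bp step, and a minority of genes planted with a North/South
expression difference. Per probe and array, the log2 signal is

baseline + probe affinity + group shift (± half the planted log2 fold
change, exonic probes of planted genes only) + replicate noise,

and the raw intensity is the exponentiated signal plus a smooth per-array
additive background (a three-period sinusoid along each chromosome plus a
per-array offset, default amplitude 100 intensity units — comparable to the
non-expressed probe level). The background is additive on the *raw* scale
deliberately: that is the artefact class the windowed-percentile subtraction
is designed to remove, so the preprocessing stage is genuinely exercised
rather than decorative. Planted effects are applied uniformly to all exonic
probes of a gene (tiling analysis operates on probe runs, not isoforms) and
identically at both stages, which is what makes the between-stage overlap
test meaningful on synthetic data.

Default fixture: 2 chromosomes × 200 kb, 80 genes of 800–2400 bp with 3
exons and short (60–100 bp) introns, minimum intergenic gap 800 bp, 10% of
genes planted at |log2FC| = 2, probe affinity sd 0.5, replicate noise sd
0.25. These sizes keep a full pipeline run around a minute while leaving
several thousand probes per chromosome so the 1001-probe background window
is meaningful; the minimum gap keeps the few-probe bleed of the long calling
window on a strong gene from reaching its neighbour, so planted-truth
bookkeeping stays unambiguous. Gene placement distributes the free space
randomly among the gaps (multinomial split), coordinates are 1-based
inclusive (GFF3 convention) and converted to 0-based half-open only when
writing BED.

What the generator does *not* emulate: sequence-composition (GC) affinity,
cross-hybridization, isoform structure, spatially correlated noise beyond
the smooth trend, and DNA sequence divergence between populations (which in
real data can depress hybridization and mimic expression differences).
Passing tests therefore demonstrate that the statistical machinery recovers
planted signal under the stated noise model — not that real-array artefacts
beyond that model are handled.

## Numerical choices and degenerate inputs

* Nearest-rank percentile (ceiling) for the background; exactly
  reproducible, no interpolation.
* Windows truncate (never pad or wrap) at chromosome ends; weights
  renormalize.
* p-values of exactly 0 are refused by the aggregation operations — a
  degenerate probe must be resolved explicitly upstream.
* Probes with N bases, unknown chromosomes, empty chromosomes, zero-MAD
  arrays, groups with fewer than two replicates, categories covering the
  whole gene list, regressions with fewer than three points or zero latitude
  variance: all are explicit errors, not silent repairs.
* Ties in gene ranking break by gene id; permutations and all simulations
  are reproducible from integer seeds, with the caller's RNG state restored.
* Exact-vs-approximate switch for the rank-sum null at m·(N−m) = 2000
  (the exact recursion's cost grows with the square of m·(N−m); past this
  point the normal approximation is accurate to a few percent).

## Problem sizes used in the test suite

Unit tests run on purpose-built fixtures of tens to thousands of probes.
The calibration and recovery checks use: 1e6 uniform null p-values for the
scenario-calling rates; the default 2×200 kb fixture (≈10,000 probes × 20
arrays) for planted-gene recovery; 50,000 simulated variances for prior
recovery; 1e6 Monte-Carlo resamples for the rank-sum normal approximation;
10,000 probes for the background oracle; and 100 replicate clines for the
outlier screen. These sizes were chosen so the full suite completes in a
few minutes while leaving the statistical assertions well-powered.

## Known limitations

* The arsinh calibration matches medians and MADs rather than maximizing
  the generalized-log likelihood; on heavily skewed arrays the two can
  differ, though both stabilize variance.
* The moderated model assumes a common residual df across probes (true
  within this pipeline, where every probe sees the same arrays).
* The permutation FDR treats categories as exchangeable; strongly
  overlapping categories make it conservative.
* The long-scenario threshold (0.1 on a 21-probe weighted geometric mean)
  admits a non-trivial per-probe false-call rate under a uniform null
  (~3×10⁻³); on sparse gene lists the resulting unplanted calls are the
  dominant error mode, which is visible in the planted-recovery results and
  should be kept in mind when interpreting small called lists.
* Latitude regressions assume independent populations; shared ancestry or
  spatial autocorrelation is not modelled.
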