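---
title: "Data-driven RNA phenotyping from base-level coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven RNA phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Annotation-based ("knowledge-driven") RNA phenotyping quantifies one
regulatory mode at a time — expression, isoform ratios, intron excision,
alternative TSS/polyA, stability — and inherits the blind spots of the gene
models it relies on: unannotated isoforms are missed or misattributed, and
the resulting phenotypes are heavily correlated with one another. `ddpheno`
takes the complementary, mechanism-agnostic route: it treats the base-level
RNA-seq coverage profile of each gene as the primary object, compresses it
into a small number of *orthogonal latent phenotypes* per gene, and exports
them in the grouped-phenotype layout that cis-QTL mappers and TWAS pipelines
consume. Each phenotype is a principal component of binned, normalized
coverage, so its loadings can be read directly as "which parts of the gene
move together".

# The procedure

For each protein-coding or lncRNA gene, the phenotyping region is the gene
span plus a 1,000 bp flank on each side. Internally all coordinates are
0-based half-open (the bigWig convention); GTF input is converted on parse.

## 1. Variance-adaptive binning

Let $c_{s,i}$ be coverage of sample $s$ at base $i$. Over a seeded draw of
up to 256 *binning samples*, we compute

$$ v_i = \operatorname{Var}_s\!\left[\, \log_2(c_{s,i+1} + q) - \log_2(c_{s,i} + q) \,\right], $$

with pseudocount $q = 8$ and the unbiased ($n-1$) variance estimator. This
*variance profile* is large where coverage changes differently across
individuals — exon edges, alternative starts/ends, variably used cassettes —
and near zero in flat or invariant stretches. A greedy left-to-right scan
accumulates $v_i$ and closes the current bin as soon as the running sum
reaches a global threshold $\tau$; the base whose entry triggers the
threshold is included in the closing bin and the accumulator resets to zero
(no carry-over of the excess). The trailing partial bin is kept. Because the
$v_i$ are non-negative the running sum is monotone, so the scan is
implemented as binary search on the cumulative profile; this is exactly the
greedy partition, just faster, and the test suite checks it against a
literal loop.

$\tau$ is shared by all genes. It is calibrated once per training set by
bisection on $\log_{10}\tau$ (40 iterations max) until the mean bin count
over a seeded sample of up to 128 genes is within 2% of the target (256
bins/gene by default). Calibration counts bins *before* subdivision and
exon exclusion: those two steps depend on per-gene geometry rather than on
the segmentation signal, and counting before them keeps the calibrated
quantity a pure function of the profiles. Bins wider than 1,024 bases are
then subdivided into $\lceil w/1024 \rceil$ near-equal parts (longer parts
first), and any bin overlapping an exon of a *different* gene — any biotype,
either strand — is removed, since coverage there cannot be attributed to the
focal gene. Removed bins stay in the scheme file (status `removed`) so kept
plus removed bins always tile the region exactly.

A uniform fixed-width segmentation (`uniform_bins()`) is provided as the
benchmarking alternative; it shares the exclusion code path.

## 2. Normalization

Per sample, total binned coverage (the sum of raw per-bin means over all
phenotyped genes' kept bins) is divided by the cohort median to give a
scaling factor; coverage is divided by that factor, then transformed as
$\log_2(x + 8)$. The order — scale, then pseudocount, then log — is fixed.
Totals are accumulated over genes in sorted gene-ID order so that results
are bit-identical however the genes were batched.

Scaling factors are recomputed for *each* dataset a model is applied to:
depth is a property of the library, not of the model.

## 3. Per-gene PCA

Genes with nonzero total coverage in fewer than 50% of samples (strictly:
fraction $\geq 0.5$ is kept) are dropped — at training, and again on the
target samples at application. Each kept gene's bins are standardized
(train mean, train sd; zero-variance bins get sd 1 so they contribute a
constant 0) and a PCA is fitted. Components are retained up to the smallest
$k$ whose cumulative explained-variance ratio reaches 0.80, capped at 16 and
at the rank bound $\min(\#\text{bins}, n_\text{samples} - 1)$ — the $-1$
because centering consumes one degree of freedom. Sample projections onto
the retained components are the phenotypes (DDP1, DDP2, ...).

Two reproducibility choices are worth stating. First, PCA signs are
arbitrary, so each component is flipped, if needed, to make its
largest-|loading| bin positive (ties resolved to the lowest bin index).
Second, when a model is applied to new data the *training* standardization
parameters are used, so a phenotype means the same linear functional of
coverage in every dataset; per-dataset re-standardization is available
behind `restandardize = TRUE` for users who prefer within-cohort scaling.

## 4. Residualization (rDDPs)

To make the latent phenotypes complementary to an existing knowledge-driven
set rather than overlapping with it, each bin feature can be residualized
against the gene's KDPs before PCA, independently per bin:

1. OLS of the bin on an intercept plus all of the gene's KDPs;
2. keep KDPs with two-sided coefficient t-test $p < 0.01$
   ($\mathrm{df} = n - \mathrm{rank}$);
3. refit on the intercept plus the kept KDPs and subtract the fitted values.

With nothing retained the residual is the centered response, which is also
the $\alpha \to 0$ limit. The regressions are solved by pivoted QR;
coefficients dropped at the rank boundary (collinear KDPs, or more KDPs
than degrees of freedom) get $p = 1$ and are never retained, which is the
graceful-degradation behaviour one wants from a screening step. Pass-1
p-values come from the joint regression; a marginal variant was considered
and rejected because correlated KDPs would then all pass or fail together.
Samples with missing KDP values are mean-imputed when they are at most 20%
of the cohort and refused otherwise — a simpler policy than
complete-case-refit hybrids, and deterministic.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `flank_bp` | 1000 | bases | captures promoter/terminator-proximal coverage |
| `pseudocount` | 8 | coverage depth | stabilizes log-variance at low depth |
| `target_mean_bins` | 256 | bins/gene | resolution vs. downstream cost |
| `n_calibration_genes` | 128 | genes | enough to pin the global threshold |
| `n_binning_samples` | 256 | samples | enough for stable per-base variances |
| `max_bin_size` | 1024 | bases | bounds within-bin averaging extent |
| `variance_target` | 0.80 | fraction | retained-variance floor per gene |
| `max_components` | 16 | components | caps phenotype count per gene |
| `min_nonzero_fraction` | 0.5 | fraction | drops effectively unexpressed genes |
| `alpha` | 0.01 | p-value | KDP retention screen |

# The synthetic cohort generator

`sim_config()` / `simulate_coverage()` state a small world in which every
pipeline property is checkable without external data. Per gene: a 5–50 kb
span, 4–12 non-overlapping exons, two isoforms (the full chain and one
skipping an internal cassette exon), and a baseline exonic depth of
$20\times$ scaled by a per-gene factor in $[1/2, 2]$. Per sample: an
expression factor $e_s \sim N(0, 1)$, a usage factor $u_s \sim N(0, 1)$,
and a depth multiplier $d_s \sim \text{LogNormal}(0, 0.25)$ (roughly a 25%
library-size CV, typical of real cohorts). Expected per-base coverage is

$$ \lambda_s(x) = d_s \cdot 2^{\,b_g e_s} \sum_i w_i(u_s)\, \beta_g\,
   \mathbf{1}[x \in \text{exons}_i], $$

with softmax usage weights $w_i$ (slope 1.5 on $u_s$), and observed
coverage is Poisson($\lambda$). The gene-specific loading
$b_g \sim U(0.5, 1.5)$ on the shared expression factor is deliberate: if
every gene responded identically, median depth-scaling would remove $e_s$
exactly and "does DDP1 recover expression variation?" would be unanswerable
by construction. Heterogeneous loadings are also the realistic case —
co-regulation is never uniform. One overlapping gene pair is placed by
default so foreign-exon exclusion is exercised. Matched KDPs
(`simulate_kdps()`) are the log total expected gene coverage (expression)
and the isoform-1 weight (isoform ratio), plus Normal noise.

What the generator does *not* emulate: read-level artifacts (mappability,
GC, splice-junction edge effects), negative-binomial overdispersion beyond
Poisson, correlated gene–gene structure beyond the shared factors, and
annotation errors. A green recovery test therefore establishes that the
pipeline's linear algebra and normalization do what they claim on clean
coverage — not that the phenotypes are heritable or biologically meaningful
in any particular cohort.

All randomness flows from a single integer seed through fixed sub-seeds
(kept below $2^{31}$), so datasets are reproducible across platforms, and
the streaming source (`sim_coverage_source()`) regenerates each gene's
stack on demand, bit-identical to the materialized version.

# Numerical choices and degenerate inputs

* Variance estimator: sample variance (ddof 1); tiny negative round-off is
  clamped to zero so the cumulative profile stays monotone.
* All-zero variance profile: one bin spanning the region.
* Calibration with all-zero profiles across all genes: an error pointing at
  the input coverage, rather than a silent degenerate threshold.
* Constant (zero-variance) gene at fitting: a 0-component model; application
  returns an empty projection rather than failing.
* Threshold bisection bracket: $[10^{-8}, \max_g \sum_i v_i]$ — at the upper
  end every gene gets one bin, at the lower end one bin per base, so the
  target is always bracketed when it is attainable.
* Model stores embed a format-version string and refuse to load anything
  else.
* Ties in the PCA sign rule and in segmentation (flat cumulative stretches)
  resolve to the lowest index, matching the literal greedy definitions.

# Known limitations

* Exon exclusion is binary; a probabilistic assignment of shared coverage
  would retain more signal for overlapping genes.
* The calibration threshold is global; strongly heteroscedastic cohorts
  might prefer per-chromosome or per-expression-stratum thresholds.
* Residualization assumes linear KDP–coverage relationships.
* BED export positions every phenotype at the gene TSS (strand-aware); tools
  that want per-bin positions should read the scheme BED instead.
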