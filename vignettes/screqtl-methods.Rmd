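---
title: "scReQTL methods: VAF-based single-cell expression QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scReQTL methods: VAF-based single-cell expression QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screqtl)
library(tibble)
```

## The model

An scReQTL is a within-individual, within-cell-type correlation between the
variant allele fraction measured from RNA reads at a heterozygous SNV locus,

$$\mathrm{VAF}_{RNA} = \frac{n_{var}}{n_{var} + n_{ref}},$$

and the expression of a gene, across single cells. Unlike a conventional
eQTL, which needs genotypes across many individuals, the continuous
$\mathrm{VAF}_{RNA}$ serves as the genetic regressor within a single donor:
cell-to-cell fluctuation in allelic fraction is correlated with
cell-to-cell fluctuation in expression. For each (locus, gene) pair the
package fits ordinary least squares of normalized expression $y_c$ on the
observed VAF $v_c$ over the informative cells $c$ of one
(donor, cell type) group,

$$y_c = \alpha + \beta\, v_c + \sum_{j=1}^{k} \gamma_j\, \mathrm{PC}_{cj} + \varepsilon_c,$$

with the top $k = 15$ principal components of the group's expression as
covariates absorbing global structure (library depth residue, cell state).
The reported statistic is the VAF coefficient $\beta$, its $t$ statistic on
$n - (k + 2)$ degrees of freedom, and a two-sided $p$. Within each group,
q-values come from the Benjamini–Hochberg step-up, valid under independence
or positive dependence; pairs with $q \le 0.05$ are called significant by
default. A pair is *cis* when the SNV position lies inside the transcribed
interval of the correlated gene (closed interval, strand ignored);
everything else is *trans*.

Key assumptions: allele counts are UMI-deduplicated so the binomial
sampling unit is a molecule; VAF dropouts (coverage below minR) are
structural and handled by complete-case fitting, never imputed; the linear
model on normalized expression is adequate for the moderately-to-highly
expressed genes the coverage requirement selects.

## Filters and their parameters

The candidate loci and cells pass through a fixed filter sequence; each
step's threshold is exposed in `pipeline_params()`.

| Step | Rule | Default |
|---|---|---|
| Cell QC | remove mito fraction > `max_mito_fraction`; genes detected < `min_genes` or > `max_genes`; total counts > `max_total_counts` | 6%, 3000, 8000, 12 500 |
| Pooled biallelic | keep loci with ≥ `min_reads_per_allele` pooled reads on **each** allele | 50 |
| Informative entry | per-cell coverage ≥ `minR` | 10 |
| Variability | remove loci with > 75% of informative VAFs in [0.4, 0.6] (stable biallelic) or in [0, 0.25] ∪ [0.75, 1] (monoallelic/skewed) | bands of `vaf_bands()` |
| Minimum cells | keep loci informative in ≥ `min_cells` cells | 20 |
| Variable genes | remove genes with ≥ 80% of cells within 20% of the gene's own range from its floor or ceiling | 0.80 / 0.20 |

All removal comparisons on the QC metrics are strict, so a cell sitting
exactly on a boundary is kept; the count thresholds (50 reads per allele,
minR, 20 cells) are inclusive ("a minimum of N" keeps N). Band intervals
are closed, so a VAF of exactly 0.4 counts as stable-band. The 75%
dominance test is strict (`> 0.75`): a locus with exactly 15 of 20
informative VAFs in a band is *not* removed. These boundary conventions are
deliberate, documented choices; every one of them is configurable.

The minimum-cells rule is not arbitrary: under a null in which each cell
independently lands in the "variable" VAF range with probability one half,
the chance that at least $\lceil 0.75\,n \rceil$ of $n$ cells do so by
accident is the exact binomial tail `chance_variability_probability()`
computes — about 0.0207 at 20 cells ($21700/2^{20}$) and 0.0547 at 10
cells ($56/1024$), decreasing as cells accumulate. Twenty cells keeps the
chance of spuriously declaring a locus variable near 2%.

```{r binomial}
chance_variability_probability(20)
chance_variability_probability(10)
```

The variability filter also has a `mode = "strict"` variant that keeps a
locus only when more than 75% of its VAFs fall inside the complementary
variable bands (0.25–0.4 ∪ 0.6–0.75). The default exclusion mode and the
strict mode disagree on mixed loci (say, half the cells near 0.5 and half
near 0.1: excluded by neither band, yet dominated by no variable band
either); the exclusion reading is the default because it removes exactly
the two archetypes the filter names — stable biallelic and
monoallelic/skewed — and nothing else.

## Normalization

Expression is depth-normalized per cell to the median total count,
`log1p`-transformed, then per-gene centered and scaled to unit variance.
This is a transparent, dependency-free normalizer, not a reimplementation
of regularized negative-binomial approaches (sctransform and kin); matrices
normalized externally can be supplied directly, and the variable-gene range
rule operates on the pre-scaling (depth-normalized log) values so it is
invariant to per-gene affine transforms. The package keeps both scales in
its `normalized_expression` object: correlations use the z-scored matrix
(so effect sizes are in SD units), while planted-effect recovery in the
validation suite uses the log scale, where generated slopes live.

PC covariates are computed within each (sample, cell type) group, on the
variable genes, from the SVD of the gene-centered matrix. Component signs
are fixed by making the largest-magnitude loading positive, so repeated
runs are bit-identical. When the requested $k$ exceeds the matrix rank the
component count is reduced with a warning rather than padded with noise.

## The synthetic-data generator

`generate_dataset()` produces every input the pipeline reads, from one
seeded configuration, with known ground truth:

* **Locus archetypes.** Stable biallelic loci center at VAF 0.5 with a
  tight Beta concentration (default 200); monoallelic/skewed loci center at
  0.05 or 0.95 (concentration 20); variable loci draw a per-locus mean
  uniformly from 0.25–0.75 and spread per-cell values around it with a low
  concentration (default 2). Defaults assign 50% stable / 25% monoallelic /
  25% variable, reflecting that the stable-band filter is expected to
  remove the majority of real loci.
* **Coverage.** Per-(locus, cell) total reads are negative binomial (mean
  25, size 5) with a 10% dropout probability; `n_var` is binomial in the
  latent VAF. Absent records mean zero coverage, exercising both
  conventions the reader accepts.
* **Expression.** Per-gene log-normal baselines (meanlog 4, sdlog 0.5 —
  moderately-to-highly expressed genes, the regime the coverage requirement
  confines the method to) with Gaussian noise on the log scale (sd 0.5).
  A planted pair adds $\beta \times \mathrm{latent\ VAF}$ on the log scale
  before exponentiation and rounding.
* **Geometry.** Genes tile a toy chromosome and each locus is placed inside
  a harboring gene, so cis pairs exist and the residence annotation is
  exercised.

What the generator does **not** emulate: UMI deduplication (counts are
already molecule counts), ambient RNA, doublets, batch effects,
transcriptome-wide gene–gene correlation structure, or allele-mapping
bias. Passing tests on this generator therefore demonstrate the
correctness and calibration of the statistical machinery under the model's
own assumptions — not robustness to the full messiness of real droplet
data.

## Validation experiments and their sizes

The test suite and the acceptance script re-run three simulation
experiments, sized to be informative while remaining quick:

* **Null calibration** — 100 replicates of 200 cells × 20 loci × 100
  genes with no planted effects. Every $q \le 0.05$ discovery is false by
  construction; the fraction of replicates with at least one discovery is
  compared against the nominal 5% with a binomial test.
* **Planted recovery** — 50 replicates of 300 cells × 20 loci × 300
  genes, coverage mean 25, one planted pair with slope 1.5 (log scale,
  noise sd 0.5). We require detection at $q \le 0.05$ in at least 80% of
  replicates and a mean recovered slope within three (model-based) standard
  errors of the truth. The 300-gene pool matters: principal components
  estimated from only ~100 genes can partially absorb a strong single-gene
  effect, biasing the slope; with hundreds of genes — and thousands in real
  analyses — no single tested gene can dominate a component.
* **Archetype separation** — 40-locus datasets of pure archetypes at high
  coverage (mean 100), verifying the variability filter removes ≥95% of
  stable loci and retains ≥90% of variable ones.

A note on the recovered slope: regressing on the *observed* VAF, which is
the latent allelic fraction plus binomial read-sampling noise, attenuates
slopes by the classical errors-in-variables factor
$\lambda = \sigma^2_{latent} / (\sigma^2_{latent} + \sigma^2_{sampling})$
(about 0.9 at coverage 25 for a well-spread locus). This bias is inherent
to any VAF-based QTL estimate at finite coverage — higher minR trades loci
for less attenuation — and is why the recovery check is phrased in standard
errors rather than demanding exact equality.

## Numerical and design choices

* **Conflicting printed thresholds.** Where the doublet cutoff is stated
  both as 12,500 UMI counts and as 125,000 raw read counts, the UMI figure
  is the default (`max_total_counts`), with the other reachable through
  configuration. Similarly, "minR > 10" and "a minimum of 10 reads"
  conflict at the boundary; the implementation keeps coverage ≥ minR with
  minR = 10.
* **FDR scope.** q-values are computed within each (sample, cell type)
  analysis group, matching the stratified design; pooling across groups
  would mix null proportions across analyses of very different sizes.
* **PCA scope.** Covariate PCs are computed per analysis group, consistent
  with FDR scoping and with the group being the unit of inference.
* **Permutation universe.** The enrichment test requires the caller to
  supply the gene universe (the analysis input genes) rather than guessing
  one, because the null distribution is meaningless without it. Permuted
  pair sets contain no self-pairs and no duplicates; a permutation p of 0
  is reported as below $1/n_{perm}$ resolution.
* **Determinism.** Every stochastic component (generator, permutations)
  is seeded explicitly; result tables are sorted (q, snv, gene); PCA signs
  are fixed. Two runs from the same inputs are byte-identical.
* **Degenerate inputs.** Constant-VAF loci, rank-deficient covariates,
  zero-informative loci, all-zero cells, and empty survivor sets all have
  defined behavior (skip records with reasons, rank reduction, removal with
  a logged rule, or an explicit error) rather than NA propagation.

## Limitations

The method only sees SNVs in transcribed, adequately covered regions, so
its loci are a biased, expression-weighted subset of heterozygous sites;
cis pairs additionally require the harboring gene itself to clear minR,
which suppresses cis discoveries relative to distance-based eQTL
annotation. Slope estimates are attenuated by read-sampling noise as
described above. The normalizer is intentionally simple; analyses sensitive
to overdispersion structure should supply externally normalized matrices.
Finally, upstream steps — barcode extraction, deduplication, SNV-aware
alignment, variant calling, cell typing — are out of scope and trusted as
given.
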