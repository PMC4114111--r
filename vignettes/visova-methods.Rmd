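---
title: "VISOVA methods: variance profiles, deterministic clustering, and the synthetic phenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VISOVA methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visova)
```

## The problem VISOVA addresses

Deep-phenotyping studies collect hundreds of behavioural summaries per
subject. The conventional display — group means with error bars, one panel
per measure — answers "do the groups differ on average?" but hides two
things that matter for neuropsychiatric phenotypes:

* **within-subject variability** (e.g. the SD of a subject's reaction times
  across trials) often carries more diagnostic signal than the mean;
* **correlation structure among measures** determines whether a profile of
  group differences reflects one latent process or many.

VISOVA puts both on one canvas: a parallel-coordinates plot whose axes are
ordered by correlation clustering, with per-group mean profiles and ±1
standard-error whiskers drawn over the subject trajectories. The package is
explicitly an *exploration* tool; it computes no p-values and makes no
inferential claims. Whiskers are descriptive standard errors
(`sd/sqrt(n)`), nothing more.

## The model and procedure

An analysis is a five-tuple written as a formula,

```
[method :] [dependent] ~ independents [| grouping] [: (subset)]
```

and executed as a fixed pipeline:

1. **Subset** the subject rows by the named subset's predicate (a
   conjunction of attribute comparisons). Subjects with a missing value in a
   predicate attribute are *excluded* — a predicate can only keep rows it
   can evaluate.
2. **Augment** the table with derived variability measures. For every
   (mean, SD) column pair detected from the dictionary (suffix conventions
   `*_MEANRT`/`*_SDRT`, `*_MEAN`/`*_SD`, `*MRT`/`*SDRT`, plus explicit
   overrides), derive CV = σ/μ, SNR = μ/σ and FF = σ²/μ.
3. **Resolve** the variable list: `*` globs expand against the dictionary in
   dictionary order; unknown names are errors, not warnings.
4. **Assign groups** from the grouping definition (the levels of a factor
   attribute, bins over a continuous one, or a union of subsets; overlapping
   unions are configuration errors).
5. **Compute** group profiles, the pairwise-complete correlation matrix,
   the variable clustering, and (for `PCA:`) the projection.
6. **Render** deterministic SVG and write the numeric tables plus a JSON
   manifest with md5 sums.

### Derived-measure rules

Ratios of noisy summaries degenerate in predictable ways, so the rules are
explicit rather than left to IEEE arithmetic:

* μ ≤ 0 — CV, SNR and FF are all `NA`. For response-time data a
  non-positive mean indicates an upstream coding problem, and a
  negative-denominator CV is meaningless.
* σ = 0 with μ > 0 — CV = 0 and FF = 0 (a genuinely constant measure has
  zero relative variability), but SNR is `NA` rather than `Inf` so that
  downstream means and correlations are not destroyed by one constant
  subject.
* σ < 0 — all `NA` (malformed input).

Each suppressed value is counted in the table's cleaning log. By
construction CV·SNR = 1 and FF = CV·σ wherever all quantities are defined;
the test suite verifies both identities at machine precision.

## Correlations, clustering and tie-breaking

Correlations are pairwise-complete (`stats::cor(use =
"pairwise.complete.obs")`); a cell is flagged *undefined* when fewer than two
complete pairs exist or a margin has zero variance. For clustering,
undefined cells are resolved to 0 (no evidence of association) with a
classed warning — silently dropping variables would change axis sets between
runs.

Variables are clustered by agglomerative hierarchical clustering on the
distance 1 − r (or 1 − |r|). The agglomeration is implemented in the
package rather than delegated to `stats::hclust`, for one reason:
**determinism under ties**. `hclust`'s merge order for tied distances
depends on input order, which would make figure output depend on column
order. The package's rules are:

* among all pairs at the minimal distance, merge the pair whose
  (smallest-member, largest-member) original-index tuple is lexicographically
  least;
* when flattening the tree to a leaf order, the subtree with the smaller
  mean original index is placed on the left.

On tie-free inputs the algorithm agrees with `stats::hclust` (average,
complete, and Ward — the package's "ward" is `ward.D2`) in both merge
heights and cophenetic distances; the test suite cross-checks this, using
`hclust` as the oracle. Trees export as merge tables and Newick strings
(via `ape`).

## Axis scaling and rendering

Three axis scalings are offered:

* `minmax` (default) — observed range to [0, 1]; preserves every point.
* `zscore` — mean ± 3 SD; comparable axes when units differ wildly.
* `robust` — 5th–95th percentile, clipped; resists heavy tails.

A degenerate axis (zero range) is flagged and drawn at mid-height rather
than erroring: one constant variable should not kill a 150-axis figure. A
subject must have at least two non-missing values among the plotted
variables to contribute a trajectory; missing values within a drawn
trajectory appear as gaps, never interpolated. Above 2000 subjects,
trajectories are subsampled by a deterministic hash of the subject
identifier so the same subjects are drawn every run.

SVG output is written by a small fixed-format writer (coordinates printed
with two decimals, fixed element order, subjects sorted by identifier), so a
rerun on identical inputs is byte-identical — figures can be hashed and
diffed. Any non-finite coordinate reaching the writer is a classed error;
it always indicates an upstream bug. `Covariance:` models render a
correlation heatmap ordered by covariance-based clustering, since a raw
covariance heatmap is dominated by units.

## The synthetic phenome generator

`synth_spec()` / `generate()` produce tables with known ground truth. The
design choices:

* **Block correlations.** Each block of m variables shares a latent factor:
  x = √ρ·z_common + √(1−ρ)·z_own, giving exchangeable within-block
  correlation ρ and (asymptotically) zero between blocks.
* **Effects in SD units.** A planted group effect shifts a variable by
  k·δ·SD for the k-th ordered level, so "δ = 0.5" means half a within-group
  SD per step regardless of the variable's scale.
* **Mean/SD pairs.** Each task stem contributes `<stem>_MEANRT`
  (μ = 500 + 50·z ms) and `<stem>_SDRT` (σ = 100·exp(0.25·z) ms, log-normal
  so SDs stay positive).
* **MCAR missingness** applied to phenotype columns only, never to
  identifiers or grouping attributes.

`cnp_like_preset("full")` mimics the scale of a large consortium
phenomics release: 1300 subjects × 150 phenotype variables (13 correlation
blocks of 10, ρ ∈ {0.60, 0.62, 0.64, 0.66}; 10 task stems), Age uniform
21–90 binned by decade, diagnosis 80% control / 20% SZ, and two planted
phenomena:

* a **monotone age effect** of δ = 0.5 SD per decade on every `*_MEANRT`
  variable — about 25 ms per decade, the magnitude of reported cognitive
  slowing;
* **SZ variability inflation**: SDRT multiplied by 1.5 in the SZ group,
  which inflates CV but leaves mean RT nearly untouched — the signature
  that motivates variance-first displays — plus a mean shift (δ = 0.8) on
  one correlation block.

Missingness is 5%, typical of curated behavioural batteries. The
`"small"` preset (200 × 20) is the same design at test-suite scale. These
problem sizes are the package's own benchmark choices, selected so the full
preset generates in well under a second and 100-seed acceptance sweeps run
in seconds.

What the generator deliberately does **not** emulate: non-Gaussian
phenotype distributions, missingness that depends on diagnosis or
performance (MNAR), site/batch effects, and longitudinal structure. Results
on the synthetic phenome bound what the pipeline can recover under clean
conditions; they do not certify behaviour under those harder regimes.

## Missing-data policy, by operation

| operation | policy |
|---|---|
| subsetting | missing predicate attribute ⇒ subject excluded |
| group assignment | missing grouping attribute ⇒ unassigned (not drawn in profiles) |
| profiles | per-cell: mean needs n ≥ 1, SE needs n ≥ 2 |
| correlations | pairwise complete; undefined cells flagged |
| clustering | undefined cells → 0 with a warning |
| PCA | complete cases only; `n_dropped` reported |
| trajectories | need ≥ 2 non-missing values; gaps drawn, never interpolated |

## Limitations

* Standard-error whiskers are descriptive; with heavy-tailed phenotypes
  they understate uncertainty, and no multiple-comparison control exists or
  is intended.
* Pairwise-complete correlation matrices need not be positive semidefinite;
  they are used only for ordering variables, not for inference or
  factor models.
* Leaf-order determinism is guaranteed for a fixed input; tiny numeric
  perturbations near a tie can still flip a subtree, as in any hierarchical
  clustering.
* PCA uses complete cases, which can bias loadings when missingness is
  structured; check `n_dropped` in the projection object.
* The parallel-coordinates display saturates above a few hundred axes;
  beyond that, use the correlation heatmap to choose axis subsets.
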