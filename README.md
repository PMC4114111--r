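# visova

Visualization of variance for phenomics tables.

Most exploratory tools for deep-phenotyping studies summarise each measure by
its group **mean** and treat the spread around that mean as noise. For many
neuropsychiatric phenotypes the spread *is* the signal: intra-individual
variability of reaction times rises with age and is selectively inflated in
schizophrenia, even where mean performance looks similar. `visova`
implements the VISOVA (VISualization Of VAriance) workflow for exactly this
situation:

1. **Derived variability measures.** For every (mean, SD) pair of repeated-
   measure summaries — e.g. `SST_MEANRT` / `SST_SDRT` — the package derives
   the coefficient of variation (CV = σ/μ), the signal-to-noise ratio
   (SNR = μ/σ) and the Fano factor (FF = σ²/μ), with explicit rules for
   degenerate inputs (non-positive means, zero SDs).
2. **Group variance profiles.** For a chosen grouping (diagnosis, age decade,
   …) it computes per-group mean profiles with ±1 standard-error whiskers
   over any set of variables.
3. **Correlation-ordered parallel coordinates.** Variables are ordered by
   deterministic hierarchical clustering of their pairwise-complete
   correlation matrix, so correlated measures sit on adjacent axes and group
   profiles are readable as shapes.
4. **Deterministic figures.** Parallel-coordinate (VISOVA) plots, clustered
   correlation heatmaps with dendrograms, and PCA projection grids are
   written as plain SVG that is byte-identical across runs — figures can be
   diffed, hashed and version-controlled.
5. **A synthetic phenome generator** with planted ground truth (correlation
   blocks, a monotone age effect, SZ variability inflation, MCAR
   missingness), so every claim the visualisations make can be tested
   against a known answer.

There is deliberately **no hypothesis testing** in the package: it is an
exploration tool. Whiskers are descriptive standard errors, not inference.

## Model formulas

Analyses are specified with a compact formula language:

```
[method :] [dependent] ~ independents [| grouping] [: (subset)]
```

- `method` — one of `VISOVA`, `PCA`, `Correlation`, `Covariance`
  (default `VISOVA` when omitted).
- `independents` — `+`-separated variable names; `*` globs expand against
  the data dictionary (`*_MEANRT`, `B01_*`).
- `grouping` — a grouping defined in the groups configuration (a factor
  attribute, or bins over a continuous one).
- `subset` — a named subject subset, e.g. `(all)`.

Examples, in the notation of the formulas above:

```
VISOVA: ~ ReactionTime | Age : (LA2K control)
VISOVA: ~ *_CV | Diagnosis : (all)
PCA: ~ B*_V* | Diagnosis : (all)
```

`parse_model()` and `format()` are exact inverses, so formulas can be stored
in catalogues and round-tripped without loss.

## Worked example

```r
library(visova)

# a 200-subject synthetic study with planted structure
study <- generate(cnp_like_preset("small", seed = 42))
study$table
#> <phenotype_table> 200 subjects x 23 variables (0 cleaning log entries)

# derive CV/SNR/FF from every detected (mean, SD) pair
pairs <- detect_pairs(study$dictionary)
pairs[1:3, ]
#>     mean_var   sd_var stem
#> 1 SST_MEANRT SST_SDRT  SST
#> 2 CPT_MEANRT CPT_SDRT  CPT
#> 3 ANT_MEANRT ANT_SDRT  ANT
tab <- augment_variability(study$table, pairs)

# group variance profiles: SZ shows inflated CV across all tasks
a <- assign_groups(tab, study$groups$groupings$Diagnosis)
prof <- group_profiles(tab, a, paste0(pairs$stem, "_CV"))
head(prof, 8)
#>     level variable      mean          se   n
#> 1 control   SST_CV 0.1753751 0.004527824 143
#> 2 control   CPT_CV 0.1718070 0.004188859 151
#> 3 control   ANT_CV 0.1839173 0.004419492 144
#> 4 control  SCWT_CV 0.1757426 0.004234370 142
#> 5      SZ   SST_CV 0.2811230 0.013734922  37
#> 6      SZ   CPT_CV 0.2490344 0.008571627  37
#> 7      SZ   ANT_CV 0.2772831 0.015039996  36
#> 8      SZ  SCWT_CV 0.2704562 0.011526060  40

# clustering recovers the planted correlation blocks as contiguous runs
cm <- correlation_matrix(study$table,
                         grep("^B", numeric_vars(study$table), value = TRUE))
cluster_variables(cm)$leaf_order
#>  [1] "B01_V01" "B01_V02" "B01_V04" "B01_V03" "B02_V01" "B02_V02" "B02_V04"
#>  [8] "B02_V03" "B03_V01" "B03_V02" "B03_V04" "B03_V03"

# one call produces the figure, tables and manifest for a formula
dir <- file.path(tempdir(), "report")
man <- run_explore(tab, tab$dictionary, study$groups,
                   "VISOVA: ~ *_CV | Diagnosis : (all)", dir)
list.files(dir)
#> [1] "correlation.svg" "correlation.tsv" "manifest.json"   "profiles.tsv"
#> [5] "visova.svg"
unlist(man$counts)
#> control      SZ
#>     160      40
```

`run_atlas()` renders a whole catalogue of formulas into a static HTML site
(one directory per entry, an `index.html`, and a `manifest.json` with md5
sums of every figure). `run_viewer()` is the no-configuration entry point:
it plots every numeric variable of a table with a single all-subjects
profile.

A thin command-line interface wraps these entry points:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "viva", package = "visova"))')
Rscript "$CLI" synth --scale small --seed 42 --out study/
Rscript "$CLI" atlas --data study/phenotypes.csv --dictionary study/dictionary.tsv \
    --groups study/groups.json --out site/
```

Exit codes distinguish parse errors (2), resolution errors (3), empty
subsets (4) and IO failures (5).

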