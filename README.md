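# nicheshift

Tools for asking whether related taxa occupy **equivalent or similar
climatic niches**, and how their suitable habitat shifts across climate
eras. The package is aimed at ecologists and biogeographers working with
presence-only occurrence records and gridded bioclimatic layers — the
typical GBIF + bioclim setting — and at methodologists who want the whole
chain reproducible and testable on synthetic landscapes with known ground
truth.

## What it computes

**Maximum-entropy species distribution model.** Given presences and a
background sample, the habitat suitability model is the L1-regularized
Gibbs distribution over background cells

> L(λ) = mean over presences of λ·f(x) − log Σ_bg exp(λ·f(x)) − Σ_j β_j |λ_j|

with features f restricted to linear, quadratic and product transforms of
the scaled variables (hinge/threshold features excluded by construction)
and per-feature penalties β_j following the published MaxEnt class
defaults. Predictions come as raw, cloglog (default) or logistic
suitability; models are evaluated on a 70/30 occurrence split with
ROC-AUC and the True Skill Statistic, projected onto other eras' climates
with clamping, and optionally zeroed off a soil (substrate) mask.

**Niche overlap.** The background environment is reduced by
correlation-matrix PCA to two axes; occurrence and availability densities
are kernel-smoothed on an R×R grid over the study-area envelope, and
overlap is Schoener's

> D = 1 − ½ Σ_cells |p₁ − p₂|  (0 = disjoint, 1 = identical)

computed on availability-corrected or raw occurrence densities.

**Permutation inference.** The *equivalency* test pools and reshuffles the
two taxa's occurrences (lower tail: "Not Equivalent" when observed D falls
below the null); the directional *similarity* test compares observed D
against D under random centroid shifts of one taxon's density within its
background envelope (upper tail: "Similar"). Both use the add-one rank
p-value (k+1)/(n_reps+1), whose floor at the default 100 replicates is
1/101 ≈ 0.0099.

**Synthetic landscapes.** A first-class generator produces spatially
autocorrelated, cross-correlated climate layers, patchy soil masks,
era-to-era climate shifts, and occurrences sampled from a known logistic
suitability surface — so every stage above is testable end to end without
external downloads.

## Worked example

A two-taxon, three-era analysis on a synthetic landscape, end to end:

```r
library(nicheshift)

cfg <- scenario_config(grid_rows = 60, grid_cols = 60, seed = 7)
run <- run_pipeline(run_config(scenario = cfg, background_n = 1500,
                               R = 60, n_reps = 100, seed = 11,
                               out_dir = "readme-run"))

glance(run$evals$taxon_a)
#> # A tibble: 1 × 9
#>     auc   tss threshold sensitivity specificity n_train n_test n_background
#> 1 0.962 0.834    0.0252       0.933       0.901      35     15         1500

run$comparison[, c("kind", "direction", "d_obs", "p_value", "verdict")]
#> # A tibble: 3 × 5
#>   kind        direction             d_obs p_value verdict
#> 1 equivalency <NA>             0.00000338 0.00990 Not Equivalent
#> 2 similarity  taxon_a->taxon_b 0.00000338 0.851   ns
#> 3 similarity  taxon_b->taxon_a 0.00000338 0.792   ns
```

The model separates taxon_a's presences from the background well
(AUC 0.96, TSS 0.83). The two taxa were generated with disjoint climatic
optima, and the tests recover exactly that: observed overlap is
essentially zero, the equivalency test rejects at its p-value floor
(1/101 = 0.0099), and neither taxon's niche predicts the other better
than random centroid shifts. The run directory additionally contains
per-era suitability maps (plain and soil-masked `.asc`), per-point
suitability extractions with boxplot summaries, serialized models,
PCA loadings, density grids and per-replicate null distributions — and
re-running with the same master seed reproduces every file byte for byte.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(suitability maps, niche density grids, null-distribution histograms, ROC
curves). A thin command-line wrapper with `simulate`, `run`, `fit`,
`project`, `extract`, `compare` and `report` subcommands lives at
`inst/cli/nicheshift.R`.

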