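---
title: "Modelling climatic niche shift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling climatic niche shift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nicheshift` implements the full computational chain used to ask whether
related taxa occupy equivalent or similar climatic niches, and how their
suitable habitat moved across climate eras: presence-background
maximum-entropy distribution models on gridded bioclimatic layers,
multi-era projection of habitat suitability, and ordination-based niche
overlap with permutation inference. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the methodology leaves genuine freedom.

```{r setup}
library(nicheshift)
```

## The maximum-entropy distribution model

Given presence records and a background ("availability") sample of the
landscape, the model estimates the Gibbs distribution over background cells

$$p_\lambda(x) \;=\; \frac{e^{\lambda' f(x)}}{\sum_{b \in \text{bg}} e^{\lambda' f(b)}},$$

maximizing the average presence log-density with an L1 penalty:

$$L(\lambda) = \overline{\lambda' f(x_{\text{pres}})}
  - \log \sum_{b} e^{\lambda' f(b)}
  - \sum_j \beta_j |\lambda_j|.$$

The feature map $f$ is deliberately restricted to **linear, quadratic and
product** transforms of the min–max-scaled variables (hinge and threshold
features are not representable by construction), which keeps response
curves smooth, unimodal-capable, and easy to read ecologically. For $d$
variables there are $d + d + d(d-1)/2$ features, e.g. 35 for the default
seven bioclimatic layers.

Per-feature penalties follow the published MaxEnt defaults:
$\beta_j = r \cdot \beta_{\text{class}}(m) \cdot s_j / \sqrt{m}$, where $m$
is the presence count, $s_j$ the feature's standard deviation over the
presences, $\beta_{\text{class}}$ the class-specific constant interpolated
in $m$, and $r$ the single user-facing `reg_multiplier` (default 1).

**Optimizer.** Proximal gradient ascent with backtracking line search and
an exact soft-threshold step for the L1 term. The backtracking condition
guarantees the penalized objective is non-decreasing at every iteration
(this invariant is asserted in the test suite on every fit). Defaults:
`max_iter = 10000`, `tol = 1e-6` on the objective change. Two degenerate
regimes are handled explicitly:

* features constant over the background carry no information about the
  Gibbs density and their coefficients are pinned to 0;
* *complete separation* — every presence feature value beyond every
  background value — makes the penalized objective unbounded whenever the
  penalty is smaller than the separation margin. The optimizer then fails
  with a diagnostic rather than returning an arbitrary iterate; a
  non-finite candidate objective in the line search counts as a rejected
  step.

**Outputs.** `raw` is the Gibbs density itself (it sums to 1 over the
training background); `cloglog` (default, the modern MaxEnt convention)
maps it onto $[0,1]$ as $1 - \exp(-e^{H}\,\text{raw})$ with $H$ the entropy
of the fitted raw distribution; `logistic` is the analogous older
transform. All transforms are strictly monotone in `raw`, so rankings —
and therefore AUC — do not depend on the choice. When projecting onto a
new era's climate, variables are clamped to the training range by default
and per-layer clamp counts are reported, since extrapolated feature values
would otherwise be driven by the quadratic tails.

**Evaluation.** Occurrences are split 70/30 (seeded shuffle,
`round(0.7 n)` training). Test presences are scored against a background
sample standing in for absences — a standard presence-background
approximation, which means "specificity" is measured against availability
rather than true absence. AUC is the Mann–Whitney probability that a
random presence outscores a random background point (ties half), equal to
the trapezoidal ROC area; TSS = sensitivity + specificity − 1 is reported
at the threshold maximizing their sum (the methodology names no threshold
rule; max-sum is the common choice and is configurable in the report). A
constant-score model is flagged and reported at chance level (AUC 0.5,
TSS 0).

**Variable screening.** Pairwise Pearson correlations over all off-nodata
cells; while any pair has $|r| \ge 0.95$ the member with the larger mean
absolute correlation to the others is dropped. A guard checks the common
rule of thumb that occurrences should number at least ten per retained
variable.

## Niche overlap in PCA environmental space

The background environment is ordinated by correlation-matrix PCA
(variables standardized, so measurement units are irrelevant) and the
first two axes define the environmental space, bounded by the minimum and
maximum scores of the whole study area. Loadings carry a deterministic
sign convention (dominant loading positive per axis) so serialized spaces
reproduce exactly.

The space is divided into an $R \times R$ grid ($R = 100$ by default, the
established convention for this framework) and three surfaces are
estimated with Gaussian product kernels:

* `occ_density` — kernel density of the taxon's occurrence scores,
  max-normalized;
* `env_density` — kernel density of the background (availability);
* `occ_corrected` — occupancy divided by availability, max-normalized:
  the taxon's use of conditions relative to how common they are.

Bandwidths follow Silverman's rule per axis on each point set, floored at
one grid-cell width so kernels never fall between cell centers. Two
numerical choices matter here. First, availability below $10^{-6}$ of its
grid peak is treated as zero availability (the corrected ratio is defined
0 there): Gaussian tails that far out are dominated by kernel-truncation
error, and without the cutoff a single stray occurrence over underflowed
availability dominates the whole corrected surface. Second, a degenerate
extent (zero span on an axis) is an error, not a silent collapse.

Overlap is Schoener's
$D = 1 - \tfrac12 \sum_{\text{cells}} |p_1 - p_2|$ on the sum-normalized
grids, ranging from 0 (disjoint) to 1 (identical). Both the corrected and
the uncorrected variant are computed and reported side by side — the
framework is used both ways in the literature and the two can differ
noticeably; `corrected = TRUE` is the package default.

## Permutation tests

Both tests use the add-one rank p-value $(k+1)/(n_{\text{reps}}+1)$ with
ties counted in the rejection tail — the only convention that never
returns 0 and whose floor with the default 100 replicates is
$1/101 = 0.0099$.

**Equivalency** (symmetric): pool both taxa's occurrence scores, shuffle,
split into the original sizes, rebuild both density grids (each against
its own background) and recompute D; repeat `n_reps` times. One-sided
lower tail: niches are "Not Equivalent" at $\alpha = 0.05$ when the
observed overlap is below essentially the whole null.

**Similarity** (directional, a→b): draw a uniform random centroid in
taxon b's background envelope, translate b's *smoothed density grid* so
its centroid lands there, truncate mass pushed outside the extent,
renormalize, and recompute D against a's observed grid. One-sided upper
tail: "Similar" when the observed overlap beats essentially all
random-centroid overlaps. Translating the density grid (rather than
resampling occurrences around a shifted centroid) is our reading of
"randomly shifting the centroid in the environmental space"; it is cheap,
exactly mass-preserving up to truncation, and the truncated fraction is
logged per replicate. A replicate whose whole mass is truncated
contributes zero overlap.

## The synthetic landscape generator

All tests and examples run on synthetic data with known ground truth. The
generator emulates, in order:

* **climate layers** — Gaussian random fields (white noise convolved with
  a Gaussian kernel, scale `autocorr_length` = 8 cells), standardized,
  mixed to a target cross-correlation via the symmetric PSD square root
  (which, unlike Cholesky, tolerates singular targets such as an exact
  correlation of 1), then rescaled to per-layer means and spatial
  standard deviations typical of a Mediterranean landscape. The default
  seven layers carry the usual bioclim names and a block correlation
  (0.5 within the temperature and precipitation groups, 0.15 across);
* **eras** — additive per-layer offsets. The magnitudes are free
  parameters; the defaults are set once at roughly 1–1.5 present-day
  spatial standard deviations for the glacial era (cooler, more seasonal,
  drier) and about a third of that for the mid era;
* **soil** — an independent autocorrelated field thresholded at the
  quantile giving `soil_fraction` = 0.061 of the landscape (the documented
  share of gypsum outcrops in the motivating study region), in contiguous
  patches of scale `soil_patch_scale` = 5 cells. The patch scale was
  chosen so that the 6.1% mask still samples environmental space broadly:
  with a handful of very large patches a realization can lack soil near
  one taxon's climatic optimum entirely, and the scenario would fail to
  instantiate the disjoint-niche ground truth it is supposed to provide;
* **taxa** — logistic suitability surfaces
  $\text{plogis}(\beta_0 + \sum\beta_i z_i + \sum\gamma_i z_i^2)$ in
  standardized layer values. The default pair peaks at $\pm 1$ sd on the
  annual-temperature and annual-precipitation layers with quadratic
  falloff 4, strong enough that 50 occurrences per taxon stay near their
  optima even when confined to soil patches — i.e. the two occupied
  niches are genuinely disjoint in environmental space;
* **occurrences** — cell centers drawn without replacement with
  probability proportional to suitability × soil mask, matching the
  per-pixel thinning applied to real records downstream.

What the generator does *not* emulate: climate physics (fields are
stationary and Gaussian), equal-area geometry (cells are degree squares),
observation bias, and taxonomic error. Passing tests therefore demonstrate
the correctness and calibration of the machinery, not the ecological
validity of any particular real-data analysis.

## Orchestration, determinism and problem sizes

`run_pipeline()` runs the whole chain and writes models (flat text),
suitability maps (`.asc`), evaluation and extraction tables (CSV), density
grids (`.asc` + JSON sidecar) and permutation results (CSV + JSON) into a
run directory. One master seed is fanned out deterministically per stage,
taxon and pair via a label hash (`fan_seed()`), so any stage can be re-run
in isolation and a repeated run is byte-identical. Boxplot summaries of
per-era suitability use type-7 (linear interpolation) quantiles and Tukey
1.5·IQR whiskers, stated in the output metadata.

The test suite exercises the chain at deliberately modest sizes — a
100 × 100 grid with 10,000 background cells and 500 occurrences for the
parameter-recovery check (Spearman ≥ 0.8 between fitted and true
suitability ranks), a 60 × 60 grid for the end-to-end determinism run, and
200 repetitions at 50 permutation replicates for the null-calibration
(Kolmogorov–Smirnov uniformity) experiment. These sizes were chosen as the
smallest at which each property is comfortably identified; all scale
upward through ordinary function arguments.

## Known limitations

* Presence-background TSS uses background points as pseudo-absences; its
  absolute value is design-dependent and should be compared only within a
  study.
* The similarity null translates the whole density grid rigidly; niches
  near the envelope boundary lose truncated mass, which the per-replicate
  log makes visible but does not correct.
* ISTA convergence is slow near the optimum; for very large feature sets
  a second-order method would be preferable.
* Only corner-registered ESRI ASCII grids are read; center-registered
  files are rejected with instructions rather than reinterpreted.
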