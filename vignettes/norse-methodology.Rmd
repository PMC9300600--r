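---
title: "Normalized sensitivity of body-composition biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized sensitivity of body-composition biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(norse)
```

## The question the model answers

Classifier-style biomarker evaluation (ROC curves, c-statistics) asks
whether a person *has* a condition. This package instead quantifies how
much a condition's prevalence *changes* when a biomarker changes — the
question relevant to someone deciding what to modify and by how much. The
core quantity is a sensitivity in the calculus sense: the derivative of
condition prevalence $P_C$ (in percent) with respect to a biomarker $B$,

$$S_{CB} = \frac{\partial P_C}{\partial B}.$$

Raw sensitivities of different biomarkers are not comparable: a percent per
kg of weight and a percent per unit of waist-to-hip ratio live on wildly
different scales. Standardizing the biomarker by its population z-score
$X = (B - \mu_B)/\sigma_B$ and applying the chain rule gives the
**normalized sensitivity score**

$$N_{CB} = \frac{\partial P_C}{\partial B}\frac{\partial B}{\partial X}
         = \sigma_B\, S_{CB},$$

a unit-less number: the percentage-point change in prevalence per one
standard deviation of the biomarker. Scores of diverse biomarkers can be
ranked directly, which is what `rank_norse_1d()` and `rank_norse_2d()` do.

## Estimation from binned maps

Prevalence is estimated on a binned grid rather than by a parametric model
of individual risk. Every map cell is $\tfrac{1}{2}\sigma_B$ wide per axis,
with edges anchored at $\mu_B$ ($\mu_B + k\,\sigma_B/2$, $k \in
\mathbb{Z}$), so maps of different biomarkers are geometrically comparable.
Internally the package bins z-scores against edges at $k/2$; this makes
every count, and hence every score, invariant under positive affine
rescaling of a biomarker up to floating-point rounding — changing waist
from cm to inches changes nothing.

Two map types are built (`build_dmap()`, `build_pmap()`): the distribution
map holds per-cell counts $n_{cell}$ and fractions $n_{cell}/n_{tot}$; the
prevalence map adds the positives $n_{cond}$ and the per-cell prevalence
$100\,n_{cond}/n_{cell}$. Cells with $n_{cell} < 40$ or
$n_{cell}/n_{tot} < 0.2\%$ are **suppressed**: blank in displays and
excluded from slope estimation, because small-cell prevalences are
binomially noisy. Both thresholds are parameters (`min_cell`, `min_frac`);
suppression applies to both map types by default (`suppress = FALSE`
disables it for d-maps).

The 1D score is the count-weighted least-squares slope of per-cell
prevalence over non-suppressed cells, computed in z-units so the slope *is*
$N_{CB}$; dividing by $\sigma_B$ recovers $S_{CB}$. Weighting by
$n_{cell}$ reflects the precision of each cell's prevalence. The global
linear fit is justified by the approximately linear prevalence–biomarker
relationships the binned maps themselves exhibit; a count-weighted local
finite-difference estimator is available as `method = "fd"` for curvature
checks.

### The regression abscissa

A subtle but consequential choice is *where* each cell sits on the x-axis.
Regressing on geometric cell centers attenuates the slope whenever the
within-cell value distribution is non-uniform (with roughly Gaussian data
at $\sigma/2$ cell width the attenuation is near 10%, and worse inside the
narrow conditional slices of a 2D map). The package therefore regresses on
the **within-cell mean z-score** by default, which is exactly unbiased when
prevalence is linear in the biomarker: the cell's prevalence is the average
outcome of its members, so pairing it with the members' average position
reproduces the underlying line exactly. `abscissa = "center"` switches to
geometric centers; maps constructed without member-level values fall back
to centers automatically.

### 2D models, row/column scores and the gradient

A 2D model `condition ~ x + y` bins jointly and reports three layers:

* **Per-row scores** (slope along x within one y-band) and **per-column
  scores** (slope along y within one x-band). These are the blue and brown
  margin numbers of a 2D prevalence map; scores with $|N| < 2$ are hidden
  from displays as visual noise but always retained in the object and in
  every aggregate.
* **Aggregated x/y scores.** The default (`scores_2d = "gradient"`) fits a
  single count-weighted bivariate regression of cell prevalence on both
  abscissas, estimating the prevalence gradient
  $[\partial P/\partial X_1, \partial P/\partial X_2]$ directly. The
  alternative (`scores_2d = "slices"`) takes the count-weighted (or
  unweighted, `aggregate = "unweighted"`) mean of the per-row/per-column
  scores.
* **Separation**: the y score minus the x score, the model's ability to
  pull apart a risk-increasing axis (e.g. waist, a proxy for abdominal
  fat) from a risk-decreasing one (e.g. residual weight at fixed waist, a
  proxy for lean mass).

The gradient default matters when the two biomarkers are strongly
correlated, the typical anthropometric situation (waist and weight
correlate at roughly 0.9). A row of the map fixes y only to within a
$\sigma/2$ band; inside that band y still varies and co-moves with x, so a
rowwise slope absorbs part of the y effect — an omitted-variable bias of
roughly 15–20% against the weaker axis at correlation 0.9, which no
amount of data removes. The joint fit controls each axis for the other and
recovers both coefficients of a linear generating model essentially
exactly (see the parameter-recovery tests). The slicewise aggregate is kept
because it is the natural summary of the margin numbers a reader sees on
the map.

## Ranking tables

`rank_norse_1d()` fits every (biomarker, condition, sex) model and
assembles: per-condition scores, per-sex averages across conditions, and
the cross-sex ranking key (mean of the two per-sex averages). The 2D
ranking (`rank_norse_2d()`) does the same over all 253 unordered pairs of
the 23 built-in biomarkers, ranking by average separation. Two reporting
conventions are fixed throughout:

* all averaging is done on **unrounded** values; and
* printed tables round **half away from zero** to one decimal
  (`round_half_away()`), so e.g. 7.65 prints as 7.7. Base R's
  round-half-even would not reproduce standard report-table arithmetic.

## The analysis population

Every fit is fully listwise: rows passing the sex and age filters (adults,
20–110 years, by default) with non-missing values for each model biomarker
*and* the condition flag. $\mu_B$ and $\sigma_B$ are recomputed on exactly
that population — per sex, per condition, per age stratum — never globally,
since scores are reported per sex and reported n's refer to the analysis
intersection. $\sigma_B$ uses the population convention (divide by $n$);
`sd_type = "sample"` switches, and the difference is immaterial at survey
n. Bins are half-open $[\text{left}, \text{right})$; the data maximum
falls in the topmost bin. Degenerate inputs error early with typed
conditions: constant biomarkers (`sigma = 0`), empty map populations, and
slopes with fewer than two usable cells (`norse_insufficient_support`).
Age stratification (`age_stratified_norse()`) marks thin strata
unavailable instead of erroring, so a curve with a sparse oldest bracket
still plots.

## The biomarker registry

The 23 built-in biomarkers come in three groups: regional (waist- and
hip-centred: WHR, WThR, ABSI, RFM, WeThR, WHtR, BAI, percent trunk fat,
waist, hip), global (PBF, fat-to-lean ratio, FMI, ponderal index, BMI,
weight, FFMI) and non-composition (limb lengths and circumferences,
height). Formulas are the standard published ones for these names
(documented in `?biomarker_registry`); where the literature varies — the
percent-trunk-fat denominator, for instance — the choice is a registry
parameter, and any formula can be replaced wholesale with
`register_biomarker()`. Measurements are canonicalized at ingest (cm, kg,
years); formulas convert internally where an index mixes metres and
centimetres.

## The synthetic cohort generator

`generate_population()` exists so that every estimator is testable against
a known truth without any survey download. It emulates the statistical
structure the method assumes:

* **Anthropometrics**: per-sex multivariate lognormal over ten
  measurements, built from a two-factor loading model (overall body size,
  central adiposity). The factor construction guarantees a positive
  semi-definite covariance and yields waist–weight correlation near 0.9
  and waist–hip near 0.85 — *synthetic design values chosen for realism,
  not survey estimates*. Trunk fat is a logit-normal share of total fat;
  lean mass is 93% of fat-free weight.
* **Ages**: integers on 20–110, uniform to 60 then tapering.
* **Prevalence**: per condition, linear in the z-scores of chosen
  biomarkers on the percent scale, clipped to [0, 100] (or logistic).
  Under the linear model the ground-truth score of a modelled biomarker is
  its coefficient (`ground_truth_norse()`); default intercepts and slopes
  keep clipped mass below 1%, so clipping bias is negligible. An optional
  age multiplier on the slope creates age-varying sensitivity with a
  closed-form per-bracket truth.
* **Missingness**: completely at random per field (default 2% on
  measurements, 1% on flags); a smoker flag supports exclusion analyses.

Defaults: 50,000 participants per sex (a cohort of roughly survey scale);
the recovery tests use 200,000 per sex to push sampling noise well below
the tolerances being verified, and smaller cohorts (8,000–60,000) where
only structure is at stake. What the generator does **not** emulate: survey
design weights, measurement error, informative missingness, age-dependent
anthropometrics, or comorbidity correlation between conditions —
conditions are drawn independently given the biomarkers. Passing recovery
tests therefore demonstrates estimator correctness under the model's own
assumptions, not robustness to the messiness of real survey data.

## Known limitations

* Scores are cross-sectional associations; nothing here supports causal or
  longitudinal claims.
* The linear slope summarises a relationship that real data only
  approximates; strong curvature is visible in the maps and the `fd`
  estimator, but the headline score remains a global slope.
* Ranking is implemented for one and two dimensions. The machinery binned
  maps provide would extend further, but cell counts thin exponentially
  with dimension and the suppression rule would hollow out the grid.
* No inference: scores are point estimates, as in the reference reports;
  confidence intervals would need a resampling layer.
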