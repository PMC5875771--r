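---
title: "Modelling nest-box occupancy under a predation-risk landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nest-box occupancy under a predation-risk landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Arboreal squirrels choosing a nest site face two pressures at once: the
composition of the surrounding forest, which sets food and movement
opportunities, and the risk of predation by large raptors whose territories
overlap the preferred habitat. `riskscape` implements the full inference
chain for studies that monitor nest boxes across years and ask how box
occupancy responds to (i) a predation-risk index derived from known predator
nest locations, (ii) land-cover composition at a home-range and a
dispersal scale, and (iii) their interactions, including a food-supply
(spruce cone crop) interaction for seed-specialist squirrels.

The package targets the classic paired-box monitoring design: boxes erected
in pairs 80–100 m apart within forest sites that are at least 0.8–1 km
apart (flying squirrel programmes), or single boxes per site (red squirrel
programmes), censused every spring.

## The predation-risk kernel

Risk at a point is scored from predator nests with a *flat-top bivariate
Gaussian kernel*. With plateau radius $f$, flank standard deviation
$\sigma$ and truncation distance $c$ (10 km by default), the height at
distance $d$ from a nest is

$$
h(d) \;=\;
\begin{cases}
1 & d \le f \\
\exp\!\big(-(d-f)^2 / 2\sigma^2\big) & f < d \le c \\
0 & d > c.
\end{cases}
$$

The plateau represents the core area where predator impact is strongest;
beyond it risk decays symmetrically in all directions. The kernel is
unit-height rather than a normalized density: the covariate enters the
occupancy model standardized, so any multiplicative rescaling of the kernel
is absorbed into the slope (this invariance is tested). Heights from
multiple nests of one predator species in one year are aggregated by
**sum** by default (cumulative exposure to several territories), with
pointwise **max** as an option; the source method does not say which was
used, and both are provided with sum as the canonical choice.

Because the behavioural mechanism may be lagged (territory memory from the
previous year) or immediate, the covariate can be built from current-year
(`lag = 0`) or previous-year (`lag = 1`) nests. A predator year missing
from the data is filled from the nearest available year, preferring the
later year — the same convention as carrying a later census backwards over
a one-year survey gap — and every fill is flagged and logged.

The kernel hyperparameters are not estimated within the likelihood;
following field practice they are selected by a grid search
(`select_kernel()`): SD in {1, 2, 3, 4} km crossed with plateau in
{500, 1000, 1500, 2000, 2500} m, each lag, refitting the full occupancy
model per candidate and choosing the minimum-AIC candidate. SD values are
interpreted in kilometres: plateau radii run to 2.5 km and the cut-off is
10 km, so metre-scale SDs would be degenerate. Ties break toward the
smaller plateau, then the smaller SD, then lag 1. Lag is searched jointly
with the hyperparameters but reported separately. Non-converged candidates
are recorded and excluded from the arg-min.

## Habitat composition

Land use is a categorical raster on a planar metric grid (ESRI ASCII
format; the original maps' construction from satellite classifications is
out of scope). Raw codes are merged to model classes — young and
mature/old stands of the same composition pooled, built-up codes pooled —
with agricultural field carried as its own class, since field layers
typically come from a separate land-use source.

Composition within a circular buffer uses the *cell-centre rule*: a cell
contributes its full area exactly when its centre lies within the radius.
This is standard zonal-statistics behaviour; whether the original analyses
used cell-centre or partial-pixel weighting is not stated, so the
cell-centre rule is canonical here and is pinned exactly by a brute-force
enumeration oracle in the tests. Areas are reported in hectares; all
coordinates and distances are metres. Buffers truncate at the grid edge;
the generator leaves a margin so study boxes are never truncated. Default
radii are 200 m and 1000 m for flying squirrels and 300 m and 2500 m for
red squirrels — roughly female home-range and dispersal scales.

## The occupancy model

Cleaned data are one record per box and year: only the earliest visit
counts (equal search effort), and box-years first checked after June are
dropped. The response is binary occupancy. The model is a logit-link
Bernoulli GLMM,

$$
\mathrm{logit}\,P(y_{ijt}=1) = \mathbf{x}_{ijt}^\top\beta + b_i + b_{ij},
\qquad b_i \sim N(0, \sigma^2_{site}),\; b_{ij} \sim N(0, \sigma^2_{box}),
$$

with box nested in site for paired-box designs and a site-only intercept
for single-box designs. Estimation maximizes the Laplace-approximate
marginal likelihood via `glmmTMB`; with no random effects the fit reduces
to ordinary logistic regression (verified against an independent
Newton–Raphson oracle to 1e-6). AIC counts fixed effects plus variance
parameters. Wald $z$ = estimate/SE with two-sided normal $p$;
$\alpha = 0.05$ throughout with no multiplicity correction.

Covariate conventions:

* all continuous covariates, including year, are standardized to mean 0,
  SD 1 (sample SD, $n-1$);
* quadratics (the field effect has an a-priori quadratic: farmland should
  help forest squirrels only up to a point) and interaction products are
  built from the standardized parents and are *not* re-standardized;
* the detection-period factor for red squirrels (census protocol change in
  2006) enters as an indicator with the early period as reference;
* a goshawk quadratic is included only in flying-squirrel models, where a
  non-linear response is plausible because goshawks also prey on the
  squirrel's main predator.

Collinearity among habitat classes is screened with variance inflation
factors, $\mathrm{VIF}_j = 1/(1-R^2_j)$, computed on main-effect columns
only (quadratics and interactions inflate VIF trivially) with iterative
removal of the worst offender until all fall below 5. Field and mature
spruce are exempt from removal as a-priori covariates of interest; year and
the detection period are mandatory and outside the screen. Note that
*complete* compositions — every cell classified, as in synthetic data —
make the all-classes design exactly collinear with the intercept, so one
class must always fall to the screen; this is why the pipeline screens
before the kernel grid search, and why the dedicated young-pine models are
reduced models (mandatory terms + risk + young pine) rather than the full
model with young pine re-added.

Model-selection support (`best_subset_search()`) exhaustively enumerates
subsets of up to 20 optional main-effect terms (quadratics travel with
their parents), ranks by AIC and reports the top 10; ties prefer fewer
terms, then lexicographic order. Interaction analysis adds
risk-by-preferred and risk-by-non-preferred products at the home-range
scale, drops those with $p \ge 0.05$ and refits. Cone-crop models join the
previous autumn's spruce cone index (it drives squirrel condition the
following spring), and fit cone-by-spruce and cone-by-pine products in
separate site-intercept models.

## Residual spatial diagnostics

`morans_i()` computes Moran's I under binary distance-band weights
($w_{ij}=1$ iff $0 < d_{ij} \le r$), not row-standardized — the minimal,
fully disclosed choice. Default radii are 50, 500 and 5000 m. Box-level
residuals are averaged per box across years by default (per-year testing is
available), and values sharing a coordinate are averaged. Units with no
neighbour within the radius carry no weight and are removed; at 50 m in a
paired-box design *nothing* is neighboured (pairs are 80–100 m apart), and
the function raises an explicit empty-weight-matrix error rather than
returning 0. Inference uses the normal approximation with
$E[I] = -1/(n-1)$; a seeded permutation test is available for small
fixtures. The statistic is pinned exactly against an $O(n^2)$ double-sum
oracle.

## The synthetic-study generator

Because the field data are not public, the generator is first-class,
tested code: every pipeline stage is exercised on data whose truth is
known.

* **Landscape** — one smoothed Gaussian random field per class (FFT
  convolution, correlation range `clustering_range_m`, default 1500 m);
  each cell takes the class maximizing field + offset, with offsets
  calibrated from the log target shares by a short deterministic
  fixed-point loop so realized shares match the target mix to well within
  the 3-point contract. Any class pair can share boundaries. The default
  mix is a farmland–forest mosaic (10% field, 2% built, the rest forest
  classes and bog) at 25 m resolution, a typical satellite-classification
  cell. The generator targets qualitative clustering only; it makes no
  claim of reproducing any real landscape's covariance.
* **Sites and boxes** — hard-core inhibition (uniform proposals on forest
  cells, rejection within 800 m of an accepted site), second box at a
  uniform bearing, 80–100 m away. Geometry is asserted on every draw. The
  automatic extent allows ~3.5 exclusion areas per site so rejection
  sampling terminates quickly.
* **Predators** — year-one nests from a Poisson process at 2 (Ural owl)
  and 1 (goshawk) pairs per 10 km², thinned to forest; each later year a
  nest keeps its territory with probability 0.85 — chosen once as
  realistic for long-lived, site-faithful raptors — else relocates.
* **Cone index** — i.i.d. log-normal yearly values with occasional mast
  years (25% mixture weight); the real series is not reproduced.
* **Outcomes** — the linear predictor assembles the true coefficients on
  standardized covariates plus site and box intercepts; defaults use the
  magnitudes reported for the field system (risk −2.4, field 0.71, field²
  −0.23, year 0.26 for flying squirrels with $\sigma_{site}=1,
  \sigma_{box}=0.5$ and kernel truth SD 3000 m / plateau 2500 m / lag 1;
  cone 0.17 and cone-by-spruce 0.08 among the red-squirrel defaults). A
  raw visit table with repeat visits and ~2% late-checked box-years is
  emitted so cleaning is exercised end to end.

Random streams are split per component (landscape, sites, predators, cones,
outcomes, visits) from the master seed, so changing one component's
parameters does not perturb the others' draws; the whole chain is
byte-reproducible under a fixed seed.

What passing tests show — and what they do not: the generator matches the
*statistical structure the analysis assumes* (logistic truth, independent
Gaussian intercepts, known kernel). Real censuses add imperfect detection,
observer effort variation, box relocation after clear-cutting and
non-stationary landscapes, none of which are emulated; parameter recovery
here validates the estimation machinery, not robustness to those
violations.

## Numerical and design choices

* Tolerances: glm reduction converged to an IRLS tolerance of 1e-12;
  standardization asserted to 1e-8; oracle identities exact or 1e-6.
* Probabilities of exactly 0/1 are clipped at 1e-12 in residuals, with a
  warning; |coefficient| > 15 triggers a separation warning.
* Whether VIF screening in the source workflow was iterative or a single
  a-priori removal is ambiguous; iterative max-VIF removal is implemented,
  and a single removal is reproducible by configuration.
* Standardization is per analysis dataset (per species and scale), the
  natural reading of "standardize all continuous covariates".
* The kernel grid search refits the full model per candidate; in the
  pipeline the search runs on the home-range-scale design, per predator
  independently (whether the source selected per species jointly or
  afterwards is ambiguous; the grid × lag search per predator is the
  superset).
* Problem sizes used by the test-suite simulations: 200 sites × 10 years
  for parameter and kernel recovery (10 replicates), 50 sites × 5 years
  × 500 outcome replicates for size calibration of the Wald test, 150
  red-squirrel sites × 17 years × 20 replicates for cone-effect recovery.
  These are the package's chosen desk-scale study conditions.

## Known limitations

* Wald standard errors from Laplace fits are mildly optimistic for
  site-level covariates that are themselves spatially smooth over scales
  comparable to the study extent — the summed 10-km kernel is exactly such
  a covariate — so 2-SE intervals for the risk slope can cover somewhat
  below nominal in compact synthetic landscapes. Relatedly, neighbouring
  kernel shapes produce nearly identical covariates: AIC gaps in the grid
  search are often small (the field system reports gaps of 1.7 and 0.8),
  so the selected (SD, plateau) pair should be read as a representative of
  a near-equivalent set, not a sharply identified quantity. The lag, by
  contrast, is well identified.
* No detection-probability (imperfect-detection) occupancy models, no
  spatially correlated random effects, no Bayesian estimation.
* GeoTIFF rasters are not read; convert to ESRI ASCII.
* The best-subset search is exhaustive and intentionally refuses more than
  20 optional terms.
* Moran's I diagnostics test residual autocorrelation; the package does not
  refit spatial models when autocorrelation is found.

## A minimal worked example

```{r, eval = FALSE}
library(riskscape)

cfg <- sim_config("flying", seed = 1, n_sites = 60, years = 2002:2007,
                  margin_m = 300)
sim <- simulate_study(cfg)

d <- sim$occ
d$risk_std  <- as.numeric(standardize(d$risk))
d$Field_std <- as.numeric(standardize(d$Field))
d$year_std  <- as.numeric(standardize(d$year))
d <- add_quadratic(d, "Field_std")

fit <- occu_glmm(
  occu_formula("occupied", c("year_std", "risk_std", "Field_std", "Field_std^2")),
  data = d, random = ~ site_id / box_id)
summary(fit)
moran_diagnostics(fit, d, radii = c(50, 500, 5000))
```
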