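# riskscape

Occupancy analysis of arboreal-squirrel nest boxes under a predation-risk
landscape.

Long-term nest-box programmes for Siberian flying squirrels (*Pteromys
volans*) and Eurasian red squirrels (*Sciurus vulgaris*) record yearly
presence/absence in boxes whose surroundings are mapped as categorical
land use, while the nests of their main avian predators (Ural owl,
northern goshawk) are censused in the same landscape. `riskscape` is for
ecologists who want to ask, with that kind of data: does proximity to
predator nests reduce box occupancy, what does habitat composition at
home-range and dispersal scales contribute, and do the two interact?

## The model

Predation risk at a box is the height of a **flat-top bivariate Gaussian
kernel** summed over predator nests: height 1 within a plateau radius
*f* of a nest, decaying as exp(−(d−f)²/2σ²) beyond it, truncated at
10 km. The plateau radius, flank SD (σ ∈ {1, 2, 3, 4} km ×
f ∈ {500, …, 2500} m) and the temporal lag of the effect (current vs
previous year's nests) are selected by refitting the full occupancy model
per candidate and minimizing AIC.

Occupancy is modelled as a logit-link Bernoulli GLMM,

```
logit P(occupied) = x'B + b_site + b_box,   b ~ N(0, sigma^2)
```

with box nested in site (paired-box designs) or site only, fitted by
Laplace-approximate maximum likelihood. Covariates are standardized
habitat areas within circular buffers (cell-centre zonal rule), the kernel
risk index, year, a detection-period factor, a quadratic field (farmland)
term, and optional predator-by-habitat and cone-crop-by-forest
interactions. Collinearity is screened by iterative VIF removal at
threshold 5; residual spatial autocorrelation is checked with Moran's I
under distance-band weights at 50/500/5000 m.

Because the field data are not public, the package ships a fully seeded
synthetic-study generator (clustered landscape, hard-core site placement,
persistent predator territories, logistic occupancy with known
coefficients) so the entire pipeline is testable end to end. See the
methods vignette (`vignettes/methods.Rmd`) for the full account.

## Worked example

Simulate a small paired-box study and fit the occupancy model:

```r
library(riskscape)

cfg <- sim_config("flying", seed = 7, n_sites = 60, years = 2002:2007,
                  extent_m = 9500, margin_m = 300)
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
```

```
binomial occupancy model (glmmTMB)
  fixed: occupied ~ year_std + risk_std + Field_std + `Field_std^2`
  random intercepts: site_id / box_id
  n = 720, logLik = -241.01, AIC = 496.0

Fixed effects (log odds):
        term estimate    se     z       p sig
 (Intercept)   -2.059 0.351 -5.86 < 1e-04   *
    year_std    0.366 0.129  2.83 0.00471   *
    risk_std   -2.441 0.252 -9.69 < 1e-04   *
   Field_std   -0.005 1.012 -0.00 0.99641
 Field_std^2   -0.247 0.499 -0.50 0.61984

Random-intercept SDs:
box_id:site_id        site_id
        0.9473         0.3468
```

The generator's truth for this draw was risk −2.4, field 0.71, field²
−0.23 per standardized unit with site/box intercept SDs 1 and 0.5. The
strong negative predation-risk effect is recovered almost exactly
(−2.44 ± 0.25 log odds per SD of kernel height) and the positive year
trend is detected; the farmland terms are honestly uninformative at only
60 sites (few boxes sit near field edges, hence the wide SEs) — they
emerge clearly at the full study sizes used in the tests and the
acceptance script. Residual spatial autocorrelation is negligible:

```r
moran_diagnostics(fit, d, radii = c(50, 500, 5000))
```

```
  radius_m   n            I     expected     variance          z         p                note
1       50  NA           NA           NA           NA         NA        NA empty weight matrix…
2      500 120 -0.062877212 -0.008403361 1.652776e-02 -0.4237221 0.6717685
3     5000 120  0.007678564 -0.008403361 9.774046e-05  1.6266752 0.1038061
```

(nothing neighbours within 50 m because paired boxes are 80–100 m apart —
the empty weight matrix is reported, not silently zeroed).

The full study workflow — cleaning, buffers at both scales, VIF screen,
kernel selection, main/young-pine/interaction/cone models, best-subset
ranking, Moran diagnostics — runs as one call over an input directory:

```r
write_study(sim, "study")
run_pipeline(pipeline_config("study", "results", species = "flying"))
```

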