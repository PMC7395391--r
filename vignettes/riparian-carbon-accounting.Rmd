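---
title: "Methods: riparian restoration carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: riparian restoration carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripcarbon)
```

`ripcarbon` turns riparian chronosequence field data — stem inventories,
soil-pit horizon records, site ages and restoration outcomes — into
per-hectare carbon densities, growth and trend models, age-indexed
projection tables, and a county-level valuation. This vignette documents
the models, the assumptions behind them, the tunable parameters, and the
design choices made where the methodology was genuinely open.

## The measurement model

### Aboveground biomass carbon

Each woody stem above the 2.5-cm DBH measurement threshold is assigned
to one of three species groups, each with its own allometric equation
(kg dry biomass from DBH in cm):

| group | equation | typical taxa |
|---|---|---|
| riparian tree | $\exp(-2.2094 + 2.3867\,\ln D)$ | willows, white alder |
| woody shrub | $\exp(-0.7152 + 1.7029\,\ln D)$ | elderberry, coyote brush |
| semi-woody | $0.174\,D$ | blackberry, wild rose |

Group membership is an explicit input column: published group lists name
example taxa only, so guessing a group from a species name would be
silently wrong for unlisted species. Standing dead stems are multiplied
by `dead_density_factor` (default 0.8, always configurable — the
decay-class density reduction appropriate to a survey should be supplied
by the analyst, and the package deliberately does not bury a constant).

Plot totals are scaled by $10^4/(\pi r^2)$ with the plot radius $r$
(default 2 m) taken from the plot record; carbon is 50% of dry biomass
(`carbon_fraction`, configurable). Per-area estimates from 2-m plots in
narrow channels are upper-end estimates — a small plot can overestimate
density when it is smaller than the canopy footprint of the trees it
samples — and the package reports them as measured without correction.

### Belowground carbon

Root stocks are predicted at the stand scale from aboveground density and
age:

$$\mathrm{BLG} = \exp(-1.3267 + 0.8877\,\ln \mathrm{ABG} + 0.1045\,\ln \mathrm{age}).$$

Two conventions needed fixing:

* **Carbon basis.** The regression is published for biomass densities,
  but applying it directly to *carbon* densities is the only convention
  that reproduces the published belowground columns cell-for-cell
  (within ±0.02 Mg C/ha of printed rounding); `root_carbon_mg_ha()`
  therefore takes and returns Mg C/ha.
* **Age zero.** $\ln 0$ is undefined; age 0 (and ABG 0) return 0 — no
  established stand, no modelled root stock. This matches the all-zero
  age-0 rows of the published projection tables.

Semi-woody stems contribute to the stand ABG that drives the root
regression; no separate semi-woody root model exists.

## Soil stocks on an equivalent soil mass basis

Comparing fixed-depth stocks across sites conflates carbon change with
bulk-density change (restoration loosens soil). Stocks for the
floodplain and upper-bank landforms are therefore expressed over a fixed
*mass* of soil: the median cumulative mass to 50 cm across profiles
(`reference_mass()`, pooled over both deep landforms by default;
`pooling = "by_landform"` standardises each landform on its own median —
the pooling set is a genuine open choice and the pooled default keeps
all deep stocks on one common basis). `profile_stock_esm()` then
accumulates element mass horizon by horizon until the reference mass is
reached, pro-rating the final horizon by mass fraction. Within a
horizon, carbon is assumed uniformly distributed over mass — the
simplest auditable interpolation rule, and the one that makes stocks
exactly invariant to horizon subdivision (a property the tests verify
against a fine-discretization oracle at 1e-9 relative tolerance). Auger
horizons below the pit depth are included so every profile can be
equalised; a profile that cannot reach the reference mass is an error
naming the deficit, never silently extrapolated.

Channel soils are different: only the top 10 cm is mineral soil above
stream sediment, and intact cores cannot be extracted, so
`channel_stock_topsoil()` computes a fixed-depth volumetric stock with
the *companion floodplain pit's* top-horizon bulk density as proxy. A
channel record without a floodplain companion is an explicit error — the
adjacent-pit rule is the only stated proxy rule, and substituting a
regional mean would silently change the estimand.

Inputs are assumed oven-dry, fine-earth (< 2 mm) basis; the loader
accepts an optional `moisture_frac` column and applies the dry-mass
correction when present. Mass-weighted property profiles
(`mass_weighted_properties()`) use the same horizon-mass weights over
0–50 cm; C:N is the ratio of weighted percentages (the weighted mean of
per-horizon ratios would not be mass-conserving).

## Chronosequence models

### Site selection

Failed revegetations fail within a year or two of planting, so a
40-year-old failure is not a 40-year-old stand; `select_for_age_regression()`
drops failures from every age-based model and keeps unrestored sites at
age 0. For *group comparisons* (restored vs. unrestored soil
properties), failures are instead pooled with unrestored sites
(`summarize_groups()`): a site with no established vegetation is treated
as continuing to erode.

### Growth curve

Stand aboveground carbon vs. age is fit with the von Bertalanffy form

$$C(t) = a\,(1 - e^{-b t})^3,$$

with asymptote $a$ (Mg C/ha) and rate $b$ (1/yr). Fitting is bounded
Levenberg–Marquardt least squares ($a \in (0, 10\,\max y]$,
$b \in (0, 5]$, parameter tolerance $10^{-8}$, 500 iterations).
Published fits chose starting values from graphical previews, which is
not reproducible; the package uses a deterministic analogue:
$a_0 = 1.05\,\max y$ and $b_0$ from a coarse grid $0.05, 0.10, \ldots,
1.0$ minimising the residual sum at $a_0$. Non-convergence is a flagged
result, not an exception, so a pipeline over several landforms reports
partial failures instead of dying. Duplicated ages carry full weight;
landforms are fit separately (the published per-landform parameters imply
separate fits, and a joint fit would pool very different asymptotes).

The printed projection-table ABG series saturates faster than any single
curve with the reported $b \le 0.14$ can, so that series is treated as
given data when reproducing published tables (it ships in
`inst/extdata/reference_abg_series.csv`), and fitted $(a, b)$ are
validated by simulation recovery only.

### Uncertainty at a target age

`vb_point_interval()` provides the 95% interval for $C(t^*)$ (default
$t^* = 20$ yr, the age used for valuation):

* **bootstrap** (default): resample sites with replacement, refit,
  evaluate at $t^*$, take percentile quantiles. Resamples that cannot
  identify the curve (no positive age, or all-zero response) are
  redrawn. Default 2000 draws.
* **posterior**: a random-walk Metropolis sampler over $(a, b)$ with a
  Gaussian likelihood (sd fixed at the least-squares residual sd) and
  independent Gaussian priors centred on the least-squares estimates
  (sd = 50% of each estimate), mirroring a Bayesian refit with the NLS
  estimates as prior centres. It is a deliberately simple sampler:
  500-iteration burn-in, 5% step sizes, no adaptation — adequate for a
  2-parameter posterior and fully deterministic under its seed.

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state, so pipelines are reproducible end to end and nothing
leaks through global state.

### Soil trend

Soil stock vs. age uses ordinary least squares a priori — a linear
accumulation is the standard first model for decadal soil change and
matches how the uncertainty is propagated (the slope's 95% CI scaled by
the target age). A constant response returns slope 0 with $r^2 = 0$
explicitly rather than relying on `summary.lm`'s degenerate arithmetic.

## Projection tables

`build_projection()` assembles, per landform and age: ABG (curve or
explicit series), BLG (root regression, 0 at age 0), cumulative soil
change (slope × age), and the total. Conventions:

* A soil trend with $p \ge 0.05$ (configurable) enters as slope 0 — an
  accumulation that cannot be distinguished from zero is not projected.
* No interpolation between tabulated ages: `density_at_age()` errors on
  an absent age. Interpolating a saturating curve linearly would bias
  early ages; requesting the age explicitly is cheap.
* When reproducing the published floodplain table, the soil slope
  implied by its printed cumulative column is 0.867 Mg C/ha/yr (the
  rounded per-m² figure would give 0.870); the reproduction fixtures use
  0.867, while pipeline runs always use the slope they fit.

## Scale-up and valuation

Per-landform: restorable (grassland) area within the landform's stream
buffer × the 20-year total density × the area-weighted success fraction.
Success discounts the area because a fraction of attempted plantings
never establishes; the bundled `restorable_areas.csv` normalises
attempted area to 100 ha so the published success *ratios* are exact
(only ratios, not areas, are published — the normalisation is labelled in
the function documentation). County totals convert to CO₂e by the molar
mass ratio 44/12 and to dollars at a configurable price per metric tonne
(Mg) of CO₂e; per-km figures divide by the restorable stream length.
Low/high bounds substitute the interval endpoints of the 20-year
densities (growth-curve interval endpoints with belowground recomputed
from each, plus the soil-slope CI endpoints when the trend is projected)
through the identical arithmetic — no re-sampling at this stage.

## The synthetic chronosequence

`generate_synthetic_dataset()` emulates the study design so every stage
is testable without archived field data: 32 restored sites aged 1–45
plus 10 unrestored age-0 sites, three landforms each, per-landform
failure probabilities (0.3812, 0.2393, 0.7322 — the complements of the
observed success rates), stand carbon following per-landform growth
curves under multiplicative lognormal noise, and soil stocks following
per-landform linear trends under additive Gaussian noise. Choices that
were open:

* **Noise families.** Lognormal for stand carbon (positive,
  right-skewed, variance growing with the mean — as stand biomass data
  are); Gaussian for soil stocks (the OLS model's own assumption).
* **Dispersion defaults.** No dispersion is published. `abg_noise_sd_log
  = 0.25` gives the wide stand scatter typical of small-plot biomass
  data; `soil_noise_sd = 2.4` kg/m² follows from the variance identity
  $r^2 = s^2_{\text{signal}}/(s^2_{\text{signal}}+s^2_{\text{noise}})$
  so that simulated soil regressions at $n \approx 30$–36 bracket the
  published $r^2$ of 0.18–0.21. Both were fixed from these calculations,
  not tuned.
* **Growth parameters.** Asymptotes from the published landform maxima
  (152.8, 229.5, 195.5 Mg C/ha); rates spread over the reported range
  0.09–0.14 with the fastest-saturating landform given the largest rate.
* **Failure draws** are independent per landform within a site,
  reflecting that success rates differ strongly by landform within the
  same project.
* **Stem realisation.** `decompose_to_stems()` draws stems (group by a
  configurable mix, DBH lognormal, clamped at 2.5 cm) until one more
  stem would overshoot the target, then sizes the final stem by
  inverting its group's allometric equation — the plot total matches the
  target within 0.5%. A target below one minimum stem emits a single
  minimum stem with a warning (stands cannot be fractional).
* **Soil realisation.** A fixed horizon template (0–20 cm at BD 1.2,
  20–50 at 1.4, auger 50–100 at 1.5) with uniform C% scaled to the
  target stock. Because every deep profile shares the template, the
  reference mass equals each profile's 50-cm mass and the noise-free
  round trip through the ESM stock and OLS trend recovers the generating
  slope exactly — a deliberate property that isolates estimator error
  from generator error in the tests.

What the generator does **not** emulate: within-plot spatial structure,
species composition gradients, depth-decaying C profiles, correlated
failure across landforms, measurement error in DBH or bulk density.
Passing recovery tests therefore demonstrates the estimators are
correct, not that real field data meet their assumptions.

## Numerical and reproducibility notes

* Problem sizes in the shipped tests: bootstrap coverage is assessed
  with 100 replicates of $n = 30$ sites and 200 bootstrap draws per
  replicate; pipeline determinism uses the full 42-site design with 200
  draws. These sizes make the whole suite run in about a minute while
  leaving the coverage check statistically meaningful (a 95% interval
  should cover in ≥ 90/100 replicates).
* The report bundle (`run_pipeline()`) is byte-identical across reruns
  of the same inputs, seed and package version; the manifest records the
  seed, the full configuration and an MD5 checksum per table.
* Degenerate inputs have defined behaviour throughout: empty stem lists
  give zero carbon; a landform with no established stand skips the
  growth fit (flagged non-converged) while soil stages run; zero-age
  variance, all-zero responses, short profiles and missing companions
  are explicit errors.

## Known limitations

* Herbaceous biomass, litter and coarse woody debris are not modelled;
  unrestored-site biomass carbon is therefore 0 by construction.
* The root regression extrapolates a temperate-forest relationship to
  shrub-dominated stands; its age term is weak (exponent 0.1045) but
  nonzero, so BLG at fixed ABG still drifts upward with age.
* Valuation is a spot price times a stock — no discounting, permanence
  buffer, or market rules.
* The 2-m plot expansion factor (≈ 796×) amplifies single-stem noise;
  densities from very small plots should be read as upper-end estimates.
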