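---
title: "Methods: bottom-up wheat straw inventories with strawinv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up wheat straw inventories with strawinv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawinv)
```

## The problem

Straw is the above-ground biomass left after grain harvest. What happens to
it — recycling into the soil, open burning, or removal — determines both the
nutrients returned to cropland and the air pollutants released. A bottom-up
inventory scales per-hectare quantities up through city-level activity data,
so its accuracy hinges on one number per city: straw yield per hectare.

The traditional shortcut multiplies grain yield by a constant straw-to-grain
ratio. But the harvest index `HI = grain / (grain + straw)` is not constant:
it rises while agronomic constraints (nutrient supply, sowing date, tiller
competition) limit biomass partitioning to grain, then plateaus and even
falls at high yield levels, where further grain gains come mainly from more
total biomass. The mirror image of a falling HI is straw growing faster than
linearly in grain. `strawinv` therefore models

$$\mathrm{straw} = a\,e^{b\,\mathrm{grain}} \qquad [\mathrm{kg\,ha^{-1}}]$$

separately per ecological wheat zone. Three zones are supported — northern
(`NC`), central (`CC`) and southern China (`SC`) — each defined by a closed
province list (`wheat_regions()`). Provinces outside the lists are refused
by `region_of_province()` rather than guessed, because assigning, say,
Tianjin to a zone would silently smuggle in a model fitted on other
provinces' agronomy.

## Fitting choices

`fit_straw_model()` minimises squared residuals in **straw space**, not log
space. Log-space fitting would down-weight exactly the high-yield
observations where the exponential and constant-ratio models differ most;
raw-space residuals keep them at full weight. The log-linear regression of
`log(straw)` on grain supplies starting values only. The optimiser is
Levenberg–Marquardt (`minpack.lm::nlsLM`, ftol/ptol `1e-12`, up to 1000
iterations); when the initialization already fits to machine precision
(noiseless or constant data) it is accepted directly, since the NLS gradient
is singular there. `r_squared` is reported in straw space as
`1 - SS_res/SS_tot`.

The exponential form is one design choice among plausible curved
alternatives (a power law being the obvious other). The fit surface takes
any `list(a =, b =)`, so a differently-fitted parameter pair can be slotted
into the downstream chain for sensitivity checks.

Records may carry straw yield, harvest index, or both.
`normalize_observations()` fills the missing one via
`straw = grain (1 - HI)/HI`; when both are present and disagree beyond
`1e-6` on HI the record is **rejected**, not averaged — an inconsistent
record is evidence of a transcription problem, and averaging would hide it.

## The accounting chain and units

All unit conversions live in one place (`R/inventory.R`) and are tested:

| quantity | unit |
|---|---|
| planting acreage | 1000 ha |
| grain / straw yield per hectare | kg ha⁻¹ |
| city straw totals, disposal amounts | 10⁴ t |
| nutrient supplies, emissions | t |

The chain per city-year is: predict straw yield per hectare from the zone
model; multiply by acreage (`kg ha⁻¹ × 1000 ha = t`, reported per 10⁴ t);
partition by disposal shares (which must sum to 1 within `1e-9`); multiply
recycled-plus-burned mass by zone nutrient fractions; multiply burned mass
by emission factors (`g kg⁻¹ ≡ kg t⁻¹`). Because every step after the model
prediction is linear, the whole inventory is homogeneous of degree one in
acreage — a property the tests assert exactly.

Two nutrient coefficient sets ship with the package. The default,
`"table1"`, puts straw potassium near 1.8% of dry matter, consistent with
measured cereal-straw composition. The `"eq3text"` variant, with P and K
tenfold higher (K ≈ 18%), circulates in the source literature; it is
physically implausible as a straw K content but is kept selectable so that
numbers computed with it can be reproduced and audited. Emission factors
default to 7.6, 0.85, 3.3, 0.37, 3.4 and 1460 g kg⁻¹ for PM2.5, SO2, NOx,
NH3, CH4 and CO2.

Missing-data semantics mirror yearbook conventions: the literal token `NA`
marks a city-year with no data, and it stays `NA` through every downstream
quantity and is excluded from aggregates; a numeric 0 acreage marks a
wheat-free municipal district and produces exact zeros. The two are never
conflated. Disposal shares can be supplied globally, per zone, or per city,
with precedence city > zone > global, because field-management surveys are
reported at varying resolution.

## Monte-Carlo uncertainty

Only the coefficients — nutrient fractions and emission factors — are
randomized; activity data and disposal shares stay fixed. Each coefficient
is drawn from `Normal(mean, mean × CV)`. The published sources for the
coefficients do not print their CVs, so the package default of 0.1 is an
illustrative value, clearly a configuration input rather than a measured
one; override it per coefficient when real CVs are available.

Negative draws (possible for a normal, impossible for a mass fraction) are
resampled by default; clamping to zero is selectable. At CV = 0.1 the
negative-tail mass is negligible (≈ Φ(−10)), so the truncation rule does not
bias the defaults. Percentiles use linear interpolation between the closest
order statistics (`quantile()` type 7) — stated explicitly because
percentile conventions differ across toolchains and a 5th percentile of
1000 draws depends on the choice. The default replicate count is 1000.

Because the randomized steps are linear in the coefficients, closed-form
means and SDs exist for every output, and the tests require the Monte-Carlo
summaries to match them within three standard errors; at 10⁵ draws the 5–95
band must span `2 × 1.6449` SDs within 2%. `normality_check()` reduces the
QQ-plot inspection to the correlation between sorted samples and theoretical
normal quantiles (pass threshold 0.99 by default); heavy-tailed samples fail
it while normal draws pass.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` fixes the study conditions for all tests:

- grain yields uniform on 1000–9000 kg ha⁻¹ (a truncated-normal sampler is
  available), spanning low- to high-yield systems;
- straw from the zone's exponential curve times mean-one multiplicative
  log-normal noise with CV 0.1 — straw yields are positive and
  heteroscedastic, which log-normal noise captures without truncation;
- generating parameters `a` = 2600/3000/2800 kg ha⁻¹ and `b` = 1.2/1.1/1.15
  × 10⁻⁴ ha kg⁻¹ for NC/CC/SC, chosen once so that the implied
  straw-to-grain ratio runs ≈ 1.0–1.3 over the grain range and the harvest
  index stays in a realistic 0.40–0.55 band;
- 500 observations per zone by default (tests scale this up or down as the
  check requires), 10 cities per zone over 2011–2015 with acreages of
  5–300 × 1000 ha, and 5% each of missing and zero-acreage city-years;
- disposal shares from a Dirichlet sampler, since real shares are
  survey-derived inputs the package deliberately does not hard-code.

The generator reproduces the *statistical shape* the pipeline assumes, not
real agronomy: no spatial correlation between neighbouring cities, no
year-on-year yield trends, no covariates (fertilizer, cultivar, sowing
date), and a within-zone noise structure that real multi-site trials do not
publish. Passing tests therefore demonstrate that the pipeline computes its
defined quantities correctly and recovers known parameters — not that any
particular regional coefficient value is right for real data.

## Numerical and degenerate-input policy

- Fit convergence: parameter tolerance `1e-12`, iteration cap 1000;
  non-convergence raises an error carrying the log-linear initialization.
- Fewer than 3 usable observations per zone: refused.
- Duplicate (city, year) keys: refused (silent deduplication would corrupt
  aggregates).
- Share triples off the simplex beyond `1e-9`: refused.
- CV = 0 collapses the Monte-Carlo exactly onto the deterministic inventory;
  this degenerate path is tested.
- Problem sizes used by the shipped checks: 50-seed repeat fits at n = 500,
  Monte-Carlo at 10³ draws (10⁵ for the quantile-width check), inventories
  of 150 synthetic city-years. These sizes make every check deterministic
  under its seed and give sampling noise comfortably below the asserted
  tolerances.

## Known limitations

- Three broad zones, not finer ecological planting zones; the zone lists are
  closed, so unlisted provinces need an explicit decision by the user.
- Uncertainty in the fitted `(a, b)` is *not* propagated — only coefficient
  uncertainty is, matching the scope of the accounting chain. A hook for
  randomizing disposal shares exists but is off by default.
- The exponential form extrapolates aggressively beyond the fitted grain
  range; predictions far above 9000 kg ha⁻¹ should be treated with caution.
- Sensitivity indices (e.g. Sobol) are out of scope.
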