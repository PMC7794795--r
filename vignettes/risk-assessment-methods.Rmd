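---
title: "Methods: multi-route cancer risk for children on oiled beaches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-route cancer risk for children on oiled beaches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beachrisk)
```

## The problem

After a major oil spill, shoreline sediment carries residues — weathered
oil and tarballs — containing polycyclic aromatic hydrocarbons (PAHs).
Children playing on such beaches contact these media intensively:
crawling, digging, hand-to-mouth behaviour, and long skin contact with
sand. `beachrisk` estimates the incremental lifetime cancer risk to a
child receptor from one such chemical (the bundled scenarios use
benzo[b]fluoranthene, a probable human carcinogen) through three
exposure routes: incidental soil ingestion (oral), dermal contact, and
inhalation of suspended particulates.

## The model

All routes follow the standard average-daily-dose formulation of
chemical risk assessment. Risk for one route is the linear low-dose
extrapolation

$$\mathrm{Risk} = \mathrm{Dose} \times SF,$$

with $SF$ the route-specific cancer slope factor (excess lifetime risk
per mg/(kg·day)). The doses, in mg/(kg·day), are

$$\mathrm{Dose_{oral}} = \frac{C \cdot IR_s \cdot RBA \cdot EF \cdot CF}{BW},
\qquad
\mathrm{Dose_{dermal}} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot EF \cdot CF}{BW},$$

$$\mathrm{Dose_{inh}} = \frac{C \cdot \tfrac{1}{PEF} \cdot IR_a \cdot ET \cdot EF}{BW},
\qquad
EF = \frac{F \cdot ED}{AT},$$

where $C$ is the medium concentration (mg/kg), $IR_s$ the soil intake
rate (mg/day), $RBA$ the oral relative bioavailability, $SA$ the skin
surface area (cm²/event), $AF$ the soil-to-skin adherence (mg/cm²),
$ABS$ the per-event dermal absorption fraction, $CF = 10^{-6}$ the
mg→kg conversion, $PEF$ the soil-to-air particulate emission factor
(m³/kg), $IR_a$ the inhalation rate (m³/day), $ET$ the exposure time
(hours/day), $F$ the visit frequency (days/year), $ED$ the exposure
duration (years), $AT$ the averaging time (days; a ~78-year lifetime,
28,489 days, for cancer endpoints), and $BW$ the body weight (kg).
Risks are additive across routes and across media for a receptor
contacting all of them, which is how `risk_table()` forms its row,
column, and grand totals.

```{r point}
sc <- load_scenario("beaches")
risk_table(sc$media, sc$profile, sc$tox)
```

## Numerical and modelling conventions

Several choices in the equations above were genuinely open; the package
resolves them as follows.

**The exposure-time multiplier.** The inhalation dose multiplies by
$ET$ in hours/day with no division by 24, which is dimensionally odd but
is the form in which this class of assessments writes the equation; the
published per-medium inhalation risks are only reproducible with $ET$
applied as a bare multiplier, so the package applies it as written. No
mass conversion factor appears in the inhalation route (the $1/PEF$
term already converts soil concentration to an air concentration).

**Exposure-factor override.** Profiles may carry
`exposure_factor_override`. The literature-default scenario needs it:
its published exposure factor (0.002948) is not the ratio of its own
published frequency, duration, and averaging time (12 × 8 / 28489 =
0.00337). The package reproduces the published parameter set verbatim
rather than silently correcting it; the override wins over the computed
ratio wherever both exist, except that a Monte Carlo run which samples
frequency recomputes EF from the sampled value and ignores the
override.

**Concentration-to-medium mapping.** The chemical survey reports one
triangular triple (0.62 / 1.46 / 4.40 mg/kg) spanning the three media,
with weathered oil described as the upper limit of what sediment can
carry. The per-medium point risks identify sediment with the central
value, weathered oil with the maximum, and tar with the minimum; the
bundled scenarios encode that mapping.

**No risk capping.** Computed risks are not clamped to [0, 1]; the
linear model is only meaningful when risks are small, and `route_risk()`
warns whenever a value exceeds 0.01.

**Degenerate inputs.** Zero frequency, zero concentration, and zero
exposure time are valid "no exposure" inputs producing zero risk; zero
body weight, averaging time, or particulate emission factor is rejected
at construction.

**Display precision.** Reports render at 3 significant figures, the
display precision risk tables conventionally use; full double precision
is available with `raw = TRUE` (or `--raw` on the command line). A
printed 3-s.f. value only pins the underlying quantity to half a unit
in its last digit, and one published inhalation cell sits exactly on a
rounding boundary (the computed value is 7.68500e-13 to six figures),
so checks against printed values compare at that half-unit resolution.

## Monte Carlo uncertainty propagation

Exposure parameters estimated from small field samples are uncertain.
Following standard probabilistic risk-assessment practice for bounded,
sparsely characterised parameters, four inputs — body weight, skin
surface area, visit frequency, and medium concentration — are given
triangular (minimum, likeliest, maximum) distributions, where the
"likeliest" slot carries the observed cohort *median* as a stand-in for
the mode. Sampling is plain independent Monte Carlo (no Latin
hypercube, no parameter correlation): each iteration draws one value
per parameter by inverse-CDF sampling, rebuilds the profile, and
evaluates all three routes through the deterministic engine for the
drawn single-medium concentration. A per-iteration result is therefore
a single-medium risk, not a three-media sum — the concentration triple
spans the media — so simulated means are not directly comparable to the
point-table route totals. Summaries are the per-route mean and the
empirical 2.5% and 97.5% quantiles, taken by linear interpolation
between order statistics (`stats::quantile()` type 7; stated because
spreadsheet tools differ in their convention). The default iteration
count is 1000, matching common practice for this design; property-style
checks in the test suite use 10^5 draws for tight tolerances.

```{r mc}
spec <- simulation_spec(sc$distributions, sc$profile, sc$tox,
                        iterations = 1000, seed = 1)
run_simulation(spec, keep_samples = FALSE)
```

Because risk is monotone in every sampled parameter (increasing in
concentration, surface area, and frequency; decreasing in body weight),
the extreme achievable risks sit at the distribution corners, which
gives an analytic envelope every simulated risk must respect — one of
the package's acceptance properties, along with a Kolmogorov–Smirnov
check of the sampler against the closed-form triangular CDF, the
per-iteration route ordering dermal > oral > inhalation that the slope
and factor structure forces, and bit-identical summaries under a fixed
seed.

## The synthetic cohort

No per-child raw data are distributable, so `generate_cohort()` creates
records with the statistical structure the analysis assumes: body
weight, skin surface area, and visit frequency drawn independently from
the triangular triples above (its defaults), frequency rounded to a
whole number of visits and floored at 1. `summarize_cohort()` then
distils a cohort exactly the way field data are distilled — per-parameter
minimum, median, maximum (and mean) — and `fit_triangular()` applies the
plug-in rule `triangular(min, median, max)`. This is deliberately not a
maximum-likelihood fit; it mirrors the summarisation step the sampling
distributions came from, so generate → summarize → fit approaches the
generating (min, median, max) as the cohort grows (tested at n = 10^4:
sample extremes within the 0.5% tails of the support, fitted central
value within 5% of the distribution's true median).

What the generator does *not* emulate: the physical correlation between
body weight and skin surface area (the analysis pipeline itself assumes
independence, so the generator does too — a documented limitation), any
age or sex structure, and derivation of surface area from height and
weight. Passing tests therefore show the pipeline is faithful to its
own distributional assumptions, not that those assumptions capture a
real cohort.

## Known limitations

- A single skin-loading event per exposure day; repeated
  wash-and-reload cycles during a visit would raise dermal dose.
- Inhalation covers suspended solid-phase particulates only, not
  gas-phase chemical.
- Uniform concentration across all beach microenvironments and routes.
- Single-chemical engine; multi-chemical aggregation would be additive
  but is not exercised by any bundled scenario.
- The literature-default scenario's dermal and inhalation columns are
  carried for completeness, but the source that parameter set reproduces
  is internally inconsistent for those cells (its dermal-tar value is
  ~3 orders of magnitude below what its own inputs yield, its
  inhalation cells require dropping the exposure-time term, and its
  oral total implies slightly different concentrations than it prints);
  only its oral cells should be compared quantitatively, and even those
  agree only to ~1%.

## Problem sizes

Deterministic point tables are 3 media × 3 routes and run in
milliseconds. The package's own checks use 10^5 Monte Carlo iterations
for distributional properties, 10^4 synthetic children for round-trip
recovery, and 1000 iterations (the default) elsewhere — sizes chosen so
sampling error is well below the tested tolerances.
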