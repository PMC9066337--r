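---
title: "Modelling a mass media campaign for weight-loss apps with a proportional multistate life table"
author: "pmsltbmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a mass media campaign for weight-loss apps with a proportional multistate life table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmsltbmi)
```

## The question the model answers

A government runs a one-off, one-year mass media campaign encouraging
adults to download and use a high-quality smartphone app for weight loss.
Some fraction of the adult population is reached and loses a little weight;
that small BMI reduction, spread over a large population, lowers the
incidence of BMI-related diseases over the remaining lifetime of the cohort.
The model quantifies the resulting health gain (quality-adjusted life years,
QALYs), the net cost to the health system (campaign cost plus downstream
cost offsets from altered disease rates and longevity), cost-effectiveness
against a willingness-to-pay threshold of NZ$45,000 per QALY, and the equity
implications for Māori versus non-Māori.

The modelled population is structured like the 2011 New Zealand adult
population: closed cohorts (no births or migration) by single year of age
18–110, sex, and ethnicity (Māori / non-Māori), simulated until everyone has
died. All results are differences between a paired business-as-usual (BAU)
arm and an intervention arm run on identical inputs.

## Model structure

### Intervention pathway

The fraction of the adult population that experiences weight loss is a
sequential uptake cascade:

$$p_\text{eligible} = p_\text{overweight} \times p_\text{smartphone}
  \times p_\text{recognition} \times p_\text{uptake}$$

with base-case values 0.73 (adults with BMI ≥ 25), 0.81 (smartphone
ownership), 0.45 (campaign recognition) and 0.14 (download-and-use),
narrowing 73% → 59.1% → 26.6% → 3.7%. Each later step is treated as
independent of BMI status, so the cascade is a plain product.

The achieved BMI reduction is a duration-weighted average of pooled trial
effects for short (≤ 3 months, −0.219 kg/m²) and long (> 3 months,
−0.609 kg/m²) app use, weighted by the observed adherence split
(53% / 47%):

$$E = E_{\le 3m} P_{\le 3m} + E_{>3m} P_{>3m} = -0.402 \;\text{kg/m}^2.$$

The full effect applies during the intervention year (year 0): the pooled
trial effects are end-of-trial measurements at ≤ 9 months, within one
annual cycle. From `regain_delay` years after the intervention year
(default 0, matching the predecessor model this analysis updates — the
sources do not say whether a maintenance period precedes regain, so the
delay is an explicit parameter), weight regain erodes the reduction at
0.03 kg/m² per month, i.e. 0.36 kg/m² per year:

$$\delta(t) = \min\{0,\; E + 12 r \max(0, t - d)\}.$$

We evaluate $\delta$ at integer years rather than averaging the within-year
decay path: the erosion rate is an annualised summary of a monthly decay
estimate, and the point evaluation keeps the stated identity that a
−0.36 kg/m² effect is exactly gone after twelve months of regain. With the
base-case effect the reduction is fully eroded early in year 2, so the
base case is, by construction, a short exposure pulse whose health
consequences play out over decades through the lag structure below.

### From BMI change to disease incidence

For each disease the association with BMI is log-linear: RR per 1 kg/m² of
BMI, attenuating linearly with age to RR = 1 at age 95 (mirroring the
standard attenuation of relative risks at old age and avoiding implausible
effects in the very old). For a sub-population of size $p$ whose mean BMI
shifts by $\delta$ under log-linear risk, the population impact fraction has
the exact closed form

$$\mathrm{PIF} = p\,(1 - e^{\beta\delta}), \qquad \beta = \ln \mathrm{RR},$$

because a pure location shift factorises out of the risk integral for *any*
baseline BMI distribution. This is the module's central modelling
commitment (the source defers the formula to its protocol); the test suite
verifies it against direct numerical integration of the risk integral over
shifted normal mixtures. Only incidence is modified — case fatality and
remission are untouched, consistently with PIFs being stated to act on
incidence rates.

Incidence responds with a delay: the PIF is averaged uniformly over integer
lags of 0–5 years for cardiovascular disease, diabetes and osteoarthritis,
and 10–30 years for cancers. A uniform spread is used because the sources
state only the windows, not a shape. In the probabilistic analysis the
window endpoints receive normal uncertainty with SD equal to 20% of the
central value (the convention used for high-uncertainty inputs), rounded to
non-negative integers with min ≤ max.

### The proportional multistate life table

Each of the 14 BMI-related diseases (coronary heart disease, stroke, type 2
diabetes, osteoarthritis, and cancers of the endometrium, kidney, liver,
esophagus, pancreas, thyroid, colorectum, breast, ovary and gallbladder) has
its own three-state table — susceptible, prevalent case, dead of the
disease — driven by incidence, case fatality and, for the ten cancers only,
remission. Each annual cycle solves the constant-rate linear system exactly
(2×2 matrix exponential in closed form), which has three consequences we
rely on: compartments can never go negative regardless of rate magnitudes,
the accounting $S + C + D = 1$ closes to machine precision, and the
within-cycle *integrals* (person-years prevalent, incident flow, death
flow) are exact rather than end-of-year approximations. The unit tests
cross-check the step against an independent ODE solver.

The main life table carries all-cause mortality and a prevalent-morbidity
utility decrement (pYLD). The intervention arm's all-cause mortality is the
baseline rate minus the summed reduction in disease-death flows; its pYLD
is the baseline decrement minus the disability-weighted reduction in
disease prevalence. Survival through a cycle is $e^{-m}$, life-years use
the half-cycle average of start/end survivors, and QALYs weight life-years
by $1 - \mathrm{pYLD}$. Cohorts close deterministically at age 110.

### Costs and discounting

Disease costs distinguish the first year of illness, subsequent years, and
the last six months of life: per stratum and year,
`incident × c_first + max(prevalent person-years − incident, 0) × c_subseq +
death flow × c_last6m`, scaled by the stratum population. The floor matters
only in the first simulated years, when the prevalence pool is smaller than
the incident flow that feeds it. Disease-table proportions are used
directly (the proportional-table approximation); the main table's survival
scales only the *unrelated* annual health-system costs, which is how living
longer costs the system more. The one-off campaign cost (NZ$2,883,000) is
booked undiscounted in year 0 of the intervention arm, so a null
intervention has a net cost exactly equal to the campaign cost — a key
identity in the test suite. Health gains and costs are discounted at 3%
per year (0% and 6% in sensitivity analyses); year 0 is undiscounted, and
the first 10-year horizon is years 0–9. US dollar figures use a single
configurable conversion factor, 0.673.

## The synthetic population

No parameter dataset is distributed with the analysis this package
re-implements, so `generate_bundle()` builds a complete synthetic stand-in
with the structural features the method assumes:

* Gompertz all-cause mortality (exponential in age) with a male multiplier
  and a configurable Māori/non-Māori gap (default 1.7), giving life
  expectancy at 18 of roughly 80 (non-Māori) versus 75 (Māori) — a
  realistic five-year ethnic survival gap. Mortality is monotone beyond
  age 60 by construction.
* An age pyramid declining faster for Māori (a younger population), with
  totals of about 3.7 million non-Māori and 0.67 million Māori adults.
* Mean BMI rising from 25 toward ~28 kg/m² through mid-life, higher for
  Māori (+1.5 kg/m²); 73% of adults overweight or obese, uniform across
  strata (the sources do not say whether this proportion varies by
  stratum, so it is a single configurable value with per-stratum overrides
  possible downstream).
* Age-increasing disease incidence with disease-specific slopes, case
  fatality high for pancreatic/liver/esophageal cancer and low for
  thyroid cancer, osteoarthritis and diabetes; remission only for the ten
  cancers; sex-specific incidence (zero male endometrial/ovarian cancer);
  a Māori incidence multiplier (default 1.3).
* Costs per disease split into first-year / subsequent-year / last-6-months,
  and unrelated annual costs rising steeply after age 80.

Seeded lognormal jitter is applied at the disease and sex level — never per
ethnicity — so that setting a gap factor to 1 removes the corresponding
ethnic difference exactly, a property the tests exploit. The same seed and
configuration reproduce the bundle bit-for-bit, and bundles round-trip
through a directory of CSVs with a JSON manifest.

What the generator does *not* emulate: correlations between diseases within
individuals (the proportional life table has none), BMI distribution shape
(the PIF needs only the mean shift), cohort trends in BMI or mortality, and
any resemblance of absolute rates to the true New Zealand schedules.
Passing tests therefore demonstrate that the machinery is correct and that
directional and structural conclusions (scenario orderings, equity
directions, cost-saving dynamics) are robust — not that the headline
numbers of the original analysis are recovered. Those depend on the
unreleased national dataset and are out of scope.

## Uncertainty analysis

The five intervention parameters are sampled independently, 2000 draws in
the full analysis:

| parameter | central | family | dispersion |
|---|---|---|---|
| smartphone ownership | 0.81 | beta | SD = 5% of central |
| campaign recognition | 0.45 | beta | SD = 20% |
| download-and-use | 0.14 | beta | SD = 20% |
| BMI effect | −0.400 kg/m² | normal | SD from 95% CI (−0.858, 0.051) |
| weight regain | 0.03 kg/m²/month | lognormal | SD = 20% |
| campaign cost | NZ$2,883,000 | gamma | SD = 20% |

Beta, lognormal and gamma draws are moment-matched to the stated mean and
SD; the normal SD is `(upper − lower) / (2 × 1.96)` ≈ 0.232. The effect
CI crosses zero, so some draws are positive (weight gain); the trajectory
handles them by odd symmetry — the effect decays toward zero at the same
regain rate — and the PIF then becomes negative (an incidence increase),
which the closed form supports. Uncertainty intervals are the empirical
2.5th/97.5th percentiles of the draws (the sources state "95% uncertainty
intervals" without a method; percentiles are the standard choice for
simulation output). Each draw is reproducible in isolation: the draw-level
RNG stream is seeded as a fixed function of (master seed, draw index).
The BAU arm is deterministic and computed once, shared across draws.

## Scenarios

Exactly one knob moves per scenario: (1) recognition 68%; (2) effect ×1.5;
(3) all users on the long-duration pooled effect −0.609; (4a/4b/4c) regain
delayed 1 year, 5 years, or removed; (5) the legacy effect size −0.430 kg
from the predecessor analysis, converted to BMI units by dividing by a mean
height squared (1.69 m → 2.856 m²; the conversion is not printed in the
sources, so the height is configurable and the choice is flagged here);
(6a/6b) discount 0% / 6%. All scenarios are expected-value runs (central
values, no sampling); whether the original base-case expected values used a
fixed seed is unstated, so central-value propagation is implemented.

Structural expectations that must hold on any bundle with positive base
gain — and are enforced in the tests: QALY gains increase with recognition,
effect size and adherence; gains are monotone in regain delay with the
no-regain envelope far above everything else; 0% discounting raises and 6%
lowers the lifetime gain; the equity adjustment (substituting non-Māori
background mortality and pYLD into Māori strata, leaving BMI, disease rates
and uptake untouched) raises Māori per-1000 gains and leaves non-Māori
results bitwise unchanged.

## Numerical choices and problem sizes

* Annual cycles; rates are continuous-time intensities converted through
  exact within-cycle solutions, not probabilities.
* Closure at age 110 bounds every lifetime quantity deterministically.
* The engine stacks all 372 cohorts (4 groups × 93 ages) and 14 diseases
  into single matrix updates; BAU transition coefficients are cached per
  year and only PIF-affected disease columns are recomputed per draw, which
  is what makes 2000-draw probabilistic runs take a few minutes.
* The package's own analyses use the full population (372 cohorts, 93-year
  horizon, 14 diseases); the test suite runs the same full pipeline with a
  200-draw probabilistic analysis as its default.
* Degenerate inputs: zero rates, zero effect, empty cascade components and
  equal-eigenvalue edge cases in the cycle solver all have exact closed
  forms (verified by tests); adjusted mortality or pYLD that would leave
  its valid range is clipped and the clip count is reported on the run
  object (`n_clipped`, zero in all shipped analyses).

## Known limitations

Comorbidity is not modelled (disease tables interact only through the
mortality/morbidity linkage); the BMI pathway is the only benefit pathway
(no diet-quality or physical-activity effects); trial effects are assumed
transportable to all eligible adults including equal effectiveness for
Māori; uptake is a one-shot cascade with no social diffusion; and the
synthetic bundle supports structural, not numerical, claims about the
original setting.
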