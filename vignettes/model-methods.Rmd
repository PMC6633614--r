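---
title: "Model methods: multistate life table cost-effectiveness of diet and physical activity interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msltce)
```

# The model in one page

`msltce` estimates how a population-level change in diet or physical
activity propagates to disease burden, quality-adjusted life years (QALYs),
and health and social care costs, in four stages:

1. **Comparative risk assessment.** An intervention shifts the mean of one
   or more exposure distributions (salt, fruit, BMI, MET hours of activity,
   ...). For each affected disease the shift becomes a potential impact
   fraction,
   $$\mathrm{PIF} = \frac{\int RR(x) f_b(x)\,dx - \int RR(x) f_s(x)\,dx}
                         {\int RR(x) f_b(x)\,dx},$$
   with $f_b$, $f_s$ the baseline and scenario exposure densities and
   $RR(x)$ the dose-response relative to the theoretical-minimum-risk
   exposure.
2. **Multistate life table.** A closed cohort population (single year of age
   15-100, by sex) is simulated annually. Each disease is a three-state
   illness-death process (never diseased, prevalent case, dead of disease)
   with rates: incidence $i$, case fatality $f$ (the annual mortality rate
   among prevalent cases), remission fixed at zero. Scenario incidence is
   baseline incidence times $\prod_k (1 - \mathrm{PIF}_k)$. Disease
   mortality feeds back into all-cause survival, so averted cases buy life
   years.
3. **Valuation.** Person-years are weighted by EQ-5D utility (baseline by
   age and sex, additive disease decrements) to give QALYs; prevalent cases
   accrue per-case NHS costs, everyone alive accrues age-specific
   unrelated-disease costs, and person-years past age 75 accrue social care
   costs scaled by lost quality of life.
4. **Economics.** Streams are discounted (1.5% a year by default) and
   summarised as $\mathrm{ICER} = (C_b - C_a)/(E_b - E_a)$, with return on
   investment $|C_b - C_a|/C_i$ reported for cost-saving interventions, and
   95% uncertainty intervals from the 2.5th/97.5th percentiles of Monte
   Carlo parameter draws (2000 runs by default).

The parameter catalogue shipped under `inst/extdata/catalogue/` carries the
relative risks, intermediate-pathway coefficients, theoretical minima,
mediation factors, utilities, and disease costs as auditable CSV tables; a
JSON digest pins their row counts and checksums.

# Exposure-to-disease machinery

## Dose-response forms

Per-unit relative risks follow
$RR(x) = v^{(x - x_{\min})/u}$ where $v$ is the catalogue value per unit
$u$ (which may be negative, e.g. "per -20 mmHg"), and $x_{\min}$ is the
theoretical minimum risk exposure. Since $x_{\min}$ is by definition the
lowest-risk exposure, the curve is clamped at $RR \ge 1$: moving past the
minimum confers no extra benefit and no extrapolated harm. BMI risks for
diabetes and cirrhosis are banded by exposure rather than age; their
log-risk is accumulated piecewise from the minimum, giving a continuous
curve with band-specific slopes. Age-banded risks (blood pressure,
cholesterol, BMI on cardiovascular disease) are step functions of age; ages
outside any printed band use the nearest band.

Physical activity uses the quarter-power form
$RR(x) = \exp\!\big(\beta\,(x/11.25)^{0.25}\big)$, so the published
$\beta$ reproduces $\exp(\beta)$ at the 11.25 MET h/wk reference dose and
the sedentary reference has $RR = 1$. The exact transform convention is not
fully pinned down by its source, so both the reference dose and the form
live in the model configuration. The dose is capped at the 133 MET h/wk
theoretical minimum.

## Integration

Exposure densities are normal, truncated to $[0, \mu + 4\sigma]$ and
renormalised, with an optional non-consumer point mass at zero intake for
fruit and vegetables (held fixed under interventions). Expected relative
risks are integrated by a 201-point trapezoid rule (`pif_grid_points` in
the configuration). This is deterministic and is tested against a
million-draw Monte Carlo oracle; a zero-SD distribution degenerates to a
point mass and the PIF reduces to $1 - RR(x_1)/RR(x_0)$ exactly.

## Intermediate pathways and mediation

Fats, dietary cholesterol, salt, and total energy act through total
cholesterol, systolic blood pressure (SBP), and BMI. Salt is converted at
17.1 mmol sodium per gram of salt (0.4 g sodium per gram, molar mass 23)
before the per-100-mmol SBP coefficient applies. The energy-to-weight
relationship is a configurable linear steady-state coefficient — default
1/94 kg per kJ/day, divided by a squared reference height (1.75 m men,
1.62 m women) to land on the BMI scale. This replaces a pair of published
energy-balance equations that are not reproduced in the catalogue sources;
it is deliberately simple, prominently configurable
(`config$energy_bmi`), and should be replaced for any application where
the energy pathway is load-bearing.

BMI, fruit, and vegetables affect IHD and stroke both directly and through
SBP/cholesterol. Applying both pathways unadjusted would double count, so
the direct relative risk is divided by the risk implied by the mediated
intermediate change (`mediation_adjust()`), and the mediated change is
added to the intermediate shift. The algebra guarantees that both pathways
jointly reproduce the unadjusted single-pathway effect; a test asserts this
identity to 1e-9. The printed fruit/vegetable mediation coefficients are
carried verbatim with their printed per-g/day units.

## Diabetes-cardiovascular coupling

Diseases are otherwise independent, but diabetes prevalence couples
dynamically to IHD and stroke incidence through
$$m = \frac{1 + p_s (RR_{dm} - 1)}{1 + p_b (RR_{dm} - 1)},$$
re-evaluated every simulated year from the two arms' current diabetes
prevalence. Because the published physical activity betas for IHD/stroke
already contain the diabetes pathway, the direct beta is reduced by the
mediated fraction (default 0.25, an assumption exposed as
`pa_diabetes_mediated_fraction`) so that direct plus mediated effects
reproduce the published total at the reference dose.

# Life table conventions

* Rates convert to probabilities by constant-rate exponentials within each
  annual cycle; the three-state disease step is the exact (closed-form)
  matrix exponential of the triangular generator, tested against a
  fine-substep Euler integration.
* The cohort is closed: no births or migration; cohorts leave the
  simulation on passing age 100. Person-years in a year with mortality rate
  $m$ are $l\,(1 - e^{-m})/m$.
* Other-cause mortality is input all-cause mortality minus
  $\sum_d f_d P_d$ at baseline, floored at zero; each simulated year adds
  back the current $f_d P_d$ of the disease sub-tables, so the scenario's
  mortality responds to averted disease.
* Risk-factor changes act on incidence only, never on case fatality.
* Background trends multiply incidence and case fatality by
  $t^{y-1}$, compounding from simulation year zero, identically in both
  arms.
* Case fatality derivation uses the identity $f = m_{dis}/P$ with an
  optional monotone smoothing spline, and reports the residual of the
  annual consistency recursion $P_{a+1} = P_a + i_a(1 - P_a) - f_a P_a$
  rather than hiding it. The synthetic generator integrates exactly this
  recursion, so its residuals are zero by construction. The simulator's
  exponential step is a slightly different (second-order-consistent)
  discretisation of the same process; on the packaged fixtures the two
  agree to better than 0.01 absolute prevalence over 40 simulated years,
  and the baseline-reproduction test asserts that bound.

# Valuation conventions

* Utility is baseline EQ-5D at attained age and sex plus additive,
  prevalence-weighted disease decrements; no comorbidity interaction term
  (sensitivity work in the source literature found none was needed). IHD
  and stroke carry a separate incident-year decrement applied to the newly
  incident share, toggleable via `incident_decrement`. Utility is floored
  at zero; on simulated trajectories the floor never binds.
* Modelled-disease costs are per prevalent case per year, from top-down
  programme-budgeting totals divided by prevalence (transcribed, with the
  three costing steps kept separate so the aggregation is auditable).
  Unrelated-disease costs accrue per person-year alive from a packaged
  *synthetic* age profile (`unrelated_costs_synthetic.csv`) that stands in
  for cost-curve estimates and should be replaced with real data for
  applied work.
* Social care: from age 75, each person-year costs
  $12 \times 4826 \times g(\text{age}, u)$ GBP, where the packaged need
  function is $g = 1 - u$ — the simplest profile that increases in lost
  quality of life, replaceable via `config$social_care_need`.
* Discounting: $PV = \sum_y v_y (1+r)^{-(y-1)}$, first model year
  undiscounted; no half-cycle correction (rates are already exact within
  the annual cycle). Both conventions are configuration-visible.
* Return on investment is reported as the positive magnitude
  $|C_b - C_a|/C_i$ for cost-saving interventions; the raw signed ratio is
  preserved alongside because the defining difference is negative exactly
  when the intervention saves money.

# Uncertainty analysis

Each uncertain parameter carries its distribution in the catalogue:
relative risks lognormal (parameterised so the median equals the point
estimate, $\sigma_{\log} = se/\hat\theta$), coefficients, minima and
decrements normal, and generic health/societal cost multipliers gamma with
mean 1 and SD 0.1. Draw seeds are derived per (seed, parameter id, run
index) by a string hash, so results are reproducible and adding a
parameter never reshuffles the draws of existing ones. Age-banded relative
risks of one exposure-disease pair share a z-score (fully correlated bands)
by default; `rr_band_correlated = FALSE` makes them independent.
Intervals are empirical 2.5th/97.5th percentiles (order statistics, linear
interpolation) over 2000 runs by default; failing runs are excluded with a
warning count.

# The synthetic baseline generator

Real applications feed the model national incidence, prevalence, case
fatality, mortality, and exposure surveys. For development and testing the
package generates internally consistent stand-ins: Gompertz all-cause
mortality, exponential-in-age incidence and case fatality curves with
plausible scales and a small seeded lognormal perturbation, prevalence
built by the annual consistency recursion (so validation residuals are
zero), populations over the starting ages, and exposure means/SDs that
drift mildly with age (activity truncated at 200 MET h/wk, fruit and
vegetables with non-consumer shares). Two profiles control problem size:
`small` (IHD and stroke, ten seeded cohorts — the test suite's workhorse,
runs in well under a second) and `full` (all eleven diseases, all 86
cohorts, a ~2-second ten-year run).

What the generator does **not** emulate: calibration to any real
population, cohort effects, survey measurement error structure, or
correlation between risk factors. Passing tests on synthetic fixtures
therefore demonstrates the machinery's correctness (oracle equivalence,
conservation, monotonicity, null invariance), not predictive validity for
any country.

# Known limitations

* Diseases are independent apart from the explicit diabetes-CVD coupling;
  co-morbidity in one person versus two people is indistinguishable.
* Only incidence responds to risk factors; interventions that would change
  survival with disease are out of reach.
* Top-down per-prevalent-case costs ignore time since diagnosis and
  end-of-life cost concentration.
* Baseline utilities already embed the modelled diseases, so decrements
  accrued through added longevity may be slightly over-counted; no
  correction is applied, and discounting limits the effect.
* The free-sugars pathway to cholesterol is not included.
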