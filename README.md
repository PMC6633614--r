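# msltce — multistate life table cost-effectiveness of diet and physical activity interventions

Public health decision makers need to compare, on one scale, what different
policies on diet and physical activity would buy in health and cost. This
package implements the standard machinery for that comparison: a
**proportional multistate life table** (MSLT) driven by **comparative risk
assessment**, producing incremental QALYs, health and social care cost
streams, incremental cost-effectiveness ratios (ICER), return on investment
(ROI) for cost-saving policies, and probabilistic uncertainty intervals.
Its intended users are health economists and epidemiological modellers.

## The model

An intervention shifts the mean of one or more exposure distributions
(salt g/day, fruit g/day, BMI, MET hours of activity per week, ...). For
each affected disease this becomes a potential impact fraction

    PIF = ( ∫ RR(x) f_b(x) dx − ∫ RR(x) f_s(x) dx ) / ∫ RR(x) f_b(x) dx

with RR(x) the dose-response relative to the theoretical-minimum-risk
exposure (clamped at RR ≥ 1), f_b and f_s the baseline and scenario
truncated-normal exposure densities. PIFs from several risk factors combine
multiplicatively on 1 − PIF; fats, salt and energy act through cholesterol,
blood pressure and BMI, with mediation adjustments preventing double
counting, and physical activity uses the quarter-power form
RR = exp(β (x/11.25)^0.25).

A closed cohort (ages 15–100 by single year of age and sex) is then
simulated annually. Each disease is an illness-death process — incidence i,
case fatality f (annual mortality among prevalent cases), no remission —
stepped by the exact matrix exponential; scenario incidence is baseline
incidence × Π(1 − PIF), with diabetes prevalence dynamically multiplying
IHD/stroke incidence. Person-years are valued with EQ-5D utilities
(baseline by age/sex + additive disease decrements), per-prevalent-case
NHS costs, unrelated-disease costs, and social care from age 75
(£4826/month scaled by lost quality of life). Discounted streams yield

    ICER = (C_b − C_a) / (E_b − E_a)        ROI = |C_b − C_a| / C_i

and 95% uncertainty intervals come from the 2.5th/97.5th percentiles of
2000 Monte Carlo parameter draws.

The parameter catalogue (relative risks, pathway coefficients, theoretical
minima, mediation factors, utilities, disease costs) ships as auditable CSV
tables in `inst/extdata/catalogue/` with a JSON digest. Baseline
epidemiology is supplied by the user or by the built-in synthetic generator,
so everything runs without external data.

## Worked example

A population salt reduction of 1 g/day costing £2m per year, over a 10-year
horizon, on the full synthetic baseline:

```r
library(msltce)
res <- run_scenario(list(profile = "full", horizon = 10, seed = 1))
res
#> <mslt_scenario_result> salt_reduction_1g
#>   horizon 10 y, discount 1.5%, perspective nhs_social_care
#>   delta QALYs (disc.): 10080.9
#>   delta cost  (disc.): GBP 174591270
#>   ICER: GBP 17319 per QALY
round(unlist(res$summary$cost_components))
#>       modelled      unrelated    social_care   intervention
#>      -32115221       31487640      156497816       18721035
#>   productivity wider_societal
#>              0              0
```

Read: lower blood pressure averts IHD and stroke, saving £32m of modelled
disease costs and gaining ~10,100 discounted QALYs; the survivors accrue
£31m of unrelated health costs and £156m of social care costs, so the net
position is £175m for an ICER of about £17,300 per QALY — under the usual
£20,000–£30,000 willingness-to-pay range. (All numbers are from the
synthetic baseline; they demonstrate the machinery, not England.)

Single pieces are available directly:

```r
ps <- load_catalogue()
population_utility(50, "male", c(diabetes = 1), ps)
#> [1] 0.729            # 0.800 baseline − 0.071 decrement
intermediate_shift(c(salt = -1), ps)[["sbp"]]
#> [1] -0.9918          # mmHg per −1 g/day salt
```

`run_sensitivity_suite()` executes the standard variant set (horizons 1, 5,
20, 100 years; NHS-only / social-care-only perspectives; productivity and
wider societal costs; 3.5% discounting; no unrelated costs; non-cancer and
directly-related disease subsets). A thin command-line wrapper with
subcommands `run / psa / sensitivity / synth / validate` is in
`inst/scripts/msltce-cli.R`.

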