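Package: msltce
Title: Multistate Life Table Cost-Effectiveness Modelling of Diet and
    Physical Activity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proportional multistate life table engine for estimating the
    cost-effectiveness and return on investment of population-level
    interventions on diet and physical activity. Exposure shifts are
    converted into potential impact fractions on disease incidence via
    direct relative risks or via blood pressure, cholesterol, and body mass
    index pathways, with mediation and diabetes-cardiovascular coupling
    adjustments; a closed adult cohort (ages 15-100, by single year of age
    and sex) is simulated through per-disease illness-death processes to
    yield quality-adjusted life years, health and social care cost streams,
    incremental cost-effectiveness ratios, and probabilistic uncertainty
    intervals. Ships a transcribed parameter catalogue (relative risks,
    intermediate-pathway coefficients, theoretical minimum risk exposures,
    EQ-5D utilities, and NHS England programme-budgeting disease costs) and
    a synthetic baseline-epidemiology generator so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
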