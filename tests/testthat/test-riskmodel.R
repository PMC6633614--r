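make_dist <- function(rf, mean, sd, nc = 0, ages = 50, unit = "g/day") {
  exposure_distribution(rf, data.frame(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2), mean = mean, sd = sd, non_consumer = nc), unit)
}

test_that("interventions shift means, preserve SDs, and floor intakes at zero", {
  d <- make_dist("salt", 8, 3)
  iv <- intervention(list(salt = list(type = "absolute", amount = -1)))
  out <- apply_intervention(d, iv)
  expect_equal(out$mean, rep(7, 2))
  expect_equal(out$sd, d$sd)

  iv2 <- intervention(list(salt = list(type = "percent", amount = -10)))
  expect_equal(apply_intervention(d, iv2)$mean, rep(7.2, 2))

  iv3 <- intervention(list(salt = list(type = "absolute", amount = -10)))
  expect_equal(apply_intervention(d, iv3)$mean, rep(0, 2))

  # untouched factor passes through
  d2 <- make_dist("fruit", 120, 60)
  expect_equal(apply_intervention(d2, iv)$mean, d2$mean)

  expect_error(intervention(list()), "at least one")
  expect_error(intervention(list(salt = list(type = "absolute", amount = NaN))),
               "finite")
})

test_that("intermediate shifts follow the pathway coefficients", {
  ps <- the_catalogue()
  # saturated fat +1 %energy -> +0.052 mmol/L cholesterol
  expect_equal(intermediate_shift(c(saturated_fat = 1), ps)[["cholesterol"]],
               0.052)
  # salt -1 g/day -> -5.80 * 17.1/100 mmHg
  expect_equal(intermediate_shift(c(salt = -1), ps)[["sbp"]],
               -5.80 * 17.1 / 100)
  expect_equal(intermediate_shift(c(salt = -1), ps)[["sbp"]], -0.9918,
               tolerance = 1e-10)
  # null deltas
  expect_equal(unname(intermediate_shift(c(salt = 0, pufa = 0), ps)),
               c(0, 0, 0))
  # energy -> BMI via configured linear coefficient / height^2
  sh <- intermediate_shift(c(total_energy = -500), ps, sex = "male")
  cfg <- ps$config$energy_bmi
  expect_equal(sh[["bmi"]], -500 * cfg$kg_per_kj_day / cfg$ref_height_m[["male"]]^2)
  expect_error(intermediate_shift(c(moonlight = 1), ps), "unknown")
})

test_that("relative risk versus the theoretical minimum clamps correctly", {
  ps <- the_catalogue()
  rr <- ps$relative_risks[ps$relative_risks$risk_factor == "red_meat" &
                            ps$relative_risks$disease == "colorectal_cancer", ]
  expect_equal(relative_risk_at(114.3, rr, 14.3), 1.30)
  expect_equal(relative_risk_at(14.3, rr, 14.3), 1)
  expect_equal(relative_risk_at(5, rr, 14.3), 1)     # below tmin: clamped
  expect_error(relative_risk_at(-1, rr, 14.3), "negative exposure")

  # protective factor: above the minimum clamps to 1, below rises above 1
  fr <- ps$relative_risks[ps$relative_risks$risk_factor == "fruit" &
                            ps$relative_risks$disease == "ihd", ]
  expect_equal(relative_risk_at(350, fr, 300), 1)
  expect_gt(relative_risk_at(100, fr, 300), 1)
  expect_equal(relative_risk_at(194, fr, 300), 1 / 0.93, tolerance = 1e-12)
})

test_that("quarter-power physical activity dose-response", {
  expect_equal(pa_relative_risk(0, -0.204), 1)
  expect_equal(pa_relative_risk(11.25, -0.204), exp(-0.204))
  # ratio at 180 vs 11.25 MET h/wk: exp(beta (16^0.25 - 1)) = exp(beta)
  expect_equal(pa_relative_risk(180, -0.204) / pa_relative_risk(11.25, -0.204),
               exp(-0.204), tolerance = 1e-12)
  # monotone non-increasing; continuous everywhere, with the curve
  # approaching 1 as the dose approaches zero (the slope, not the value, is
  # unbounded there)
  r <- pa_relative_risk(seq(0, 150, by = 0.5), -0.204)
  expect_true(all(diff(r) <= 0))
  expect_equal(pa_relative_risk(1e-10, -0.204), 1, tolerance = 1e-2)
  r1 <- pa_relative_risk(seq(1, 150, by = 0.01), -0.204)
  expect_lt(max(abs(diff(r1))), 1e-3)
  # dose capped at the theoretical minimum
  expect_equal(pa_relative_risk(150, -0.204, tmin = 133),
               pa_relative_risk(133, -0.204))
  expect_error(pa_relative_risk(-5, -0.204), ">= 0")
})

test_that("physical activity categories split at 0/60/150 minutes", {
  expect_equal(as.character(categorize_pa(c(0, 1, 59, 60, 149, 150, 300))),
               c("sedentary", "under_active", "under_active", "active",
                 "active", "recommended", "recommended"))
  expect_error(categorize_pa(-1), ">= 0")
})

test_that("mediation adjustment preserves the total effect", {
  ps <- the_catalogue()
  rr <- ps$relative_risks[ps$relative_risks$risk_factor == "bmi" &
                            ps$relative_risks$disease == "stroke" &
                            ps$relative_risks$band_low == 35, ]
  med <- ps$mediation[ps$mediation$disease == "stroke" &
                        ps$mediation$exposure == "bmi", ]
  sbp <- ps$relative_risks[ps$relative_risks$risk_factor == "sbp" &
                             ps$relative_risks$disease == "stroke" &
                             ps$relative_risks$band_low == 0, ]
  adj <- mediation_adjust(rr, med, sbp)
  expect_equal(adj$value, 1.76 / (1 / 0.36)^(3.25 / 20), tolerance = 1e-12)
  expect_equal(adj$value, 1.4909, tolerance = 1e-4)

  # zero mediation coefficient leaves the RR unchanged
  med0 <- med; med0$coefficient <- 0
  expect_equal(mediation_adjust(rr, med0, sbp)$value, rr$value)

  # identity: adjusted direct RR times the mediated SBP RR equals the
  # unadjusted total per 5 kg/m^2
  d_bmi <- 5
  d_sbp <- med$coefficient * d_bmi
  total <- adj$value^(d_bmi / rr$unit_value) *
    sbp$value^(d_sbp / sbp$unit_value)
  expect_equal(total, rr$value, tolerance = 1e-9)

  # mismatched rows are rejected
  expect_error(mediation_adjust(rr, ps$mediation[ps$mediation$disease == "ihd" &
    ps$mediation$exposure == "bmi", ], sbp), "does not match")
})

test_that("diabetes-CVD multiplier follows the prevalence-mix formula", {
  expect_equal(diabetes_cvd_multiplier(0.1, 0.1, 1.85), 1)
  expect_equal(diabetes_cvd_multiplier(0.05, 0.10, 1.85),
               1.0425 / 1.0850, tolerance = 1e-12)
  expect_equal(diabetes_cvd_multiplier(0.3, 0.7, 1), 1)
  expect_error(diabetes_cvd_multiplier(0.1, 0.1, 0), "positive")
  expect_error(diabetes_cvd_multiplier(1.2, 0.1, 1.85), "\\[0, 1\\]")
})

test_that("physical activity beta de-confounding splits and recombines", {
  expect_equal(pa_rr_deconfound(-0.204, 0), -0.204)
  expect_equal(pa_rr_deconfound(-0.204, 0.25), -0.153)
  # composite at the reference dose reproduces the published total
  bt <- -0.204; frac <- 0.25
  bd <- pa_rr_deconfound(bt, frac)
  mediated <- exp(bt * frac)
  expect_equal(exp(bd) * mediated, exp(bt), tolerance = 1e-6)
  expect_error(pa_rr_deconfound(-0.204, 1.1), "flip")
})
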