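test_that("PIF is zero for identical distributions and flat risk", {
  ps <- the_catalogue()
  fun <- msltce:::rr_curve(ps, "red_meat", "colorectal_cancer", "male", 50)
  expect_equal(msltce:::pif_1d(fun, 60, 25, 60, 25), 0)
  # RR of 1 per unit => zero PIF whatever the shift
  flat <- function(x) rep(1, length(x))
  expect_equal(msltce:::pif_1d(flat, 60, 25, 40, 25), 0)
})

test_that("degenerate (point-mass) PIF matches the closed form", {
  ps <- the_catalogue()
  fun <- msltce:::rr_curve(ps, "red_meat", "colorectal_cancer", "male", 50)
  # 114.3 -> 14.3 g/day: PIF = 1 - 1/1.30
  expect_equal(msltce:::pif_1d(fun, 114.3, 0, 14.3, 0),
               1 - 1 / 1.30, tolerance = 1e-9)
  # arbitrary pair of point masses
  expect_equal(msltce:::pif_1d(fun, 90, 0, 50, 0),
               1 - fun(50) / fun(90), tolerance = 1e-9)
})

test_that("trapezoid PIF agrees with a Monte Carlo oracle", {
  ps <- the_catalogue()
  cases <- expand.grid(mean = c(40, 80, 120), sd = c(10, 40),
                       shift = c(-20, -5))
  fun <- msltce:::rr_curve(ps, "red_meat", "colorectal_cancer", "male", 50)
  for (k in seq_len(nrow(cases))) {
    m <- cases$mean[k]; s <- cases$sd[k]; sh <- cases$shift[k]
    got <- msltce:::pif_1d(fun, m, s, m + sh, s, n = 201)
    mc <- mc_pif_oracle(fun, m, s, m + sh, s, n = 1e5, seed = k)
    expect_lt(abs(got - mc$pif), 3 * mc$se + 1e-4)
  }
})

test_that("non-consumer point mass enters the mixture", {
  ps <- the_catalogue()
  fun <- msltce:::rr_curve(ps, "fruit", "ihd", "male", 50)
  # all mass at zero intake: expected RR is RR(0) in both arms
  expect_equal(msltce:::pif_1d(fun, 120, 50, 160, 50, 1, 1), 0)
  mc <- mc_pif_oracle(fun, 120, 50, 160, 50, 0.25, 0.25, n = 1e5, seed = 7)
  got <- msltce:::pif_1d(fun, 120, 50, 160, 50, 0.25, 0.25)
  expect_lt(abs(got - mc$pif), 3 * mc$se + 1e-4)
})

test_that("PIF sign tracks the direction of benefit", {
  ps <- the_catalogue()
  # harmful factor: shifting the mean toward the minimum is beneficial
  fun <- msltce:::rr_curve(ps, "red_meat", "colorectal_cancer", "male", 50)
  expect_gt(msltce:::pif_1d(fun, 80, 30, 60, 30), 0)
  expect_lt(msltce:::pif_1d(fun, 80, 30, 100, 30), 0)
  # protective factor: raising intake toward the minimum is beneficial
  fr <- msltce:::rr_curve(ps, "fruit", "ihd", "male", 50)
  expect_gt(msltce:::pif_1d(fr, 120, 50, 160, 50), 0)
  expect_lt(msltce:::pif_1d(fr, 120, 50, 80, 50), 0)
})

test_that("compute_pif maps age bands and sexes over a distribution", {
  ps <- the_catalogue()
  d <- exposure_distribution("sbp", data.frame(
    sex = rep(c("male", "female"), each = 3),
    age = rep(c(45, 65, 85), 2), mean = 140, sd = 15), "mmHg")
  iv <- intervention(list(sbp = list(type = "absolute", amount = -5)))
  s <- apply_intervention(d, iv)
  p <- compute_pif(d, s, "stroke", ps)
  expect_identical(nrow(p), 6L)
  expect_true(all(p$pif > 0))
  # steeper RR at younger ages => larger PIF
  expect_gt(p$pif[p$sex == "male" & p$age == 45],
            p$pif[p$sex == "male" & p$age == 85])
})

test_that("multiplicative combination of PIFs", {
  expect_equal(combine_pifs(c(0.2, 0.1)), 1 - 0.8 * 0.9)
  expect_equal(combine_pifs(0.3), 0.3)
  expect_equal(combine_pifs(c(0, 0)), 0)
})

test_that("scenario PIFs: mediated BMI pathway reproduces the total effect", {
  # When BMI alone shifts (point masses), the adjusted direct BMI PIF
  # combined with the mediated SBP PIF must equal the PIF computed from the
  # unadjusted total BMI relative risk.
  ps <- the_catalogue()
  ages <- 45
  mk <- function(rf, mean, unit) exposure_distribution(rf, data.frame(
    sex = c("male", "female"), age = ages, mean = mean, sd = 0), unit)
  exposures <- list(bmi = mk("bmi", 29, "kg/m2"),
                    sbp = mk("sbp", 138, "mmHg"),
                    cholesterol = mk("cholesterol", 5.0, "mmol/L"))
  iv <- intervention(list(bmi = list(type = "absolute", amount = -2)))
  got <- compute_scenario_pifs(exposures, iv, ps, diseases = "stroke",
                               dm_coupling = FALSE)
  # oracle: unadjusted total BMI effect, no mediation split
  ps0 <- load_catalogue(config = list(apply_mediation = FALSE))
  want <- compute_scenario_pifs(exposures, iv, ps0, diseases = "stroke",
                                dm_coupling = FALSE)
  expect_equal(got$pif, want$pif, tolerance = 1e-9)
})

test_that("null intervention yields zero PIFs everywhere", {
  ps <- the_catalogue()
  exposures <- generate_exposure_survey(seed = 3)
  iv <- intervention(list(salt = list(type = "absolute", amount = 0)))
  p <- compute_scenario_pifs(exposures, iv, ps, diseases = c("ihd", "stroke"))
  expect_true(all(abs(p$pif) < 1e-12))
})
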