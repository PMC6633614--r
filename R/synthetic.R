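# Synthetic baseline inputs: internally consistent epidemiology and exposure
# surveys so the full pipeline runs and is testable without external data.

# Smooth age curves (rates per person-year at age a) per disease; scales are
# chosen to be epidemiologically plausible for a high-income population, not
# calibrated to any country.
synth_disease_shapes <- function() {
  list(
    ihd =               list(inc0 = 6e-5, inc_g = 0.075, cf0 = 0.015, cf_g = 0.035),
    stroke =            list(inc0 = 3e-5, inc_g = 0.080, cf0 = 0.020, cf_g = 0.035),
    diabetes =          list(inc0 = 3e-4, inc_g = 0.045, cf0 = 0.004, cf_g = 0.030),
    breast_cancer =     list(inc0 = 1.2e-4, inc_g = 0.045, cf0 = 0.020, cf_g = 0.015),
    colorectal_cancer = list(inc0 = 1.5e-5, inc_g = 0.075, cf0 = 0.035, cf_g = 0.012),
    lung_cancer =       list(inc0 = 8e-6, inc_g = 0.085, cf0 = 0.180, cf_g = 0.008),
    stomach_cancer =    list(inc0 = 3e-6, inc_g = 0.080, cf0 = 0.110, cf_g = 0.008),
    liver_cancer =      list(inc0 = 2e-6, inc_g = 0.080, cf0 = 0.200, cf_g = 0.006),
    kidney_cancer =     list(inc0 = 5e-6, inc_g = 0.070, cf0 = 0.050, cf_g = 0.010),
    pancreatic_cancer = list(inc0 = 2e-6, inc_g = 0.085, cf0 = 0.300, cf_g = 0.005),
    liver_cirrhosis =   list(inc0 = 4e-5, inc_g = 0.040, cf0 = 0.060, cf_g = 0.015))
}

#' Generate internally consistent baseline epidemiology
#'
#' Builds per-disease incidence and case fatality as smooth exponential age
#' curves (with a small seeded lognormal perturbation of the scales),
#' obtains prevalence by forward integration of the annual illness-death
#' recursion from age 15 (so the consistency residual of
#' [derive_case_fatality()] is exactly zero), sets all-cause mortality
#' as a Gompertz curve plus the disease-specific contributions (so
#' other-cause mortality is non-negative by construction), and lays a
#' population over the starting ages. Breast cancer incidence is zeroed in
#' men.
#'
#' The `"small"` profile keeps two diseases (IHD, stroke) and seeds ten
#' cohorts (start ages 15, 20, ..., 60); the `"full"` profile keeps all
#' eleven diseases and all 86 single-year cohorts. Both cover rates for
#' every attainable age 15-100.
#'
#' @param profile `"small"` or `"full"`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param diseases Optional disease subset overriding the profile's set.
#' @return List `epi` (data frame `disease`, `sex`, `age`, `incidence`,
#'   `prevalence`, `case_fatality`, `trend`) and `life_table` (data frame
#'   `sex`, `age`, `population`, `mortality`).
#' @export
generate_baseline_epi <- function(profile = c("small", "full"), seed = 1L,
                                  diseases = NULL) {
  profile <- match.arg(profile)
  ages <- 15:100
  shapes <- synth_disease_shapes()
  diseases <- diseases %||%
    if (profile == "small") c("ihd", "stroke") else names(shapes)
  bad <- setdiff(diseases, names(shapes))
  if (length(bad)) stop_msltce("unknown disease(s): ", paste(bad, collapse = ", "))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mix_seed(seed, "baseline_epi"))

  epi <- list()
  for (sx in c("male", "female")) {
    sex_mult <- if (sx == "male") 1.15 else 0.9
    for (d in diseases) {
      p <- shapes[[d]]
      jit_i <- stats::rlnorm(1, 0, 0.1)
      jit_f <- stats::rlnorm(1, 0, 0.1)
      inc <- p$inc0 * sex_mult * jit_i * exp(p$inc_g * (ages - 15))
      cf <- p$cf0 * jit_f * exp(p$cf_g * (ages - 15))
      if (d == "breast_cancer" && sx == "male") inc[] <- 0
      # forward integration of the annual illness-death recursion
      # P(a+1) = P(a) + i(a) (1 - P(a)) - f(a) P(a), starting disease-free,
      # so the consistency residual reported by derive_case_fatality() is
      # zero by construction
      prev <- numeric(length(ages))
      for (k in seq_along(ages)[-1L]) {
        p <- prev[k - 1L]
        prev[k] <- min(max(p + inc[k - 1L] * (1 - p) - cf[k - 1L] * p, 0), 1)
      }
      epi[[paste(sx, d)]] <- data.frame(
        disease = d, sex = sx, age = ages, incidence = inc,
        prevalence = prev, case_fatality = cf, trend = 1,
        stringsAsFactors = FALSE)
    }
  }
  epi <- do.call(rbind, c(epi, list(make.row.names = FALSE)))

  lt <- list()
  for (sx in c("male", "female")) {
    gomp <- (if (sx == "male") 4e-5 else 3e-5) * exp(0.088 * (ages - 15))
    dis_mort <- vapply(ages, function(a) {
      e <- epi[epi$sex == sx & epi$age == a, , drop = FALSE]
      sum(e$case_fatality * e$prevalence)
    }, numeric(1))
    start_ages <- if (profile == "small") seq(15, 60, by = 5) else ages
    pop <- ifelse(ages %in% start_ages,
                  round(60000 * exp(-0.004 * (ages - 15))), 0)
    lt[[sx]] <- data.frame(sex = sx, age = ages, population = pop,
                           mortality = gomp + dis_mort,
                           stringsAsFactors = FALSE)
  }
  list(epi = epi, life_table = do.call(rbind, c(lt, list(make.row.names = FALSE))))
}

#' Generate a synthetic exposure survey
#'
#' Plausible per-age/sex means and SDs for each risk factor in its native
#' units, emulating the summaries a national diet and activity survey would
#' provide: intakes drift mildly with age, physical activity declines with
#' age and is truncated at 200 MET h/wk, and fruit and vegetables carry a
#' non-consumer share. Deterministic given the seed.
#'
#' @param factors Risk factors to generate (default: every factor the
#'   catalogue can use).
#' @param seed Integer seed.
#' @param ages Ages covered (default 15-100).
#' @return Named list of [exposure_distribution()] objects.
#' @export
generate_exposure_survey <- function(factors = NULL, seed = 1L, ages = 15:100) {
  spec <- list(
    # mean at age 15 (male), age slope per year, SD as share of mean, units
    fruit = list(m0 = 110, slope = 0.6, cv = 0.7, unit = "g/day", nc = 0.22),
    vegetables = list(m0 = 120, slope = 0.5, cv = 0.6, unit = "g/day", nc = 0.18),
    fibre = list(m0 = 13, slope = 0.04, cv = 0.35, unit = "g/day"),
    fibre_cereal = list(m0 = 6, slope = 0.02, cv = 0.4, unit = "g/day"),
    red_meat = list(m0 = 55, slope = -0.1, cv = 0.6, unit = "g/day"),
    processed_meat = list(m0 = 30, slope = -0.08, cv = 0.7, unit = "g/day"),
    total_fat = list(m0 = 34, slope = 0, cv = 0.18, unit = "%energy"),
    saturated_fat = list(m0 = 12.5, slope = 0, cv = 0.22, unit = "%energy"),
    mufa = list(m0 = 12, slope = 0, cv = 0.2, unit = "%energy"),
    pufa = list(m0 = 6, slope = 0, cv = 0.25, unit = "%energy"),
    dietary_cholesterol = list(m0 = 0.25, slope = 0, cv = 0.4, unit = "g/day"),
    salt = list(m0 = 8.4, slope = -0.01, cv = 0.35, unit = "g/day"),
    total_energy = list(m0 = 9200, slope = -12, cv = 0.25, unit = "kJ/day"),
    sbp = list(m0 = 118, slope = 0.45, cv = 0.10, unit = "mmHg"),
    cholesterol = list(m0 = 4.3, slope = 0.015, cv = 0.20, unit = "mmol/L"),
    bmi = list(m0 = 23, slope = 0.08, cv = 0.17, unit = "kg/m2"),
    physical_activity = list(m0 = 32, slope = -0.25, cv = 0.8,
                             unit = "METhr/wk"))
  factors <- factors %||% names(spec)
  bad <- setdiff(factors, names(spec))
  if (length(bad)) stop_msltce("unknown risk factor(s): ", paste(bad, collapse = ", "))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  out <- list()
  for (rf in factors) {
    p <- spec[[rf]]
    set.seed(mix_seed(seed, "exposure", rf))
    jit <- stats::rlnorm(2, 0, 0.05)      # sex-specific scale perturbation
    rows <- list()
    for (k in 1:2) {
      sx <- c("male", "female")[k]
      sex_mult <- if (sx == "male") 1 else
        switch(rf, red_meat = 0.7, processed_meat = 0.65, salt = 0.8,
               total_energy = 0.78, physical_activity = 0.8, bmi = 0.99, 1)
      m <- pmax((p$m0 + p$slope * (ages - 15)) * sex_mult * jit[k], 0.01)
      if (rf == "physical_activity") m <- pmin(m, 200)
      if (rf == "bmi") m <- pmin(m, 32)
      rows[[sx]] <- data.frame(sex = sx, age = ages, mean = m,
                               sd = pmax(m * p$cv, 1e-3),
                               non_consumer = p$nc %||% 0,
                               stringsAsFactors = FALSE)
    }
    out[[rf]] <- exposure_distribution(rf, do.call(rbind, c(rows,
                 list(make.row.names = FALSE))), unit_label = p$unit)
  }
  out
}
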