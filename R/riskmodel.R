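#' Construct an exposure distribution
#'
#' Per age and sex summary (mean, SD) of one risk factor in its native units,
#' with an optional non-consumer share (the point mass at zero intake used
#' for fruit and vegetables).
#'
#' @param risk_factor Risk factor name (see `mslt_risk_factors()` vocabulary).
#' @param data Data frame with columns `sex`, `age`, `mean`, `sd` and
#'   optionally `non_consumer`.
#' @param unit_label Native units (e.g. "g/day", "mmHg", "METhr/wk").
#' @return An `exposure_distribution`: the data frame with attributes.
#' @export
exposure_distribution <- function(risk_factor, data, unit_label = "") {
  stopifnot(all(c("sex", "age", "mean", "sd") %in% names(data)))
  if (!risk_factor %in% mslt_risk_factors()) {
    stop_msltce("unknown risk factor: ", risk_factor)
  }
  if (is.null(data$non_consumer)) data$non_consumer <- 0
  if (any(data$sd < 0)) stop_msltce("exposure SD must be >= 0")
  if (any(data$non_consumer < 0 | data$non_consumer > 1)) {
    stop_msltce("non-consumer share must lie in [0, 1]")
  }
  if (risk_factor == "physical_activity" && any(data$mean > 200)) {
    stop_msltce("MET h/wk exceeds the 200 survey truncation limit")
  }
  structure(data, risk_factor = risk_factor, unit_label = unit_label,
            class = c("exposure_distribution", class(data)))
}

#' Define an intervention on one or more risk factors
#'
#' @param shifts Named list, one entry per risk factor touched. Each entry is
#'   `list(type =, amount =)` with `type` one of `"absolute"` (additive delta
#'   in native units), `"percent"` (relative change in percent, e.g. -10), or
#'   `"set_mean"` (replace the mean).
#' @param cost Intervention cost stream in GBP, one value per model year
#'   (recycled to the horizon with zeros).
#' @param label Scenario label.
#' @return An `mslt_intervention`.
#' @export
intervention <- function(shifts, cost = 0, label = "intervention") {
  if (!length(shifts)) stop_msltce("an intervention must touch at least one risk factor")
  bad <- setdiff(names(shifts), mslt_risk_factors())
  if (length(bad)) stop_msltce("unknown risk factor(s): ", paste(bad, collapse = ", "))
  for (s in shifts) {
    if (!s$type %in% c("absolute", "percent", "set_mean")) {
      stop_msltce("unknown shift type: ", s$type)
    }
    if (!is.finite(s$amount)) stop_msltce("shift amount must be finite")
  }
  structure(list(shifts = shifts, cost = cost, label = label),
            class = "mslt_intervention")
}

#' Apply an intervention to an exposure distribution
#'
#' Shifts the mean according to the intervention rule; the SD and the
#' non-consumer share are preserved. Intake exposures are floored at zero.
#'
#' @param dist An [exposure_distribution()].
#' @param iv An [intervention()]. Factors not named in `iv` are untouched.
#' @return The shifted `exposure_distribution`.
#' @export
apply_intervention <- function(dist, iv) {
  stopifnot(inherits(dist, "exposure_distribution"),
            inherits(iv, "mslt_intervention"))
  rf <- attr(dist, "risk_factor")
  s <- iv$shifts[[rf]]
  if (is.null(s)) return(dist)
  m <- switch(s$type,
              absolute = dist$mean + s$amount,
              percent = dist$mean * (1 + s$amount / 100),
              set_mean = rep(s$amount, nrow(dist)))
  if (any(!is.finite(m))) stop_msltce("intervention produced a non-finite mean")
  if (rf %in% intake_factors()) m <- pmax(m, 0)
  dist$mean <- m
  dist
}

#' Shift of the intermediate risk factors implied by dietary changes
#'
#' Converts mean changes of the diet factors operating through intermediates
#' into changes of systolic blood pressure (mmHg), total cholesterol
#' (mmol/L), and BMI (kg/m^2). Salt is converted from g/day to mmol of
#' urinary sodium before the per-100-mmol coefficient applies; total energy
#' uses the configurable linear steady-state coefficient divided by the
#' squared sex-specific reference height.
#'
#' @param deltas Named numeric vector of mean exposure changes in native
#'   units (e.g. `c(salt = -1)` for one gram of salt per day less).
#' @param ps An `mslt_catalogue`.
#' @param sex `"male"` or `"female"` (only used for the energy-BMI pathway).
#' @return Named numeric vector `c(sbp =, cholesterol =, bmi =)`.
#' @export
intermediate_shift <- function(deltas, ps, sex = "male") {
  stopifnot(inherits(ps, "mslt_catalogue"))
  sex <- check_sex(sex)
  ie <- ps$intermediate_effects
  out <- c(sbp = 0, cholesterol = 0, bmi = 0)
  for (rf in names(deltas)) {
    row <- ie[ie$risk_factor == rf, , drop = FALSE]
    if (!nrow(row)) stop_msltce("unknown intermediate-pathway factor: ", rf)
    d <- deltas[[rf]]
    if (rf == "salt") {
      d <- d * ps$config$salt_na_mmol_per_g        # g/day -> mmol Na/24h
    }
    if (rf == "total_energy") {
      eb <- ps$config$energy_bmi
      coef <- eb$kg_per_kj_day / eb$ref_height_m[[sex]]^2
      out["bmi"] <- out["bmi"] + d * coef
    } else {
      out[row$intermediate] <- out[row$intermediate] +
        d * row$coefficient / row$unit_value
    }
  }
  out
}

# Log relative risk at exposure x for an rr_per_unit row, before clamping.
# Exposure-banded rows (BMI) accumulate piecewise log-linear slopes from the
# theoretical minimum; age-banded and unbanded rows use a single slope.
log_rr_raw <- function(x, rows, tmin) {
  if (nrow(rows) == 1L && rows$band_type[1L] != "exposure") {
    return(log(rows$value[1L]) * (x - tmin) / rows$unit_value[1L])
  }
  # piecewise-constant slope by exposure band; integrate from tmin to x
  # (the first band extends downwards, the last upwards)
  rows <- rows[order(rows$band_low), , drop = FALSE]
  s <- log(rows$value) / rows$unit_value
  base <- min(c(x, tmin, rows$band_low)) - 1
  lo <- c(base, rows$band_low[-1L])
  hi <- c(rows$band_low[-1L], Inf)
  antideriv <- function(v) {
    out <- 0
    for (j in seq_along(s)) {
      out <- out + s[j] * (pmin(pmax(v, lo[j]), hi[j]) - lo[j])
    }
    out
  }
  antideriv(x) - antideriv(tmin)
}

#' Relative risk at an exposure level versus the theoretical minimum
#'
#' `RR(x) = value^((x - tmin) / unit)` for the per-unit form, clamped so that
#' no exposure confers extra benefit beyond the theoretical minimum
#' (`RR >= 1` everywhere relative to the minimum-risk exposure). Exposure
#' levels are in the factor's native units; negative intakes are rejected.
#'
#' @param exposure Exposure value(s) in native units.
#' @param rr One or more rows of the catalogue `relative_risks` table for a
#'   single exposure-disease pair (several rows only for exposure-banded
#'   risks such as BMI on diabetes).
#' @param tmin Theoretical minimum risk exposure in the same units.
#' @param clamp Clamp `RR` at 1 below/beyond the minimum (default TRUE).
#' @return Relative risk(s) versus the theoretical minimum.
#' @export
relative_risk_at <- function(exposure, rr, tmin, clamp = TRUE) {
  stopifnot(nrow(rr) >= 1L, all(rr$form == "rr_per_unit"))
  if (rr$risk_factor[1L] %in% intake_factors() && any(exposure < 0)) {
    stop_msltce("negative exposure for intake factor ", rr$risk_factor[1L])
  }
  out <- exp(log_rr_raw(exposure, rr, tmin))
  if (clamp) out <- pmax(out, 1)
  out
}

#' Physical activity relative risk (quarter-power dose-response)
#'
#' `RR(x) = exp(beta * (x / ref)^0.25)` with `ref = 11.25` MET h/wk, so the
#' published beta reproduces `exp(beta)` at the unit dose and the sedentary
#' reference (zero dose) has `RR = 1`. The dose is capped at the theoretical
#' minimum risk level when one is supplied (no extra benefit beyond it).
#'
#' @param met_hours MET hours per week (>= 0).
#' @param beta Beta of the quarter-power transform (negative = protective).
#' @param ref_dose Reference dose in MET h/wk (default 11.25).
#' @param tmin Optional dose cap in MET h/wk.
#' @return Relative risk(s) versus sedentary.
#' @export
pa_relative_risk <- function(met_hours, beta, ref_dose = 11.25, tmin = NULL) {
  if (any(met_hours < 0)) stop_msltce("MET hours must be >= 0")
  x <- met_hours
  if (!is.null(tmin)) x <- pmin(x, tmin)
  exp(beta * (x / ref_dose)^0.25)
}

#' Physical activity category from weekly moderate-activity minutes
#'
#' Categories: `sedentary` (0 min), `under_active` (0-60 min exclusive),
#' `active` (60 to under 150 min), `recommended` (150 min or more, the UK
#' Chief Medical Officers' recommendation).
#'
#' @param minutes_moderate_per_week Minutes of moderate activity per week.
#' @return Factor with levels sedentary/under_active/active/recommended.
#' @export
categorize_pa <- function(minutes_moderate_per_week) {
  m <- minutes_moderate_per_week
  if (any(m < 0)) stop_msltce("minutes of activity must be >= 0")
  lev <- c("sedentary", "under_active", "active", "recommended")
  out <- ifelse(m == 0, "sedentary",
         ifelse(m < 60, "under_active",
         ifelse(m < 150, "active", "recommended")))
  factor(out, levels = lev)
}

#' Strip a mediated pathway from a direct relative risk
#'
#' When an exposure acts on a disease both directly and through an
#' intermediate (e.g. BMI on stroke partly via blood pressure), applying both
#' pathways double-counts. The direct per-unit relative risk is divided by
#' the relative risk implied by the mediated intermediate change, so that the
#' direct and mediated pathways applied jointly reproduce the published
#' total effect.
#'
#' @param rr Single row of the `relative_risks` table: the total direct
#'   effect (per `unit_value` of the exposure).
#' @param med Matching row of the `mediation` table: change in the
#'   intermediate per one native unit of the exposure.
#' @param intermediate_rr Single row of the `relative_risks` table for the
#'   intermediate on the same disease (age band already selected).
#' @return The `rr` row with its `value` replaced by the mediation-adjusted
#'   relative risk.
#' @export
mediation_adjust <- function(rr, med, intermediate_rr) {
  stopifnot(nrow(rr) == 1L, nrow(med) == 1L, nrow(intermediate_rr) == 1L)
  if (med$disease != rr$disease || med$exposure != rr$risk_factor) {
    stop_msltce("mediation row does not match the exposure-disease pair")
  }
  delta_int <- med$coefficient * rr$unit_value      # intermediate change per RR unit
  rr_mediated <- intermediate_rr$value^(delta_int / intermediate_rr$unit_value)
  rr$value <- rr$value / rr_mediated
  rr
}

#' Diabetes-cardiovascular incidence multiplier
#'
#' The population relative incidence of IHD or stroke implied by a change in
#' diabetes prevalence:
#' `(1 + p_scenario (RR - 1)) / (1 + p_baseline (RR - 1))`, where `RR` is the
#' risk of the cardiovascular disease given diabetes.
#'
#' @param p_dm_scenario,p_dm_baseline Diabetes prevalence in `[0, 1]`.
#' @param rr_dm Relative risk of the cardiovascular outcome given diabetes.
#' @return Incidence multiplier (1 when prevalences coincide).
#' @export
diabetes_cvd_multiplier <- function(p_dm_scenario, p_dm_baseline, rr_dm) {
  if (any(rr_dm <= 0)) stop_msltce("diabetes relative risk must be positive")
  if (any(p_dm_scenario < 0 | p_dm_scenario > 1 |
          p_dm_baseline < 0 | p_dm_baseline > 1)) {
    stop_msltce("prevalences must lie in [0, 1]")
  }
  (1 + p_dm_scenario * (rr_dm - 1)) / (1 + p_dm_baseline * (rr_dm - 1))
}

#' Remove the diabetes-mediated share of a physical activity beta
#'
#' The published physical activity betas for IHD and stroke contain the
#' pathway through diabetes. When the model couples diabetes prevalence to
#' cardiovascular incidence dynamically, the direct beta is reduced so that
#' direct plus diabetes-mediated effects reproduce the published total at
#' the reference dose: `beta_direct = beta_total * (1 - mediated_fraction)`.
#'
#' @param beta_total Published beta (quarter-power transform).
#' @param mediated_fraction Share of the total effect mediated via diabetes,
#'   in `[0, 1)`.
#' @return The direct-effect beta.
#' @export
pa_rr_deconfound <- function(beta_total, mediated_fraction) {
  if (mediated_fraction < 0 || mediated_fraction >= 1) {
    stop_msltce("mediated fraction must lie in [0, 1); larger values would ",
                "flip the sign of the direct effect")
  }
  beta_total * (1 - mediated_fraction)
}
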