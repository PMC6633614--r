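# Morbidity: EQ-5D utility weighting of person-years.

#' Mean utility of a population stratum
#'
#' Baseline age- and sex-specific EQ-5D utility plus additive disease
#' decrements weighted by prevalence; no comorbidity interaction term is
#' applied. For diseases with a separate incident-year decrement (IHD,
#' stroke) the newly incident share gets the incident value in the year of
#' onset when `incident` shares are supplied. The result is floored at 0.
#'
#' @param age Attained age (0-100).
#' @param sex `"male"` or `"female"`.
#' @param disease_prevalences Named numeric vector of prevalent proportions.
#' @param ps An `mslt_catalogue`.
#' @param incident Optional named vector of newly incident proportions (only
#'   used when the catalogue has incident-phase decrements and the config
#'   enables them).
#' @return Mean utility in `[0, 1]`.
#' @export
population_utility <- function(age, sex, disease_prevalences = numeric(),
                               ps, incident = NULL) {
  sex <- check_sex(sex)
  bu <- ps$baseline_utilities
  u <- bu[[sex]][match(age, bu$age)]
  if (any(is.na(u))) stop_msltce("age outside the baseline utility table")
  if (length(disease_prevalences)) {
    if (any(disease_prevalences < 0 | disease_prevalences > 1)) {
      stop_msltce("prevalences must lie in [0, 1]")
    }
    for (d in names(disease_prevalences)) {
      dec <- decrement_lookup(ps, d, "prevalent")
      u <- u + disease_prevalences[[d]] * dec
      if (!is.null(incident) && !is.na(incident[d]) &&
          isTRUE(ps$config$incident_decrement)) {
        dinc <- decrement_lookup(ps, d, "incident")
        u <- u + incident[[d]] * (dinc - dec)
      }
    }
  }
  pmax(u, 0)
}

# Utility for every row of a trajectory data frame.
trajectory_utility <- function(traj, ps) {
  diseases <- sub("^prev_", "", grep("^prev_", names(traj), value = TRUE))
  bu <- ps$baseline_utilities
  u_m <- bu$male[match(traj$age, bu$age)]
  u_f <- bu$female[match(traj$age, bu$age)]
  u <- ifelse(traj$sex == "male", u_m, u_f)
  use_inc <- isTRUE(ps$config$incident_decrement)
  for (d in diseases) {
    dec <- decrement_lookup(ps, d, "prevalent")
    u <- u + traj[[paste0("prev_", d)]] * dec
    if (use_inc) {
      dinc <- decrement_lookup(ps, d, "incident")
      if (dinc != dec) {
        u <- u + traj[[paste0("inc_", d)]] * (dinc - dec)
      }
    }
  }
  pmax(u, 0)
}

#' Quality-adjusted life year stream of a model run
#'
#' Yearly QALYs per arm: person-years weighted by the stratum mean utility
#' (baseline utility at attained age plus prevalence-weighted disease
#' decrements).
#'
#' @param run An `mslt_run` from [run_mslt()].
#' @param ps An `mslt_catalogue`.
#' @return Data frame `scenario`, `year`, `qalys`, `person_years`.
#' @export
qaly_stream <- function(run, ps) {
  stopifnot(inherits(run, "mslt_run"))
  one <- function(traj, label) {
    u <- trajectory_utility(traj, ps)
    q <- stats::aggregate(cbind(qalys = traj$person_years * u,
                                person_years = traj$person_years),
                          by = list(year = traj$year), FUN = sum)
    q$scenario <- label
    q[, c("scenario", "year", "qalys", "person_years")]
  }
  rbind(one(run$baseline, "baseline"), one(run$scenario, "scenario"))
}
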