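# Cost streams, discounting, and cost-effectiveness / return on investment.

#' Total NHS disease cost from its programme-budgeting components
#'
#' Exact sum of the three top-down costing steps (programme budgeting,
#' specialised services, primary care), all in GBP thousands.
#'
#' @param programme_budgeting,specialised_services,primary_care Component
#'   expenditures (GBP 000s), vectorised.
#' @return Total disease cost (GBP 000s).
#' @export
aggregate_disease_cost <- function(programme_budgeting, specialised_services,
                                   primary_care) {
  if (any(c(programme_budgeting, specialised_services, primary_care) < 0)) {
    stop_msltce("cost components must be >= 0")
  }
  programme_budgeting + specialised_services + primary_care
}

#' Modelled-disease and unrelated health cost streams
#'
#' Yearly modelled cost is prevalent person-years per disease times the
#' annual cost per prevalent case; unrelated cost is person-years alive
#' times the age- and sex-specific annual spend on diseases outside the
#' model.
#'
#' @param traj One trajectory of an `mslt_run` (a long data frame).
#' @param ps An `mslt_catalogue`.
#' @return Data frame `year`, `modelled_cost`, `unrelated_cost` with
#'   attribute `by_disease` (year x disease modelled cost breakdown).
#' @export
health_costs <- function(traj, ps) {
  diseases <- sub("^prev_", "", grep("^prev_", names(traj), value = TRUE))
  dc <- ps$disease_costs
  miss <- setdiff(diseases, dc$disease)
  if (length(miss)) {
    stop_msltce("no cost entry for disease(s): ", paste(miss, collapse = ", "))
  }
  years <- sort(unique(traj$year))
  by_dis <- matrix(0, length(years), length(diseases),
                   dimnames = list(years, diseases))
  for (d in diseases) {
    per_case <- dc$cost_per_prevalent_case[dc$disease == d]
    v <- traj$person_years * traj[[paste0("prev_", d)]] * per_case
    agg <- tapply(v, traj$year, sum)
    by_dis[names(agg), d] <- agg
  }
  uc <- ps$unrelated_costs
  u <- uc$annual_cost[match(paste(traj$sex, traj$age), paste(uc$sex, uc$age))]
  if (any(is.na(u))) stop_msltce("unrelated cost profile does not cover all ages")
  unrel <- tapply(traj$person_years * u, traj$year, sum)
  out <- data.frame(year = years,
                    modelled_cost = rowSums(by_dis),
                    unrelated_cost = as.numeric(unrel[as.character(years)]))
  attr(out, "by_disease") <- by_dis
  out
}

#' Social care cost stream
#'
#' From the minimum social-care age (75 by default) onwards, each
#' person-year costs twelve months of residential care scaled by the need
#' function `g(age, utility)`, a packaged, replaceable profile increasing in
#' lost quality of life.
#'
#' @param traj One trajectory of an `mslt_run`.
#' @param ps An `mslt_catalogue` (supplies the monthly cost, the minimum
#'   age, and `config$social_care_need`).
#' @return Data frame `year`, `social_cost`.
#' @export
social_care_costs <- function(traj, ps) {
  g <- ps$config$social_care_need
  u <- trajectory_utility(traj, ps)
  eligible <- traj$age >= ps$social_care$min_age
  v <- ifelse(eligible,
              traj$person_years * 12 * ps$social_care$monthly_cost *
                pmin(pmax(g(traj$age, u), 0), 1),
              0)
  agg <- tapply(v, traj$year, sum)
  data.frame(year = as.integer(names(agg)), social_cost = as.numeric(agg))
}

#' Present value of a yearly stream
#'
#' `PV = sum(v_y / (1 + rate)^(y - 1))`: the first model year is
#' undiscounted (configurable through the offset).
#'
#' @param stream Yearly values (year 1 first).
#' @param rate Annual discount rate (e.g. 0.015).
#' @param year_offset Exponent offset; 1 leaves year 1 undiscounted.
#' @return Present value (scalar).
#' @export
discount <- function(stream, rate, year_offset = 1) {
  if (rate < -1) stop_msltce("discount rate below -100%")
  y <- seq_along(stream)
  sum(stream / (1 + rate)^(y - year_offset))
}

#' Cost-effectiveness of an intervention
#'
#' Incremental cost-effectiveness ratio `(C_b - C_a) / (E_b - E_a)` where
#' subscript `b` is the intervention arm (intervention cost plus health and
#' social care expenditure) and `a` the no-intervention arm, both discounted
#' over the same horizon. Dominant (cost-saving and health-gaining) and
#' dominated results are classified instead of reported as a ratio, and a
#' zero QALY difference flags the ICER undefined rather than dividing.
#'
#' @param C_b,C_a Discounted costs (GBP), intervention and comparator arm.
#' @param E_b,E_a Discounted QALYs, intervention and comparator arm.
#' @return An `mslt_econ_result`: list with `delta_cost`, `delta_qalys`,
#'   `icer`, `classification` (one of "icer", "dominant", "dominated",
#'   "undefined").
#' @export
cost_effectiveness <- function(C_b, C_a, E_b, E_a) {
  dC <- C_b - C_a
  dE <- E_b - E_a
  cls <- if (dE == 0) "undefined"
         else if (dC < 0 && dE > 0) "dominant"
         else if (dC > 0 && dE < 0) "dominated"
         else "icer"
  structure(list(delta_cost = dC, delta_qalys = dE,
                 icer = if (cls == "undefined") NA_real_ else dC / dE,
                 classification = cls),
            class = "mslt_econ_result")
}

#' @export
print.mslt_econ_result <- function(x, ...) {
  cat("<mslt_econ_result>\n")
  cat(sprintf("  delta cost : GBP %.0f\n", x$delta_cost))
  cat(sprintf("  delta QALYs: %.2f\n", x$delta_qalys))
  cat("  result     :",
      switch(x$classification,
             icer = sprintf("ICER GBP %.0f per QALY", x$icer),
             dominant = "dominant (cost-saving, health-gaining)",
             dominated = "dominated (costlier, health-losing)",
             undefined = "ICER undefined (no QALY difference)"), "\n")
  invisible(x)
}

#' Return on investment of a cost-saving intervention
#'
#' For interventions whose discounted cost difference `C_b - C_a` is
#' negative, the money saved for every GBP 1 of intervention spend:
#' `|C_b - C_a| / C_i` (the raw signed ratio is kept alongside). For
#' non-cost-saving interventions the ROI is withheld with a reason.
#'
#' @param C_b,C_a Discounted costs, intervention and comparator arm.
#' @param C_i Discounted intervention cost (> 0).
#' @return List `roi` (GBP saved per GBP 1, or NA), `signed` (raw
#'   `(C_b - C_a) / C_i`), `reason` (NULL, or why ROI is withheld).
#' @export
return_on_investment <- function(C_b, C_a, C_i) {
  if (C_i <= 0) stop_msltce("intervention cost must be positive")
  dC <- C_b - C_a
  if (dC >= 0) {
    return(list(roi = NA_real_, signed = dC / C_i, reason = "not cost-saving"))
  }
  list(roi = abs(dC) / C_i, signed = dC / C_i, reason = NULL)
}
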