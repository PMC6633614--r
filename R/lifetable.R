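# Proportional multistate life table: per-disease illness-death processes
# whose disease mortality feeds back into all-cause cohort survival.

# Exact one-year transition of the (healthy, diseased, dead-of-disease)
# chain with constant rates i (incidence) and f (case fatality): the closed
# form of the matrix exponential of the triangular generator.
illness_death_step <- function(S, C, i, f, t = 1) {
  S1 <- S * exp(-i * t)
  g <- ifelse(abs(f - i) > 1e-12,
              (exp(-i * t) - exp(-f * t)) / (f - i),
              t * exp(-i * t))
  C1 <- C * exp(-f * t) + S * i * g
  list(S = S1, C = C1, deaths = (S + C) - (S1 + C1), incident = S - S1)
}

#' One-year transition of a disease illness-death process
#'
#' Advances the proportions (healthy, diseased, dead-of-disease) by one year
#' under constant incidence and case fatality rates, using the exact matrix
#' exponential (closed form) of the constant-rate generator. Remission is
#' zero throughout the model.
#'
#' @param state Numeric vector `c(healthy, diseased, dead)` of proportions.
#' @param incidence Incidence rate per person-year.
#' @param case_fatality Case fatality rate per person-year (annual mortality
#'   rate among prevalent cases).
#' @param trend_multiplier Multiplier applied to both rates (annual trend
#'   compounded outside this function).
#' @return List: `state` (new proportions), `disease_deaths`, `incident`
#'   (proportion newly diseased during the year).
#' @export
step_disease <- function(state, incidence, case_fatality, trend_multiplier = 1) {
  stopifnot(length(state) == 3L)
  if (incidence < 0 || case_fatality < 0 || trend_multiplier < 0) {
    stop_msltce("rates must be >= 0")
  }
  r <- illness_death_step(state[1L], state[2L],
                          incidence * trend_multiplier,
                          case_fatality * trend_multiplier)
  new <- c(r$S, r$C, state[3L] + r$deaths)
  if (any(new < -1e-12) || any(new > 1 + 1e-12)) {
    stop_msltce("disease state proportions left [0, 1]")
  }
  list(state = new, disease_deaths = r$deaths, incident = r$incident)
}

#' Derive case fatality from disease mortality and prevalence
#'
#' Case fatality (the annual mortality rate among prevalent cases) is the
#' ratio of the disease-specific mortality rate to prevalence, optionally
#' smoothed by a monotone spline. The residual of the illness-death
#' recursion `P(a+1) = P(a) + i(a)(1 - P) - f(a) P` is attached so input
#' inconsistency is visible rather than silent.
#'
#' @param incidence,prevalence,disease_mortality Numeric vectors by age.
#' @param ages Ages (default `seq_along`).
#' @param smooth Apply a monotone smoothing spline to the raw ratio.
#' @return Numeric vector of case fatality rates with attribute `residual`
#'   (illness-death recursion residual, one shorter than the input).
#' @export
derive_case_fatality <- function(incidence, prevalence, disease_mortality,
                                 ages = seq_along(incidence), smooth = FALSE) {
  if (any(prevalence == 0 & disease_mortality > 0)) {
    stop_msltce("positive disease mortality with zero prevalence")
  }
  f <- ifelse(disease_mortality == 0, 0, disease_mortality / prevalence)
  if (smooth && sum(f > 0) > 4) {
    pos <- f > 0
    sp <- stats::smooth.spline(ages[pos], log(f[pos]))
    f[pos] <- exp(stats::predict(sp, ages[pos])$y)
  }
  n <- length(f)
  res <- prevalence[-1L] -
    (prevalence[-n] + incidence[-n] * (1 - prevalence[-n]) - f[-n] * prevalence[-n])
  attr(f, "residual") <- res
  f
}

#' Apply potential impact fractions to baseline epidemiology
#'
#' Scenario incidence is baseline incidence times `prod(1 - PIF_k)` per
#' disease/age/sex, times the diabetes-CVD multiplier for IHD and stroke.
#' Case fatality is never modified (risk factor changes act on incidence
#' only).
#'
#' @param epi Disease epidemiology data frame (`disease`, `sex`, `age`,
#'   `incidence`, `prevalence`, `case_fatality`, `trend`).
#' @param pifs Data frame `disease`, `sex`, `age`, `pif` (already combined),
#'   or NULL for no change.
#' @param dm_multiplier Incidence multiplier applied to IHD and stroke
#'   (static form of the diabetes coupling; default 1).
#' @return The scenario epidemiology data frame.
#' @export
apply_pifs <- function(epi, pifs = NULL, dm_multiplier = 1) {
  out <- epi
  if (!is.null(pifs) && nrow(pifs)) {
    key_e <- paste(epi$disease, epi$sex, epi$age)
    agg <- stats::aggregate(pif ~ disease + sex + age, data = pifs,
                            FUN = function(p) 1 - prod(1 - p))
    idx <- match(key_e, paste(agg$disease, agg$sex, agg$age))
    mult <- ifelse(is.na(idx), 1, 1 - agg$pif[idx])
    out$incidence <- out$incidence * mult
  }
  cvd <- out$disease %in% c("ihd", "stroke")
  out$incidence[cvd] <- out$incidence[cvd] * dm_multiplier
  out
}

# Rate lookup matrices [age, disease] for one sex.
epi_matrices <- function(epi, sex, ages, diseases) {
  e <- epi[epi$sex == sex, , drop = FALSE]
  mk <- function(col) {
    m <- matrix(0, length(ages), length(diseases),
                dimnames = list(ages, diseases))
    idx <- cbind(match(e$age, ages), match(e$disease, diseases))
    ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
    m[idx[ok, , drop = FALSE]] <- e[[col]][ok]
    m
  }
  list(incidence = mk("incidence"), prevalence = mk("prevalence"),
       case_fatality = mk("case_fatality"),
       trend = {
         m <- mk("trend"); m[m == 0] <- 1; m
       })
}

#' Run the proportional multistate life table
#'
#' Simulates a closed cohort population (each single year of age 15-100, by
#' sex) over `horizon` years, for a baseline arm and a scenario arm that
#' share all machinery. Each disease is an independent illness-death process
#' except for the explicit diabetes coupling: each simulated year, the gap
#' between scenario and baseline diabetes prevalence multiplies IHD and
#' stroke incidence through the published diabetes-CVD relative risks.
#' All-cause mortality each year is baseline other-cause mortality (input
#' all-cause minus the case-fatality-times-prevalence contributions of the
#' modelled diseases) plus the current disease-specific mortality of the
#' disease tables, so scenario survival responds to disease changes.
#'
#' @param epi Baseline epidemiology: data frame `disease`, `sex`, `age`,
#'   `incidence`, `prevalence`, `case_fatality`, `trend` covering every age
#'   a cohort can attain.
#' @param life_table Data frame `sex`, `age`, `population`, `mortality`
#'   (all-cause rate per person-year).
#' @param horizon Number of simulated years (1 to 100; cohorts are dropped
#'   on passing age 100 regardless).
#' @param pifs Optional PIF set (as from [compute_scenario_pifs()]) applied
#'   to scenario incidence by attained age.
#' @param ps Catalogue; needed for the diabetes coupling relative risks.
#' @param dm_coupling Couple diabetes prevalence to IHD/stroke incidence.
#' @return An `mslt_run`: list with `baseline` and `scenario` trajectories
#'   (long data frames: `sex`, `start_age`, `age`, `year`, `alive`,
#'   `person_years`, `mortality_rate`, and per-disease `prev_*` / `inc_*`
#'   columns, person counts scaled by cohort population), plus `horizon`,
#'   `diseases`.
#' @export
run_mslt <- function(epi, life_table, horizon = 10, pifs = NULL, ps = NULL,
                     dm_coupling = TRUE) {
  if (horizon <= 0) stop_msltce("horizon must be positive")
  horizon <- as.integer(horizon)
  diseases <- sort(unique(epi$disease))
  sexes <- intersect(c("male", "female"), unique(life_table$sex))
  dm_on <- dm_coupling && "diabetes" %in% diseases && !is.null(ps) &&
    any(diseases %in% c("ihd", "stroke"))

  arm_names <- if (is.null(pifs)) "baseline" else c("baseline", "scenario")
  run <- list()
  for (sx in sexes) {
    lt <- life_table[life_table$sex == sx, , drop = FALSE]
    lt <- lt[order(lt$age), , drop = FALSE]
    ages <- lt$age
    mats <- epi_matrices(epi, sx, ages, diseases)
    # PIF multiplier by attained age [age, disease]
    pif_mult <- matrix(1, length(ages), length(diseases),
                       dimnames = list(ages, diseases))
    if (!is.null(pifs)) {
      p <- pifs[pifs$sex == sx, , drop = FALSE]
      idx <- cbind(match(p$age, ages), match(p$disease, diseases))
      ok <- !is.na(idx[, 1]) & !is.na(idx[, 2])
      pif_mult[idx[ok, , drop = FALSE]] <- 1 - p$pif[ok]
    }
    # other-cause mortality from baseline identities
    dis_mort0 <- rowSums(mats$case_fatality * mats$prevalence)
    m_other <- pmax(lt$mortality - dis_mort0, 0)

    rr_dm <- c(ihd = NA_real_, stroke = NA_real_)
    if (dm_on) {
      for (d in intersect(c("ihd", "stroke"), diseases)) {
        row <- rr_lookup(ps, "diabetes", d, sx)
        if (nrow(row)) rr_dm[d] <- row$value[1L]
      }
    }

    nC <- length(ages)                       # one cohort per starting age
    base_dm_prev <- matrix(0, nC, horizon)   # baseline diabetes prevalence
    for (arm in arm_names) {
      S <- 1 - mats$prevalence               # [cohort(start age), disease]
      C <- mats$prevalence
      l <- rep(1, nC)
      recs <- vector("list", horizon)
      for (y in seq_len(horizon)) {
        a <- ages + y - 1L                   # attained age per cohort
        act <- which(a <= max(ages) & l > 0)
        if (!length(act)) break
        ai <- match(a[act], ages)
        inc <- mats$incidence[ai, , drop = FALSE] *
          mats$trend[ai, , drop = FALSE]^(y - 1)
        cf <- mats$case_fatality[ai, , drop = FALSE] *
          mats$trend[ai, , drop = FALSE]^(y - 1)
        if (arm == "scenario") {
          inc <- inc * pif_mult[ai, , drop = FALSE]
        }
        alive_frac <- S[act, , drop = FALSE] + C[act, , drop = FALSE]
        prev <- ifelse(alive_frac > 0, C[act, , drop = FALSE] / alive_frac, 0)
        if (arm == "baseline" && "diabetes" %in% diseases) {
          base_dm_prev[act, y] <- prev[, "diabetes"]
        }
        if (arm == "scenario" && dm_on) {
          for (d in intersect(c("ihd", "stroke"), diseases)) {
            if (is.na(rr_dm[d])) next
            mult <- diabetes_cvd_multiplier(prev[, "diabetes"],
                                            base_dm_prev[act, y], rr_dm[d])
            inc[, d] <- inc[, d] * mult
          }
        }
        # disease sub-table step (proportional: independent of other-cause death)
        st <- illness_death_step(S[act, , drop = FALSE],
                                 C[act, , drop = FALSE], inc, cf)
        # cohort mortality: other-cause + disease-specific contributions
        m <- m_other[ai] + rowSums(cf * prev)
        surv <- exp(-m)
        py <- ifelse(m > 0, l[act] * (1 - surv) / m, l[act])
        N <- lt$population
        recs[[y]] <- data.frame(
          sex = sx, start_age = ages[act], age = a[act], year = y,
          alive = l[act] * N[act], person_years = py * N[act],
          mortality_rate = m, stringsAsFactors = FALSE)
        prev_rec <- prev
        inc_rec <- ifelse(alive_frac > 0, st$incident / alive_frac, 0)
        colnames(prev_rec) <- paste0("prev_", diseases)
        colnames(inc_rec) <- paste0("inc_", diseases)
        recs[[y]] <- cbind(recs[[y]], prev_rec, inc_rec)
        S[act, ] <- st$S
        C[act, ] <- st$C
        l[act] <- l[act] * surv
        l[setdiff(seq_len(nC), act)] <- 0
      }
      traj <- do.call(rbind, recs)
      run[[arm]] <- rbind(run[[arm]], traj)
    }
  }
  structure(list(baseline = run$baseline,
                 scenario = run$scenario %||% run$baseline,
                 horizon = horizon, diseases = diseases, sexes = sexes),
            class = "mslt_run")
}

#' @export
print.mslt_run <- function(x, ...) {
  cat("<mslt_run> horizon", x$horizon, "years,",
      length(x$diseases), "diseases,",
      paste(x$sexes, collapse = "+"), "\n")
  py <- c(baseline = sum(x$baseline$person_years),
          scenario = sum(x$scenario$person_years))
  cat("  person-years: baseline", format(py[1], big.mark = ","),
      " scenario", format(py[2], big.mark = ","), "\n")
  invisible(x)
}
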