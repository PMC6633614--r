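# Potential impact fractions: expected relative risk under truncated-normal
# exposure densities, and the scenario-level PIF orchestration.

# Expected RR over a normal density truncated to [0, mean + 4 sd] and
# renormalized, mixed with an optional point mass at zero intake
# (non-consumers). sd = 0 degenerates to a point mass at the mean.
expected_rr <- function(rr_fun, mean, sd, non_consumer = 0, n = 201) {
  consumer <- if (sd <= 0) {
    rr_fun(max(mean, 0))
  } else {
    hi <- mean + 4 * sd
    if (hi <= 0) {
      rr_fun(0)
    } else {
      x <- seq(0, hi, length.out = n)
      w <- stats::dnorm(x, mean, sd)
      dx <- x[2L] - x[1L]
      z <- sum((w[-1L] + w[-n]) / 2) * dx
      f <- rr_fun(x) * w
      (sum((f[-1L] + f[-n]) / 2) * dx) / z
    }
  }
  out <- (1 - non_consumer) * consumer + non_consumer * rr_fun(0)
  if (!is.finite(out)) stop_msltce("non-finite expected relative risk")
  out
}

# One-dimensional PIF between two exposure densities under a common RR curve.
pif_1d <- function(rr_fun, mean_b, sd_b, mean_s, sd_s,
                   non_consumer_b = 0, non_consumer_s = 0, n = 201) {
  eb <- expected_rr(rr_fun, mean_b, sd_b, non_consumer_b, n)
  es <- expected_rr(rr_fun, mean_s, sd_s, non_consumer_s, n)
  (eb - es) / eb
}

# RR curve factory for one (risk factor, disease, sex, age) cell.
rr_curve <- function(ps, risk_factor, disease, sex, age,
                     value_override = NULL) {
  rows <- rr_lookup(ps, risk_factor, disease, sex, age)
  if (!nrow(rows)) return(NULL)
  form <- rows$form[1L]
  if (form == "beta_quarter_power") {
    beta <- value_override %||% rows$value[1L]
    ref <- ps$config$pa_reference_dose
    tmin <- tmin_lookup(ps, risk_factor)
    return(function(x) pa_relative_risk(x, beta, ref_dose = ref, tmin = tmin))
  }
  if (form != "rr_per_unit") return(NULL)
  if (!is.null(value_override)) rows$value <- value_override
  tmin <- tmin_lookup(ps, risk_factor)
  function(x) relative_risk_at(x, rows, tmin)
}

#' Potential impact fraction for one risk factor and disease
#'
#' `PIF = (int RR f_base - int RR f_scenario) / int RR f_base`, where the
#' exposure densities are normals truncated to `[0, mean + 4 SD]` (with an
#' optional non-consumer point mass at zero) and the relative risk curve is
#' referenced and clamped at the theoretical minimum. Integration is by
#' trapezoid on a fixed grid, so results are deterministic and can be checked
#' against a Monte Carlo oracle.
#'
#' @param base,scen [exposure_distribution()] objects for the same factor.
#' @param disease Disease name.
#' @param ps An `mslt_catalogue`.
#' @param sexes Sexes to compute (default both).
#' @return Data frame `sex`, `age`, `pif`; zero rows if the catalogue has no
#'   relative risk linking this factor to the disease.
#' @export
compute_pif <- function(base, scen, disease, ps, sexes = c("male", "female")) {
  stopifnot(inherits(base, "exposure_distribution"),
            inherits(scen, "exposure_distribution"))
  rf <- attr(base, "risk_factor")
  if (!identical(rf, attr(scen, "risk_factor"))) {
    stop_msltce("baseline and scenario describe different risk factors")
  }
  n <- ps$config$pif_grid_points
  out <- list()
  for (sx in sexes) {
    b <- base[base$sex == sx, , drop = FALSE]
    s <- scen[scen$sex == sx, , drop = FALSE]
    if (!nrow(b)) next
    s <- s[match(b$age, s$age), , drop = FALSE]
    pif <- vapply(seq_len(nrow(b)), function(i) {
      fun <- rr_curve(ps, rf, disease, sx, b$age[i])
      if (is.null(fun)) return(NA_real_)
      pif_1d(fun, b$mean[i], b$sd[i], s$mean[i], s$sd[i],
             b$non_consumer[i], s$non_consumer[i], n)
    }, numeric(1))
    keep <- !is.na(pif)
    if (any(keep)) {
      out[[sx]] <- data.frame(sex = sx, age = b$age[keep], pif = pif[keep],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sex = character(), age = integer(), pif = numeric()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Combine potential impact fractions multiplicatively
#'
#' Independent risk factors acting on one disease combine on the survival
#' scale: `1 - prod(1 - PIF_k)`.
#'
#' @param pifs Numeric vector of PIFs.
#' @return Combined PIF.
#' @export
combine_pifs <- function(pifs) 1 - prod(1 - pifs)

#' Scenario potential impact fractions for every disease, age, and sex
#'
#' Orchestrates the full risk model for one intervention: applies the
#' exposure shifts, routes diet factors through the blood pressure,
#' cholesterol, and BMI pathways, strips mediated components from the direct
#' relative risks of BMI, fruit, and vegetables on IHD and stroke (adding
#' them back through the intermediate shift so the total effect is
#' preserved), and uses the diabetes-stripped physical activity betas for
#' IHD/stroke when the dynamic diabetes coupling is active.
#'
#' @param exposures Named list of baseline [exposure_distribution()]s. Must
#'   contain every factor the intervention touches, and the intermediates
#'   (`sbp`, `cholesterol`, `bmi`) whenever a pathway into them is touched.
#' @param iv An [intervention()].
#' @param ps An `mslt_catalogue`.
#' @param diseases Diseases to compute (default: full modelled set).
#' @param dm_coupling Whether diabetes-CVD coupling is active downstream
#'   (controls the physical activity beta de-confounding).
#' @return An `mslt_pif_set`: data frame `disease`, `sex`, `age`, `pif`
#'   (combined over risk factors).
#' @export
compute_scenario_pifs <- function(exposures, iv, ps,
                                  diseases = mslt_diseases(),
                                  dm_coupling = TRUE) {
  stopifnot(inherits(iv, "mslt_intervention"))
  touched <- names(iv$shifts)
  missing <- setdiff(touched, names(exposures))
  if (length(missing)) {
    stop_msltce("no exposure distribution supplied for: ",
                paste(missing, collapse = ", "))
  }
  cfg <- ps$config
  scn <- exposures
  for (rf in touched) scn[[rf]] <- apply_intervention(exposures[[rf]], iv)

  ref_dist <- exposures[[1L]]
  sexes <- unique(ref_dist$sex)
  ages <- sort(unique(ref_dist$age))
  grid <- expand.grid(sex = sexes, age = ages, stringsAsFactors = FALSE)

  # mean shift per touched factor, by sex/age row order of `grid`
  delta_of <- function(rf) {
    b <- exposures[[rf]]; s <- scn[[rf]]
    key <- paste(b$sex, b$age)
    d <- s$mean - b$mean
    d[match(paste(grid$sex, grid$age), key)]
  }

  table3_factors <- c("total_fat", "saturated_fat", "mufa", "pufa",
                      "dietary_cholesterol", "salt", "total_energy")
  direct_factors <- c("fruit", "vegetables", "fibre", "fibre_cereal",
                      "red_meat", "processed_meat")
  mediated_exposures <- c("bmi", "fruit", "vegetables")

  # global (disease-independent) intermediate deltas from the diet pathways
  t3 <- intersect(touched, table3_factors)
  int_delta <- matrix(0, nrow(grid), 3,
                      dimnames = list(NULL, c("sbp", "cholesterol", "bmi")))
  for (rf in t3) {
    d <- delta_of(rf)
    for (i in seq_len(nrow(grid))) {
      if (is.na(d[i]) || d[i] == 0) next
      sh <- intermediate_shift(stats::setNames(list(d[i]), rf), ps,
                               sex = grid$sex[i])
      int_delta[i, ] <- int_delta[i, ] + sh[colnames(int_delta)]
    }
  }
  # direct interventions on the intermediates themselves
  for (int in intersect(touched, mslt_intermediates())) {
    int_delta[, int] <- int_delta[, int] + delta_of(int)
  }

  med_coef <- function(disease, exposure, intermediate) {
    m <- ps$mediation
    row <- m[m$disease == disease & m$exposure == exposure &
               m$intermediate == intermediate, , drop = FALSE]
    if (nrow(row)) row else NULL
  }

  out <- list()
  for (dis in diseases) {
    parts <- list()   # each: data.frame(sex, age, pif)

    # -- direct diet factors -------------------------------------------------
    for (rf in intersect(touched, direct_factors)) {
      if (cfg$apply_mediation && dis %in% c("ihd", "stroke") &&
          rf %in% mediated_exposures) next  # handled with mediation below
      parts[[paste0("direct_", rf)]] <-
        compute_pif(exposures[[rf]], scn[[rf]], dis, ps, sexes)
    }

    # -- physical activity ---------------------------------------------------
    if ("physical_activity" %in% touched) {
      rows <- rr_lookup(ps, "physical_activity", dis, sexes[1L])
      if (nrow(rows)) {
        beta <- rows$value[1L]
        if (dm_coupling && dis %in% c("ihd", "stroke") &&
            "diabetes" %in% diseases) {
          beta <- pa_rr_deconfound(beta, cfg$pa_diabetes_mediated_fraction)
        }
        b <- exposures$physical_activity; s <- scn$physical_activity
        pif <- vapply(seq_len(nrow(b)), function(i) {
          fun <- rr_curve(ps, "physical_activity", dis, b$sex[i], b$age[i],
                          value_override = beta)
          si <- which(s$sex == b$sex[i] & s$age == b$age[i])
          pif_1d(fun, b$mean[i], b$sd[i], s$mean[si], s$sd[si],
                 b$non_consumer[i], s$non_consumer[si], cfg$pif_grid_points)
        }, numeric(1))
        parts$physical_activity <- data.frame(sex = b$sex, age = b$age,
                                              pif = pif, stringsAsFactors = FALSE)
      }
    }

    # -- mediated direct exposures on IHD/stroke ----------------------------
    # disease-specific extra intermediate shift carried by mediation
    med_delta <- int_delta * 0
    if (cfg$apply_mediation && dis %in% c("ihd", "stroke")) {
      for (rf in intersect(touched, mediated_exposures)) {
        if (rf == "bmi") next  # BMI handled via the intermediate pathway below
        d <- delta_of(rf)
        for (int in c("sbp", "cholesterol")) {
          m <- med_coef(dis, rf, int)
          if (!is.null(m)) med_delta[, int] <- med_delta[, int] + d * m$coefficient
        }
        # adjusted direct PIF
        b <- exposures[[rf]]; s <- scn[[rf]]
        pif <- vapply(seq_len(nrow(b)), function(i) {
          rows <- rr_lookup(ps, rf, dis, b$sex[i], b$age[i])
          if (!nrow(rows)) return(NA_real_)
          for (int in c("sbp", "cholesterol")) {
            m <- med_coef(dis, rf, int)
            irow <- rr_lookup(ps, int, dis, b$sex[i], b$age[i])
            if (!is.null(m) && nrow(irow)) {
              rows <- mediation_adjust(rows, m, irow)
            }
          }
          fun0 <- rr_curve(ps, rf, dis, b$sex[i], b$age[i],
                           value_override = rows$value)
          si <- which(s$sex == b$sex[i] & s$age == b$age[i])
          pif_1d(fun0, b$mean[i], b$sd[i], s$mean[si], s$sd[si],
                 b$non_consumer[i], s$non_consumer[si], cfg$pif_grid_points)
        }, numeric(1))
        keep <- !is.na(pif)
        if (any(keep)) {
          parts[[paste0("mediated_", rf)]] <-
            data.frame(sex = b$sex[keep], age = b$age[keep], pif = pif[keep],
                       stringsAsFactors = FALSE)
        }
      }
    }

    # -- intermediate pathways (BMI first: its shift feeds mediated SBP) -----
    for (int in c("bmi", "sbp", "cholesterol")) {
      dtot <- int_delta[, int] + med_delta[, int]
      if (all(abs(dtot) < 1e-15, na.rm = TRUE)) next
      if (is.null(exposures[[int]])) {
        stop_msltce("a pathway shifts '", int, "' but no baseline ",
                    "distribution for it was supplied")
      }
      b <- exposures[[int]]
      pif <- vapply(seq_len(nrow(b)), function(i) {
        gi <- which(grid$sex == b$sex[i] & grid$age == b$age[i])
        d <- dtot[gi]
        if (!is.finite(d) || d == 0) return(NA_real_)
        value_override <- NULL
        rows <- rr_lookup(ps, int, dis, b$sex[i], b$age[i])
        if (!nrow(rows)) return(NA_real_)
        if (int == "bmi" && cfg$apply_mediation && dis %in% c("ihd", "stroke")) {
          m <- med_coef(dis, "bmi", "sbp")
          irow <- rr_lookup(ps, "sbp", dis, b$sex[i], b$age[i])
          if (!is.null(m) && nrow(irow)) {
            rows <- mediation_adjust(rows, m, irow)
          }
          value_override <- rows$value
        }
        fun <- rr_curve(ps, int, dis, b$sex[i], b$age[i],
                        value_override = value_override)
        pif_1d(fun, b$mean[i], b$sd[i], b$mean[i] + d, b$sd[i],
               b$non_consumer[i], b$non_consumer[i], cfg$pif_grid_points)
      }, numeric(1))
      keep <- !is.na(pif)
      if (any(keep)) {
        parts[[paste0("intermediate_", int)]] <-
          data.frame(sex = b$sex[keep], age = b$age[keep], pif = pif[keep],
                     stringsAsFactors = FALSE)
      }
      # BMI shifts carry their own mediated SBP component for IHD/stroke
      if (int == "bmi" && cfg$apply_mediation && dis %in% c("ihd", "stroke")) {
        m <- med_coef(dis, "bmi", "sbp")
        if (!is.null(m)) med_delta[, "sbp"] <- med_delta[, "sbp"] +
            dtot * m$coefficient
      }
    }

    # -- combine -------------------------------------------------------------
    if (!length(parts)) next
    comb <- grid
    comb$pif <- 0
    one_minus <- rep(1, nrow(grid))
    for (p in parts) {
      if (!nrow(p)) next
      idx <- match(paste(grid$sex, grid$age), paste(p$sex, p$age))
      v <- ifelse(is.na(idx), 0, p$pif[idx])
      one_minus <- one_minus * (1 - v)
    }
    comb$pif <- 1 - one_minus
    comb$disease <- dis
    out[[dis]] <- comb[, c("disease", "sex", "age", "pif")]
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else data.frame(disease = character(), sex = character(),
                         age = integer(), pif = numeric())
  class(res) <- c("mslt_pif_set", class(res))
  res
}
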