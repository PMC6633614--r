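# Scenario orchestration: configuration, the end-to-end pipeline, and the
# sensitivity-analysis harness.

#' Default scenario configuration
#'
#' The primary-analysis settings: 10-year horizon, 1.5% annual discount rate
#' on both costs and health outcomes, an NHS-plus-social-care perspective
#' including unrelated-disease costs, and intervention costs counted
#' whoever bears them. The default exemplar intervention is a population
#' salt reduction of 1 g/day at GBP 2 million per year.
#'
#' @return Named list of scenario settings; every entry can be overridden by
#'   the `config` argument of [run_scenario()] (unknown keys are rejected).
#' @export
scenario_defaults <- function() {
  list(
    label = "salt_reduction_1g",
    seed = 1L,
    profile = "full",
    horizon = 10L,
    discount_rate = 0.015,
    discount_rate_costs = NULL,        # NULL = same as discount_rate
    perspective = "nhs_social_care",   # nhs | social_care | nhs_social_care
    include_unrelated = TRUE,
    include_productivity = FALSE,
    include_wider_societal = FALSE,
    diseases = "all",                  # all | no_cancer | directly_related | vector
    dm_coupling = TRUE,
    intervention = list(
      shifts = list(salt = list(type = "absolute", amount = -1)),
      annual_cost = 2e6,
      cost = NULL),                    # explicit per-year stream overrides annual_cost
    productivity_stream = 0,           # user-supplied per-year GBP differences
    wider_societal_stream = 0,
    model_config = list(),             # overrides for default_model_config()
    psa = list(enabled = FALSE, n_runs = 2000)
  )
}

check_config_keys <- function(config, defaults, path = "") {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra)) {
    stop_msltce("unknown configuration key(s): ",
                paste0(path, extra, collapse = ", "))
  }
  for (k in c("intervention", "psa")) {
    if (k %in% names(config) && is.list(config[[k]])) {
      check_config_keys(config[[k]], defaults[[k]], paste0(k, "."))
    }
  }
  invisible(TRUE)
}

resolve_diseases <- function(spec, shifts, profile) {
  if (length(spec) > 1 || !spec[1] %in% c("all", "no_cancer", "directly_related")) {
    return(spec)
  }
  full <- if (profile == "small") c("ihd", "stroke") else mslt_diseases()
  switch(spec[1],
    all = full,
    no_cancer = intersect(full, c("ihd", "stroke", "diabetes", "liver_cirrhosis")),
    directly_related = {
      diet <- setdiff(names(shifts), "physical_activity")
      dis <- character()
      if (length(diet)) dis <- c(dis, "ihd", "stroke")
      if ("physical_activity" %in% names(shifts)) {
        dis <- c(dis, "ihd", "stroke", "diabetes", "breast_cancer",
                 "colorectal_cancer")
      }
      intersect(full, unique(dis))
    })
}

#' Run a full cost-effectiveness scenario
#'
#' End-to-end pipeline: load the parameter catalogue, generate (or accept)
#' baseline epidemiology and exposure distributions, convert the
#' intervention into potential impact fractions, run baseline and scenario
#' cohorts through the multistate life table, weight person-years by
#' utility, accumulate health, social care, and intervention cost streams,
#' discount, and compute cost-effectiveness and return on investment.
#'
#' @param config Named list of overrides of [scenario_defaults()], or the
#'   path of a YAML file holding them. Unknown keys are rejected by name.
#' @param out_dir Optional directory: writes `summary.json`, `streams.csv`,
#'   and `log.txt` (catalogue digest and seed make the bundle reproducible).
#' @param inputs Optional list with pre-built `epi`, `life_table`,
#'   `exposures` (defaults are generated synthetically from the seed).
#' @return An `mslt_scenario_result`: list with `summary` (label, settings,
#'   discounted outcomes, cost components, ICER/ROI, PSA intervals if run),
#'   `streams` (per-arm, per-year undiscounted cost and QALY streams), and
#'   the `run` object.
#' @export
run_scenario <- function(config = list(), out_dir = NULL, inputs = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- scenario_defaults()
  check_config_keys(config, defaults)
  cfg <- utils::modifyList(defaults, config)
  cfg$discount_rate_costs <- cfg$discount_rate_costs %||% cfg$discount_rate

  ps <- load_catalogue(config = cfg$model_config)
  horizon <- if (identical(cfg$horizon, "lifetime")) 100L else as.integer(cfg$horizon)

  iv_cost <- cfg$intervention$cost %||%
    rep(cfg$intervention$annual_cost, horizon)
  iv_cost <- c(iv_cost, rep(0, max(0, horizon - length(iv_cost))))[1:horizon]
  iv <- intervention(cfg$intervention$shifts, cost = iv_cost, label = cfg$label)

  diseases <- resolve_diseases(cfg$diseases, iv$shifts, cfg$profile)
  if (is.null(inputs)) {
    base <- generate_baseline_epi(cfg$profile, seed = cfg$seed, diseases = diseases)
    exposures <- generate_exposure_survey(seed = cfg$seed)
  } else {
    base <- inputs
    base$epi <- base$epi[base$epi$disease %in% diseases, , drop = FALSE]
    exposures <- inputs$exposures
  }

  evaluate <- function(ps) {
    pifs <- compute_scenario_pifs(exposures, iv, ps, diseases,
                                  dm_coupling = cfg$dm_coupling)
    run <- run_mslt(base$epi, base$life_table, horizon, pifs, ps,
                    dm_coupling = cfg$dm_coupling)
    q <- qaly_stream(run, ps)
    years <- seq_len(horizon)   # cohorts may die out before the horizon
    hmult <- attr(ps, "health_cost_multiplier") %||% 1
    smult <- attr(ps, "societal_cost_multiplier") %||% 1

    stream_of <- function(df, col) {
      v <- numeric(length(years))
      v[df$year] <- df[[col]]
      v
    }
    arm_costs <- function(traj) {
      hc <- health_costs(traj, ps)
      sc <- social_care_costs(traj, ps)
      list(modelled = stream_of(hc, "modelled_cost") * hmult,
           unrelated = stream_of(hc, "unrelated_cost") * hmult,
           social = stream_of(sc, "social_cost") * smult,
           by_disease = attr(hc, "by_disease"))
    }
    cb <- arm_costs(run$baseline)
    cs <- arm_costs(run$scenario)
    pad <- function(x) {
      x <- c(x, rep(0, max(0, length(years) - length(x))))
      x[seq_along(years)]
    }

    rc <- cfg$discount_rate_costs
    off <- ps$config$discount_year_offset
    components <- c(
      modelled = discount(cs$modelled - cb$modelled, rc, off),
      unrelated = if (cfg$include_unrelated)
        discount(cs$unrelated - cb$unrelated, rc, off) else 0,
      social_care = discount(cs$social - cb$social, rc, off),
      intervention = discount(pad(iv$cost), rc, off),
      productivity = discount(pad(cfg$productivity_stream), rc, off) * smult,
      wider_societal = discount(pad(cfg$wider_societal_stream), rc, off) * smult)

    sel <- switch(cfg$perspective,
      nhs = c("modelled", "unrelated", "intervention"),
      social_care = c("social_care", "intervention"),
      nhs_social_care = c("modelled", "unrelated", "social_care", "intervention"),
      stop_msltce("unknown perspective: ", cfg$perspective))
    if (cfg$include_productivity) sel <- c(sel, "productivity")
    if (cfg$include_wider_societal) sel <- c(sel, "wider_societal")

    qb <- stream_of(q[q$scenario == "baseline", ], "qalys")
    qs <- stream_of(q[q$scenario == "scenario", ], "qalys")
    E_a <- discount(qb, cfg$discount_rate, off)
    E_b <- discount(qs, cfg$discount_rate, off)
    dC <- sum(components[sel])
    ce <- cost_effectiveness(dC, 0, E_b, E_a)
    C_i <- components[["intervention"]]
    roi <- if (ce$delta_cost < 0 && C_i > 0)
      return_on_investment(dC, 0, C_i) else
      list(roi = NA_real_, signed = NA_real_,
           reason = if (C_i <= 0) "no intervention cost" else "not cost-saving")

    list(ce = ce, roi = roi, components = components, selected = sel,
         E_b = E_b, E_a = E_a, run = run, q = q, qb = qb, qs = qs,
         cb = cb, cs = cs, pifs = pifs, years = years,
         iv_cost = pad(iv$cost))
  }

  res <- evaluate(ps)

  psa_summary <- NULL
  if (isTRUE(cfg$psa$enabled)) {
    psa_summary <- run_psa(function(draw) {
      r <- evaluate(draw)
      c(delta_cost = r$ce$delta_cost, delta_qalys = r$ce$delta_qalys,
        icer = r$ce$icer)
    }, ps, n_runs = cfg$psa$n_runs, seed = cfg$seed)
  }

  streams <- rbind(
    data.frame(scenario = "baseline", year = res$years,
               qalys = res$qb, modelled_cost = res$cb$modelled,
               unrelated_cost = res$cb$unrelated,
               social_cost = res$cb$social, intervention_cost = 0),
    data.frame(scenario = "scenario", year = res$years,
               qalys = res$qs, modelled_cost = res$cs$modelled,
               unrelated_cost = res$cs$unrelated,
               social_cost = res$cs$social, intervention_cost = res$iv_cost))

  summary <- list(
    label = cfg$label, seed = cfg$seed, profile = cfg$profile,
    horizon = horizon, perspective = cfg$perspective,
    discount_rate = cfg$discount_rate,
    discount_rate_costs = cfg$discount_rate_costs,
    diseases = diseases,
    delta_cost = res$ce$delta_cost,
    delta_qalys = res$ce$delta_qalys,
    icer = res$ce$icer,
    classification = res$ce$classification,
    roi = res$roi$roi, roi_signed = res$roi$signed,
    roi_reason = res$roi$reason,
    cost_components = as.list(res$components),
    perspective_components = res$selected,
    qalys_baseline_discounted = res$E_a,
    qalys_scenario_discounted = res$E_b)
  if (!is.null(psa_summary)) {
    summary$psa <- list(n_runs = cfg$psa$n_runs,
                        intervals = as.data.frame(psa_summary))
  }

  out <- structure(list(summary = summary, streams = streams, run = res$run,
                        pifs = res$pifs, config = cfg),
                   class = "mslt_scenario_result")
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

#' @export
print.mslt_scenario_result <- function(x, ...) {
  s <- x$summary
  cat("<mslt_scenario_result>", s$label, "\n")
  cat(sprintf("  horizon %d y, discount %.1f%%, perspective %s\n",
              s$horizon, 100 * s$discount_rate, s$perspective))
  cat(sprintf("  delta QALYs (disc.): %.1f\n", s$delta_qalys))
  cat(sprintf("  delta cost  (disc.): GBP %.0f\n", s$delta_cost))
  cat("  ", switch(s$classification,
      icer = sprintf("ICER: GBP %.0f per QALY", s$icer),
      dominant = sprintf("dominant; ROI GBP %.2f saved per GBP 1", s$roi),
      dominated = "dominated",
      undefined = "ICER undefined (no QALY difference)"), "\n", sep = "")
  invisible(x)
}

write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.csv(result$streams, file.path(out_dir, "streams.csv"),
                   row.names = FALSE)
  digest <- catalogue_digest()
  log <- c(paste("label:", result$summary$label),
           paste("seed:", result$summary$seed),
           paste("horizon:", result$summary$horizon),
           "catalogue digest:",
           vapply(names(digest), function(f)
             paste0("  ", f, " rows=", digest[[f]]$rows, " md5=", digest[[f]]$md5),
             character(1)))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Run the standard sensitivity-analysis suite
#'
#' Executes the enumerated variants of the primary analysis: time horizons
#' of 1, 5, 20, and 100 years; NHS-only and social-care-only perspectives;
#' adding productivity and all wider societal costs; a 3.5% discount rate;
#' dropping unrelated-disease costs; restricting to the non-cancer disease
#' set (IHD, stroke, diabetes, liver cirrhosis); and restricting to the
#' diseases directly related to the intervention's risk factors.
#'
#' @param config Base scenario configuration (overrides of
#'   [scenario_defaults()]).
#' @param out_dir Optional directory; one bundle sub-directory per variant.
#' @return List with `results` (named list of `mslt_scenario_result`) and
#'   `errors` (named list of failure messages; failing variants do not stop
#'   the others).
#' @export
run_sensitivity_suite <- function(config = list(), out_dir = NULL) {
  variants <- list(
    horizon_1 = list(horizon = 1L),
    horizon_5 = list(horizon = 5L),
    horizon_20 = list(horizon = 20L),
    horizon_100 = list(horizon = 100L),
    nhs_perspective = list(perspective = "nhs"),
    social_care_perspective = list(perspective = "social_care"),
    with_productivity = list(include_productivity = TRUE),
    all_wider_societal = list(include_productivity = TRUE,
                              include_wider_societal = TRUE),
    discount_3_5 = list(discount_rate = 0.035, discount_rate_costs = 0.035),
    no_unrelated_costs = list(include_unrelated = FALSE),
    no_cancer = list(diseases = "no_cancer"),
    directly_related_only = list(diseases = "directly_related"))
  results <- list(); errors <- list()
  for (nm in names(variants)) {
    vcfg <- utils::modifyList(config, variants[[nm]])
    res <- tryCatch(
      run_scenario(vcfg, out_dir = if (is.null(out_dir)) NULL else
        file.path(out_dir, nm)),
      error = function(e) e)
    if (inherits(res, "error")) errors[[nm]] <- conditionMessage(res)
    else results[[nm]] <- res
  }
  list(results = results, errors = errors)
}
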