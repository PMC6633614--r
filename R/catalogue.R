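#' Load the parameter catalogue
#'
#' Reads the delimited-text parameter catalogue (relative risks,
#' intermediate-pathway coefficients, theoretical minimum risk exposures,
#' mediation factors, EQ-5D utilities, disease and social-care costs) into a
#' validated `mslt_catalogue` object. The packaged default catalogue is the
#' transcription of the published parameter tables that drive the model.
#'
#' @param path Directory holding the catalogue CSV files. Defaults to the
#'   catalogue shipped with the package.
#' @param config Model configuration list; see [default_model_config()].
#'   Entries given here override the defaults.
#' @return An object of class `mslt_catalogue`: a list of data frames
#'   (`relative_risks`, `intermediate_effects`, `theoretical_minima`,
#'   `mediation`, `baseline_utilities`, `utility_decrements`, `disease_costs`,
#'   `unrelated_costs`), a `social_care` list (`monthly_cost`, `min_age`),
#'   and the model `config`.
#' @examples
#' ps <- load_catalogue()
#' subset(ps$intermediate_effects, risk_factor == "saturated_fat")
#' @export
load_catalogue <- function(path = NULL, config = list()) {
  path <- path %||% system.file("extdata", "catalogue", package = "msltce")
  if (!nzchar(path) || !dir.exists(path)) {
    stop_msltce("catalogue directory not found: ", path)
  }
  tables <- c(relative_risks = "relative_risks.csv",
              intermediate_effects = "intermediate_effects.csv",
              theoretical_minima = "theoretical_minima.csv",
              mediation = "mediation_factors.csv",
              baseline_utilities = "baseline_utilities.csv",
              utility_decrements = "utility_decrements.csv",
              disease_costs = "disease_costs.csv",
              unrelated_costs = "unrelated_costs_synthetic.csv",
              social_care = "social_care.csv")
  missing <- tables[!file.exists(file.path(path, tables))]
  if (length(missing)) {
    stop_msltce("catalogue is missing required table(s): ",
                paste(missing, collapse = ", "))
  }
  read1 <- function(f) {
    df <- utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
    df
  }
  ps <- lapply(tables, read1)

  # numeric coercion checks: every declared numeric column must parse
  num_cols <- list(
    relative_risks = c("unit_value", "value", "se"),
    intermediate_effects = c("unit_value", "coefficient", "se"),
    theoretical_minima = c("value", "se"),
    mediation = c("coefficient", "se"),
    baseline_utilities = c("age", "male", "female"),
    utility_decrements = c("value", "se"),
    disease_costs = c("programme_budgeting", "specialised_services",
                      "primary_care", "total_printed", "cost_per_prevalent_case"),
    unrelated_costs = c("age", "annual_cost"),
    social_care = "value")
  for (tb in names(num_cols)) {
    for (cl in num_cols[[tb]]) {
      v <- ps[[tb]][[cl]]
      if (is.null(v)) stop_msltce("table '", tb, "' lacks column '", cl, "'")
      vn <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(vn)
      if (any(bad)) {
        stop_msltce("malformed numeric in table '", tb, "', column '", cl,
                    "': ", paste(utils::head(v[bad], 3), collapse = ", "))
      }
      ps[[tb]][[cl]] <- vn
    }
  }

  # vocabulary checks
  bad_dis <- setdiff(unique(c(ps$relative_risks$disease,
                              ps$utility_decrements$disease,
                              ps$disease_costs$disease,
                              ps$mediation$disease)), mslt_diseases())
  if (length(bad_dis)) {
    stop_msltce("unknown disease name(s) in catalogue: ",
                paste(bad_dis, collapse = ", "))
  }
  bad_rf <- setdiff(unique(c(ps$relative_risks$risk_factor,
                             ps$intermediate_effects$risk_factor,
                             ps$theoretical_minima$risk_factor,
                             ps$mediation$exposure)), mslt_risk_factors())
  if (length(bad_rf)) {
    stop_msltce("unknown risk factor name(s) in catalogue: ",
                paste(bad_rf, collapse = ", "))
  }

  sc <- ps$social_care
  out <- ps[setdiff(names(ps), "social_care")]
  out$social_care <- list(
    monthly_cost = sc$value[sc$key == "monthly_cost"],
    min_age = sc$value[sc$key == "min_age"])
  out$config <- utils::modifyList(default_model_config(), config)
  out$path <- path
  class(out) <- "mslt_catalogue"
  out
}

#' Default model configuration
#'
#' Tunable constants of the risk model and economic engine, separate from the
#' transcribed parameter tables. Everything here is a modelling convention
#' rather than an estimated quantity; each can be overridden through the
#' `config` argument of [load_catalogue()] or a scenario config.
#'
#' @return Named list:
#' \describe{
#' \item{salt_na_mmol_per_g}{mmol of urinary sodium per gram of dietary salt
#'   (17.1 = 0.4 g sodium per g salt / 23 g/mol, times 1000).}
#' \item{energy_bmi}{Linear steady-state energy-to-weight coefficient
#'   (kg per kJ/day; default 1/94) and sex-specific reference heights (m) used
#'   to convert a kJ/day change into a BMI change.}
#' \item{pa_reference_dose}{MET h/wk unit dose of the quarter-power physical
#'   activity dose-response (11.25).}
#' \item{pa_diabetes_mediated_fraction}{Share of the physical activity effect
#'   on IHD/stroke that is mediated via diabetes and stripped from the direct
#'   beta when the diabetes-CVD coupling is active (default 0.25).}
#' \item{apply_mediation}{Strip intermediate-mediated components from direct
#'   relative risks of BMI/fruit/vegetables on IHD and stroke (default TRUE).}
#' \item{incident_decrement}{Apply the incident-year utility decrement for
#'   IHD and stroke (default TRUE).}
#' \item{pif_grid_points}{Trapezoid grid size for potential impact fraction
#'   integration (default 201).}
#' \item{rr_band_correlated}{Draw age-banded relative risks of one
#'   exposure-disease pair from a shared z-score in the PSA (default TRUE).}
#' \item{discount_year_offset}{Discount exponent for model year y is
#'   `y - discount_year_offset`; 1 means the first model year is undiscounted.}
#' \item{social_care_need}{Function of (age, utility) in `[0, 1]`: the share of
#'   a person-year at that age and utility spent in residential care. Default
#'   `1 - utility`, the simplest profile increasing in lost quality of life.}
#' }
#' @export
default_model_config <- function() {
  list(
    salt_na_mmol_per_g = 17.1,
    energy_bmi = list(kg_per_kj_day = 1 / 94,
                      ref_height_m = c(male = 1.75, female = 1.62)),
    pa_reference_dose = 11.25,
    pa_diabetes_mediated_fraction = 0.25,
    apply_mediation = TRUE,
    incident_decrement = TRUE,
    pif_grid_points = 201,
    rr_band_correlated = TRUE,
    discount_year_offset = 1,
    social_care_need = function(age, utility) pmin(pmax(1 - utility, 0), 1)
  )
}

#' @export
print.mslt_catalogue <- function(x, ...) {
  cat("<mslt_catalogue>\n")
  cat("  relative risks:      ", nrow(x$relative_risks), "rows\n")
  cat("  intermediate effects:", nrow(x$intermediate_effects), "rows\n")
  cat("  theoretical minima:  ", nrow(x$theoretical_minima), "rows\n")
  cat("  mediation factors:   ", nrow(x$mediation), "rows\n")
  cat("  utilities: baseline ages ", min(x$baseline_utilities$age), "-",
      max(x$baseline_utilities$age), ", ", nrow(x$utility_decrements),
      " disease decrements\n", sep = "")
  cat("  disease costs:       ", nrow(x$disease_costs), "diseases\n")
  cat("  social care: GBP", x$social_care$monthly_cost, "per month from age",
      x$social_care$min_age, "\n")
  invisible(x)
}

#' Save a catalogue back to delimited text
#'
#' Writes every catalogue table as CSV so that `load_catalogue(save dir)`
#' round-trips losslessly.
#'
#' @param ps An `mslt_catalogue`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_catalogue <- function(ps, path) {
  stopifnot(inherits(ps, "mslt_catalogue"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- c(relative_risks = "relative_risks.csv",
             intermediate_effects = "intermediate_effects.csv",
             theoretical_minima = "theoretical_minima.csv",
             mediation = "mediation_factors.csv",
             baseline_utilities = "baseline_utilities.csv",
             utility_decrements = "utility_decrements.csv",
             disease_costs = "disease_costs.csv",
             unrelated_costs = "unrelated_costs_synthetic.csv")
  for (tb in names(files)) {
    utils::write.csv(ps[[tb]], file.path(path, files[[tb]]), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(key = c("monthly_cost", "min_age"),
               value = c(ps$social_care$monthly_cost, ps$social_care$min_age)),
    file.path(path, "social_care.csv"), row.names = FALSE)
  invisible(path)
}

#' Validate a parameter catalogue
#'
#' Checks every catalogue invariant and returns the findings rather than
#' stopping: non-negative standard errors, positive relative risks for the
#' per-unit form, non-overlapping age bands within an exposure-disease-sex
#' combination, baseline utilities inside `[0, 1]` and non-increasing with
#' age, non-positive utility decrements, non-negative cost components, and
#' mediation triples restricted to the published set.
#'
#' @param ps An `mslt_catalogue`.
#' @return A data frame with columns `table`, `finding` (empty when the
#'   catalogue is valid).
#' @export
validate_catalogue <- function(ps) {
  stopifnot(inherits(ps, "mslt_catalogue"))
  found <- list()
  note <- function(table, finding) {
    found[[length(found) + 1L]] <<- data.frame(table = table, finding = finding,
                                               stringsAsFactors = FALSE)
  }

  rr <- ps$relative_risks
  if (any(rr$se < 0, na.rm = TRUE)) note("relative_risks", "negative standard error")
  bad <- rr$form == "rr_per_unit" & rr$value <= 0
  if (any(bad)) {
    note("relative_risks", paste0("non-positive relative risk for ",
         paste(rr$risk_factor[bad], rr$disease[bad], sep = "->", collapse = "; ")))
  }
  # overlapping age bands
  ab <- rr[rr$band_type == "age", , drop = FALSE]
  if (nrow(ab)) {
    for (key in unique(paste(ab$risk_factor, ab$disease, ab$sex))) {
      g <- ab[paste(ab$risk_factor, ab$disease, ab$sex) == key, , drop = FALSE]
      g <- g[order(g$band_low), , drop = FALSE]
      if (nrow(g) > 1 && any(g$band_low[-1] <= g$band_high[-nrow(g)])) {
        note("relative_risks", paste0("overlapping age bands for ", key))
      }
    }
  }

  ie <- ps$intermediate_effects
  if (any(ie$distribution[!is.na(ie$coefficient)] != "normal")) {
    note("intermediate_effects", "distribution must be normal")
  }
  if (any(!nzchar(ie$unit_label))) note("intermediate_effects", "missing units")

  tm <- ps$theoretical_minima
  if (any(tm$value < 0)) note("theoretical_minima", "negative minimum risk exposure")
  if (any(tm$se < 0)) note("theoretical_minima", "negative standard error")

  med <- ps$mediation
  allowed <- c("stroke|bmi|sbp", "stroke|fruit|sbp", "stroke|vegetables|sbp",
               "stroke|fruit|cholesterol", "stroke|vegetables|cholesterol",
               "ihd|bmi|sbp", "ihd|fruit|sbp", "ihd|vegetables|sbp",
               "ihd|fruit|cholesterol", "ihd|vegetables|cholesterol")
  extra <- setdiff(paste(med$disease, med$exposure, med$intermediate, sep = "|"),
                   allowed)
  if (length(extra)) {
    note("mediation", paste0("mediation triple not in the published set: ",
                             paste(extra, collapse = "; ")))
  }

  bu <- ps$baseline_utilities
  for (sx in c("male", "female")) {
    u <- bu[[sx]][order(bu$age)]
    if (any(u < 0 | u > 1)) note("baseline_utilities", "baseline utility out of [0,1]")
    if (any(diff(u) > 1e-12)) {
      note("baseline_utilities", paste0("baseline utility increasing with age (",
                                        sx, ")"))
    }
  }

  ud <- ps$utility_decrements
  if (any(ud$value > 0)) note("utility_decrements", "positive utility decrement")
  if (any(ud$se < 0)) note("utility_decrements", "negative standard error")

  dc <- ps$disease_costs
  comp <- c("programme_budgeting", "specialised_services", "primary_care",
            "cost_per_prevalent_case")
  for (cl in comp) {
    if (any(dc[[cl]] < 0, na.rm = TRUE)) {
      note("disease_costs", paste0("negative cost component: ", cl))
    }
  }
  if (any(ps$unrelated_costs$annual_cost < 0)) {
    note("unrelated_costs", "negative unrelated annual cost")
  }
  if (ps$social_care$monthly_cost < 0) note("social_care", "negative monthly cost")

  if (length(found)) do.call(rbind, found) else
    data.frame(table = character(), finding = character(), stringsAsFactors = FALSE)
}

#' Catalogue digest
#'
#' Row counts and MD5 checksums of the catalogue files, used for the
#' transcription audit and to stamp result bundles.
#'
#' @param path Catalogue directory (default: packaged catalogue).
#' @return Named list per file: `rows`, `md5`.
#' @export
catalogue_digest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "catalogue", package = "msltce")
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  out <- lapply(files, function(f) {
    list(rows = nrow(utils::read.csv(f)), md5 = unname(tools::md5sum(f)))
  })
  names(out) <- basename(files)
  out
}

# Internal lookups ------------------------------------------------------------

# Relative-risk rows for one (risk_factor, disease, sex); age-banded rows are
# reduced to the band containing `age` (step function; ages outside any band
# use the nearest band).
rr_lookup <- function(ps, risk_factor, disease, sex = "male", age = NULL) {
  rr <- ps$relative_risks
  g <- rr[rr$risk_factor == risk_factor & rr$disease == disease &
            (rr$sex == "all" | rr$sex == sex), , drop = FALSE]
  if (!nrow(g)) return(g)
  if (!is.null(age) && any(g$band_type == "age")) {
    ab <- g[g$band_type == "age", , drop = FALSE]
    hit <- which(ab$band_low <= age & age <= ab$band_high)
    if (!length(hit)) {
      hit <- which.min(pmin(abs(age - ab$band_low), abs(age - ab$band_high)))
    }
    g <- rbind(ab[hit[1L], , drop = FALSE], g[g$band_type != "age", , drop = FALSE])
    g <- g[1L, , drop = FALSE]
  }
  g
}

tmin_lookup <- function(ps, risk_factor) {
  tm <- ps$theoretical_minima
  row <- tm[tm$risk_factor == tmin_alias(risk_factor), , drop = FALSE]
  if (!nrow(row)) {
    stop_msltce("no theoretical minimum for risk factor '", risk_factor, "'")
  }
  row$value[1L]
}

decrement_lookup <- function(ps, disease, phase = c("prevalent", "incident")) {
  phase <- match.arg(phase)
  ud <- ps$utility_decrements
  row <- ud[ud$disease == disease & ud$phase == phase, , drop = FALSE]
  if (!nrow(row)) row <- ud[ud$disease == disease & ud$phase == "all", , drop = FALSE]
  if (!nrow(row)) stop_msltce("no utility decrement for disease '", disease, "'")
  row$value[1L]
}
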