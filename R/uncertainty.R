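# Probabilistic sensitivity analysis: parameter sampling and percentile
# summaries over repeated model runs.

#' Draws from one uncertain parameter's distribution
#'
#' Lognormal draws are parameterised so the sample median equals the point
#' estimate (`meanlog = log(value)`, `sdlog = se / value`); normal draws
#' have mean equal to the point estimate; gamma draws use shape and rate
#' matched to the stated mean and SD (the generic cost multiplier has mean
#' 1, SD 0.1).
#'
#' @param value Point estimate.
#' @param se Standard error (SD for the gamma multiplier).
#' @param distribution `"lognormal"`, `"normal"`, or `"gamma"`.
#' @param n Number of draws.
#' @param seed Integer seed (a private stream; the caller's RNG state is
#'   untouched).
#' @return Numeric vector of `n` draws.
#' @export
sample_parameter_draws <- function(value, se, distribution, n = 1L, seed = 1L) {
  if (is.na(se)) stop_msltce("parameter has a distribution but no SE")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  switch(distribution,
    lognormal = {
      if (value <= 0) stop_msltce("lognormal point estimate must be positive")
      stats::rlnorm(n, meanlog = log(value), sdlog = se / value)
    },
    normal = stats::rnorm(n, value, se),
    gamma = {
      shape <- (value / se)^2
      stats::rgamma(n, shape = shape, rate = value / se^2)
    },
    stop_msltce("unknown distribution: ", distribution))
}

# Enumerate the uncertain parameters of a catalogue with stable string ids.
param_index <- function(ps) {
  rr <- ps$relative_risks
  ids <- list(
    data.frame(table = "relative_risks", row = seq_len(nrow(rr)),
               id = paste("rr", rr$risk_factor, rr$disease, rr$sex,
                          rr$band_type, rr$band_low, sep = "|"),
               group = paste("rr", rr$risk_factor, rr$disease, rr$sex,
                             sep = "|"),
               value = rr$value, se = rr$se, distribution = rr$distribution,
               stringsAsFactors = FALSE))
  ie <- ps$intermediate_effects
  ok <- !is.na(ie$coefficient)
  ids <- c(ids, list(
    data.frame(table = "intermediate_effects", row = which(ok),
               id = paste("ie", ie$risk_factor[ok], ie$intermediate[ok], sep = "|"),
               group = NA, value = ie$coefficient[ok], se = ie$se[ok],
               distribution = ie$distribution[ok], stringsAsFactors = FALSE)))
  tm <- ps$theoretical_minima
  ids <- c(ids, list(
    data.frame(table = "theoretical_minima", row = seq_len(nrow(tm)),
               id = paste("tmin", tm$risk_factor, sep = "|"), group = NA,
               value = tm$value, se = tm$se, distribution = tm$distribution,
               stringsAsFactors = FALSE)))
  md <- ps$mediation
  ids <- c(ids, list(
    data.frame(table = "mediation", row = seq_len(nrow(md)),
               id = paste("med", md$disease, md$exposure, md$intermediate, sep = "|"),
               group = NA, value = md$coefficient, se = md$se,
               distribution = md$distribution, stringsAsFactors = FALSE)))
  ud <- ps$utility_decrements
  ids <- c(ids, list(
    data.frame(table = "utility_decrements", row = seq_len(nrow(ud)),
               id = paste("udec", ud$disease, ud$phase, sep = "|"), group = NA,
               value = ud$value, se = ud$se, distribution = ud$distribution,
               stringsAsFactors = FALSE)))
  ids <- c(ids, list(
    data.frame(table = "multiplier", row = 1:2,
               id = c("mult|health_costs", "mult|societal_costs"), group = NA,
               value = 1, se = 0.1, distribution = "gamma",
               stringsAsFactors = FALSE)))
  do.call(rbind, ids)
}

#' Sample one probabilistic realisation of the parameter catalogue
#'
#' Every uncertain parameter (relative risks, pathway coefficients,
#' theoretical minima, mediation coefficients, utility decrements, and the
#' generic health/societal cost multipliers) is drawn from its declared
#' distribution. Substream seeds are derived per (seed, parameter id, run
#' index), so the same `(seed, index)` always reproduces the same draw and
#' adding parameters never reshuffles existing ones. Age-banded relative
#' risks of one exposure-disease pair share a z-score by default (fully
#' correlated bands; set `rr_band_correlated = FALSE` in the config for
#' independence).
#'
#' @param ps An `mslt_catalogue`.
#' @param seed Integer PSA seed.
#' @param index Run index (1-based).
#' @return A new `mslt_catalogue` with sampled values; the cost multipliers
#'   are attached as attributes `health_cost_multiplier` and
#'   `societal_cost_multiplier`.
#' @export
sample_parameters <- function(ps, seed = 1L, index = 1L) {
  idx <- param_index(ps)
  draw <- ps
  correlated <- isTRUE(ps$config$rr_band_correlated)
  z_of <- function(id) {
    s <- mix_seed(seed, id, index)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(s)
    stats::rnorm(1)
  }
  vals <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    if (is.na(p$se) || p$se == 0) { vals[k] <- p$value; next }
    stream_id <- if (correlated && !is.na(p$group)) p$group else p$id
    z <- z_of(stream_id)
    vals[k] <- switch(p$distribution,
      lognormal = exp(log(p$value) + z * p$se / p$value),
      normal = p$value + z * p$se,
      gamma = stats::qgamma(stats::pnorm(z), shape = (p$value / p$se)^2,
                            rate = p$value / p$se^2))
  }
  for (tb in unique(idx$table)) {
    sel <- idx$table == tb
    if (tb == "relative_risks") draw$relative_risks$value[idx$row[sel]] <- vals[sel]
    if (tb == "intermediate_effects")
      draw$intermediate_effects$coefficient[idx$row[sel]] <- vals[sel]
    if (tb == "theoretical_minima")
      draw$theoretical_minima$value[idx$row[sel]] <- pmax(vals[sel], 0)
    if (tb == "mediation") draw$mediation$coefficient[idx$row[sel]] <- vals[sel]
    if (tb == "utility_decrements")
      draw$utility_decrements$value[idx$row[sel]] <- pmin(vals[sel], 0)
  }
  mult <- vals[idx$table == "multiplier"]
  attr(draw, "health_cost_multiplier") <- mult[1L]
  attr(draw, "societal_cost_multiplier") <- mult[2L]
  attr(draw, "psa_index") <- index
  draw
}

#' Run a Monte Carlo probabilistic sensitivity analysis
#'
#' Evaluates a model closure once per parameter draw and summarises each
#' output by its empirical 2.5th and 97.5th percentiles (order statistics
#' with linear interpolation), the standard 95% uncertainty interval of the
#' model family. 2000 runs is the default, the point at which the intervals
#' have typically converged.
#'
#' @param model Function taking a sampled `mslt_catalogue` and returning a
#'   named numeric vector of outputs.
#' @param ps The point-estimate `mslt_catalogue`.
#' @param n_runs Number of runs (>= 2; default 2000).
#' @param seed Integer PSA seed.
#' @return An `mslt_psa_summary`: data frame `output`, `point`, `lower`,
#'   `upper` with attributes `runs` (per-run output matrix), `n_failed`.
#' @export
run_psa <- function(model, ps, n_runs = 2000, seed = 1L) {
  if (n_runs < 2) stop_msltce("n_runs must be >= 2")
  point <- model(ps)
  runs <- matrix(NA_real_, n_runs, length(point),
                 dimnames = list(NULL, names(point)))
  failed <- 0L
  for (i in seq_len(n_runs)) {
    out <- tryCatch(model(sample_parameters(ps, seed, i)),
                    error = function(e) NULL)
    if (is.null(out)) failed <- failed + 1L else runs[i, ] <- out[names(point)]
  }
  if (failed) warning(failed, " of ", n_runs, " PSA runs failed and were excluded")
  qs <- apply(runs, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, type = 7)
  res <- data.frame(output = names(point), point = as.numeric(point),
                    lower = qs[1L, ], upper = qs[2L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, runs = runs, n_failed = failed, class = c("mslt_psa_summary",
                                                           class(res)))
}
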