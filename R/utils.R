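#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical disease and risk-factor vocabularies used across the catalogue,
# the life table, and the cost/utility accounting.
mslt_diseases <- function() {
  c("ihd", "stroke", "diabetes", "breast_cancer", "colorectal_cancer",
    "lung_cancer", "stomach_cancer", "liver_cancer", "kidney_cancer",
    "pancreatic_cancer", "liver_cirrhosis")
}

mslt_risk_factors <- function() {
  c("fruit", "vegetables", "fibre", "fibre_cereal", "red_meat",
    "processed_meat", "cholesterol", "sbp", "bmi", "diabetes",
    "physical_activity", "total_fat", "saturated_fat", "mufa", "pufa",
    "dietary_cholesterol", "salt", "total_energy")
}

mslt_intermediates <- function() c("sbp", "cholesterol", "bmi")

# Risk factors whose native scale is an intake that cannot go negative.
intake_factors <- function() {
  c("fruit", "vegetables", "fibre", "fibre_cereal", "red_meat",
    "processed_meat", "physical_activity", "total_fat", "saturated_fat",
    "mufa", "pufa", "dietary_cholesterol", "salt", "total_energy")
}

check_sex <- function(sex) {
  sex <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  sex
}

# Deterministic 31-bit stream seed from an integer seed and string labels.
# Polynomial string hash so per-parameter substreams are stable when
# parameters are added or reordered.
mix_seed <- function(seed, ...) {
  m <- 2147483629
  h <- as.double(seed %% m)
  for (part in as.character(c(...))) {
    for (k in utf8ToInt(part)) h <- (h * 131 + k) %% m
  }
  as.integer(h)
}

# Theoretical-minimum lookups fall back through aliases (cereal fibre shares
# the fibre minimum).
tmin_alias <- function(risk_factor) {
  switch(risk_factor, fibre_cereal = "fibre", risk_factor)
}

stop_msltce <- function(...) stop(..., call. = FALSE)
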