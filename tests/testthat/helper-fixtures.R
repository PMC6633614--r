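# Shared fixtures and independent oracles for the test suite.

the_catalogue <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- load_catalogue()
    ps
  }
})

# Monte Carlo oracle for the potential impact fraction: draws from the same
# truncated normal (plus non-consumer point mass) and averages the RR curve.
mc_pif_oracle <- function(rr_fun, mean_b, sd_b, mean_s, sd_s,
                          nc_b = 0, nc_s = 0, n = 1e5, seed = 1) {
  draw_err <- function(mean, sd, nc) {
    x <- if (sd <= 0) rep(max(mean, 0), n) else {
      hi <- mean + 4 * sd
      u <- stats::runif(n, stats::pnorm(0, mean, sd), stats::pnorm(hi, mean, sd))
      stats::qnorm(u, mean, sd)
    }
    r <- rr_fun(x)
    zero <- stats::runif(n) < nc
    r[zero] <- rr_fun(0)
    r
  }
  set.seed(seed)
  rb <- draw_err(mean_b, sd_b, nc_b)
  rs <- draw_err(mean_s, sd_s, nc_s)
  eb <- mean(rb); es <- mean(rs)
  pif <- (eb - es) / eb
  # delta-method MC standard error of the ratio
  se <- sqrt(stats::var(rs) / n / eb^2 +
             stats::var(rb) / n * (es / eb^2)^2)
  list(pif = pif, se = se)
}

# Fine-substep Euler oracle for the one-year illness-death transition
# (vectorised over cases; first-order, so the substep count is chosen to
# push the truncation error well below the comparison tolerance).
euler_step_oracle <- function(S, C, i, f, substeps = 4e5) {
  h <- 1 / substeps
  for (k in seq_len(substeps)) {
    dS <- -i * S
    dC <- i * S - f * C
    S <- S + h * dS
    C <- C + h * dC
  }
  list(S = S, C = C)
}

# A single-cohort, single-disease epidemiology fixture with constant rates,
# for closed-form life table checks.
toy_inputs <- function(inc = 0, cf = 0, mort = 0.05, prev0 = 0,
                       start_age = 15, ages = 15:100) {
  epi <- expand.grid(sex = c("male", "female"), age = ages,
                     stringsAsFactors = FALSE)
  epi$disease <- "ihd"
  epi$incidence <- inc
  epi$prevalence <- prev0
  epi$case_fatality <- cf
  epi$trend <- 1
  lt <- expand.grid(sex = c("male", "female"), age = ages,
                    stringsAsFactors = FALSE)
  lt$population <- ifelse(lt$age == start_age, 1000, 0)
  lt$mortality <- mort + cf * prev0
  list(epi = epi, life_table = lt)
}
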