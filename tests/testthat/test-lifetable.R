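test_that("case fatality is disease mortality over prevalence", {
  f <- derive_case_fatality(incidence = rep(0.01, 5),
                            prevalence = rep(0.05, 5),
                            disease_mortality = rep(0.001, 5))
  expect_equal(as.numeric(f), rep(0.02, 5))
  f0 <- derive_case_fatality(rep(0.01, 5), rep(0.05, 5), rep(0, 5))
  expect_equal(as.numeric(f0), rep(0, 5))
  expect_error(derive_case_fatality(0.01, 0, 0.001), "zero prevalence")
})

test_that("the illness-death recursion reaches the i/(i+f) steady state", {
  # forward-integrate dP/da = i(1-P) - f P with constant rates
  i <- 0.01; f <- 0.1
  P <- 0
  for (k in 1:2000) P <- P + i * (1 - P) - f * P
  expect_equal(P, i / (i + f), tolerance = 1e-9)
  expect_equal(P, 0.0909, tolerance = 1e-3)
})

test_that("generated prevalence has zero consistency residual", {
  b <- generate_baseline_epi("small", seed = 4)
  for (sx in c("male", "female")) {
    e <- b$epi[b$epi$disease == "ihd" & b$epi$sex == sx, ]
    e <- e[order(e$age), ]
    m <- e$case_fatality * e$prevalence
    f <- derive_case_fatality(e$incidence, pmax(e$prevalence, 1e-300), m,
                              ages = e$age)
    expect_lt(max(abs(attr(f, "residual"))), 1e-9)
  }
})

test_that("one-year disease step matches the fine-substep Euler oracle", {
  # randomized rate grids
  set.seed(42)
  i <- stats::runif(25, 0, 0.3)
  f <- stats::runif(25, 0, 0.5)
  S <- stats::runif(25, 0.3, 1)
  C <- stats::runif(25, 0, 1 - S)
  want <- euler_step_oracle(S, C, i, f)
  for (k in 1:25) {
    got <- step_disease(c(S[k], C[k], 1 - S[k] - C[k]), i[k], f[k])
    expect_lt(abs(got$state[1] - want$S[k]), 1e-6)
    expect_lt(abs(got$state[2] - want$C[k]), 1e-6)
  }
  # equal-rate edge case (closed form switches to its limit branch)
  got <- step_disease(c(1, 0, 0), 0.2, 0.2)
  want <- euler_step_oracle(1, 0, 0.2, 0.2)
  expect_lt(abs(got$state[2] - want$C), 1e-6)
})

test_that("disease step conserves mass and handles null rates", {
  got <- step_disease(c(0.9, 0.1, 0), 0, 0)
  expect_equal(got$state, c(0.9, 0.1, 0))
  got2 <- step_disease(c(0.7, 0.2, 0.1), 0.1, 0.2)
  expect_equal(sum(got2$state), 1, tolerance = 1e-12)
  expect_equal(got2$disease_deaths, got2$state[3] - 0.1, tolerance = 1e-12)
  # trend multiplier scales the rates
  a <- step_disease(c(1, 0, 0), 0.05, 0.1, trend_multiplier = 2)
  b <- step_disease(c(1, 0, 0), 0.1, 0.2)
  expect_equal(a$state, b$state)
  expect_error(step_disease(c(1, 0, 0), -0.1, 0), ">= 0")
})

test_that("PIFs scale incidence multiplicatively; case fatality untouched", {
  b <- generate_baseline_epi("small", seed = 1)
  pifs <- data.frame(disease = "ihd", sex = "male", age = 50,
                     pif = c(0.2, 0.1))
  out <- apply_pifs(b$epi, pifs)
  sel <- b$epi$disease == "ihd" & b$epi$sex == "male" & b$epi$age == 50
  expect_equal(out$incidence[sel], b$epi$incidence[sel] * 0.8 * 0.9)
  expect_equal(out$case_fatality, b$epi$case_fatality)
  other <- !sel
  expect_equal(out$incidence[other], b$epi$incidence[other])
  # null PIFs and unit multiplier change nothing
  expect_equal(apply_pifs(b$epi, NULL, 1), b$epi)
  # diabetes multiplier hits IHD and stroke only
  out2 <- apply_pifs(b$epi, NULL, 0.95)
  cvd <- out2$disease %in% c("ihd", "stroke")
  expect_equal(out2$incidence[cvd], b$epi$incidence[cvd] * 0.95)
})

test_that("toy cohort life years match the closed-form geometric sum", {
  m <- 0.05
  toy <- toy_inputs(inc = 0, cf = 0, mort = m)
  run <- run_mslt(toy$epi, toy$life_table, horizon = 10)
  tr <- run$baseline[run$baseline$sex == "male" & run$baseline$start_age == 15, ]
  tr <- tr[order(tr$year), ]
  expect_identical(nrow(tr), 10L)
  # survivorship l_y = exp(-m (y-1)); person-years l_y (1 - e^-m)/m
  want_py <- 1000 * exp(-m * (0:9)) * (1 - exp(-m)) / m
  expect_equal(tr$person_years, want_py, tolerance = 1e-9)
  expect_equal(sum(tr$person_years),
               1000 * (1 - exp(-m)) / m * (1 - exp(-10 * m)) / (1 - exp(-m)),
               tolerance = 1e-9)
})

test_that("null scenario reproduces the baseline exactly at any horizon", {
  b <- generate_baseline_epi("small", seed = 2)
  pif0 <- data.frame(disease = "ihd", sex = "male", age = 15:100, pif = 0)
  for (h in c(1, 5, 20)) {
    run <- run_mslt(b$epi, b$life_table, horizon = h, pifs = pif0,
                    ps = the_catalogue())
    expect_identical(run$scenario, run$baseline)
  }
})

test_that("run horizon controls the number of simulated years", {
  b <- generate_baseline_epi("small", seed = 1)
  run <- run_mslt(b$epi, b$life_table, horizon = 10)
  expect_identical(sort(unique(run$baseline$year)), 1:10)
  expect_error(run_mslt(b$epi, b$life_table, horizon = 0), "positive")
})

test_that("cohort accounting: survivors decline, proportions stay in [0,1]", {
  b <- generate_baseline_epi("small", seed = 5)
  run <- run_mslt(b$epi, b$life_table, horizon = 40)
  tr <- run$baseline
  for (key in unique(paste(tr$sex, tr$start_age))) {
    g <- tr[paste(tr$sex, tr$start_age) == key, ]
    expect_true(all(diff(g$alive) <= 1e-9))
  }
  pcols <- grep("^prev_", names(tr), value = TRUE)
  for (cl in pcols) expect_true(all(tr[[cl]] >= 0 & tr[[cl]] <= 1))
  # cohorts are dropped past age 100
  expect_lte(max(tr$age), 100)
})

test_that("simulated prevalence tracks the input baseline prevalence", {
  # The inputs are built by the annual Euler recursion while the simulation
  # uses the exact exponential step; both are first-order-consistent
  # discretisations, so baseline prevalence should reproduce the inputs to
  # within the discretisation gap.
  b <- generate_baseline_epi("small", seed = 1)
  run <- run_mslt(b$epi, b$life_table, horizon = 40)
  tr <- run$baseline
  key <- paste(b$epi$sex, b$epi$age, b$epi$disease)
  for (d in c("ihd", "stroke")) {
    inp <- b$epi$prevalence[match(paste(tr$sex, tr$age, d), key)]
    expect_lt(max(abs(tr[[paste0("prev_", d)]] - inp)), 0.01)
  }
})

test_that("beneficial PIFs never reduce life years", {
  ps <- the_catalogue()
  b <- generate_baseline_epi("small", seed = 6)
  pifs <- expand.grid(disease = c("ihd", "stroke"),
                      sex = c("male", "female"), age = 15:100,
                      stringsAsFactors = FALSE)
  pifs$pif <- 0.3
  for (h in c(5, 20, 86)) {
    run <- run_mslt(b$epi, b$life_table, horizon = h, pifs = pifs, ps = ps)
    py <- tapply(run$scenario$person_years, run$scenario$year, sum) -
      tapply(run$baseline$person_years, run$baseline$year, sum)
    expect_true(all(py >= -1e-9))
  }
})

test_that("diabetes coupling lowers IHD incidence when diabetes falls", {
  ps <- the_catalogue()
  b <- generate_baseline_epi("full", seed = 1,
                             diseases = c("ihd", "stroke", "diabetes"))
  pifs <- data.frame(disease = "diabetes", sex = rep(c("male", "female"),
                     each = 86), age = rep(15:100, 2), pif = 0.5)
  run_c <- run_mslt(b$epi, b$life_table, horizon = 30, pifs = pifs, ps = ps,
                    dm_coupling = TRUE)
  run_n <- run_mslt(b$epi, b$life_table, horizon = 30, pifs = pifs, ps = ps,
                    dm_coupling = FALSE)
  # with coupling, scenario IHD prevalence ends lower than without
  end_c <- run_c$scenario[run_c$scenario$year == 30, ]
  end_n <- run_n$scenario[run_n$scenario$year == 30, ]
  expect_lt(sum(end_c$prev_ihd * end_c$person_years),
            sum(end_n$prev_ihd * end_n$person_years))
  # baselines agree (coupling is a no-op when arms coincide)
  expect_equal(run_c$baseline, run_n$baseline)
})

test_that("trend multipliers compound annually on the rates", {
  ages <- 15:100
  epi <- toy_inputs(inc = 0.02, cf = 0.05, mort = 0.01)$epi
  epi$trend <- 0.97
  lt <- toy_inputs()$life_table
  lt$mortality <- 0.01
  run <- run_mslt(epi, lt, horizon = 3)
  tr <- run$baseline[run$baseline$sex == "male" & run$baseline$start_age == 15, ]
  # replicate by stepping the chain by hand with compounding trends
  S <- 1; C <- 0
  for (y in 1:3) {
    got <- tr$prev_ihd[tr$year == y]
    expect_equal(got, C / (S + C), tolerance = 1e-12)
    st <- step_disease(c(S, C, 1 - S - C), 0.02 * 0.97^(y - 1),
                       0.05 * 0.97^(y - 1))
    S <- st$state[1]; C <- st$state[2]
  }
})
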