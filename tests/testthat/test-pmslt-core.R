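test_that("annual disease step matches a fine-grained ODE solution", {
  # independent oracle: lsoda on the continuous three-state system
  ode_step <- function(S0, C0, i, f, r) {
    rhs <- function(t, y, parms) {
      with(as.list(y), list(c(
        S = -i * S + r * C,
        C = i * S - (f + r) * C,
        D = f * C,
        INC = i * S,
        CPY = C
      )))
    }
    y0 <- c(S = S0, C = C0, D = 0, INC = 0, CPY = 0)
    out <- deSolve::lsoda(y0, times = c(0, 1), func = rhs,
                          rtol = 1e-10, atol = 1e-12)
    out[2, -1]
  }
  cases <- list(
    list(S = 1, C = 0, i = 0.01, f = 0.1, r = 0),
    list(S = 0.8, C = 0.15, i = 0.005, f = 0.12, r = 0.15),  # cancer-like
    list(S = 0.6, C = 0.3, i = 0.05, f = 0.4, r = 0.05),
    list(S = 1, C = 0, i = 0.12, f = 0.12, r = 0)            # equal-rate edge
  )
  for (cs in cases) {
    got <- step_disease(cs$S, cs$C, 0, cs$i, cs$f, cs$r)
    want <- ode_step(cs$S, cs$C, cs$i, cs$f, cs$r)
    expect_equal(got$S, unname(want["S"]), tolerance = 1e-7)
    expect_equal(got$C, unname(want["C"]), tolerance = 1e-7)
    expect_equal(got$D, unname(want["D"]), tolerance = 1e-7)
    expect_equal(got$incident, unname(want["INC"]), tolerance = 1e-7)
    expect_equal(got$prevalent_py, unname(want["CPY"]), tolerance = 1e-7)
  }
})

test_that("disease step honours null and full-impact edge cases and conserves mass", {
  st <- step_disease(0.9, 0, 0.1, incidence = 0, case_fatality = 0.2,
                     remission = 0)
  expect_equal(st$S, 0.9)
  expect_equal(st$C, 0)
  expect_equal(st$D, 0.1)

  full <- step_disease(1, 0.2, 0, incidence = 0.05, case_fatality = 0.1,
                       remission = 0, pif = 1)
  expect_equal(full$incident, 0)

  set.seed(31)
  for (k in 1:50) {
    S <- runif(1); C <- runif(1, 0, 1 - S); D <- 1 - S - C
    st <- step_disease(S, C, D, incidence = runif(1, 0, 0.3),
                       case_fatality = runif(1, 0, 0.5),
                       remission = runif(1, 0, 0.3),
                       pif = runif(1, -0.5, 1))
    expect_lt(abs(st$S + st$C + st$D - 1), 1e-9)
    expect_true(st$S >= 0 && st$C >= 0 && st$D >= D - 1e-12)
  }
  expect_error(step_disease(1, 0, 0, incidence = -0.1, case_fatality = 0),
               "rates")
})

test_that("full disease tables close their accounting at every horizon", {
  b <- test_bundle()
  traj <- bmi_effect_trajectory(-0.4, effect_spec(), horizon = 93)
  pifs <- build_pif_series(b, uptake_cascade(), traj)
  zero <- run_disease_lifetable(b, pifs * 0, list(sex = "female",
                                                  ethnicity = "maori",
                                                  age = 40),
                                "coronary_heart_disease")
  expect_equal(zero$bau_prevalent_py, zero$int_prevalent_py)
  expect_equal(zero$bau_disease_deaths, zero$int_disease_deaths)

  chd <- run_disease_lifetable(b, pifs, list(sex = "male",
                                             ethnicity = "non_maori",
                                             age = 45),
                               "coronary_heart_disease")
  # prevalence falls while the PIF bites (a small late-life catch-up is
  # expected once the spared susceptibles age into high-incidence years)
  expect_true(all(chd$int_prevalent_py[1:15] <= chd$bau_prevalent_py[1:15]))
  expect_true(any(chd$int_prevalent_py < chd$bau_prevalent_py))
  expect_lt(sum(chd$int_prevalent_py), sum(chd$bau_prevalent_py))
})

test_that("remission lowers long-run prevalence relative to a no-remission disease", {
  S <- 1; C <- 0; D <- 0
  S2 <- 1; C2 <- 0; D2 <- 0
  prev_rem <- prev_no <- 0
  for (t in 1:40) {
    st <- step_disease(S, C, D, 0.01, 0.05, remission = 0.15)
    S <- st$S; C <- st$C; D <- st$D; prev_rem <- st$prevalent_py
    st2 <- step_disease(S2, C2, D2, 0.01, 0.05, remission = 0)
    S2 <- st2$S; C2 <- st2$C; D2 <- st2$D; prev_no <- st2$prevalent_py
  }
  expect_lt(prev_rem, prev_no)
})

test_that("main life table follows closed-form survival with half-cycle correction", {
  lt0 <- run_main_lifetable(rep(0, 5), 0)
  expect_equal(lt0$survivors_end, rep(1, 5))
  expect_equal(sum(lt0$life_years), 5)
  expect_equal(lt0$qalys, lt0$life_years)

  lt <- run_main_lifetable(rep(0.1, 3), 0.2)
  expect_equal(lt$survivors_end, exp(-c(0.1, 0.2, 0.3)))
  expect_equal(lt$life_years,
               c((1 + exp(-0.1)) / 2, (exp(-0.1) + exp(-0.2)) / 2,
                 (exp(-0.2) + exp(-0.3)) / 2))
  expect_equal(lt$qalys, lt$life_years * 0.8)
  expect_true(all(diff(lt$survivors_end) <= 0))
})

test_that("discounting follows 1/(1+r)^t with year 0 undiscounted", {
  expect_equal(discount_series(c(1, 2, 3), 0), 6)
  expect_equal(discount_series(c(0, 103), 0.03), 100)
  v <- c(5, 4, 3, 2, 1)
  expect_true(discount_series(v, 0.06) < discount_series(v, 0.03))
  expect_true(discount_series(v, 0.03) < discount_series(v, 0))
  expect_error(discount_series(v, -0.01), "rate")
})

test_that("a null intervention yields zero QALY change and net cost equal to the campaign cost", {
  b <- test_bundle()
  r0 <- run_pmslt(b, cascade = uptake_cascade(p_uptake = 0),
                  intervention_cost = 2883000)
  expect_true(all(abs(r0$delta_qalys) < 1e-12))
  expect_true(all(abs(r0$delta_costs) < 1e-12))
  s <- summarize_run(r0)
  expect_equal(s$net_cost_nzd, rep(2883000, 3))
  expect_equal(s$qalys_gained, rep(0, 3))

  r1 <- run_pmslt(b, effect = 0, intervention_cost = 500)
  expect_true(all(abs(r1$delta_qalys) < 1e-12))
  expect_equal(summarize_run(r1, horizons = Inf)$net_cost_nzd, 500)
})

test_that("cost accounting agrees between the summary path and the detail arrays", {
  # single-disease bundle surgery: only first-year CHD costs are nonzero, so
  # the net cost offset must equal the discounted reduction in CHD incidence
  b <- test_bundle()
  b$diseases$cost_first_year <- ifelse(
    b$diseases$disease == "coronary_heart_disease", 1, 0)
  b$diseases$cost_subsequent_year <- 0
  b$diseases$cost_last_6m <- 0
  b$unrelated_cost$cost <- 0
  run <- run_pmslt(b, intervention_cost = 0)

  traj <- bmi_effect_trajectory(weighted_effect_size(effect_spec()),
                                effect_spec(), horizon = 93)
  pifs <- build_pif_series(b, uptake_cascade(), traj)
  manual <- 0
  st <- b$demography[b$demography$sex == "female" &
                       b$demography$ethnicity == "maori", ]
  for (a in c(25, 50)) {
    lt <- run_disease_lifetable(b, pifs, list(sex = "female",
                                              ethnicity = "maori", age = a),
                                "coronary_heart_disease")
    manual <- manual + st$population[st$age == a] *
      discount_series(lt$int_incident - lt$bau_incident, 0.03)
  }
  # same quantity from the run's per-stratum delta-cost matrix
  sel <- run$strata$sex == "female" & run$strata$ethnicity == "maori" &
    run$strata$age %in% c(25, 50)
  dwt <- 1 / 1.03^run$years
  from_run <- sum(run$delta_costs[sel, ] %*% dwt)
  expect_equal(from_run, manual, tolerance = 1e-9)
  expect_lt(from_run, 0)   # fewer incident cases -> cost savings
})
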