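test_that("parameter sampling matches the stated families and moments", {
  # CI -> SD arithmetic for the normal effect size
  d <- param_distributions()
  expect_equal(d$effect$sd, (0.051 - (-0.858)) / 3.92, tolerance = 1e-12)

  # zero dispersion collapses every draw onto the central values
  d0 <- d
  for (nm in c("p_smartphone", "p_recognition", "p_uptake", "effect",
               "regain_rate", "intervention_cost")) d0[[nm]]$sd <- 0
  d0$lag_sd_frac <- 0
  p <- sample_parameters(d0, seed = 1, draw_index = 1)
  expect_equal(p$effect, -0.400)
  expect_equal(p$p_recognition, 0.45)
  expect_equal(p$intervention_cost, 2883000)
  expect_equal(p$lag_windows$lag_min, disease_catalogue()$lag_min)
  expect_equal(p$lag_windows$lag_max, disease_catalogue()$lag_max)

  # beta recognition draws: mean 0.45, SD 20% of it, support [0, 1]
  draws <- vapply(1:10000, function(i) {
    sample_parameters(d, seed = 5, draw_index = i)$p_recognition
  }, numeric(1))
  expect_equal(mean(draws), 0.45, tolerance = 0.003)
  expect_equal(stats::sd(draws), 0.09, tolerance = 0.05)
  expect_true(all(draws > 0 & draws < 1))

  # lognormal and gamma draws stay positive and hit their means
  reg <- vapply(1:5000, function(i) {
    sample_parameters(d, seed = 6, draw_index = i)$regain_rate
  }, numeric(1))
  expect_true(all(reg > 0))
  expect_equal(mean(reg), 0.03, tolerance = 0.01)

  # infeasible beta dispersion is a configuration error
  dbad <- d
  dbad$p_recognition$sd <- 0.6
  expect_error(sample_parameters(dbad, 1, 1), "beta")

  # identical (seed, draw) pairs reproduce the draw in isolation
  expect_identical(sample_parameters(d, seed = 9, draw_index = 42),
                   sample_parameters(d, seed = 9, draw_index = 42))
})

test_that("empirical 95% interval of sampled draws covers the analytic interval", {
  d <- param_distributions()
  eff <- vapply(1:2000, function(i) {
    sample_parameters(d, seed = 3, draw_index = i)$effect
  }, numeric(1))
  qs <- unname(quantile(eff, c(0.025, 0.975)))
  expect_lt(abs(qs[1] - (-0.858)), 0.05)
  expect_lt(abs(qs[2] - 0.051), 0.05)
})

test_that("Monte Carlo at zero dispersion reproduces the expected-value run", {
  b <- test_bundle()
  d0 <- param_distributions()
  for (nm in c("p_smartphone", "p_recognition", "p_uptake", "effect",
               "regain_rate", "intervention_cost")) d0[[nm]]$sd <- 0
  d0$lag_sd_frac <- 0
  mc <- run_monte_carlo(b, n_draws = 1, seed = 1, distributions = d0)
  ev <- run_pmslt(b, effect = -0.400)
  expect_equal(mc$draws$qalys, lifetime_qalys(ev), tolerance = 1e-9)
  expect_equal(mc$draws$net_cost, lifetime_net_cost(ev), tolerance = 1e-9)
  expect_equal(mc$summary$mean[mc$summary$quantity == "qalys"],
               mc$summary$lower95[mc$summary$quantity == "qalys"])

  mc2 <- run_monte_carlo(b, n_draws = 5, seed = 11)
  mc3 <- run_monte_carlo(b, n_draws = 5, seed = 11)
  expect_identical(mc2$draws, mc3$draws)
})

test_that("equity adjustment equalises background survival and leaves non-Maori untouched", {
  b <- test_bundle()
  eq <- equity_adjust(b)
  d <- eq$demography
  for (sx in SEXES) {
    m <- d[d$sex == sx & d$ethnicity == "maori", ]
    nm <- d[d$sex == sx & d$ethnicity == "non_maori", ]
    expect_equal(m$mortality[order(m$age)], nm$mortality[order(nm$age)])
    expect_equal(m$pyld[order(m$age)], nm$pyld[order(nm$age)])
  }
  expect_identical(eq$demography[eq$demography$ethnicity == "non_maori", ],
                   b$demography[b$demography$ethnicity == "non_maori", ])
  expect_identical(eq$bmi, b$bmi)
  expect_identical(eq$disease_rates, b$disease_rates)
  expect_identical(equity_adjust(eq)$demography, eq$demography)

  # Maori per-1000 QALY gains rise once background life expectancy is equal
  base <- base_run()
  eq_run <- memo("equity_run", run_pmslt(eq))
  sel <- base$strata$ethnicity == "maori"
  dwt <- 1 / 1.03^base$years
  pop_m <- sum(base$strata$population[sel])
  per1000 <- function(run) 1000 * sum(run$delta_qalys[sel, ] %*% dwt) / pop_m
  expect_gt(per1000(eq_run), per1000(base))

  # non-Maori results are bitwise unchanged by the adjustment
  nm_sel <- !sel
  expect_identical(eq_run$delta_qalys[nm_sel, ], base$delta_qalys[nm_sel, ])
  expect_identical(eq_run$delta_costs[nm_sel, ], base$delta_costs[nm_sel, ])
})

test_that("scenario suite applies exactly the documented overrides", {
  expect_error(run_scenario(test_bundle(), "s99"), "valid ids")

  base <- scenario_run("base")
  expect_equal(lifetime_qalys(base), lifetime_qalys(base_run()))

  q <- vapply(c("base", "s1_recognition68", "s2_effect_x1.5",
                "s3_full_adherence", "s4a_delay1", "s4b_delay5",
                "s4c_no_regain"),
              function(id) lifetime_qalys(scenario_run(id)), numeric(1))
  expect_true(q[["s1_recognition68"]] > q[["base"]])
  expect_true(q[["s2_effect_x1.5"]] > q[["base"]])
  expect_true(q[["s3_full_adherence"]] > q[["base"]])
  expect_true(q[["s4c_no_regain"]] > q[["s4b_delay5"]])
  expect_true(q[["s4b_delay5"]] > q[["s4a_delay1"]])
  expect_true(q[["s4a_delay1"]] > q[["base"]])

  # discount-rate variants re-price the same per-year deltas
  s6a <- scenario_run("s6a_disc0")
  s6b <- scenario_run("s6b_disc6")
  expect_equal(s6a$discount_rate, 0)
  expect_equal(s6b$discount_rate, 0.06)
  expect_gt(lifetime_qalys(s6a), lifetime_qalys(base))
  expect_lt(lifetime_qalys(s6b), lifetime_qalys(base))

  # the legacy effect size is weaker than the updated pooled estimate
  expect_lt(lifetime_qalys(scenario_run("s5_legacy_effect")),
            lifetime_qalys(base))
})

test_that("percent differences and cost-effectiveness labels follow the reporting rules", {
  expect_equal(percent_difference(276, 183), 51)
  expect_equal(percent_difference(183, 183), 0)
  expect_equal(percent_difference(14727, 183), 7948)
  expect_error(percent_difference(10, 0), "zero")

  expect_equal(classify_cost_effectiveness(-606000, 181), "cost_saving")
  expect_equal(classify_cost_effectiveness(45000 * 10, 10), "cost_effective")
  expect_equal(classify_cost_effectiveness(1e9, 1), "not_cost_effective")
  expect_equal(classify_cost_effectiveness(1000, 0), "dominated")
})

test_that("report tables deliver consistent totals and per-1000 arithmetic", {
  b <- test_bundle()
  run <- base_run()
  rep <- report_tables(run, b)
  all_row <- rep$overall[rep$overall$group == "all", ]
  expect_equal(all_row$qalys, lifetime_qalys(run), tolerance = 1e-9)
  expect_equal(all_row$net_cost_nzd, lifetime_net_cost(run), tolerance = 1e-9)
  expect_equal(all_row$qalys_per_1000,
               1000 * all_row$qalys / sum(b$demography$population))
  expect_equal(all_row$net_cost_usd, all_row$net_cost_nzd * 0.673)

  # subgroup QALYs add back to the total
  expect_equal(sum(rep$subgroups$qalys), all_row$qalys, tolerance = 1e-9)
  # denominators shrink to the target population, so per-1000 gains grow
  tgt <- rep$target_population[rep$target_population$group == "all_target", ]
  expect_gt(tgt$qalys_per_1000, all_row$qalys_per_1000)
  expect_equal(tgt$qalys_per_1000, all_row$qalys_per_1000 / 0.73,
               tolerance = 1e-9)

  # ethnic split: higher per-capita gain for Maori on the synthetic bundle
  m <- rep$overall[rep$overall$group == "maori", ]
  nm <- rep$overall[rep$overall$group == "non_maori", ]
  expect_equal(m$qalys + nm$qalys, all_row$qalys, tolerance = 1e-9)
})
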