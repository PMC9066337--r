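# Probabilistic sensitivity analysis, scenario suite, equity adjustment and
# reporting. The five uncertain intervention parameters follow the stated
# distribution families (beta for the three cascade proportions, normal for
# the effect size via its 95% CI, lognormal for the regain rate, gamma for
# the campaign cost), with SDs as fixed percentages of the central value;
# lag-window endpoints get 20%-SD normal uncertainty rounded to integers.

#' Default uncertainty distributions for the intervention parameters
#'
#' Central values and dispersions: smartphone ownership 81% (beta, SD 5%),
#' campaign recognition 45% (beta, SD 20%), app uptake 14% (beta, SD 20%),
#' BMI effect -0.400 kg/m^2 (normal, SD from the 95% CI -0.858 to 0.051),
#' weight regain 0.03 kg/m^2/month (lognormal, SD 20%), campaign cost
#' NZ$2,883,000 (gamma, SD 20%). Lag-window endpoints carry 20%-SD normal
#' uncertainty, rounded to non-negative integers.
#'
#' @return Named list of distribution specs (`family`, `mean`, `sd`).
#' @export
param_distributions <- function() {
  ci_sd <- (0.051 - (-0.858)) / (2 * 1.96)
  list(
    p_smartphone = list(family = "beta", mean = 0.81, sd = 0.05 * 0.81),
    p_recognition = list(family = "beta", mean = 0.45, sd = 0.20 * 0.45),
    p_uptake = list(family = "beta", mean = 0.14, sd = 0.20 * 0.14),
    effect = list(family = "normal", mean = -0.400, sd = ci_sd),
    regain_rate = list(family = "lognormal", mean = 0.03, sd = 0.20 * 0.03),
    intervention_cost = list(family = "gamma", mean = 2883000,
                             sd = 0.20 * 2883000),
    lag_sd_frac = 0.20
  )
}

.draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) %% 40000 + 1) * 50021 + draw_index) %% 2147483646L
}

.sample_one <- function(d) {
  if (d$sd == 0) return(d$mean)
  switch(d$family,
    beta = {
      v <- d$sd^2
      if (v >= d$mean * (1 - d$mean)) {
        stop("sample_parameters: SD too large for a beta distribution with ",
             "mean ", d$mean, call. = FALSE)
      }
      k <- d$mean * (1 - d$mean) / v - 1
      rbeta(1, d$mean * k, (1 - d$mean) * k)
    },
    normal = rnorm(1, d$mean, d$sd),
    lognormal = {
      sdlog2 <- log(1 + (d$sd / d$mean)^2)
      rlnorm(1, log(d$mean) - sdlog2 / 2, sqrt(sdlog2))
    },
    gamma = rgamma(1, shape = (d$mean / d$sd)^2, rate = d$mean / d$sd^2),
    stop("sample_parameters: unknown family '", d$family, "'", call. = FALSE)
  )
}

#' Sample one Monte Carlo parameter draw
#'
#' Beta, lognormal and gamma draws are moment-matched to the stated mean and
#' SD; the normal effect size uses the SD implied by its 95% CI. Parameters
#' are sampled independently; the draw is fully reproducible from
#' `(seed, draw_index)` via a fixed per-draw substream.
#'
#' @param distributions A [param_distributions()] list.
#' @param seed Master seed.
#' @param draw_index Draw number (1-based).
#' @param lag_windows Central per-disease lag windows (data.frame with
#'   `disease`, `lag_min`, `lag_max`); endpoints are perturbed with
#'   normal(SD = 20% of central) noise, rounded to non-negative integers
#'   with `lag_min <= lag_max` enforced.
#' @return Named list: the sampled parameter values plus `lag_windows`.
#' @export
sample_parameters <- function(distributions = param_distributions(),
                              seed = 1L, draw_index = 1L,
                              lag_windows = disease_catalogue()) {
  set.seed(.draw_seed(seed, draw_index))
  pars <- list()
  for (nm in c("p_smartphone", "p_recognition", "p_uptake", "effect",
               "regain_rate", "intervention_cost")) {
    pars[[nm]] <- .sample_one(distributions[[nm]])
  }
  lf <- distributions$lag_sd_frac %||% 0.20
  lw <- lag_windows[c("disease", "lag_min", "lag_max")]
  if (lf > 0) {
    # one perturbation per distinct window, shared by its diseases
    key <- paste(lw$lag_min, lw$lag_max)
    for (k in unique(key)) {
      sel <- key == k
      mn <- lw$lag_min[sel][1]; mx <- lw$lag_max[sel][1]
      mn2 <- max(0L, as.integer(round(rnorm(1, mn, lf * max(mn, 1)))))
      mx2 <- max(0L, as.integer(round(rnorm(1, mx, lf * max(mx, 1)))))
      if (mn2 > mx2) mn2 <- mx2
      lw$lag_min[sel] <- mn2
      lw$lag_max[sel] <- mx2
    }
  }
  pars$lag_windows <- lw
  pars
}

#' Equity adjustment: equalise background survival and morbidity
#'
#' Replaces the Maori strata's all-cause mortality and pYLD schedules with
#' the same-age, same-sex non-Maori schedules, removing ethnic differences
#' in background life expectancy so that health gains for Maori are not
#' discounted by shorter remaining lifespans. BMI, disease rates and the
#' uptake cascade are left untouched.
#'
#' @param bundle A `pmslt_bundle`.
#' @return The adjusted bundle.
#' @export
equity_adjust <- function(bundle) {
  d <- bundle$demography
  for (sx in SEXES) {
    src <- d[d$sex == sx & d$ethnicity == "non_maori", ]
    sel <- d$sex == sx & d$ethnicity == "maori"
    m <- match(d$age[sel], src$age)
    d$mortality[sel] <- src$mortality[m]
    d$pyld[sel] <- src$pyld[m]
  }
  bundle$demography <- d
  bundle
}

SCENARIO_IDS <- c("base", "s1_recognition68", "s2_effect_x1.5",
                  "s3_full_adherence", "s4a_delay1", "s4b_delay5",
                  "s4c_no_regain", "s5_legacy_effect", "s6a_disc0",
                  "s6b_disc6")

# Scenario overrides on (cascade, effect spec, direct effect, discount).
scenario_settings <- function(scenario_id, mean_height_m = 1.69) {
  if (!scenario_id %in% SCENARIO_IDS) {
    stop("run_scenario: unknown scenario '", scenario_id, "'; valid ids: ",
         paste(SCENARIO_IDS, collapse = ", "), call. = FALSE)
  }
  s <- list(cascade = uptake_cascade(), spec = effect_spec(),
            effect = NULL, discount_rate = 0.03)
  switch(scenario_id,
    base = NULL,
    s1_recognition68 = { s$cascade <- uptake_cascade(p_recognition = 0.68) },
    `s2_effect_x1.5` = { s$effect <- 1.5 * weighted_effect_size(s$spec) },
    s3_full_adherence = { s$spec <- effect_spec(p_short = 0, p_long = 1) },
    s4a_delay1 = { s$spec <- effect_spec(regain_delay = 1) },
    s4b_delay5 = { s$spec <- effect_spec(regain_delay = 5) },
    s4c_no_regain = { s$spec <- effect_spec(no_regain = TRUE) },
    s5_legacy_effect = { s$effect <- -0.430 / mean_height_m^2 },
    s6a_disc0 = { s$discount_rate <- 0 },
    s6b_disc6 = { s$discount_rate <- 0.06 }
  )
  s
}

#' Run one expected-value scenario
#'
#' All parameters at central values, with exactly the scenario's overrides:
#' higher campaign recognition (68%), a 50% larger effect size, all users on
#' the long-duration pooled effect, weight regain delayed by 1 or 5 years or
#' removed, the legacy (weight-unit) effect size converted to BMI units, or
#' 0%/6% discount rates.
#'
#' @param bundle A `pmslt_bundle`.
#' @param scenario_id One of `"base"`, `"s1_recognition68"`,
#'   `"s2_effect_x1.5"`, `"s3_full_adherence"`, `"s4a_delay1"`,
#'   `"s4b_delay5"`, `"s4c_no_regain"`, `"s5_legacy_effect"`, `"s6a_disc0"`,
#'   `"s6b_disc6"`.
#' @param intervention_cost One-off campaign cost (NZ$).
#' @param mean_height_m Mean adult height used to convert the legacy
#'   weight-unit effect (kg) to BMI units (kg/m^2).
#' @return A `pmslt_run`.
#' @export
run_scenario <- function(bundle, scenario_id = "base",
                         intervention_cost = 2883000,
                         mean_height_m = 1.69) {
  s <- scenario_settings(scenario_id, mean_height_m)
  eff <- if (is.null(s$effect)) s$spec else s$effect
  run_pmslt(bundle, cascade = s$cascade, effect = eff,
            intervention_cost = intervention_cost,
            discount_rate = s$discount_rate)
}

# One Monte Carlo draw: intervention arm only (business as usual is shared).
mc_draw <- function(d, p, s, cb, bundle, B, dis_bau, main_bau, dw,
                    discount_rate) {
  casc <- uptake_cascade(p_overweight = s$cascade$p_overweight,
                         p_smartphone = p$p_smartphone,
                         p_recognition = p$p_recognition,
                         p_uptake = p$p_uptake)
  spec <- s$spec
  spec$regain_rate <- p$regain_rate
  traj <- bmi_effect_trajectory(p$effect, spec, horizon = cb$nage,
                                allow_positive = TRUE)
  pifs <- build_pif_series(bundle, casc, traj, lag_windows = p$lag_windows,
                           beta_cache = B)
  dis_int <- simulate_diseases(cb, pifs, detail = FALSE)
  link <- link_mortality_morbidity(dis_bau, dis_int, cb)
  main_int <- main_table_matrix(cb, link$mortality, link$pyld)
  pop <- cb$strata$population
  eth <- cb$strata$ethnicity
  sex <- cb$strata$sex
  dq <- pop * (main_int$qalys - main_bau$qalys)
  costs <- compute_costs(dis_bau, dis_int, main_bau, main_int, cb,
                         p$intervention_cost)
  qrow <- function(sel) sum(dq[sel, , drop = FALSE] %*% dw)
  crow <- function(sel) sum(costs$delta_costs[sel, , drop = FALSE] %*% dw)
  all_sel <- rep(TRUE, nrow(dq))
  data.frame(
    draw = d,
    qalys = qrow(all_sel),
    net_cost = p$intervention_cost + crow(all_sel),
    qalys_maori = qrow(eth == "maori"),
    qalys_non_maori = qrow(eth == "non_maori"),
    qalys_male = qrow(sex == "male"),
    qalys_female = qrow(sex == "female"),
    effect = p$effect, p_recognition = p$p_recognition,
    p_uptake = p$p_uptake, p_smartphone = p$p_smartphone,
    regain_rate = p$regain_rate, intervention_cost = p$intervention_cost
  )
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Samples the intervention parameters independently for each draw, runs the
#' paired simulation (the business-as-usual arm is computed once and
#' shared), and summarises lifetime QALYs gained and net cost with means and
#' 95% uncertainty intervals (2.5th/97.5th empirical percentiles), overall
#' and by sex and ethnicity.
#'
#' @param bundle A `pmslt_bundle`.
#' @param scenario_id Scenario whose central values anchor the draws.
#' @param n_draws Number of draws (2000 in the full analysis).
#' @param seed Master seed; draw `d` is reproducible in isolation.
#' @param discount_rate Annual discount rate.
#' @param distributions A [param_distributions()] list.
#' @return An `uncertainty_result`: `draws` (per-draw data.frame), `summary`
#'   (mean and UI per quantity), `n_draws`, `seed`.
#' @export
run_monte_carlo <- function(bundle, scenario_id = "base", n_draws = 2000,
                            seed = 1L, discount_rate = 0.03,
                            distributions = param_distributions()) {
  s <- scenario_settings(scenario_id)
  cb <- compile_bundle(bundle)
  dis_bau <- simulate_diseases(cb, NULL, detail = FALSE)
  main_bau <- main_table_matrix(cb, cb$m_base, cb$pyld_base)
  dw <- 1 / (1 + discount_rate)^(seq_len(cb$nage) - 1)
  B <- pif_beta_array(bundle)

  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    p <- sample_parameters(distributions, seed, d)
    draws[[d]] <- tryCatch(
      mc_draw(d, p, s, cb, bundle, B, dis_bau, main_bau, dw, discount_rate),
      error = function(e) {
        stop("run_monte_carlo: draw ", d, " failed (",
             conditionMessage(e), "); sampled parameters: ",
             paste(sprintf("%s=%.6g", names(p)[1:6], unlist(p[1:6])),
                   collapse = ", "), call. = FALSE)
      })
  }
  draws <- do.call(rbind, draws)
  qty <- c("qalys", "net_cost", "qalys_maori", "qalys_non_maori",
           "qalys_male", "qalys_female")
  summ <- do.call(rbind, lapply(qty, function(q) {
    x <- draws[[q]]
    data.frame(quantity = q, mean = mean(x),
               lower95 = unname(quantile(x, 0.025)),
               upper95 = unname(quantile(x, 0.975)),
               stringsAsFactors = FALSE)
  }))
  structure(list(draws = draws, summary = summ, n_draws = n_draws,
                 seed = seed, scenario = scenario_id,
                 discount_rate = discount_rate),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat("<uncertainty_result> scenario", x$scenario, "-", x$n_draws,
      "draws, seed", x$seed, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Percent difference of a scenario from the base case
#'
#' @param scenario_value,base_value Scenario and base-case values
#'   (`base_value` must be nonzero).
#' @return `100 * (scenario - base) / base`, rounded to the nearest integer
#'   for reporting.
#' @export
percent_difference <- function(scenario_value, base_value) {
  if (any(base_value == 0)) {
    stop("percent_difference: base value is zero; comparison undefined",
         call. = FALSE)
  }
  round(100 * (scenario_value - base_value) / base_value)
}

#' Classify cost-effectiveness against a willingness-to-pay threshold
#'
#' @param net_cost Net health-system cost (negative = savings).
#' @param qalys QALYs gained.
#' @param threshold Willingness-to-pay per QALY (default NZ$45,000,
#'   approximately New Zealand's GDP per capita).
#' @return `"cost_saving"` (net cost < 0), `"cost_effective"` (cost per QALY
#'   at or below the threshold), `"not_cost_effective"`, or `"dominated"`
#'   (positive cost with no QALY gain).
#' @export
classify_cost_effectiveness <- function(net_cost, qalys, threshold = 45000) {
  if (net_cost < 0) return("cost_saving")
  if (qalys <= 0) return("dominated")
  if (net_cost / qalys <= threshold) "cost_effective" else "not_cost_effective"
}
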