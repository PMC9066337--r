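# Reporting layer: totals and per-1000 health gains and net costs by
# subgroup (sex x ethnicity x age band) and horizon. Age bands are a
# reporting aggregation over the model's single-year cohorts.

.age_band <- function(age) {
  cut(age, breaks = c(-Inf, 24, 44, 64, Inf),
      labels = c("18-24", "25-44", "45-64", "65+"))
}

#' Report tables for a paired run
#'
#' Builds the study's reporting surfaces: lifetime (or fixed-horizon)
#' QALYs gained and net costs, total and per 1000 population, overall, by
#' ethnicity, by sex, and by sex x ethnicity x age band (ages at baseline:
#' 25-44, 45-64, 65+ plus 18-24); and per-1000 gains among the target
#' population (adults with overweight or obesity). Costs are reported in
#' NZ$ and, via the configured conversion factor, US$.
#'
#' @param run A `pmslt_run`.
#' @param bundle The `pmslt_bundle` the run used (population denominators).
#' @param cascade The [uptake_cascade()] used (target-population
#'   denominator = population x `p_overweight`).
#' @param horizon Years (default `Inf` = lifetime).
#' @param discount_rate Discount rate (defaults to the run's).
#' @return List of data.frames: `overall`, `subgroups`, `target_population`.
#' @export
report_tables <- function(run, bundle, cascade = uptake_cascade(),
                          horizon = Inf, discount_rate = run$discount_rate) {
  st <- run$strata
  nt <- if (is.finite(horizon)) min(horizon, length(run$years)) else length(run$years)
  w <- 1 / (1 + discount_rate)^(run$years[seq_len(nt)])
  q_s <- as.vector(run$delta_qalys[, seq_len(nt), drop = FALSE] %*% w)
  c_s <- as.vector(run$delta_costs[, seq_len(nt), drop = FALSE] %*% w)
  usd <- run$meta$nz_to_us %||% 0.673

  agg <- function(sel, label, with_intervention_cost = TRUE) {
    pop <- sum(st$population[sel])
    q <- sum(q_s[sel])
    cc <- sum(c_s[sel])
    if (with_intervention_cost) {
      # campaign cost allocated to subgroups by population share
      cc <- cc + run$intervention_cost * pop / sum(st$population)
    }
    data.frame(group = label, population = pop, qalys = q,
               qalys_per_1000 = 1000 * q / pop,
               net_cost_nzd = cc, net_cost_usd = cc * usd,
               stringsAsFactors = FALSE)
  }

  overall <- rbind(
    agg(rep(TRUE, nrow(st)), "all"),
    agg(st$ethnicity == "non_maori", "non_maori"),
    agg(st$ethnicity == "maori", "maori"),
    agg(st$sex == "male", "male"),
    agg(st$sex == "female", "female")
  )

  bands <- .age_band(st$age)
  sub <- NULL
  for (sx in SEXES) for (eth in ETHNICITIES) for (b in levels(bands)) {
    sel <- st$sex == sx & st$ethnicity == eth & bands == b
    if (!any(sel)) next
    row <- agg(sel, paste(sx, eth, b, sep = "/"))
    row$sex <- sx; row$ethnicity <- eth; row$age_band <- b
    sub <- rbind(sub, row)
  }

  p_ow <- if (inherits(cascade, "uptake_cascade")) cascade$p_overweight else cascade
  tgt <- rbind(
    within(agg(rep(TRUE, nrow(st)), "all_target"), {
      population <- population * p_ow
      qalys_per_1000 <- 1000 * qalys / population
    }),
    within(agg(st$ethnicity == "non_maori", "non_maori_target"), {
      population <- population * p_ow
      qalys_per_1000 <- 1000 * qalys / population
    }),
    within(agg(st$ethnicity == "maori", "maori_target"), {
      population <- population * p_ow
      qalys_per_1000 <- 1000 * qalys / population
    })
  )

  list(overall = overall, subgroups = sub, target_population = tgt)
}
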