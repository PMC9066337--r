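# Synthetic parameter bundle: a complete, internally consistent stand-in for
# the national epidemiological dataset the model is normally parameterised
# with (strata populations, mortality, morbidity, BMI, 14 disease tables,
# costs). Everything is generated from closed-form age curves with seeded
# disease-level jitter, so a seed + config reproduces the bundle exactly.

#' Generator settings for a synthetic parameter bundle
#'
#' Defaults emulate the broad structure of the 2011 New Zealand adult
#' population: a younger Indigenous (Maori) population with higher all-cause
#' mortality, higher mean BMI and higher disease incidence than non-Maori;
#' Gompertz mortality; age-increasing disease incidence; remission for
#' cancers only; and disease costs split into first year of illness,
#' subsequent years, and the last six months of life.
#'
#' @param base_year Calendar year of the baseline cohort (cohort ages are
#'   ages at this year).
#' @param closure_age Age by which everyone is dead; the simulation horizon
#'   for a cohort aged `a` is `closure_age - a` years.
#' @param total_population Total adult population across all strata.
#' @param maori_share Share of the adult population that is Maori.
#' @param maori_mortality_gap Multiplier (> 0) on Maori all-cause mortality
#'   relative to non-Maori of the same age and sex; 1 removes the gap.
#' @param maori_incidence_gap Multiplier on Maori disease incidence.
#' @param maori_bmi_gap Additive gap (kg/m^2, >= 0) on Maori mean BMI.
#' @param maori_pyld_gap Multiplier on Maori prevalent morbidity (pYLD).
#' @param mortality_base All-cause mortality at age 18 (events/person-year,
#'   non-Maori female).
#' @param mortality_slope Gompertz log-slope of mortality per year of age.
#' @param male_mortality_mult Male-vs-female mortality multiplier.
#' @param p_overweight Proportion of adults with BMI >= 25, applied
#'   uniformly across strata unless overridden downstream.
#' @param cost_scale Multiplier applied to every disease and unrelated cost.
#' @param rr_attenuation_age Age at and beyond which relative risks per BMI
#'   unit have fully attenuated to 1.
#' @return A list of generator settings (class `pmslt_config`).
#' @export
bundle_config <- function(base_year = 2011,
                          closure_age = 110,
                          total_population = 4.37e6,
                          maori_share = 0.153,
                          maori_mortality_gap = 1.7,
                          maori_incidence_gap = 1.3,
                          maori_bmi_gap = 1.5,
                          maori_pyld_gap = 1.15,
                          mortality_base = 1.3e-4,
                          mortality_slope = 0.095,
                          male_mortality_mult = 1.35,
                          p_overweight = 0.73,
                          cost_scale = 1,
                          rr_attenuation_age = 95) {
  cfg <- as.list(environment())
  num_pos <- c("total_population", "maori_mortality_gap",
               "maori_incidence_gap", "maori_pyld_gap", "mortality_base",
               "mortality_slope", "male_mortality_mult", "cost_scale")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("bundle_config: field '", f, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (cfg$maori_share < 0 || cfg$maori_share > 1) {
    stop("bundle_config: field 'maori_share' must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$maori_bmi_gap < 0) {
    stop("bundle_config: field 'maori_bmi_gap' must be >= 0", call. = FALSE)
  }
  if (cfg$p_overweight <= 0 || cfg$p_overweight >= 1) {
    stop("bundle_config: field 'p_overweight' must lie in (0, 1)",
         call. = FALSE)
  }
  if (cfg$closure_age <= 18) {
    stop("bundle_config: field 'closure_age' must exceed 18", call. = FALSE)
  }
  class(cfg) <- "pmslt_config"
  cfg
}

# Per-disease base parameters (rates at age 50, non-Maori female).
# inc_g / cf_g are log-slopes per year of age; rr is the relative risk per
# 1 kg/m^2 BMI before age attenuation; costs are NZ$ per case-event.
disease_base_table <- function() {
  d <- disease_catalogue()
  base <- data.frame(
    disease = d$disease,
    inc0  = c(3e-3, 1.5e-3, 6e-3, 5e-3,
              3e-4, 2e-4, 8e-5, 1e-4, 1.2e-4, 1.5e-4, 6e-4, 8e-4, 1.8e-4, 8e-5),
    inc_g = c(0.070, 0.085, 0.050, 0.040,
              0.045, 0.050, 0.050, 0.055, 0.055, 0.020, 0.060, 0.030, 0.045, 0.050),
    cf0   = c(0.040, 0.080, 0.004, 0.0005,
              0.020, 0.060, 0.350, 0.300, 0.450, 0.010, 0.100, 0.040, 0.150, 0.250),
    cf_g  = c(0.040, 0.040, 0.050, 0.030,
              0.010, 0.010, 0.005, 0.005, 0.005, 0.010, 0.010, 0.010, 0.010, 0.005),
    remission = c(0, 0, 0, 0,
                  0.12, 0.10, 0.05, 0.05, 0.03, 0.15, 0.10, 0.12, 0.08, 0.06),
    disability_weight = c(0.08, 0.12, 0.05, 0.10,
                          0.12, 0.12, 0.20, 0.20, 0.25, 0.06, 0.15, 0.10, 0.15, 0.15),
    rr = c(1.08, 1.06, 1.20, 1.04,
           1.12, 1.06, 1.05, 1.05, 1.03, 1.04, 1.04, 1.02, 1.03, 1.08),
    male_inc_mult = c(1.6, 1.2, 1.2, 0.8,
                      0, 1.3, 1.5, 1.5, 1.1, 0.5, 1.1, 0.01, 0, 0.8),
    cost_first_year = c(12000, 15000, 4000, 6000,
                        20000, 25000, 30000, 28000, 30000, 18000, 28000,
                        25000, 26000, 24000),
    cost_subsequent_year = c(2500, 4000, 1800, 1200,
                             5000, 6000, 8000, 8000, 9000, 3000, 6000,
                             5000, 7000, 7000),
    cost_last_6m = c(25000, 22000, 12000, 5000,
                     30000, 32000, 35000, 35000, 38000, 20000, 34000,
                     30000, 33000, 32000),
    stringsAsFactors = FALSE
  )
  merge(d, base, by = "disease", sort = FALSE)
}

#' Generate a synthetic parameter bundle
#'
#' Builds the full input set for the proportional multistate life table:
#' demography (population counts, all-cause mortality, prevalent-morbidity
#' pYLD), BMI distribution summaries, epidemiological rates for the 14
#' BMI-related diseases, relative risks per BMI unit with age attenuation,
#' disease cost schedules and unrelated annual health-system costs.
#' The same `seed` and `config` always reproduce an identical bundle.
#'
#' @param seed Integer seed for the disease-level jitter.
#' @param config A [bundle_config()] object.
#' @return A `pmslt_bundle`: a list with data.frames `demography`, `bmi`,
#'   `disease_rates`, `diseases`, `rr`, `unrelated_cost` and a `meta` list.
#' @export
generate_bundle <- function(seed = 1L, config = bundle_config()) {
  if (!inherits(config, "pmslt_config")) config <- do.call(bundle_config, config)
  set.seed(as.integer(seed) %% 2147483646L)
  ages <- 18:config$closure_age
  nage <- length(ages)

  # Seeded jitter, drawn once per sex / disease so that ethnicity enters only
  # through the configured gap multipliers (gap = 1 removes the gap exactly).
  m0_jit <- exp(rnorm(2, 0, 0.05))           # per sex
  g_jit  <- exp(rnorm(2, 0, 0.02))
  base <- disease_base_table()
  nd <- nrow(base)
  inc_jit  <- exp(rnorm(nd, 0, 0.10))
  cost_jit <- exp(rnorm(nd, 0, 0.10))
  unrel_jit <- exp(rnorm(1, 0, 0.05))

  # --- demography -----------------------------------------------------------
  demo <- expand.grid(sex = SEXES, ethnicity = ETHNICITIES, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  demo <- demo[order(demo$sex, demo$ethnicity, demo$age), ]
  rownames(demo) <- NULL

  # Age pyramid: exponential decline, steeper for the younger Maori
  # population; scaled to the configured totals with a 50/50 sex split.
  kappa <- ifelse(demo$ethnicity == "maori", 0.045, 0.025)
  w <- exp(-kappa * (demo$age - 18))
  tot <- c(maori = config$total_population * config$maori_share,
           non_maori = config$total_population * (1 - config$maori_share))
  demo$population <- 0
  for (eth in ETHNICITIES) {
    for (sx in SEXES) {
      sel <- demo$ethnicity == eth & demo$sex == sx
      demo$population[sel] <- w[sel] / sum(w[sel]) * tot[[eth]] / 2
    }
  }

  sexi <- match(demo$sex, SEXES)
  m0 <- config$mortality_base * m0_jit[sexi] *
    ifelse(demo$sex == "male", config$male_mortality_mult, 1)
  gg <- config$mortality_slope * g_jit[sexi]
  demo$mortality <- m0 * exp(gg * (demo$age - 18)) *
    ifelse(demo$ethnicity == "maori", config$maori_mortality_gap, 1)

  pyld <- 0.03 + 0.12 / (1 + exp(-(demo$age - 70) / 9))
  demo$pyld <- pmin(pyld * ifelse(demo$ethnicity == "maori",
                                  config$maori_pyld_gap, 1), 0.95)

  # --- BMI ------------------------------------------------------------------
  bmi <- demo[c("sex", "ethnicity", "age")]
  mean_bmi <- 25 + 3.2 * (1 - exp(-(bmi$age - 18) / 22)) -
    0.02 * pmax(bmi$age - 75, 0) +
    ifelse(bmi$sex == "female", -0.4, 0) +
    ifelse(bmi$ethnicity == "maori", config$maori_bmi_gap, 0)
  bmi$mean_bmi <- pmin(pmax(mean_bmi, 18), 45)
  bmi$sd_bmi <- 4.2
  bmi$p_overweight <- config$p_overweight

  # --- disease rates per stratum -------------------------------------------
  grid <- expand.grid(disease = base$disease, sex = SEXES,
                      ethnicity = ETHNICITIES, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$disease, grid$sex, grid$ethnicity, grid$age), ]
  rownames(grid) <- NULL
  di <- match(grid$disease, base$disease)
  inc <- base$inc0[di] * inc_jit[di] * exp(base$inc_g[di] * (grid$age - 50)) *
    ifelse(grid$sex == "male", base$male_inc_mult[di], 1) *
    ifelse(grid$ethnicity == "maori", config$maori_incidence_gap, 1)
  grid$incidence <- pmin(inc, 0.15)
  grid$case_fatality <- pmin(base$cf0[di] * exp(base$cf_g[di] * (grid$age - 50)),
                             0.6)
  grid$remission <- base$remission[di]

  diseases <- data.frame(
    disease = base$disease,
    class = base$class,
    disability_weight = base$disability_weight,
    cost_first_year = base$cost_first_year * cost_jit * config$cost_scale,
    cost_subsequent_year = base$cost_subsequent_year * cost_jit * config$cost_scale,
    cost_last_6m = base$cost_last_6m * cost_jit * config$cost_scale,
    lag_min = base$lag_min,
    lag_max = base$lag_max,
    stringsAsFactors = FALSE
  )

  # Relative risks per BMI unit, log-linearly attenuated with age so that
  # RR = 1 at and beyond rr_attenuation_age.
  rr <- expand.grid(disease = base$disease, age = ages,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rr <- rr[order(rr$disease, rr$age), ]
  rownames(rr) <- NULL
  att <- pmin(1, pmax(0, (config$rr_attenuation_age - rr$age) /
                           (config$rr_attenuation_age - 45)))
  rr$rr_per_unit <- exp(log(base$rr[match(rr$disease, base$disease)]) * att)

  unrel <- expand.grid(sex = SEXES, age = ages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  unrel <- unrel[order(unrel$sex, unrel$age), ]
  rownames(unrel) <- NULL
  unrel$cost <- (1500 + 9000 / (1 + exp(-(unrel$age - 82) / 7))) *
    ifelse(unrel$sex == "male", 1.05, 1) * unrel_jit * config$cost_scale

  bundle <- list(
    demography = demo,
    bmi = bmi,
    disease_rates = grid,
    diseases = diseases,
    rr = rr,
    unrelated_cost = unrel,
    meta = list(base_year = config$base_year,
                closure_age = config$closure_age,
                nz_to_us = 0.673,
                seed = as.integer(seed))
  )
  class(bundle) <- "pmslt_bundle"
  bundle
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant the simulation relies on and returns a
#' character vector of human-readable violations (empty when the bundle is
#' valid). Each violation names the offending stratum, disease or field.
#'
#' @param bundle A `pmslt_bundle`.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_bundle <- function(bundle) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  need <- c("demography", "bmi", "disease_rates", "diseases", "rr",
            "unrelated_cost", "meta")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) {
    return(paste0("bundle: missing component '", miss, "'"))
  }
  ages <- 18:bundle$meta$closure_age
  strata <- expand.grid(sex = SEXES, ethnicity = ETHNICITIES, age = ages,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(df) paste(df$sex, df$ethnicity, df$age)
  if (!setequal(key(bundle$demography), key(strata)) ||
      nrow(bundle$demography) != nrow(strata)) {
    add("demography: strata are not exactly sex x ethnicity x age 18..closure")
  }
  if (!setequal(key(bundle$bmi), key(strata)) ||
      nrow(bundle$bmi) != nrow(strata)) {
    add("bmi: strata are not exactly sex x ethnicity x age 18..closure")
  }

  d <- bundle$demography
  lab <- paste0(d$sex, "/", d$ethnicity, "/", d$age)
  bad <- which(!is.finite(d$population) | d$population < 0)
  for (i in bad) add(paste0("demography[", lab[i], "]: population < 0"))
  bad <- which(!is.finite(d$mortality) | d$mortality <= 0)
  for (i in bad) add(paste0("demography[", lab[i], "]: mortality must be > 0"))
  bad <- which(!is.finite(d$pyld) | d$pyld < 0 | d$pyld >= 1)
  for (i in bad) add(paste0("demography[", lab[i], "]: pyld outside [0, 1)"))
  # mortality non-decreasing beyond age 60 within each sex x ethnicity
  for (sx in SEXES) for (eth in ETHNICITIES) {
    m <- d[d$sex == sx & d$ethnicity == eth & d$age >= 60, ]
    m <- m[order(m$age), ]
    if (nrow(m) > 1 && any(diff(m$mortality) < -1e-12)) {
      add(paste0("demography[", sx, "/", eth,
                 "]: mortality decreasing beyond age 60"))
    }
  }

  b <- bundle$bmi
  lab <- paste0(b$sex, "/", b$ethnicity, "/", b$age)
  bad <- which(b$mean_bmi < 18 | b$mean_bmi > 45)
  for (i in bad) add(paste0("bmi[", lab[i], "]: mean_bmi outside [18, 45]"))
  bad <- which(b$sd_bmi <= 0)
  for (i in bad) add(paste0("bmi[", lab[i], "]: sd_bmi must be > 0"))
  bad <- which(b$p_overweight <= 0 | b$p_overweight >= 1)
  for (i in bad) add(paste0("bmi[", lab[i], "]: p_overweight outside (0, 1)"))

  cat_d <- disease_catalogue()$disease
  if (!setequal(bundle$diseases$disease, cat_d) ||
      nrow(bundle$diseases) != length(cat_d)) {
    add("diseases: must contain each of the 14 diseases exactly once")
  }
  ds <- bundle$diseases
  bad <- which(ds$disability_weight < 0 | ds$disability_weight >= 1)
  for (i in bad) add(paste0("diseases[", ds$disease[i],
                            "]: disability_weight outside [0, 1)"))
  for (f in c("cost_first_year", "cost_subsequent_year", "cost_last_6m")) {
    bad <- which(ds[[f]] < 0)
    for (i in bad) add(paste0("diseases[", ds$disease[i], "]: ", f, " < 0"))
  }

  r <- bundle$disease_rates
  lab <- paste0(r$disease, "/", r$sex, "/", r$ethnicity, "/", r$age)
  for (f in c("incidence", "case_fatality", "remission")) {
    bad <- which(!is.finite(r[[f]]) | r[[f]] < 0)
    for (i in bad) add(paste0("disease_rates[", lab[i], "]: ", f, " < 0"))
  }
  bad <- which(r$remission > 0 & !(r$disease %in% CANCERS))
  for (i in unique(paste0(r$disease[bad]))) {
    add(paste0("disease_rates[", i, "]: remission > 0 for a non-cancer"))
  }
  dkey <- function(df) paste(df$disease, df$sex, df$ethnicity, df$age)
  full <- expand.grid(disease = cat_d, sex = SEXES, ethnicity = ETHNICITIES,
                      age = ages, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (!setequal(dkey(r), dkey(full)) || nrow(r) != nrow(full)) {
    add("disease_rates: strata x disease grid incomplete")
  }

  rr <- bundle$rr
  bad <- which(rr$rr_per_unit < 1 - 1e-12)
  for (i in bad) add(paste0("rr[", rr$disease[i], "/", rr$age[i],
                            "]: rr_per_unit < 1"))
  bad <- which(bundle$unrelated_cost$cost < 0)
  for (i in bad) add(paste0("unrelated_cost[", bundle$unrelated_cost$sex[i],
                            "/", bundle$unrelated_cost$age[i], "]: cost < 0"))
  v
}

#' @export
print.pmslt_bundle <- function(x, ...) {
  cat("<pmslt_bundle>\n")
  cat("  base year:", x$meta$base_year, " closure age:", x$meta$closure_age, "\n")
  cat("  strata   :", nrow(x$demography), "(sex x ethnicity x age)\n")
  cat("  diseases :", nrow(x$diseases), "\n")
  cat("  population:", format(round(sum(x$demography$population)), big.mark = ","),
      "\n")
  invisible(x)
}
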