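# Intervention pathway: a mass media campaign promotes a weight-loss
# smartphone app. The eligible fraction of the adult population is an
# uptake cascade (overweight/obese x smartphone ownership x campaign
# recognition x download-and-use); eligible users achieve a duration-weighted
# pooled BMI reduction which then erodes through weight regain.

#' Intervention uptake cascade
#'
#' Sequential proportions from the total adult population to app users who
#' experience weight loss. Defaults are the base-case values: 73% with
#' overweight or obesity, 81% smartphone ownership, 45% campaign recognition
#' and 14% downloading and using the app.
#'
#' @param p_overweight,p_smartphone,p_recognition,p_uptake Proportions in
#'   `[0, 1]`.
#' @return An `uptake_cascade` object.
#' @export
uptake_cascade <- function(p_overweight = 0.73, p_smartphone = 0.81,
                           p_recognition = 0.45, p_uptake = 0.14) {
  x <- list(p_overweight = p_overweight, p_smartphone = p_smartphone,
            p_recognition = p_recognition, p_uptake = p_uptake)
  for (f in names(x)) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("uptake_cascade: '", f, "' must be a proportion in [0, 1]",
           call. = FALSE)
    }
  }
  structure(x, class = "uptake_cascade")
}

#' Eligible fraction of the total adult population
#'
#' Multiplies the cascade through: with the base-case values the eligible
#' population narrows from 73% (overweight/obese) to 59.1% (smartphone
#' owners) to 26.6% (campaign recognition) to 3.7% (app users who lose
#' weight). The cumulative products are attached as the `"intermediates"`
#' attribute.
#'
#' @param cascade An [uptake_cascade()].
#' @return The final eligible proportion, with attribute `intermediates`
#'   (named cumulative products after each cascade step).
#' @export
eligible_fraction <- function(cascade) {
  if (!inherits(cascade, "uptake_cascade")) cascade <- do.call(uptake_cascade, cascade)
  p <- unlist(cascade, use.names = FALSE)
  cum <- cumprod(p)
  names(cum) <- c("overweight", "x_smartphone", "x_recognition", "x_uptake")
  structure(cum[[4]], intermediates = cum)
}

#' App effect-size specification
#'
#' The pooled BMI reduction is a duration-weighted average of short
#' (<= 3 months of use) and long (> 3 months) trial effects, weighted by the
#' observed adherence split. Weight regain erodes the achieved reduction at
#' `regain_rate` BMI units per month, starting `regain_delay` years after
#' the intervention year ends; `no_regain` freezes the reduction for life.
#'
#' @param e_short,e_long Pooled effect sizes (kg/m^2) for short/long use.
#' @param p_short,p_long Proportions of users in each duration class;
#'   must sum to 1.
#' @param regain_rate Weight regain (kg/m^2 per month, >= 0).
#' @param regain_delay Years after the intervention year before regain
#'   begins (>= 0).
#' @param no_regain If `TRUE`, the achieved reduction never erodes.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(e_short = -0.219, e_long = -0.609,
                        p_short = 0.53, p_long = 0.47,
                        regain_rate = 0.03, regain_delay = 0,
                        no_regain = FALSE) {
  if (abs(p_short + p_long - 1) > 1e-9) {
    stop("effect_spec: p_short + p_long must equal 1", call. = FALSE)
  }
  if (regain_rate < 0) stop("effect_spec: regain_rate must be >= 0", call. = FALSE)
  if (regain_delay < 0) stop("effect_spec: regain_delay must be >= 0", call. = FALSE)
  structure(list(e_short = e_short, e_long = e_long, p_short = p_short,
                 p_long = p_long, regain_rate = regain_rate,
                 regain_delay = regain_delay, no_regain = isTRUE(no_regain)),
            class = "effect_spec")
}

#' Duration-weighted app effect size
#'
#' `E = e_short * p_short + e_long * p_long`. With the default adherence
#' split (53% short, 47% long) and pooled subgroup effects (-0.219, -0.609)
#' this is -0.402 kg/m^2, the base-case BMI reduction (-0.400 after the
#' source's rounding).
#'
#' @param spec An [effect_spec()].
#' @return BMI change in kg/m^2 (negative = loss).
#' @export
weighted_effect_size <- function(spec) {
  if (!inherits(spec, "effect_spec")) spec <- do.call(effect_spec, spec)
  spec$e_short * spec$p_short + spec$e_long * spec$p_long
}

#' Per-year BMI-change trajectory for eligible users
#'
#' Year 0 is the intervention year, in which the full effect applies.
#' From `regain_delay` years later, regain erodes the reduction linearly at
#' `12 * regain_rate` kg/m^2 per year, clipped at zero:
#' `delta(t) = min(0, effect + 12 * regain_rate * max(0, t - regain_delay))`.
#' With the base-case regain of 0.03 kg/m^2 per month, an effect of -0.36
#' is fully eroded at t = 1.
#'
#' @param effect Achieved BMI change at year 0 (kg/m^2, must be <= 0 unless
#'   `allow_positive`).
#' @param spec An [effect_spec()] supplying the regain dynamics.
#' @param horizon Number of annual cycles (>= 1); the trajectory covers
#'   t = 0 .. horizon - 1.
#' @param allow_positive Permit a positive effect (used when propagating
#'   parameter uncertainty whose support crosses zero); the trajectory then
#'   decays toward zero by odd symmetry.
#' @return Numeric vector `delta` of length `horizon` (class
#'   `bmi_trajectory`).
#' @export
bmi_effect_trajectory <- function(effect, spec = effect_spec(), horizon,
                                  allow_positive = FALSE) {
  if (!inherits(spec, "effect_spec")) spec <- do.call(effect_spec, spec)
  if (!is.numeric(effect) || length(effect) != 1L || !is.finite(effect)) {
    stop("bmi_effect_trajectory: effect must be a finite number", call. = FALSE)
  }
  if (effect > 0 && !allow_positive) {
    stop("bmi_effect_trajectory: effect must be <= 0 (an intervention must ",
         "not increase BMI)", call. = FALSE)
  }
  if (horizon < 1) stop("bmi_effect_trajectory: horizon must be >= 1", call. = FALSE)
  t <- seq_len(horizon) - 1
  if (spec$no_regain) {
    delta <- rep(effect, horizon)
  } else {
    erosion <- 12 * spec$regain_rate * pmax(0, t - spec$regain_delay)
    mag <- pmax(abs(effect) - erosion, 0)
    delta <- sign(effect) * mag
  }
  structure(delta, class = "bmi_trajectory")
}
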