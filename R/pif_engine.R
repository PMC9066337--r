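# Population impact fractions under a mean BMI shift. A proportion
# p_eligible of the population shifts its BMI by delta under a log-linear
# relative-risk function RR(b) = exp(beta * (b - b_ref)); a pure location
# shift then factorises out of the risk integral, giving the closed form
# PIF = p_eligible * (1 - exp(beta * delta)),
# which is exact for any baseline BMI distribution. Lag windows spread the
# incidence response over time (0-5 years for CVD/diabetes/osteoarthritis,
# 10-30 years for cancers) as a uniform average over integer-year lags.

#' Population impact fraction for a mean BMI shift in a sub-population
#'
#' @param p_eligible Proportion of the population experiencing the shift
#'   (`[0, 1]`).
#' @param delta BMI change in kg/m^2 (negative = reduction).
#' @param beta Log relative risk per 1 kg/m^2 BMI (>= 0).
#' @return `p_eligible * (1 - exp(beta * delta))`; positive values are
#'   incidence reductions. Vectorised over all arguments.
#' @export
pif_mean_shift <- function(p_eligible, delta, beta) {
  if (any(p_eligible < 0 | p_eligible > 1)) {
    stop("pif_mean_shift: p_eligible must lie in [0, 1]", call. = FALSE)
  }
  if (any(beta < 0)) stop("pif_mean_shift: beta must be >= 0", call. = FALSE)
  p_eligible * (1 - exp(beta * delta))
}

#' Spread a PIF series over a lag window
#'
#' The lagged PIF at year `t` is the mean of the raw PIF over integer lags
#' `lag_min .. lag_max` years back (raw PIF is zero before year 0). A
#' `[0, 0]` window is the identity; mass is conserved once the horizon
#' contains the full lag tail.
#'
#' @param raw Numeric vector (years `0 .. length(raw) - 1`) or a matrix /
#'   3-d array whose last dimension is year.
#' @param lag_min,lag_max Integer lag window bounds, `0 <= lag_min <= lag_max`.
#' @return Lagged series with the same shape and horizon as `raw`.
#' @export
apply_lag <- function(raw, lag_min, lag_max) {
  lag_min <- as.integer(round(lag_min)); lag_max <- as.integer(round(lag_max))
  if (lag_min < 0 || lag_min > lag_max) {
    stop("apply_lag: need 0 <= lag_min <= lag_max", call. = FALSE)
  }
  lag_one <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (l in lag_min:lag_max) {
      idx <- seq_len(n) - l
      keep <- idx >= 1
      out[keep] <- out[keep] + x[idx[keep]]
    }
    out / (lag_max - lag_min + 1)
  }
  if (is.null(dim(raw))) return(lag_one(raw))
  dm <- dim(raw)
  nt <- dm[length(dm)]
  mat <- matrix(raw, ncol = nt)        # rows: all leading dims, cols: years
  out <- matrix(0, nrow(mat), nt)
  for (l in lag_min:lag_max) {
    src <- seq_len(nt) - l
    keep <- src >= 1
    out[, keep] <- out[, keep] + mat[, src[keep], drop = FALSE]
  }
  out <- out / (lag_max - lag_min + 1)
  array(out, dim = dm, dimnames = dimnames(raw))
}

#' Build the lagged PIF array for a bundle and intervention
#'
#' For each 2011 cohort age, disease and simulation year, computes the raw
#' PIF from the eligible fraction, the BMI-change trajectory and the
#' age-specific log relative risk at the cohort's attained age, then applies
#' the disease-class lag window.
#'
#' @param bundle A `pmslt_bundle`.
#' @param cascade An [uptake_cascade()].
#' @param trajectory A [bmi_effect_trajectory()] covering the full horizon.
#' @param lag_windows Optional data.frame with columns `disease`, `lag_min`,
#'   `lag_max` overriding the bundle's windows (used for per-draw lag
#'   uncertainty).
#' @param beta_cache Optional precomputed array from [pif_beta_array()]
#'   (reused across Monte Carlo draws).
#' @return Array `[cohort age at 2011, disease, year]` of lagged PIFs,
#'   shared across sex/ethnicity strata (relative risks vary by age only).
#' @export
build_pif_series <- function(bundle, cascade, trajectory, lag_windows = NULL,
                             beta_cache = NULL) {
  B <- beta_cache %||% pif_beta_array(bundle)
  dm <- dim(B)
  nage <- dm[1]; nd <- dm[2]; horizon <- dm[3]
  delta <- as.numeric(trajectory)
  if (length(delta) < horizon) {
    delta <- c(delta, rep(delta[length(delta)], horizon - length(delta)))
  }
  p_elig <- as.numeric(eligible_fraction(cascade))
  dcat <- bundle$diseases

  pif <- p_elig * (1 - exp(B * rep(delta[seq_len(horizon)], each = nage * nd)))

  lw <- dcat[c("disease", "lag_min", "lag_max")]
  if (!is.null(lag_windows)) {
    m <- match(lw$disease, lag_windows$disease)
    lw$lag_min[!is.na(m)] <- lag_windows$lag_min[m[!is.na(m)]]
    lw$lag_max[!is.na(m)] <- lag_windows$lag_max[m[!is.na(m)]]
  }
  key <- paste(lw$lag_min, lw$lag_max)
  for (k in unique(key)) {
    sel <- which(key == k)
    if (lw$lag_min[sel[1]] == 0L && lw$lag_max[sel[1]] == 0L) next
    sub <- pif[, sel, , drop = FALSE]
    pif[, sel, ] <- apply_lag(sub, lw$lag_min[sel[1]], lw$lag_max[sel[1]])
  }
  dimnames(pif) <- list(NULL, dcat$disease, NULL)
  pif
}

#' Log relative risk per BMI unit at each cohort's attained age
#'
#' Precomputes `beta[cohort age, disease, year] = log RR` at the attained
#' age `min(age + year, closure)`; cacheable across Monte Carlo draws since
#' relative risks do not carry sampled uncertainty.
#'
#' @param bundle A `pmslt_bundle`.
#' @return Array `[cohort age, disease, year]`.
#' @export
pif_beta_array <- function(bundle) {
  ages <- 18:bundle$meta$closure_age
  nage <- length(ages)
  dcat <- bundle$diseases
  nd <- nrow(dcat)
  rr <- bundle$rr
  beta_mat <- matrix(0, nage, nd, dimnames = list(NULL, dcat$disease))
  for (j in seq_len(nd)) {
    rj <- rr[rr$disease == dcat$disease[j], ]
    beta_mat[, j] <- log(rj$rr_per_unit[match(ages, rj$age)])
  }
  ai <- pmin(outer(ages, seq_len(nage) - 1L, "+"), bundle$meta$closure_age) - 17L
  B <- array(0, dim = c(nage, nd, nage))
  for (t in seq_len(nage)) B[, , t] <- beta_mat[ai[, t], , drop = FALSE]
  B
}

#' Export a PIF array to a long data.frame
#'
#' @param pif Array from [build_pif_series()].
#' @param base_age First cohort age (default 18).
#' @return data.frame with columns `age`, `disease`, `year`, `pif`.
#' @export
pif_to_df <- function(pif, base_age = 18L) {
  dm <- dim(pif)
  df <- expand.grid(age = base_age + seq_len(dm[1]) - 1L,
                    disease = dimnames(pif)[[2]],
                    year = seq_len(dm[3]) - 1L,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$pif <- as.vector(pif)
  df
}
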