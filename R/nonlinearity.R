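# Age-trend model discrimination for aDMPs: a straight line
# beta = k*age + b, a power law fitted as ln(beta) = alpha*ln(age) + p,
# and an exponential fitted as ln(beta) = gamma*age + q. The log-space
# fits are least squares in the transformed axes but are always SCORED on
# the original beta scale, R^2 = 1 - RSS/TSS, so the three models compete
# on one footing. R^2 of a back-transformed fit may be negative.

.ols_xy <- function(x, y) {
  cx <- x - mean(x)
  sxx <- sum(cx^2)
  if (sxx <= 0) stop("degenerate design: all ages equal")
  slope <- sum(cx * y) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

.r2_original_scale <- function(obs, fitted) {
  tss <- sum((obs - mean(obs))^2)
  if (tss <= sum(obs^2) * 1e-14) return(0)
  1 - sum((obs - fitted)^2) / tss
}

#' Linear age-trend fit
#'
#' @param ages,betas numeric vectors, `n >= 3`.
#' @return list with slope `k`, intercept `b` and `r_squared`.
#' @export
fit_linear <- function(ages, betas) {
  stopifnot(length(ages) == length(betas), length(ages) >= 3)
  f <- .ols_xy(ages, betas)
  fitted <- f$intercept + f$slope * ages
  list(k = f$slope, b = f$intercept,
       r_squared = .r2_original_scale(betas, fitted))
}

#' Power-law age-trend fit
#'
#' OLS of `ln(beta)` on `ln(age)` gives exponent `alpha` and log-scale
#' intercept `p`; fitted values are back-transformed,
#' `beta_hat = exp(p) * age^alpha`, and R-squared is computed on the
#' original beta scale. Betas are floored at `floor` before taking logs so
#' the fit is always defined; ages must be strictly positive.
#'
#' @inheritParams fit_linear
#' @param floor lower bound applied to betas before the log transform.
#' @return list with `alpha`, `p` and `r_squared` (original scale; may be
#'   negative).
#' @export
fit_power <- function(ages, betas, floor = 1e-6) {
  stopifnot(length(ages) == length(betas), length(ages) >= 3)
  if (any(ages <= 0)) stop("power-law fit requires strictly positive ages")
  f <- .ols_xy(log(ages), log(pmax(betas, floor)))
  fitted <- exp(f$intercept) * ages^f$slope
  list(alpha = f$slope, p = f$intercept,
       r_squared = .r2_original_scale(betas, fitted))
}

#' Exponential age-trend fit
#'
#' OLS of `ln(beta)` on age gives rate `gamma` and log-scale intercept
#' `q`; fitted values are back-transformed,
#' `beta_hat = exp(q) * exp(gamma * age)`, and R-squared is computed on
#' the original beta scale.
#'
#' @inheritParams fit_power
#' @return list with `gamma`, `q` and `r_squared` (original scale; may be
#'   negative).
#' @export
fit_exponential <- function(ages, betas, floor = 1e-6) {
  stopifnot(length(ages) == length(betas), length(ages) >= 3)
  f <- .ols_xy(ages, log(pmax(betas, floor)))
  fitted <- exp(f$intercept) * exp(f$slope * ages)
  list(gamma = f$slope, q = f$intercept,
       r_squared = .r2_original_scale(betas, fitted))
}

# "at least `margin` higher" comparison of determination coefficients.
# Multiplicative when the reference is positive (the published phrasing is
# a percentage of the coefficient); absolute fallback when the reference
# R^2 is non-positive, where a multiplicative gate is meaningless.
.r2_exceeds <- function(r2, ref, margin) {
  if (ref > 0) r2 >= (1 + margin) * ref else r2 >= ref + margin
}

#' Choose between beta and complementary-beta orientation
#'
#' Fits the power-law and exponential models both to `beta` and to the
#' demethylated fraction `1 - beta`. If the best nonlinear determination
#' coefficient on `1 - beta` is at least 5% higher than on `beta`, the
#' complementary orientation is adopted and all three models are reported
#' against `1 - beta`; ties and everything else default to `beta`.
#'
#' @inheritParams fit_power
#' @param margin relative advantage required to switch orientation
#'   (default 0.05).
#' @return list with `orientation` (`"beta"`/`"complement"`) and `fits`, a
#'   list of the `linear`, `power`, `exponential` fits in the chosen
#'   orientation.
#' @export
choose_orientation <- function(ages, betas, margin = 0.05, floor = 1e-6) {
  fit_all <- function(y) list(linear = fit_linear(ages, y),
                              power = fit_power(ages, y, floor),
                              exponential = fit_exponential(ages, y, floor))
  fb <- fit_all(betas)
  fc <- fit_all(1 - betas)
  best_b <- max(fb$power$r_squared, fb$exponential$r_squared)
  best_c <- max(fc$power$r_squared, fc$exponential$r_squared)
  if (.r2_exceeds(best_c, best_b, margin))
    list(orientation = "complement", fits = fc)
  else
    list(orientation = "beta", fits = fb)
}

#' Classify the age-trend law of a probe
#'
#' Compares the three determination coefficients in the chosen
#' orientation. Let `R2_nl` be the larger of the power and exponential
#' R-squared: if it is at least 5% higher than the linear R-squared the
#' probe is strongly nonlinear, labelled by the larger nonlinear fit
#' (`nonlinear_power` or `nonlinear_exponential`, ties going to power); if
#' it merely lies within 5% of the linear R-squared the probe is
#' `weak_nonlinear`; otherwise `linear`. When the linear R-squared is
#' non-positive the 5% margins are applied absolutely.
#'
#' @param fits list with elements `linear`, `power`, `exponential` as
#'   returned by the fitting functions (e.g. `choose_orientation()$fits`).
#' @param margin the 5% margin (default 0.05).
#' @return one of `"nonlinear_power"`, `"nonlinear_exponential"`,
#'   `"weak_nonlinear"`, `"linear"`.
#' @export
classify_trend <- function(fits, margin = 0.05) {
  r2l <- fits$linear$r_squared
  r2p <- fits$power$r_squared
  r2e <- fits$exponential$r_squared
  r2nl <- max(r2p, r2e)
  if (.r2_exceeds(r2nl, r2l, margin)) {
    if (r2p >= r2e) "nonlinear_power" else "nonlinear_exponential"
  } else {
    lower <- if (r2l > 0) (1 - margin) * r2l else r2l - margin
    if (r2nl >= lower) "weak_nonlinear" else "linear"
  }
}

#' Fit and classify age-trend models for a set of probes
#'
#' Runs [choose_orientation()] and [classify_trend()] for each probe of a
#' cross-sectional cohort (typically the aDMPs of one sex).
#'
#' @param cohort a cross-sectional [meth_cohort()].
#' @param probes character vector of probe ids (default: all).
#' @param margin the 5% comparison margin.
#' @param floor beta floor before log transforms.
#' @return data.frame, one row per probe: orientation, the parameters and
#'   original-scale R-squared of the three fits, and `class`.
#' @export
fit_trend_models <- function(cohort, probes = rownames(cohort$beta),
                             margin = 0.05, floor = 1e-6) {
  stopifnot(inherits(cohort, "meth_cohort"))
  ages <- cohort$samples$age
  if (any(ages <= 0))
    stop("trend-model discrimination requires strictly positive ages")
  rows <- lapply(probes, function(pr) {
    ch <- choose_orientation(ages, cohort$beta[pr, ], margin, floor)
    f <- ch$fits
    data.frame(probe_id = pr, orientation = ch$orientation,
               k = f$linear$k, b = f$linear$b,
               r2_linear = f$linear$r_squared,
               alpha = f$power$alpha, p = f$power$p,
               r2_pow = f$power$r_squared,
               gamma = f$exponential$gamma, q = f$exponential$q,
               r2_exp = f$exponential$r_squared,
               class = classify_trend(f, margin))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
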