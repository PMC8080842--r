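#' Select age-associated differentially methylated positions (aDMPs)
#'
#' Per sex, each probe's beta values are regressed on age; probes qualify
#' when the absolute slope exceeds `min_abs_slope` (0.001 per year, i.e. at
#' least 0.1 beta over a century) AND the regression R-squared exceeds the
#' `r2_percentile`-th percentile of the R-squared distribution over all
#' tested probes of that sex (linear-interpolation percentile).
#'
#' @param cohort a cross-sectional [meth_cohort()].
#' @param min_abs_slope minimum absolute slope per year (default 0.001).
#' @param r2_percentile percentile gate on R-squared, in (0, 100)
#'   (default 99).
#' @param sexes strata to analyse.
#' @return data.frame, one row per (probe, sex): `probe_id`, `sex`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `r2_threshold`, `admp`.
#' @export
select_admps <- function(cohort, min_abs_slope = 0.001, r2_percentile = 99,
                         sexes = c("male", "female")) {
  stopifnot(inherits(cohort, "meth_cohort"),
            min_abs_slope > 0, r2_percentile > 0, r2_percentile < 100)
  if (nrow(cohort$beta) < 10L)
    stop("at least 10 probes are required for a meaningful percentile gate")
  res <- lapply(sexes, function(sx) {
    co <- subset_cohort(cohort, cohort$samples$sex == sx)
    fit <- row_age_regression(co$beta, co$samples$age)
    thr <- unname(stats::quantile(fit$r_squared, r2_percentile / 100,
                                  type = 7))
    data.frame(probe_id = rownames(co$beta), sex = sx,
               slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, p_value = fit$p_value,
               r2_threshold = thr,
               admp = abs(fit$slope) > min_abs_slope & fit$r_squared > thr,
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Select aDaVMPs among the aDMPs
#'
#' The aDMPs whose sliding-window variance also changes significantly with
#' age: the sigma-squared-on-age regression must reach BH-adjusted
#' `p < alpha`, with BH applied over the aDMP set within each sex.
#'
#' @param cohort a cross-sectional [meth_cohort()].
#' @param admps data.frame from [select_admps()] (rows with `admp == TRUE`
#'   are considered) or a character vector of probe ids (single stratum).
#' @param alpha BH-adjusted threshold (default 0.001).
#' @param half_width sliding-window half width in years.
#' @param sexes strata to analyse when `admps` is a data.frame.
#' @return data.frame, one row per (aDMP probe, sex): variance-regression
#'   estimates, adjusted p-value `q_sigma2` and the `adavmp` flag.
#' @export
select_adavmps <- function(cohort, admps, alpha = 0.001, half_width = 5,
                           sexes = c("male", "female")) {
  stopifnot(inherits(cohort, "meth_cohort"))
  if (is.character(admps))
    admps <- data.frame(probe_id = admps, sex = sexes[1], admp = TRUE)
  res <- lapply(intersect(sexes, unique(admps$sex)), function(sx) {
    ids <- admps$probe_id[admps$sex == sx & admps$admp]
    if (length(ids) == 0L)
      return(data.frame(probe_id = character(), sex = character(),
                        sigma2_slope = numeric(), p_sigma2 = numeric(),
                        q_sigma2 = numeric(), adavmp = logical()))
    vr <- sigma2_age_regression(subset_cohort(cohort, probes = ids),
                                sex = sx, half_width = half_width)
    q <- bh_adjust(vr$p_value)
    data.frame(probe_id = vr$probe_id, sex = sx,
               sigma2_slope = vr$slope, p_sigma2 = vr$p_value,
               q_sigma2 = q, adavmp = q < alpha, row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(probe_id = character(), sex = character(),
                      sigma2_slope = numeric(), p_sigma2 = numeric(),
                      q_sigma2 = numeric(), adavmp = logical())
  out
}

#' Direction class of an aDaVMP
#'
#' The four classes combine the signs of the methylation-level slope and
#' the variability slope: both increase (`up_up`), both decrease
#' (`down_down`), methylation decreases while variability increases
#' (`down_up`), methylation increases while variability decreases
#' (`up_down`). Zero slopes cannot occur after the selection gates and are
#' an error.
#'
#' @param beta_slope,sigma2_slope numeric vectors of OLS slopes.
#' @return character vector of direction classes.
#' @export
classify_direction <- function(beta_slope, sigma2_slope) {
  stopifnot(length(beta_slope) == length(sigma2_slope),
            all(is.finite(beta_slope)), all(is.finite(sigma2_slope)))
  if (any(beta_slope == 0 | sigma2_slope == 0))
    stop("zero slope cannot be direction-classified (unreachable after selection gates)")
  ifelse(beta_slope > 0,
         ifelse(sigma2_slope > 0, "up_up", "up_down"),
         ifelse(sigma2_slope > 0, "down_up", "down_down"))
}

# Raw per-probe ingredients of the scaling-law inference: orientation and
# the unadjusted age-trend p-values of the CV^2 and Fano series.
# Window means exactly 0 or 1 would make the normalised ratio undefined and
# are excluded pointwise (counted in `n_excluded`).
.noise_scaling_raw <- function(ages, betas, beta_slope, sigma2_slope,
                               half_width = 5) {
  wm <- sliding_window_mean(ages, betas, half_width)
  s2 <- (betas - wm)^2
  orientation <- if (sign(beta_slope) != sign(sigma2_slope))
    "one_minus_beta" else "beta"
  m <- if (orientation == "one_minus_beta") 1 - wm else wm
  keep <- m != 0 & m != 1
  cv2 <- s2[keep] / m[keep]^2
  fano <- s2[keep] / m[keep]
  list(orientation = orientation,
       p_cv2 = regress_on_age(ages[keep], cv2)$p_value,
       p_fano = regress_on_age(ages[keep], fano)$p_value,
       n_excluded = sum(!keep))
}

#' Infer the variance-mean scaling law of aDaVMPs
#'
#' For each probe, the variance series is normalised two ways: the squared
#' coefficient of variation `CV^2 = sigma^2 / <beta>^2` and the Fano factor
#' `F = sigma^2 / <beta>`. When methylation level and variability trend in
#' opposite directions the normalisation uses the demethylated fraction
#' `1 - <beta>` instead. Each normalised series is regressed on age and the
#' p-values are BH-adjusted across the probe set (per statistic). If the
#' CV^2 trend is not significant the probe's law is `sigma2 ~ beta^2`
#' (`"quadratic"`); otherwise, if the Fano trend is not significant, the
#' law is `sigma2 ~ beta` (`"linear"`); if both normalisations remain
#' age-dependent the law is `NA`. When both fail to reject, the quadratic
#' law takes precedence and the tie is flagged in column `tie`.
#'
#' @param cohort a cross-sectional [meth_cohort()] (subset to one sex for
#'   the published design).
#' @param probes character vector of aDaVMP probe ids.
#' @param beta_slope,sigma2_slope per-probe OLS slopes of methylation level
#'   and variance on age (same order as `probes`); computed from the
#'   cohort when omitted.
#' @param alpha BH-adjusted threshold for rejecting age independence
#'   (default 0.001).
#' @param half_width sliding-window half width in years.
#' @return data.frame, one row per probe: `probe_id`, `orientation`,
#'   `p_cv2`, `q_cv2`, `p_fano`, `q_fano`, `law`
#'   (`"quadratic"`/`"linear"`/`NA`), `tie`.
#' @export
infer_noise_scaling <- function(cohort, probes, beta_slope = NULL,
                                sigma2_slope = NULL, alpha = 0.001,
                                half_width = 5) {
  stopifnot(inherits(cohort, "meth_cohort"), length(probes) >= 1)
  ages <- cohort$samples$age
  B <- cohort$beta[probes, , drop = FALSE]
  if (is.null(beta_slope))
    beta_slope <- row_age_regression(B, ages)$slope
  if (is.null(sigma2_slope)) {
    co <- subset_cohort(cohort, probes = probes)
    sigma2_slope <- row_age_regression(cohort_sigma2(co, half_width), ages)$slope
  }
  stopifnot(length(beta_slope) == length(probes),
            length(sigma2_slope) == length(probes))
  raw <- lapply(seq_along(probes), function(i)
    .noise_scaling_raw(ages, B[i, ], beta_slope[i], sigma2_slope[i],
                       half_width))
  p_cv2 <- vapply(raw, `[[`, numeric(1), "p_cv2")
  p_fano <- vapply(raw, `[[`, numeric(1), "p_fano")
  q_cv2 <- bh_adjust(p_cv2)
  q_fano <- bh_adjust(p_fano)
  cv2_flat <- q_cv2 >= alpha
  fano_flat <- q_fano >= alpha
  law <- ifelse(cv2_flat, "quadratic",
                ifelse(fano_flat, "linear", NA_character_))
  data.frame(probe_id = probes,
             orientation = vapply(raw, `[[`, character(1), "orientation"),
             p_cv2 = p_cv2, q_cv2 = q_cv2,
             p_fano = p_fano, q_fano = q_fano,
             law = law, tie = cv2_flat & fano_flat, row.names = NULL)
}
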