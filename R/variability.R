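#' Pointwise variability of a methylation series
#'
#' The population-average variability of a probe at each sample is the
#' squared deviation of its beta value from the 10-year sliding-window mean
#' at that sample's age: `sigma2 = (beta - <beta>)^2`.
#'
#' @param ages numeric vector of ages.
#' @param betas numeric vector of methylation values, same length.
#' @param half_width sliding-window half width in years (default 5).
#' @return data.frame with columns `age`, `beta`, `window_mean`, `sigma2`.
#' @export
pointwise_sigma2 <- function(ages, betas, half_width = 5) {
  wm <- sliding_window_mean(ages, betas, half_width)
  data.frame(age = ages, beta = betas, window_mean = wm,
             sigma2 = (betas - wm)^2)
}

# sigma2 matrix for all probes of a cohort (probes x samples)
cohort_sigma2 <- function(cohort, half_width = 5) {
  wm <- row_window_means(cohort$beta, cohort$samples$age, half_width)
  (cohort$beta - wm)^2
}

#' Per-probe age regression of the sliding-window variance
#'
#' For every probe, computes the pointwise variance series `sigma2` and
#' regresses it on age, optionally within one sex.
#'
#' @param cohort a [meth_cohort()].
#' @param sex `"male"`, `"female"`, or `NULL` for all samples.
#' @param half_width sliding-window half width in years.
#' @return data.frame (one row per probe): `probe_id`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
sigma2_age_regression <- function(cohort, sex = NULL, half_width = 5) {
  stopifnot(inherits(cohort, "meth_cohort"))
  if (!is.null(sex)) cohort <- subset_cohort(cohort, cohort$samples$sex == sex)
  s2 <- cohort_sigma2(cohort, half_width)
  out <- row_age_regression(s2, cohort$samples$age)
  cbind(probe_id = rownames(cohort$beta), out, row.names = NULL)
}

#' Select age-associated variably methylated positions (aVMPs)
#'
#' A probe is an aVMP when its variance-on-age regression is significant in
#' the primary (cross-sectional) cohort at BH-adjusted `p < alpha_primary`
#' AND in the secondary (longitudinal) cohort at BH-adjusted
#' `p < alpha_secondary`. BH correction is applied within each
#' (cohort, sex) stratum over all probes shared by the two cohorts. Males
#' and females are analysed separately.
#'
#' @param primary,secondary [meth_cohort()] objects sharing (part of) a
#'   probe universe. `secondary = NULL` selects on the primary cohort alone
#'   (degraded single-dataset mode, flagged with a warning).
#' @param alpha_primary,alpha_secondary BH-adjusted significance thresholds
#'   (defaults 0.001 and 0.05).
#' @param half_width sliding-window half width in years.
#' @param sexes which strata to analyse (default both).
#' @return data.frame with one row per (probe, sex): adjusted p-values per
#'   cohort and the logical `avmp` flag.
#' @export
select_avmps <- function(primary, secondary = NULL,
                         alpha_primary = 0.001, alpha_secondary = 0.05,
                         half_width = 5, sexes = c("male", "female")) {
  stopifnot(inherits(primary, "meth_cohort"))
  if (is.null(secondary)) {
    warning("no secondary cohort: aVMP intersection skipped, ",
            "selection reflects the primary dataset only")
    shared <- rownames(primary$beta)
  } else {
    shared <- intersect(rownames(primary$beta), rownames(secondary$beta))
    if (length(shared) == 0L)
      stop("primary and secondary cohorts share no probes")
  }
  res <- lapply(sexes, function(sx) {
    rp <- sigma2_age_regression(subset_cohort(primary, probes = shared),
                                sex = sx, half_width = half_width)
    qp <- bh_adjust(rp$p_value)
    out <- data.frame(probe_id = rp$probe_id, sex = sx,
                      p_primary = rp$p_value, q_primary = qp)
    if (is.null(secondary)) {
      out$p_secondary <- NA_real_
      out$q_secondary <- NA_real_
      out$avmp <- qp < alpha_primary
    } else {
      rs <- sigma2_age_regression(subset_cohort(secondary, probes = shared),
                                  sex = sx, half_width = half_width)
      qs <- bh_adjust(rs$p_value)
      out$p_secondary <- rs$p_value
      out$q_secondary <- qs
      out$avmp <- qp < alpha_primary & qs < alpha_secondary
    }
    out
  })
  do.call(rbind, res)
}
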