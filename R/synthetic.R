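# Synthetic cohort generator. Emulates the statistical structures the
# variability analysis assumes: cross-sectional cohorts with age-dependent
# variance, longitudinal cohorts whose individuals either follow
# heterogeneous linear trajectories diverging from a common origin
# (deterministic divergence) or biased random walks (stochastic
# fluctuation), same-sex twin pairs sharing trajectory parameters, and
# probe-level trend laws (linear, power, exponential, constant) combined
# with noise-scaling laws (sigma ~ beta, sigma^2 ~ beta, sigma^2 ~ beta^3,
# constant).

#' Trend specification for a synthetic probe
#'
#' Describes the population-mean trajectory of one probe. The law applies
#' either to the methylation fraction itself (`orientation = "beta"`) or to
#' the demethylated fraction (`orientation = "complement"`, i.e. the law
#' describes `1 - beta`).
#'
#' Defaults encode the study conditions of a strongly age-trending blood
#' CpG: a linear gain of 0.005 beta per year from 0.15, a power law
#' `0.13 * age^0.3`, an exponential `0.15 * exp(0.01 * age)`, or a
#' constant level 0.4.
#'
#' @param law `"linear"`, `"power"`, `"exponential"` or `"constant"`.
#' @param k,b slope (per year) and intercept of the linear law.
#' @param a,alpha scale and exponent of the power law `a * age^alpha`.
#' @param scale,gamma scale and rate of the exponential law
#'   `scale * exp(gamma * age)`.
#' @param level the constant law's level.
#' @param orientation `"beta"` or `"complement"`.
#' @return an object of class `trend_spec`.
#' @export
trend_spec <- function(law = c("linear", "power", "exponential", "constant"),
                       k = 0.005, b = 0.15, a = 0.13, alpha = 0.3,
                       scale = 0.15, gamma = 0.01, level = 0.4,
                       orientation = c("beta", "complement")) {
  law <- match.arg(law)
  orientation <- match.arg(orientation)
  params <- switch(law,
    linear = list(k = k, b = b),
    power = list(a = a, alpha = alpha),
    exponential = list(scale = scale, gamma = gamma),
    constant = list(level = level))
  structure(list(law = law, params = params, orientation = orientation),
            class = "trend_spec")
}

# Mean of the trend variable (beta or 1-beta, per orientation) at `ages`.
trend_value <- function(spec, ages) {
  p <- spec$params
  switch(spec$law,
    linear = p$k * ages + p$b,
    power = p$a * ages^p$alpha,
    exponential = p$scale * exp(p$gamma * ages),
    constant = rep(p$level, length(ages)))
}

# Mean beta trajectory (orientation applied).
trend_beta <- function(spec, ages) {
  u <- trend_value(spec, ages)
  if (spec$orientation == "complement") 1 - u else u
}

#' Noise specification for a synthetic probe
#'
#' Describes how a probe's scatter around its mean trajectory is generated.
#' `scaling` sets the visit-level noise law relative to the (oriented)
#' mean level `u`: `"additive_constant"` (sd = magnitude),
#' `"cv_constant"` (sd = magnitude * u, so the coefficient of variation is
#' age-flat and sigma^2 ~ beta^2), `"fano_constant"`
#' (sd = magnitude * sqrt(u), so the Fano factor is age-flat and
#' sigma^2 ~ beta) or `"cubic"` (sd = magnitude * u^1.5, sigma^2 ~ beta^3,
#' a law neither normalisation removes). `mechanism` sets the longitudinal
#' structure: `"divergence"` draws one trajectory-slope perturbation per
#' individual (twins share the draw up to a small jitter), anchored at the
#' cohort's minimum age so that trajectories fan out; `"random_walk"`
#' evolves each individual as a biased random walk whose drift equals the
#' trend's increment.
#'
#' @param scaling one of `"additive_constant"`, `"cv_constant"`,
#'   `"fano_constant"`, `"cubic"`.
#' @param magnitude dimensionless noise coefficient, `>= 0`.
#' @param mechanism `"divergence"` or `"random_walk"`.
#' @param divergence_sd sd (per year) of the per-individual slope
#'   perturbation used by the divergence mechanism.
#' @param step_sd random-walk step scale: a step over `dt` years has sd
#'   `step_sd * sqrt(dt)`.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(scaling = c("additive_constant", "cv_constant",
                                   "fano_constant", "cubic"),
                       magnitude = 0.01,
                       mechanism = c("divergence", "random_walk"),
                       divergence_sd = 0.002, step_sd = 0.02) {
  scaling <- match.arg(scaling)
  mechanism <- match.arg(mechanism)
  stopifnot(magnitude >= 0, divergence_sd >= 0, step_sd >= 0)
  structure(list(scaling = scaling, magnitude = magnitude,
                 mechanism = mechanism, divergence_sd = divergence_sd,
                 step_sd = step_sd), class = "noise_spec")
}

.noise_sd <- function(noise, u) {
  u <- pmax(u, 0)
  switch(noise$scaling,
    additive_constant = rep(noise$magnitude, length(u)),
    cv_constant = noise$magnitude * u,
    fano_constant = noise$magnitude * sqrt(u),
    cubic = noise$magnitude * u^1.5)
}

#' Configuration of a synthetic cohort
#'
#' @param probes named list; each element is a list with components
#'   `trend` (a [trend_spec()]) and `noise` (a [noise_spec()]). Names are
#'   the probe ids.
#' @param n_individuals number of individuals.
#' @param visits_per_individual 1 for a cross-sectional design; `> 1` for
#'   a longitudinal design with fixed visit spacing.
#' @param age_range two ages in years, `min < max`. Cross-sectional ages
#'   are drawn uniformly over the range; longitudinal baseline ages are
#'   drawn so the last visit stays inside the range.
#' @param visit_spacing years between consecutive visits.
#' @param twin_fraction proportion of individuals paired as same-sex twins
#'   sharing baseline age and (for divergence probes) trajectory
#'   parameters, in `[0, 1]`.
#' @param sex_ratio probability that an individual (or pair) is male.
#' @param twin_jitter_frac intra-pair jitter of the shared divergence
#'   draw, as a fraction of `divergence_sd` (default 0.1; a value of 0
#'   would collapse twin SNR onto the trajectory SNR).
#' @param dataset label stored in the sample sheet.
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(probes, n_individuals,
                          visits_per_individual = 1,
                          age_range = c(14, 94), visit_spacing = 3,
                          twin_fraction = 0, sex_ratio = 0.5,
                          twin_jitter_frac = 0.1,
                          dataset = "synthetic", seed = 1) {
  stopifnot(is.list(probes),
            n_individuals >= 1, visits_per_individual >= 1,
            length(age_range) == 2, age_range[1] < age_range[2],
            visit_spacing > 0, twin_fraction >= 0, twin_fraction <= 1,
            sex_ratio >= 0, sex_ratio <= 1, twin_jitter_frac >= 0)
  if (length(probes) > 0 && (is.null(names(probes)) ||
                             anyDuplicated(names(probes))))
    stop("probes must be a named list with unique probe ids")
  span <- (visits_per_individual - 1) * visit_spacing
  if (span >= diff(age_range))
    stop("visit schedule does not fit inside the age range")
  grid <- seq(age_range[1], age_range[2], length.out = 201)
  for (pid in names(probes)) {
    pr <- probes[[pid]]
    if (!inherits(pr$trend, "trend_spec") || !inherits(pr$noise, "noise_spec"))
      stop("probe '", pid, "' must have a trend_spec and a noise_spec")
    u <- trend_value(pr$trend, grid)
    if (pr$trend$law %in% c("power", "exponential") && any(u <= 0))
      stop("probe '", pid, "': ", pr$trend$law,
           " law requires strictly positive mean values over the age span")
    bmean <- trend_beta(pr$trend, grid)
    if (any(bmean < 0 | bmean > 1))
      stop("probe '", pid,
           "': mean trajectory exits [0, 1] over the configured age span")
  }
  structure(list(probes = probes, n_individuals = n_individuals,
                 visits_per_individual = visits_per_individual,
                 age_range = age_range, visit_spacing = visit_spacing,
                 twin_fraction = twin_fraction, sex_ratio = sex_ratio,
                 twin_jitter_frac = twin_jitter_frac,
                 dataset = dataset, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws the sampling design (individuals, twin pairs, visit ages, sexes)
#' and then simulates every probe according to its trend and noise
#' specifications. Divergence probes perturb each individual's trajectory
#' slope (twins share the perturbation up to the configured jitter) and
#' add visit-level noise per the scaling law; random-walk probes evolve
#' each individual from its first visit as
#' `value(t + dt) = value(t) + trend_increment + step`, with step sd
#' `step_sd * sqrt(dt)` (in a cross-sectional design, where no
#' within-individual walk exists, the marginal displacement
#' `N(0, step_sd^2 * (age - age_min))` of a walk from the cohort's minimum
#' age is used). All betas are clipped to `[1e-6, 1 - 1e-6]` so that
#' downstream log fits are always defined.
#'
#' @param config a [cohort_config()]. The seed inside the config fully
#'   determines the output.
#' @return a [meth_cohort()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  v <- config$visits_per_individual
  rng <- config$age_range
  sp <- config$visit_spacing
  n_pairs <- floor(config$twin_fraction * n / 2)
  unit <- c(rep(seq_len(n_pairs), each = 2),
            seq_len(n - 2 * n_pairs) + n_pairs)
  n_units <- n_pairs + (n - 2 * n_pairs)
  unit_sex <- ifelse(stats::runif(n_units) < config$sex_ratio,
                     "male", "female")
  hi_base <- if (v == 1) rng[2] else rng[2] - (v - 1) * sp
  unit_base <- stats::runif(n_units, rng[1], hi_base)
  base <- unit_base[unit]
  sexes <- unit_sex[unit]
  twin_pair <- ifelse(seq_len(n) <= 2 * n_pairs,
                      sprintf("tp%04d", unit), NA_character_)
  ind_id <- sprintf("i%04d", seq_len(n))
  ages <- as.vector(t(outer(base, (seq_len(v) - 1) * sp, `+`)))
  samples <- data.frame(
    sample_id = sprintf("%s_v%d", rep(ind_id, each = v), rep(seq_len(v), n)),
    individual_id = rep(ind_id, each = v),
    age = ages,
    sex = rep(sexes, each = v),
    twin_pair_id = rep(twin_pair, each = v),
    dataset = config$dataset,
    stringsAsFactors = FALSE)
  is_twin <- rep(!is.na(twin_pair), each = v)
  beta <- matrix(NA_real_, length(config$probes), nrow(samples),
                 dimnames = list(names(config$probes), samples$sample_id))
  for (pid in names(config$probes)) {
    pr <- config$probes[[pid]]
    noise <- pr$noise
    u_mean <- trend_value(pr$trend, ages)
    if (noise$mechanism == "divergence") {
      d_unit <- stats::rnorm(n_units, 0, noise$divergence_sd)
      d_ind <- d_unit[unit]
      jit <- config$twin_jitter_frac * noise$divergence_sd
      has_twin <- !is.na(twin_pair)
      d_ind[has_twin] <- d_ind[has_twin] +
        stats::rnorm(sum(has_twin), 0, jit)
      u_ind <- u_mean + rep(d_ind, each = v) * (ages - rng[1])
      u <- u_ind + stats::rnorm(length(ages), 0, .noise_sd(noise, u_ind))
    } else {
      if (v == 1) {
        walk <- stats::rnorm(n, 0, noise$step_sd * sqrt(ages - rng[1]))
        u_core <- u_mean + walk
      } else {
        steps <- matrix(stats::rnorm(n * (v - 1), 0,
                                     noise$step_sd * sqrt(sp)), n, v - 1)
        walk <- cbind(0, t(apply(steps, 1L, cumsum)))
        u_core <- u_mean + as.vector(t(walk))
      }
      u <- u_core + stats::rnorm(length(ages), 0, .noise_sd(noise, u_mean))
    }
    b <- if (pr$trend$orientation == "complement") 1 - u else u
    beta[pid, ] <- pmin(pmax(b, 1e-6), 1 - 1e-6)
  }
  meth_cohort(beta, samples)
}

#' Ground truth of a synthetic cohort configuration
#'
#' One row per probe echoing its generating law, parameters, noise scaling
#' and mechanism -- the recovery target for downstream tests.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `probe_id`, `law`, `orientation`,
#'   the law parameters (`k`, `b`, `a`, `alpha`, `scale`, `gamma`,
#'   `level`; `NA` where not applicable), `scaling`, `magnitude`,
#'   `mechanism`, `divergence_sd`, `step_sd`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  empty <- data.frame(probe_id = character(), law = character(),
                      orientation = character(), k = numeric(),
                      b = numeric(), a = numeric(), alpha = numeric(),
                      scale = numeric(), gamma = numeric(),
                      level = numeric(), scaling = character(),
                      magnitude = numeric(), mechanism = character(),
                      divergence_sd = numeric(), step_sd = numeric())
  if (length(config$probes) == 0L) return(empty)
  rows <- lapply(names(config$probes), function(pid) {
    pr <- config$probes[[pid]]
    p <- pr$trend$params
    g <- function(nm) if (!is.null(p[[nm]])) p[[nm]] else NA_real_
    data.frame(probe_id = pid, law = pr$trend$law,
               orientation = pr$trend$orientation,
               k = g("k"), b = g("b"), a = g("a"), alpha = g("alpha"),
               scale = g("scale"), gamma = g("gamma"), level = g("level"),
               scaling = pr$noise$scaling, magnitude = pr$noise$magnitude,
               mechanism = pr$noise$mechanism,
               divergence_sd = pr$noise$divergence_sd,
               step_sd = pr$noise$step_sd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate a probe specification
#'
#' Convenience builder: `n` probes sharing one trend and noise
#' specification, ids `prefix_001 ...`.
#'
#' @param n number of probes.
#' @param trend a [trend_spec()].
#' @param noise a [noise_spec()].
#' @param prefix probe-id prefix.
#' @return named list suitable for [cohort_config()].
#' @export
probe_set <- function(n, trend, noise, prefix = "cg") {
  stopifnot(n >= 0)
  out <- rep(list(list(trend = trend, noise = noise)), n)
  names(out) <- sprintf("%s_%04d", prefix, seq_len(n))
  out
}
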