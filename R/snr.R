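# Signal-to-noise ratios for methylation trajectories, twin pairs and
# pooled point clouds. All three statistics share one policy for
# vanishing deviations: per-point ratios with deviation < epsilon are
# excluded; if every point of a unit is excluded (a perfect fit) the unit's
# SNR is the cap; finite means are clamped to [0, snr_cap].

# Row-wise capped mean-of-ratios. NUM and DEV are probes x points.
.row_snr <- function(NUM, DEV, epsilon = 1e-8, snr_cap = 1e6) {
  keep <- DEV >= epsilon
  R <- NUM / DEV
  R[!keep] <- 0
  cnt <- rowSums(keep)
  out <- ifelse(cnt > 0, rowSums(R) / cnt, snr_cap)
  pmin(pmax(out, 0), snr_cap)
}

#' Signal-to-noise ratio of one longitudinal trajectory
#'
#' Fits the individual's beta values on age by OLS and computes the mean
#' over points of (fitted value) / |observed - fitted|. Points whose
#' absolute deviation falls below `epsilon` are excluded from the mean; a
#' trajectory fitted exactly (all points excluded) returns `snr_cap`.
#' Only individuals with at least three measurements at distinct ages are
#' eligible.
#'
#' @param ages,betas numeric vectors of the individual's visit ages and
#'   methylation values.
#' @param epsilon deviation floor below which a point is excluded.
#' @param snr_cap upper bound for the reported SNR.
#' @return a single non-negative number.
#' @export
snr_trajectory <- function(ages, betas, epsilon = 1e-8, snr_cap = 1e6) {
  stopifnot(length(ages) == length(betas))
  if (length(unique(ages)) < 3L)
    stop("trajectory ineligible: fewer than 3 measurements at distinct ages")
  ca <- ages - mean(ages)
  slope <- sum(ca * betas) / sum(ca^2)
  fitted <- mean(betas) + slope * ca
  .row_snr(matrix(fitted, nrow = 1), matrix(abs(betas - fitted), nrow = 1),
           epsilon, snr_cap)
}

# Per-individual trajectory SNRs for every probe at once.
# Returns list(snr = per-probe mean, per_individual = probes x individuals
# matrix, individuals = ids, skipped = ineligible ids).
snr_trajectories_all <- function(cohort, epsilon = 1e-8, snr_cap = 1e6) {
  B <- cohort$beta
  s <- cohort$samples
  groups <- split(seq_len(nrow(s)), s$individual_id)
  eligible <- vapply(groups, function(ii) length(unique(s$age[ii])) >= 3L,
                     logical(1))
  skipped <- names(groups)[!eligible]
  groups <- groups[eligible]
  if (length(groups) == 0L)
    return(list(snr = rep(NA_real_, nrow(B)), per_individual = NULL,
                individuals = character(), skipped = skipped))
  Z <- matrix(NA_real_, nrow(B), length(groups),
              dimnames = list(rownames(B), names(groups)))
  for (k in seq_along(groups)) {
    ii <- groups[[k]]
    a <- s$age[ii]
    ca <- a - mean(a)
    Bi <- B[, ii, drop = FALSE]
    slope <- as.vector(Bi %*% ca) / sum(ca^2)
    fitted <- rowMeans(Bi) + outer(slope, ca)
    Z[, k] <- .row_snr(fitted, abs(Bi - fitted), epsilon, snr_cap)
  }
  list(snr = rowMeans(Z), per_individual = Z,
       individuals = names(groups), skipped = skipped)
}

#' Trajectory SNR of one probe, averaged over individuals
#'
#' Computes [snr_trajectory()] for every eligible individual (at least
#' three visits at distinct ages) and returns the unweighted mean.
#'
#' @param cohort a longitudinal [meth_cohort()].
#' @param probe probe id.
#' @inheritParams snr_trajectory
#' @return list with `snr` (probe-level mean, `NA` if no individual is
#'   eligible), `per_individual` (named vector) and `skipped` (ids of
#'   ineligible individuals).
#' @export
snr_trajectories_probe <- function(cohort, probe, epsilon = 1e-8,
                                   snr_cap = 1e6) {
  stopifnot(inherits(cohort, "meth_cohort"), probe %in% rownames(cohort$beta))
  all <- snr_trajectories_all(subset_cohort(cohort, probes = probe),
                              epsilon, snr_cap)
  list(snr = unname(all$snr[1]),
       per_individual = if (is.null(all$per_individual)) numeric()
                        else all$per_individual[1, ],
       skipped = all$skipped)
}

# Alignment weights for one twin pair, from ages alone. For each age in the
# union where exactly one twin was measured, the other twin's value is
# linearly interpolated between its two bracketing measurements, provided
# the age lies strictly inside that twin's observed span (no
# extrapolation). Returns NULL when no age can be synchronized; pair
# eligibility (>= 2 points) is enforced by the SNR stage, not here.
# Each twin contributes index/weight triples (iL, iR, w): value =
# w * v[iL] + (1 - w) * v[iR]; measured points have iL == iR, w == 1.
.twin_alignment <- function(ages1, ages2) {
  if (anyDuplicated(ages1) || anyDuplicated(ages2))
    stop("duplicated visit ages within a twin")
  o1 <- order(ages1); o2 <- order(ages2)
  a1 <- ages1[o1];   a2 <- ages2[o2]
  ages <- sort(unique(c(a1, a2)))
  one <- function(a_sorted, ord) {
    iL <- iR <- integer(length(ages)); w <- numeric(length(ages))
    ok <- logical(length(ages))
    m <- match(ages, a_sorted)
    meas <- !is.na(m)
    iL[meas] <- iR[meas] <- ord[m[meas]]; w[meas] <- 1; ok[meas] <- TRUE
    interior <- !meas & ages > a_sorted[1] & ages < a_sorted[length(a_sorted)]
    if (any(interior)) {
      j <- findInterval(ages[interior], a_sorted)
      iL[interior] <- ord[j]; iR[interior] <- ord[j + 1L]
      w[interior] <- (a_sorted[j + 1L] - ages[interior]) /
                     (a_sorted[j + 1L] - a_sorted[j])
      ok[interior] <- TRUE
    }
    list(iL = iL, iR = iR, w = w, ok = ok)
  }
  t1 <- one(a1, o1); t2 <- one(a2, o2)
  keep <- t1$ok & t2$ok
  if (!any(keep)) return(NULL)
  list(age = ages[keep],
       i1L = t1$iL[keep], i1R = t1$iR[keep], w1 = t1$w[keep],
       i2L = t2$iL[keep], i2R = t2$iR[keep], w2 = t2$w[keep])
}

#' Synchronize the visit series of a twin pair
#'
#' At every age where exactly one twin was measured, the other twin's value
#' is linearly interpolated between its two bracketing measurements; ages
#' outside a twin's observed span are dropped (no extrapolation). Returns
#' the ages at which both twins have a (measured or interpolated) value.
#'
#' @param ages1,values1 visit ages and values of the first twin.
#' @param ages2,values2 visit ages and values of the second twin.
#' @return data.frame with columns `age`, `value1`, `value2`; zero rows if
#'   no age can be synchronized. Pairs need at least two synchronized
#'   points to enter [snr_twin_pairs_probe()].
#' @export
align_twin_points <- function(ages1, values1, ages2, values2) {
  stopifnot(length(ages1) == length(values1),
            length(ages2) == length(values2),
            length(ages1) >= 1, length(ages2) >= 1)
  al <- .twin_alignment(ages1, ages2)
  if (is.null(al))
    return(data.frame(age = numeric(), value1 = numeric(),
                      value2 = numeric()))
  data.frame(age = al$age,
             value1 = al$w1 * values1[al$i1L] + (1 - al$w1) * values1[al$i1R],
             value2 = al$w2 * values2[al$i2L] + (1 - al$w2) * values2[al$i2R])
}

# Twin-pair SNRs for all probes. Pairs must be same-sex with >= 2
# synchronized points after alignment.
snr_twin_pairs_all <- function(cohort, epsilon = 1e-8, snr_cap = 1e6) {
  B <- cohort$beta
  s <- cohort$samples
  tp_ids <- unique(stats::na.omit(s$twin_pair_id))
  Zs <- list(); skipped <- character()
  for (tp in tp_ids) {
    rows <- s[!is.na(s$twin_pair_id) & s$twin_pair_id == tp, ]
    inds <- unique(rows$individual_id)
    if (length(inds) != 2L ||
        length(unique(rows$sex)) != 1L) { skipped <- c(skipped, tp); next }
    r1 <- which(s$individual_id == inds[1])
    r2 <- which(s$individual_id == inds[2])
    al <- tryCatch(.twin_alignment(s$age[r1], s$age[r2]),
                   error = function(e) NULL)
    if (is.null(al) || length(al$age) < 2L) { skipped <- c(skipped, tp); next }
    V1 <- B[, r1[al$i1L], drop = FALSE] * rep(al$w1, each = nrow(B)) +
          B[, r1[al$i1R], drop = FALSE] * rep(1 - al$w1, each = nrow(B))
    V2 <- B[, r2[al$i2L], drop = FALSE] * rep(al$w2, each = nrow(B)) +
          B[, r2[al$i2R], drop = FALSE] * rep(1 - al$w2, each = nrow(B))
    Zs[[tp]] <- .row_snr((V1 + V2) / 2, abs(V1 - V2) / 2, epsilon, snr_cap)
  }
  if (length(Zs) == 0L)
    return(list(snr = rep(NA_real_, nrow(B)), per_pair = NULL,
                pairs = character(), skipped = skipped))
  Z <- do.call(cbind, Zs)
  rownames(Z) <- rownames(B)
  list(snr = rowMeans(Z), per_pair = Z, pairs = names(Zs), skipped = skipped)
}

#' Twin-pair SNR of one probe, averaged over pairs
#'
#' For each eligible same-sex twin pair the visit series are synchronized
#' with [align_twin_points()]; at each synchronized point the pair mean
#' `(v1 + v2) / 2` and the deviation `|v1 - v2| / 2` enter the capped
#' mean-of-ratios, and the probe value is the unweighted mean over pairs.
#'
#' @inheritParams snr_trajectories_probe
#' @return list with `snr` (`NA` if no eligible pair), `per_pair` and
#'   `skipped`.
#' @export
snr_twin_pairs_probe <- function(cohort, probe, epsilon = 1e-8,
                                 snr_cap = 1e6) {
  stopifnot(inherits(cohort, "meth_cohort"), probe %in% rownames(cohort$beta))
  all <- snr_twin_pairs_all(subset_cohort(cohort, probes = probe),
                            epsilon, snr_cap)
  list(snr = unname(all$snr[1]),
       per_pair = if (is.null(all$per_pair)) numeric() else all$per_pair[1, ],
       skipped = all$skipped)
}

# Cloud SNRs (pooled points, longitudinal structure ignored) for all probes.
snr_cloud_all <- function(cohort, epsilon = 1e-8, snr_cap = 1e6,
                          half_width = 5) {
  W <- row_window_means(cohort$beta, cohort$samples$age, half_width)
  .row_snr(W, abs(cohort$beta - W), epsilon, snr_cap)
}

#' Cloud SNR of one probe
#'
#' Pools all beta values of the probe, ignoring individual and longitudinal
#' attributes; the reference level at each point is the 10-year
#' sliding-window mean and the deviation is the absolute difference from
#' it. Same epsilon/cap policy as [snr_trajectory()].
#'
#' @inheritParams snr_trajectories_probe
#' @param half_width sliding-window half width in years.
#' @return a single non-negative number.
#' @export
snr_cloud_probe <- function(cohort, probe, epsilon = 1e-8, snr_cap = 1e6,
                            half_width = 5) {
  stopifnot(inherits(cohort, "meth_cohort"), probe %in% rownames(cohort$beta))
  if (ncol(cohort$beta) < 2L) stop("cloud SNR requires at least 2 samples")
  unname(snr_cloud_all(subset_cohort(cohort, probes = probe),
                       epsilon, snr_cap, half_width)[1])
}

#' Deterministic vs stochastic call from an SNR pair
#'
#' A probe is called deterministic when its trajectory SNR strictly exceeds
#' its cloud SNR (`log10` ratio > 0): the spread between individual
#' trajectories, not within-trajectory fluctuation, dominates the
#' cross-sectional variance. Equality maps to stochastic.
#'
#' @param snr_trajectories,snr_cloud numeric vectors of probe-level SNRs.
#' @return character vector `"deterministic"`/`"stochastic"` (`NA` where
#'   either SNR is not assessable).
#' @export
classify_determinism <- function(snr_trajectories, snr_cloud) {
  ifelse(is.na(snr_trajectories) | is.na(snr_cloud), NA_character_,
         ifelse(snr_trajectories > snr_cloud, "deterministic", "stochastic"))
}

#' SNR profile of every probe in a longitudinal cohort
#'
#' Computes the three probe-level signal-to-noise statistics (individual
#' trajectories, twin pairs, pooled cloud), the key quantifier
#' `log10(SNR_trajectories / SNR_cloud)` and the deterministic/stochastic
#' call.
#'
#' @param cohort a longitudinal [meth_cohort()] (one sex stratum for the
#'   published design; the function itself does not stratify).
#' @inheritParams snr_cloud_probe
#' @return data.frame with one row per probe: `probe_id`,
#'   `snr_trajectories`, `snr_twin_pairs` (`NA` without eligible pairs),
#'   `snr_cloud`, `log10_ratio`, `call`. The ids of skipped individuals and
#'   twin pairs are attached as attributes `skipped_individuals` and
#'   `skipped_pairs`.
#' @export
snr_profiles <- function(cohort, epsilon = 1e-8, snr_cap = 1e6,
                         half_width = 5) {
  stopifnot(inherits(cohort, "meth_cohort"))
  tr <- snr_trajectories_all(cohort, epsilon, snr_cap)
  tw <- snr_twin_pairs_all(cohort, epsilon, snr_cap)
  cl <- snr_cloud_all(cohort, epsilon, snr_cap, half_width)
  lr <- ifelse(is.na(tr$snr) | is.na(cl) | tr$snr <= 0 | cl <= 0,
               NA_real_, log10(tr$snr / cl))
  out <- data.frame(probe_id = rownames(cohort$beta),
                    snr_trajectories = unname(tr$snr),
                    snr_twin_pairs = unname(tw$snr),
                    snr_cloud = unname(cl),
                    log10_ratio = unname(lr),
                    call = classify_determinism(tr$snr, cl))
  attr(out, "skipped_individuals") <- tr$skipped
  attr(out, "skipped_pairs") <- tw$skipped
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Supremum distance between the two empirical CDFs with the asymptotic
#' p-value, as used to compare SNR distributions between sexes.
#'
#' @param sample_a,sample_b numeric vectors.
#' @return list with `statistic` and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
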