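test_that("trajectory SNR reproduces the hand-worked example", {
  # OLS through (50,0.5),(60,0.7),(70,0.6): fit 0.3 + 0.005*age,
  # deviations 0.05, 0.1, 0.05, ratios 11, 6, 13 -> mean 10
  expect_equal(snr_trajectory(c(50, 60, 70), c(0.5, 0.7, 0.6)), 10)
  # an exact line has no deviations: capped
  expect_equal(snr_trajectory(c(50, 60, 70), c(0.5, 0.6, 0.7)), 1e6)
  # ratios are scale-invariant
  expect_equal(snr_trajectory(c(50, 60, 70), 2 * c(0.5, 0.7, 0.6)), 10)
  expect_error(snr_trajectory(c(50, 60), c(0.5, 0.6)), "ineligible")
  expect_error(snr_trajectory(c(50, 50, 60), c(0.5, 0.6, 0.7)), "ineligible")
})

test_that("probe-level trajectory SNR averages eligible individuals", {
  co <- toy_longitudinal(
    visits = list(i1 = c(50, 60, 70), i2 = c(55, 60, 65), i3 = c(50, 60)),
    values = list(i1 = c(0.5, 0.7, 0.6), i2 = c(0.41, 0.44, 0.41),
                  i3 = c(0.5, 0.6)))
  got <- snr_trajectories_probe(co, "cg_0001")
  z1 <- snr_trajectory(c(50, 60, 70), c(0.5, 0.7, 0.6))
  z2 <- snr_trajectory(c(55, 60, 65), c(0.41, 0.44, 0.41))
  expect_equal(got$snr, mean(c(z1, z2)))
  expect_equal(got$skipped, "i3")   # only two visits
  # vectorised path agrees with a naive lm() loop on generated data
  cog <- generate_cohort(cohort_config(dxs_panel(4, 4), 25, 4, c(48, 98), 3,
                                       seed = 501))
  prof <- snr_profiles(cog)
  sm <- cog$samples
  for (p in rownames(cog$beta)[c(1, 5)]) {
    zs <- sapply(split(seq_len(nrow(sm)), sm$individual_id), function(ii) {
      fit <- lm(cog$beta[p, ii] ~ sm$age[ii])
      dev <- abs(resid(fit))
      keep <- dev >= 1e-8
      if (!any(keep)) 1e6 else min(mean(fitted(fit)[keep] / dev[keep]), 1e6)
    })
    expect_equal(prof$snr_trajectories[prof$probe_id == p], mean(zs),
                 tolerance = 1e-10)
  }
})

test_that("twin alignment interpolates interior points and never extrapolates", {
  al <- align_twin_points(c(60, 70), c(0.4, 0.6), 65, 0.55)
  expect_equal(al$age, 65)
  expect_equal(al$value1, 0.5)    # linear interpolation of twin A
  expect_equal(al$value2, 0.55)
  # identical ages: identity alignment
  al2 <- align_twin_points(c(50, 60), c(0.1, 0.2), c(50, 60), c(0.3, 0.4))
  expect_equal(al2$value1, c(0.1, 0.2))
  expect_equal(al2$value2, c(0.3, 0.4))
  # a visit before the other twin's first age is dropped (no
  # extrapolation); interior ages of both spans are kept
  al3 <- align_twin_points(c(60, 70), c(0.4, 0.6), c(55, 65), c(0.5, 0.55))
  expect_equal(al3$age, c(60, 65))
  expect_equal(al3$value2[1], 0.525)   # twin B interpolated at 60
})

test_that("twin-pair SNR reproduces the hand-worked example", {
  co <- toy_longitudinal(
    visits = list(i1 = c(60, 70), i2 = c(60, 70),
                  i3 = c(60, 70), i4 = c(60, 70)),
    values = list(i1 = c(0.6, 0.7), i2 = c(0.4, 0.5),
                  i3 = c(0.55, 0.55), i4 = c(0.55, 0.55)),
    pairs = list(tp1 = c("i1", "i2"), tp2 = c("i3", "i4")))
  got <- snr_twin_pairs_probe(co, "cg_0001")
  # pair 1: means 0.5, 0.6; deviations 0.1, 0.1 -> (5 + 6)/2 = 5.5
  expect_equal(unname(got$per_pair[["tp1"]]), 5.5)
  # identical twins: zero deviations -> capped
  expect_equal(unname(got$per_pair[["tp2"]]), 1e6)
  # probe value is the unweighted mean over pairs
  expect_equal(got$snr, mean(c(5.5, 1e6)))
  # a pair with a single synchronizable point is skipped
  co2 <- toy_longitudinal(
    visits = list(i1 = c(60, 70), i2 = 65),
    values = list(i1 = c(0.4, 0.6), i2 = 0.55),
    pairs = list(tp1 = c("i1", "i2")))
  got2 <- snr_twin_pairs_probe(co2, "cg_0001")
  expect_true(is.na(got2$snr))
  expect_equal(got2$skipped, "tp1")
})

test_that("cloud SNR pools points against sliding-window means", {
  co <- toy_cohort(c(0.4, 0.6), ages = c(50, 52))
  # both samples share one window: means 0.5, deviations 0.1 -> SNR 5
  expect_equal(snr_cloud_probe(co, "cg_0001"), 5)
  co2 <- toy_cohort(rep(0.3, 6), ages = seq(40, 90, 10))
  expect_equal(snr_cloud_probe(co2, "cg_0001"), 1e6)
  # permutation invariance
  set.seed(502)
  ages <- runif(50, 20, 80)
  vals <- runif(50, 0.2, 0.8)
  perm <- sample(50)
  expect_equal(snr_cloud_probe(toy_cohort(vals, ages), "cg_0001"),
               snr_cloud_probe(toy_cohort(vals[perm], ages[perm]), "cg_0001"),
               tolerance = 1e-12)
})

test_that("determinism calls follow the strict SNR-ratio boundary", {
  expect_equal(classify_determinism(10, 1), "deterministic")
  expect_equal(classify_determinism(0.8, 1), "stochastic")
  expect_equal(classify_determinism(1, 1), "stochastic")
  expect_equal(classify_determinism(NA, 1), NA_character_)
})

test_that("divergence and random-walk cohorts separate in SNR space", {
  co <- generate_cohort(cohort_config(dxs_panel(60, 60), 150, 4,
                                      c(48, 98), 3, seed = 503))
  prof <- snr_profiles(co)
  div <- grepl("^div", prof$probe_id)
  expect_gte(mean(prof$call[div] == "deterministic"), 0.9)
  # random-walk probes sit near the ratio boundary, far below divergence
  expect_lt(abs(median(prof$log10_ratio[!div])), 0.2)
  expect_gt(median(prof$log10_ratio[div]),
            median(prof$log10_ratio[!div]) + 0.5)
})

test_that("twin SNR lies between trajectory and cloud SNR on divergence data", {
  co <- generate_cohort(cohort_config(dxs_panel(50, 0), 150, 4, c(48, 98), 3,
                                      twin_fraction = 80 / 150, seed = 504))
  prof <- snr_profiles(co)
  expect_gt(median(prof$snr_trajectories), median(prof$snr_twin_pairs))
  expect_gt(median(prof$snr_twin_pairs), median(prof$snr_cloud))
})

test_that("the KS comparison matches ECDF enumeration", {
  expect_equal(ks_compare(1:10, 1:10)$statistic, 0)
  expect_equal(ks_compare(1:5, 11:15)$statistic, 1)
  expect_equal(ks_compare(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  set.seed(505)
  for (rep in 1:10) {
    x <- rnorm(30)
    y <- rnorm(40, 0.3)
    expect_equal(ks_compare(x, y)$statistic, ks_stat_oracle(x, y),
                 tolerance = 1e-12)
  }
})
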