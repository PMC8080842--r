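test_that("the seed fully determines the generated cohort", {
  cfg <- cohort_config(dxs_panel(5, 5), 20, 3, c(48, 98), 3,
                       twin_fraction = 0.4, seed = 401)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$samples, b$samples)
  c2 <- generate_cohort(cohort_config(dxs_panel(5, 5), 20, 3, c(48, 98), 3,
                                      twin_fraction = 0.4, seed = 402))
  expect_false(identical(a$beta, c2$beta))
})

test_that("zero-noise divergence probes lie exactly on the trend line", {
  probes <- probe_set(2, trend_spec("linear", k = 0.002, b = 0.2),
                      noise_spec("additive_constant", 0, "divergence",
                                 divergence_sd = 0))
  co <- generate_cohort(cohort_config(probes, 30, 4, c(30, 90), 3,
                                      seed = 403))
  expected <- 0.002 * co$samples$age + 0.2
  expect_equal(unname(co$beta[1, ]), expected, tolerance = 1e-12)
  expect_equal(unname(co$beta[2, ]), expected, tolerance = 1e-12)
})

test_that("generated betas are clipped and dimensions are as configured", {
  cfg <- cohort_config(dxs_panel(3, 3), 25, 4, c(48, 98), 3,
                       twin_fraction = 0.5, seed = 404)
  co <- generate_cohort(cfg)
  expect_equal(dim(co$beta), c(6, 100))
  expect_true(all(co$beta >= 1e-6 & co$beta <= 1 - 1e-6))
  # twins share sex and visit ages
  sm <- co$samples
  for (tp in unique(na.omit(sm$twin_pair_id))) {
    pair <- sm[!is.na(sm$twin_pair_id) & sm$twin_pair_id == tp, ]
    expect_length(unique(pair$sex), 1)
    ages <- split(pair$age, pair$individual_id)
    expect_equal(ages[[1]], ages[[2]])
  }
})

test_that("divergence probes show variance growth with age", {
  co <- generate_cohort(cohort_config(dxs_panel(5, 0), 150, 4, c(48, 98), 3,
                                      seed = 405))
  vr <- sigma2_age_regression(co)
  expect_true(all(vr$slope > 0))
  expect_true(all(vr$p_value < 1e-4))
})

test_that("cv_constant probes have age-flat CV2 but age-growing sigma2", {
  probes <- scaling_panel(3, 0)
  co <- generate_cohort(cohort_config(probes, 600, age_range = c(14, 94),
                                      sex_ratio = 1, seed = 406))
  ages <- co$samples$age
  for (i in 1:3) {
    s <- pointwise_sigma2(ages, co$beta[i, ])
    cv2 <- s$sigma2 / s$window_mean^2
    expect_gt(regress_on_age(ages, cv2)$p_value, 0.01)
    expect_lt(regress_on_age(ages, s$sigma2)$p_value, 0.01)
  }
})

test_that("random-walk increments have variance linear in the lag", {
  probes <- probe_set(40, trend_spec("constant", level = 0.5),
                      noise_spec("additive_constant", 0, "random_walk",
                                 step_sd = 0.02))
  co <- generate_cohort(cohort_config(probes, 80, 5, c(48, 98), 3,
                                      seed = 407))
  idx <- split(seq_len(nrow(co$samples)), co$samples$individual_id)
  lag_var <- sapply(1:4, function(lag) {
    incs <- unlist(lapply(idx, function(ii) {
      v <- co$beta[, ii, drop = FALSE]
      v[, (1 + lag):5] - v[, 1:(5 - lag), drop = FALSE]
    }))
    var(incs)
  })
  expect_equal(lag_var / lag_var[1], 1:4, tolerance = 0.15)
})

test_that("twin trajectories are closer within pairs than between pairs", {
  probes <- dxs_panel(10, 0)
  co <- generate_cohort(cohort_config(probes, 60, 4, c(48, 98), 3,
                                      twin_fraction = 1, seed = 408))
  sm <- co$samples
  slope_of <- function(ii, p) {
    a <- sm$age[ii]
    sum((a - mean(a)) * (co$beta[p, ii] - mean(co$beta[p, ii]))) /
      sum((a - mean(a))^2)
  }
  idx <- split(seq_len(nrow(sm)), sm$individual_id)
  prop_closer <- sapply(1:10, function(p) {
    slopes <- vapply(idx, slope_of, numeric(1), p = p)
    pair_of <- vapply(split(sm$twin_pair_id, sm$individual_id),
                      `[`, character(1), 1)[names(idx)]
    intra <- sapply(unique(pair_of), function(tp) {
      s <- slopes[pair_of == tp]
      abs(s[1] - s[2])
    })
    inter <- abs(outer(slopes, slopes, "-"))
    median(intra) < median(inter[upper.tri(inter)])
  })
  expect_gte(mean(prop_closer), 0.9)
})

test_that("invalid configurations are rejected with the probe named", {
  runaway <- probe_set(1, trend_spec("linear", k = 0.02, b = 0.5),
                       noise_spec(), prefix = "bad")
  expect_error(cohort_config(runaway, 10, age_range = c(14, 94), seed = 1),
               "bad_0001.*exits \\[0, 1\\]")
  neg <- probe_set(1, trend_spec("power", a = -0.1, alpha = 0.3),
                   noise_spec(), prefix = "neg")
  expect_error(cohort_config(neg, 10, seed = 1), "strictly positive")
  expect_error(cohort_config(dxs_panel(1, 0), 10, 30, c(48, 98), 3, seed = 1),
               "schedule")
})

test_that("the truth table echoes the configuration", {
  probes <- c(probe_set(1, trend_spec("power", a = 0.13, alpha = 0.3),
                        noise_spec("cv_constant", 0.05), "pow"),
              dxs_panel(2, 3))
  cfg <- cohort_config(probes, 10, seed = 409)
  tt <- truth_table(cfg)
  expect_equal(nrow(tt), 6)
  expect_equal(tt$law[1], "power")
  expect_equal(tt$alpha[1], 0.3)
  expect_true(is.na(tt$k[1]))
  expect_equal(table(tt$mechanism)[["random_walk"]], 3)
  expect_equal(table(tt$mechanism)[["divergence"]], 3)
  empty <- cohort_config(setNames(list(), character()), 10, seed = 1)
  expect_equal(nrow(truth_table(empty)), 0)
})
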