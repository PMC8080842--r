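make_admp_cohort <- function(seed = 601) {
  # 90 noise-only probes around a flat level plus 10 strong linear trends
  probes <- c(
    probe_set(90, trend_spec("constant", level = 0.4),
              noise_spec("additive_constant", 0.02, divergence_sd = 0),
              "null"),
    probe_set(10, trend_spec("linear", k = 0.004, b = 0.2),
              noise_spec("additive_constant", 0.02, divergence_sd = 0),
              "trend"))
  generate_cohort(cohort_config(probes, 800, age_range = c(14, 94),
                                seed = seed))
}

test_that("aDMP selection applies the slope and R2-percentile gates", {
  co <- make_admp_cohort()
  sel <- select_admps(co)
  # brute-force reapplication of both gates per sex
  for (sx in c("male", "female")) {
    cs <- subset_cohort(co, co$samples$sex == sx)
    slopes <- r2 <- numeric(nrow(cs$beta))
    for (i in seq_len(nrow(cs$beta))) {
      f <- ols_oracle(cs$samples$age, cs$beta[i, ])
      slopes[i] <- f$slope; r2[i] <- f$r_squared
    }
    want <- abs(slopes) > 0.001 & r2 > quantile(r2, 0.99)
    expect_equal(sel$admp[sel$sex == sx], unname(want))
  }
  # the percentile gate keeps roughly the top 1%
  expect_lte(sum(sel$admp), 6)
  expect_true(all(grepl("^trend", sel$probe_id[sel$admp])))
  # a probe with slope below the gate is rejected regardless of R2
  weak <- toy_cohort(matrix(rep(0.3 + 5e-4 * seq(20, 80, length = 400),
                                each = 12), 12, byrow = FALSE),
                     ages = seq(20, 80, length = 400))
  sel2 <- select_admps(weak, sexes = "female")
  expect_false(any(sel2$admp))
})

test_that("aDaVMP selection keeps aDMPs with age-dependent variance", {
  probes <- c(
    probe_set(5, trend_spec("linear", k = 0.004, b = 0.15),
              noise_spec("cv_constant", 0.08, divergence_sd = 0), "grow"),
    probe_set(5, trend_spec("linear", k = 0.004, b = 0.15),
              noise_spec("additive_constant", 0.01, divergence_sd = 0),
              "const"))
  co <- generate_cohort(cohort_config(probes, 1000, age_range = c(14, 94),
                                      sex_ratio = 1, seed = 602))
  admps <- data.frame(probe_id = rownames(co$beta), sex = "male",
                      admp = TRUE)
  sel <- select_adavmps(co, admps, sexes = "male")
  expect_true(all(sel$adavmp[grepl("^grow", sel$probe_id)]))
  expect_false(any(sel$adavmp[grepl("^const", sel$probe_id)]))
  empty <- select_adavmps(co, data.frame(probe_id = character(),
                                         sex = character(),
                                         admp = logical()))
  expect_equal(nrow(empty), 0)
})

test_that("direction classes follow the slope sign pairs", {
  expect_equal(classify_direction(c(1, -1, -1, 1), c(1, -1, 1, -1)),
               c("up_up", "down_down", "down_up", "up_down"))
  expect_error(classify_direction(0, 1), "zero slope")
})

test_that("noise-scaling inference recovers the generating law", {
  co <- generate_cohort(cohort_config(scaling_panel(10, 10, 10), 700,
                                      age_range = c(14, 94), sex_ratio = 1,
                                      seed = 603))
  ns <- infer_noise_scaling(co, rownames(co$beta))
  grp <- sub("_.*", "", ns$probe_id)
  expect_gte(mean(ns$law[grp == "cv"] == "quadratic", na.rm = TRUE), 0.9)
  expect_gte(mean(ns$law[grp == "fa"] == "linear", na.rm = TRUE), 0.8)
  expect_gte(mean(is.na(ns$law[grp == "cu"])), 0.6)
  expect_true(all(ns$orientation == "beta"))
})

test_that("opposite level/variance trends flip the normalisation", {
  # demethylating probe whose variance still grows: noise scales with 1-beta
  probes <- probe_set(5, trend_spec("linear", orientation = "complement"),
                      noise_spec("cv_constant", 0.08, divergence_sd = 0))
  co <- generate_cohort(cohort_config(probes, 700, age_range = c(14, 94),
                                      sex_ratio = 1, seed = 604))
  ns <- infer_noise_scaling(co, rownames(co$beta))
  expect_true(all(ns$orientation == "one_minus_beta"))
  expect_gte(mean(ns$law == "quadratic", na.rm = TRUE), 0.8)
})
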