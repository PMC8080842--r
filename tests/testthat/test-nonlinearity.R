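test_that("noiseless generating laws are recovered exactly", {
  ages <- seq(20, 90, length.out = 50)
  lin <- fit_linear(ages, 0.2 + 0.003 * ages)
  expect_equal(lin$k, 0.003, tolerance = 1e-10)
  expect_equal(lin$b, 0.2, tolerance = 1e-10)
  expect_equal(lin$r_squared, 1, tolerance = 1e-10)
  pow <- fit_power(ages, 0.08 * ages^0.5)
  expect_equal(pow$alpha, 0.5, tolerance = 1e-10)
  expect_equal(exp(pow$p), 0.08, tolerance = 1e-10)
  expect_equal(pow$r_squared, 1, tolerance = 1e-10)
  ex <- fit_exponential(ages, 0.1 * exp(0.01 * ages))
  expect_equal(ex$gamma, 0.01, tolerance = 1e-10)
  expect_equal(exp(ex$q), 0.1, tolerance = 1e-10)
  expect_equal(ex$r_squared, 1, tolerance = 1e-10)
})

test_that("constant responses give zero R2 and flat parameters", {
  ages <- seq(20, 90, length.out = 30)
  expect_equal(fit_linear(ages, rep(0.4, 30))$r_squared, 0)
  pw <- fit_power(ages, rep(0.4, 30))
  expect_equal(pw$alpha, 0, tolerance = 1e-12)
  expect_equal(exp(pw$p), 0.4, tolerance = 1e-12)
  expect_equal(pw$r_squared, 0)
  ex <- fit_exponential(ages, rep(0.4, 30))
  expect_equal(ex$gamma, 0, tolerance = 1e-12)
  expect_equal(ex$r_squared, 0)
})

test_that("back-transformed fits match a hand oracle on random data", {
  set.seed(701)
  ages <- runif(40, 15, 90)
  betas <- runif(40, 0.1, 0.9)
  pw <- fit_power(ages, betas)
  o <- ols_oracle(log(ages), log(betas))
  expect_equal(pw$alpha, unname(o$slope), tolerance = 1e-10)
  fitted <- exp(unname(o$intercept)) * ages^unname(o$slope)
  expect_equal(pw$r_squared,
               1 - sum((betas - fitted)^2) / sum((betas - mean(betas))^2),
               tolerance = 1e-10)
  ex <- fit_exponential(ages, betas)
  o2 <- ols_oracle(ages, log(betas))
  expect_equal(ex$gamma, unname(o2$slope), tolerance = 1e-10)
})

test_that("a truly linear trend is scored worse by the power model", {
  set.seed(702)
  ages <- runif(700, 14, 94)
  betas <- 0.3 + 0.002 * ages + rnorm(700, 0, 0.01)
  ch <- choose_orientation(ages, betas)
  expect_lt(ch$fits$power$r_squared, ch$fits$linear$r_squared)
})

test_that("the complementary-beta rule picks the better-fitting orientation", {
  ages <- seq(20, 90, length.out = 60)
  # demethylation following an exact power law: the beta-scale log fits
  # score poorly, the complement refit is exact
  co <- choose_orientation(ages, 1 - 0.025 * ages^0.8)
  expect_equal(co$orientation, "complement")
  expect_equal(co$fits$power$alpha, 0.8, tolerance = 1e-10)
  expect_equal(co$fits$power$r_squared, 1, tolerance = 1e-10)
  bo <- choose_orientation(ages, 0.08 * ages^0.4)
  expect_equal(bo$orientation, "beta")
  # symmetric noise around 0.5: no 5% advantage either way -> default beta
  set.seed(703)
  sym <- choose_orientation(ages, 0.5 + rnorm(60, 0, 0.01))
  expect_equal(sym$orientation, "beta")
})

test_that("trend classification follows the 5% margins", {
  fits <- function(l, p, e)
    list(linear = list(r_squared = l), power = list(r_squared = p),
         exponential = list(r_squared = e))
  expect_equal(classify_trend(fits(0.5, 0.6, 0.4)), "nonlinear_power")
  expect_equal(classify_trend(fits(0.5, 0.4, 0.6)), "nonlinear_exponential")
  expect_equal(classify_trend(fits(0.5, 0.51, 0.4)), "weak_nonlinear")
  expect_equal(classify_trend(fits(0.5, 0.4, 0.41)), "linear")
  # ties between the nonlinear fits go to the power law
  expect_equal(classify_trend(fits(0.5, 0.6, 0.6)), "nonlinear_power")
})

test_that("classification is invariant to duplicating every sample", {
  set.seed(704)
  ages <- runif(200, 14, 94)
  betas <- pmin(pmax(0.1 * ages^0.35 + rnorm(200, 0, 0.02), 1e-6), 1)
  one <- choose_orientation(ages, betas)
  two <- choose_orientation(rep(ages, 2), rep(betas, 2))
  expect_equal(classify_trend(one$fits), classify_trend(two$fits))
  expect_equal(one$fits$power$alpha, two$fits$power$alpha, tolerance = 1e-12)
})

test_that("trend-model fitting rejects non-positive ages", {
  co <- toy_cohort(runif(10, 0.3, 0.5), ages = seq(0, 90, length.out = 10))
  expect_error(fit_trend_models(co), "strictly positive")
})
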