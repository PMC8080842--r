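#' Ordinary least-squares regression of a quantity on age
#'
#' Fits `y = slope * age + intercept` by OLS and reports the two-sided
#' t-test p-value for the null hypothesis of zero slope. This is the single
#' statistical test used throughout the pipeline for age dependence of
#' methylation level, variance, CV-squared and Fano series.
#'
#' Degenerate responses are handled explicitly: a response with (numerically)
#' zero variance has slope 0, R-squared 0 and p-value 1; a response fitted
#' exactly by a non-flat line has p-value 0.
#'
#' @param ages numeric vector of ages; must not all be equal.
#' @param y numeric response of the same length, `n >= 3`.
#' @return list with `slope`, `intercept`, `p_value`, `r_squared`, `n`.
#' @export
regress_on_age <- function(ages, y) {
  stopifnot(is.numeric(ages), is.numeric(y), length(ages) == length(y))
  n <- length(ages)
  if (n < 3L) stop("age regression requires at least 3 samples")
  if (!all(is.finite(ages)) || !all(is.finite(y)))
    stop("non-finite values in age regression input")
  fit <- row_age_regression(matrix(y, nrow = 1), ages)
  list(slope = fit$slope, intercept = fit$intercept,
       p_value = fit$p_value, r_squared = fit$r_squared, n = n)
}

# Vectorised per-row OLS on a shared covariate. Y is probes x samples.
# Returns a data.frame with slope, intercept, r_squared, p_value per row.
# Closed-form normal equations; tolerances guard exact-fit and constant
# responses (see regress_on_age).
row_age_regression <- function(Y, x) {
  stopifnot(is.matrix(Y), ncol(Y) == length(x))
  n <- length(x)
  cx <- x - mean(x)
  sxx <- sum(cx^2)
  if (sxx <= 0) stop("degenerate design: all ages equal")
  slope <- as.vector(Y %*% cx) / sxx
  ybar <- rowMeans(Y)
  intercept <- ybar - slope * mean(x)
  resid <- Y - outer(slope, x) - intercept
  rss <- rowSums(resid^2)
  tss <- rowSums((Y - ybar)^2)
  # scale-aware tolerance: responses constant to machine precision
  tiny <- pmax(tss, rowSums(Y^2)) * 1e-14
  r2 <- ifelse(tss > tiny, 1 - rss / tss, 0)
  r2 <- pmin(pmax(r2, 0), 1)
  se2 <- rss / pmax(n - 2L, 1L) / sxx
  tstat <- ifelse(se2 > 0, slope / sqrt(se2), NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  # exact fits: se == 0 -> reject unless the slope itself is zero
  exact <- !is.finite(tstat) | rss <= tiny
  p[exact] <- ifelse(abs(slope[exact]) > sqrt(tiny[exact] / sxx), 0, 1)
  data.frame(slope = slope, intercept = intercept, r_squared = r2,
             p_value = p, n = n, row.names = rownames(Y))
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment: p-values are sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and returned in input
#' order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
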