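#' Sliding-window mean over age
#'
#' For each sample at age `a`, returns the mean of `values` over all samples
#' whose age lies in the closed interval `[a - half_width, a + half_width]`.
#' The window is evaluated at every sample's own age, so it always contains
#' at least the sample itself; windows at the edges of the age range are
#' truncated, not padded.
#'
#' @param ages numeric vector of ages in years.
#' @param values numeric vector, same length as `ages`.
#' @param half_width half of the window width in years; the default of 5
#'   years gives the conventional 10-year sliding window.
#' @return numeric vector of per-sample window means, in input order.
#' @export
sliding_window_mean <- function(ages, values, half_width = 5) {
  stopifnot(length(ages) == length(values), length(ages) >= 1,
            is.numeric(ages), is.numeric(values), half_width > 0)
  drop(row_window_means(matrix(values, nrow = 1), ages, half_width))
}

# Window index bounds in age-sorted space. Returns the permutation `order`
# and, for each sorted sample, the first (lo) and last (hi) sorted index
# inside its closed window. Bounds are inclusive on both ends.
window_bounds <- function(ages, half_width) {
  o <- order(ages)
  a <- ages[o]
  lo <- findInterval(a - half_width, a, left.open = TRUE) + 1L
  hi <- findInterval(a + half_width, a)
  list(order = o, lo = lo, hi = hi)
}

# Row-wise sliding-window means for a probes x samples matrix. Uses one
# cumulative sum per row over the age-sorted columns, so cost is
# O(probes x samples) regardless of window width.
row_window_means <- function(mat, ages, half_width = 5) {
  stopifnot(is.matrix(mat), ncol(mat) == length(ages))
  wb <- window_bounds(ages, half_width)
  ms <- mat[, wb$order, drop = FALSE]
  cs <- if (nrow(ms) == 1L) matrix(cumsum(ms), nrow = 1) else
    t(apply(ms, 1L, cumsum))
  cs0 <- cbind(0, cs)
  means_sorted <- (cs0[, wb$hi + 1L, drop = FALSE] -
                   cs0[, wb$lo, drop = FALSE]) /
    rep(wb$hi - wb$lo + 1L, each = nrow(ms))
  out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  out[, wb$order] <- means_sorted
  out
}
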