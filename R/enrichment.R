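#' Fisher's exact test on a 2x2 table
#'
#' The odds ratio is reported as the sample cross-product `(a*d)/(b*c)`
#' (`Inf` when `b*c == 0` with `a*d > 0`; `NA` when both products vanish);
#' the p-value is the exact hypergeometric test, two-sided by the
#' minimum-likelihood convention.
#'
#' @param a,b,c,d non-negative integer cell counts: in-list and
#'   in-category, in-list and out, background and in-category, background
#'   and out.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(a, b, c, d, alternative = "two.sided") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf else NA_real_
  p <- stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE),
                          alternative = alternative)$p.value
  list(odds_ratio = or, p_value = p)
}

#' Genomic-context enrichment of a probe list
#'
#' Tests whether a probe list is over-represented in each CpG-island
#' relation, gene-region group and the enhancer flag, by Fisher's exact
#' test against the background of all other probes in the analysed
#' universe. Probes without annotation are excluded from both margins (and
#' reported in the `n_unannotated` attribute).
#'
#' @param probes character vector, the probe list (must be a subset of
#'   `universe`).
#' @param universe character vector of all analysed probes.
#' @param annotation data.frame from [read_probe_annotation()].
#' @param alternative passed to [fisher_exact()].
#' @return data.frame with one row per category level: `field`,
#'   `category`, counts `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @export
enrich_probe_list <- function(probes, universe, annotation,
                              alternative = "two.sided") {
  if (!all(probes %in% universe))
    stop("probe list must be a subset of the universe")
  ann_ids <- annotation$probe_id
  unannotated <- setdiff(universe, ann_ids)
  universe <- intersect(universe, ann_ids)
  probes <- intersect(probes, ann_ids)
  idx <- match(universe, ann_ids)
  in_list <- universe %in% probes
  cats <- list(island_relation = .island_levels,
               region_group = .region_levels,
               enhancer = c(TRUE, FALSE))
  rows <- list()
  for (field in names(cats)) {
    vals <- annotation[[field]][idx]
    for (lv in cats[[field]]) {
      inc <- vals == lv
      a <- sum(in_list & inc);  b <- sum(in_list & !inc)
      c_ <- sum(!in_list & inc); d <- sum(!in_list & !inc)
      ft <- fisher_exact(a, b, c_, d, alternative)
      rows[[length(rows) + 1L]] <-
        data.frame(field = field, category = as.character(lv),
                   a = a, b = b, c = c_, d = d,
                   odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- length(unannotated)
  out
}
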