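#' Methylation cohort container
#'
#' Bundles a probes x samples matrix of methylation beta values with the
#' per-sample metadata the pipeline needs (age, sex, individual, optional
#' twin pair, dataset label). Residualised cohorts (after cell-composition
#' adjustment) use the same container with `value_type = "residual"`, whose
#' values are non-negative but not bounded by 1.
#'
#' @param beta numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `individual_id`,
#'   `age`, `sex` (`"male"`/`"female"`), optional `twin_pair_id`
#'   (NA for untwinned individuals) and `dataset`.
#' @param value_type `"beta"` (values constrained to `[0, 1]`) or
#'   `"residual"`.
#' @return an object of class `meth_cohort`: a list with elements `beta`,
#'   `samples`, `value_type`.
#' @export
meth_cohort <- function(beta, samples, value_type = c("beta", "residual")) {
  value_type <- match.arg(value_type)
  stopifnot(is.matrix(beta), is.numeric(beta), is.data.frame(samples))
  if (is.null(rownames(beta)) || anyNA(rownames(beta)) ||
      any(rownames(beta) == "") || anyDuplicated(rownames(beta)))
    stop("beta matrix must have unique, non-missing probe ids as rownames")
  req <- c("sample_id", "individual_id", "age", "sex")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (!"twin_pair_id" %in% names(samples)) samples$twin_pair_id <- NA_character_
  if (!"dataset" %in% names(samples)) samples$dataset <- "unspecified"
  samples$sample_id <- as.character(samples$sample_id)
  samples$individual_id <- as.character(samples$individual_id)
  samples$twin_pair_id <- as.character(samples$twin_pair_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (is.null(colnames(beta)) || !identical(colnames(beta), samples$sample_id)) {
    extra <- setdiff(colnames(beta), samples$sample_id)
    absent <- setdiff(samples$sample_id, colnames(beta))
    if (length(extra) || length(absent))
      stop("sample reconciliation failed; in matrix but not sheet: [",
           paste(extra, collapse = ", "), "]; in sheet but not matrix: [",
           paste(absent, collapse = ", "), "]")
    beta <- beta[, samples$sample_id, drop = FALSE]
  }
  if (!all(is.finite(beta))) stop("non-finite values in beta matrix")
  if (value_type == "beta" && (any(beta < 0) || any(beta > 1))) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s'",
                 rownames(beta)[bad[1]], colnames(beta)[bad[2]]))
  }
  if (!all(is.finite(samples$age)) || any(samples$age < 0))
    stop("sample ages must be finite and non-negative")
  if (!all(samples$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  paired <- samples[!is.na(samples$twin_pair_id),
                    c("individual_id", "twin_pair_id", "sex")]
  if (nrow(paired)) {
    paired <- unique(paired)
    for (tp in split(paired, paired$twin_pair_id)) {
      if (length(unique(tp$individual_id)) != 2L)
        stop("twin_pair_id '", tp$twin_pair_id[1],
             "' must be shared by exactly two individuals")
      if (length(unique(tp$sex)) != 1L)
        warning("twin_pair_id '", tp$twin_pair_id[1],
                "' pairs individuals of different sex; the pair will be ",
                "excluded from twin-based statistics")
    }
  }
  structure(list(beta = beta, samples = samples, value_type = value_type),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(paste0("meth_cohort: %d probes x %d samples (%s values)\n",
                     "  %d individuals, %d twin pairs, ages %.1f-%.1f\n"),
              nrow(x$beta), ncol(x$beta), x$value_type,
              length(unique(x$samples$individual_id)),
              length(unique(stats::na.omit(x$samples$twin_pair_id))),
              min(x$samples$age), max(x$samples$age)))
  invisible(x)
}

#' Subset a cohort by samples and/or probes
#'
#' @param cohort a [meth_cohort()].
#' @param samples logical/integer/character index into the samples.
#' @param probes index into the probes (default: keep all).
#' @return a `meth_cohort` restricted to the selection.
#' @export
subset_cohort <- function(cohort, samples = NULL, probes = NULL) {
  stopifnot(inherits(cohort, "meth_cohort"))
  b <- cohort$beta
  s <- cohort$samples
  if (!is.null(probes)) b <- b[probes, , drop = FALSE]
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, s$sample_id)
    b <- b[, samples, drop = FALSE]
    s <- s[samples, , drop = FALSE]
    rownames(s) <- NULL
  }
  # sex-restricted subsets can orphan a twin: degrade those to untwinned
  tp <- s$twin_pair_id
  if (any(!is.na(tp))) {
    n_ind <- tapply(s$individual_id, tp, function(v) length(unique(v)))
    orphan <- names(n_ind)[n_ind != 2L]
    s$twin_pair_id[s$twin_pair_id %in% orphan] <- NA_character_
  }
  meth_cohort(b, s, value_type = cohort$value_type)
}

.read_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a cohort from a beta matrix file and a sample sheet
#'
#' The beta matrix is delimited text (TSV or CSV by extension) whose first
#' column holds probe ids and whose remaining columns are samples. The
#' sample sheet is delimited text with at least `sample_id`,
#' `individual_id`, `age`, `sex`; optional `twin_pair_id`, `dataset`.
#' Matrix columns are reordered to sample-sheet order.
#'
#' @param beta_path,sample_sheet_path file paths.
#' @return a [meth_cohort()].
#' @export
read_cohort <- function(beta_path, sample_sheet_path) {
  raw <- .read_table(beta_path)
  if (ncol(raw) < 2L) stop("beta matrix file has no sample columns")
  probe_ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric beta at probe '%s', sample '%s'",
                   probe_ids[bad[1]], names(vals)[j]))
    out <- which(v < 0 | v > 1)
    if (length(out))
      stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s'",
                   probe_ids[out[1]], names(vals)[j]))
    vals[[j]] <- v
  }
  beta <- as.matrix(vals)
  rownames(beta) <- probe_ids
  sheet <- .read_table(sample_sheet_path)
  meth_cohort(beta, sheet)
}

#' Write a cohort to delimited text
#'
#' Values are written with 17 significant digits so that read/write round
#' trips are bit-stable.
#'
#' @param cohort a [meth_cohort()].
#' @param beta_path,sample_sheet_path output file paths (extension picks
#'   the delimiter, TSV default).
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, beta_path, sample_sheet_path) {
  stopifnot(inherits(cohort, "meth_cohort"))
  sep <- if (grepl("\\.csv$", beta_path, ignore.case = TRUE)) "," else "\t"
  chr <- formatC(cohort$beta, digits = 17, format = "g")
  df <- data.frame(probe_id = rownames(cohort$beta), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(cohort$beta))
  utils::write.table(df, beta_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  sep2 <- if (grepl("\\.tsv$|\\.txt$", sample_sheet_path,
                    ignore.case = TRUE)) "\t" else ","
  utils::write.table(cohort$samples, sample_sheet_path, sep = sep2,
                     row.names = FALSE, quote = FALSE)
  invisible(c(beta_path, sample_sheet_path))
}

.island_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                    "OpenSea")
.region_levels <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                    "3'UTR", "Intergenic")

#' Read a probe annotation table
#'
#' Expects delimited text with columns `probe_id`, `chromosome`, `position`
#' (1-based), `island_relation`, `region_group`, `enhancer`. Island and
#' gene-region tokens are validated against the closed Illumina-style
#' vocabularies; unknown tokens are rejected with their row number.
#'
#' @param path file path.
#' @return data.frame with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  ann <- .read_table(path)
  if (nrow(ann) == 0L) {
    ann <- data.frame(probe_id = character(), chromosome = character(),
                      position = integer(), island_relation = character(),
                      region_group = character(), enhancer = logical())
    return(ann)
  }
  req <- c("probe_id", "chromosome", "position", "island_relation",
           "region_group", "enhancer")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicated probe_id in annotation")
  bad <- which(!ann$island_relation %in% .island_levels)
  if (length(bad))
    stop(sprintf("unknown island_relation '%s' at row %d",
                 ann$island_relation[bad[1]], bad[1]))
  bad <- which(!ann$region_group %in% .region_levels)
  if (length(bad))
    stop(sprintf("unknown region_group '%s' at row %d",
                 ann$region_group[bad[1]], bad[1]))
  ann$enhancer <- as.logical(ann$enhancer)
  if (anyNA(ann$enhancer)) stop("enhancer column must be logical")
  ann
}

.cell_types <- c("CD8T", "CD4T", "NK", "Bcell", "Gran")

#' Read per-sample blood cell fractions
#'
#' Delimited text with `sample_id` plus the five reference blood cell
#' proportions `CD8T`, `CD4T`, `NK`, `Bcell`, `Gran`, each in `[0, 1]`.
#'
#' @param path file path.
#' @return data.frame of fractions.
#' @export
read_cell_fractions <- function(path) {
  cf <- .read_table(path)
  miss <- setdiff(c("sample_id", .cell_types), names(cf))
  if (length(miss))
    stop("cell fractions missing columns: ", paste(miss, collapse = ", "))
  for (ct in .cell_types) {
    if (any(cf[[ct]] < 0 | cf[[ct]] > 1, na.rm = TRUE))
      stop("cell fraction out of [0, 1] in column ", ct)
  }
  cf
}

#' Adjust methylation for blood cell composition
#'
#' Per probe (and, by default, separately within each sex), beta values are
#' regressed by OLS on the five cell-type proportions plus an intercept;
#' the residuals are then shifted up by the absolute value of the smallest
#' residual of that probe/stratum (no shift when the minimum is already
#' non-negative), so the adjusted values are non-negative. Collinear
#' covariate columns (e.g. identical fractions across samples) are dropped
#' via rank-revealing QR rather than raising an error.
#'
#' @param cohort a [meth_cohort()] of beta values.
#' @param fractions data.frame as returned by [read_cell_fractions()];
#'   every cohort sample must be present.
#' @param stratify_by_sex run the regression separately for males and
#'   females (default `TRUE`).
#' @return a `meth_cohort` with `value_type = "residual"`.
#' @export
adjust_for_cell_composition <- function(cohort, fractions,
                                        stratify_by_sex = TRUE) {
  stopifnot(inherits(cohort, "meth_cohort"))
  idx <- match(cohort$samples$sample_id, fractions$sample_id)
  if (anyNA(idx))
    stop("missing cell fractions for samples: ",
         paste(cohort$samples$sample_id[is.na(idx)], collapse = ", "))
  Fm <- as.matrix(fractions[idx, .cell_types])
  strata <- if (stratify_by_sex) split(seq_len(ncol(cohort$beta)),
                                       cohort$samples$sex)
            else list(all = seq_len(ncol(cohort$beta)))
  res <- cohort$beta
  for (ii in strata) {
    X <- cbind(intercept = 1, Fm[ii, , drop = FALSE])
    dec <- qr(X)
    rk <- dec$rank
    if (length(ii) < ncol(X) + 2L)
      stop(sprintf("stratum has %d samples; need at least %d for %d regressors",
                   length(ii), ncol(X) + 2L, ncol(X)))
    Q <- qr.Q(dec)[, seq_len(rk), drop = FALSE]
    B <- cohort$beta[, ii, drop = FALSE]
    R <- B - (B %*% Q) %*% t(Q)
    mn <- apply(R, 1L, min)
    R <- R + pmax(0, -mn)
    res[, ii] <- R
  }
  meth_cohort(res, cohort$samples, value_type = "residual")
}

#' Export probe positions as BED intervals
#'
#' Writes a 0-based half-open BED file (`position - 1`, `position`) for a
#' probe list, using coordinates from a probe annotation table.
#'
#' @param probes character vector of probe ids.
#' @param annotation data.frame from [read_probe_annotation()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_probe_bed <- function(probes, annotation, path) {
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx))
    stop("probes missing from annotation: ",
         paste(probes[is.na(idx)], collapse = ", "))
  bed <- data.frame(chrom = annotation$chromosome[idx],
                    start = annotation$position[idx] - 1L,
                    end = annotation$position[idx],
                    name = probes)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
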