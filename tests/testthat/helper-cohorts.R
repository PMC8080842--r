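# Small cohort builders used across test files.

# Wrap a beta matrix (or vector of betas for a single probe) as a
# cross-sectional cohort with one individual per sample.
toy_cohort <- function(beta, ages, sex = "female", dataset = "toy") {
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = 1,
                                       dimnames = list("cg_0001", NULL))
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg_%04d", seq_len(nrow(beta)))
  n <- ncol(beta)
  ids <- sprintf("s%03d", seq_len(n))
  colnames(beta) <- ids
  meth_cohort(beta, data.frame(
    sample_id = ids, individual_id = ids, age = ages,
    sex = rep_len(sex, n), twin_pair_id = NA_character_,
    dataset = dataset))
}

# Longitudinal cohort with explicit per-individual visit ages and values
# for a single probe. `visits` is a named list: individual -> ages;
# `values` the matching methylation values; `pairs` an optional named list
# twin_pair_id -> c(ind1, ind2).
toy_longitudinal <- function(visits, values, sex = NULL, pairs = NULL) {
  inds <- names(visits)
  if (is.null(sex)) sex <- setNames(rep("female", length(inds)), inds)
  rows <- do.call(rbind, lapply(inds, function(id)
    data.frame(individual_id = id, age = visits[[id]])))
  rows$sample_id <- sprintf("%s_v%d", rows$individual_id,
                            ave(seq_len(nrow(rows)), rows$individual_id,
                                FUN = seq_along))
  rows$sex <- sex[rows$individual_id]
  rows$twin_pair_id <- NA_character_
  if (!is.null(pairs))
    for (tp in names(pairs))
      rows$twin_pair_id[rows$individual_id %in% pairs[[tp]]] <- tp
  rows$dataset <- "toy_long"
  beta <- matrix(unlist(values, use.names = FALSE), nrow = 1,
                 dimnames = list("cg_0001", rows$sample_id))
  meth_cohort(beta, rows)
}

# The two default study panels (documented in the methods vignette).
dxs_trend <- function() trend_spec("linear", k = 0.001, b = 0.4)

dxs_panel <- function(n_div, n_rw, noise = 0.005) {
  c(probe_set(n_div, dxs_trend(),
              noise_spec("additive_constant", noise, "divergence"), "div"),
    probe_set(n_rw, dxs_trend(),
              noise_spec("additive_constant", noise, "random_walk"), "rw"))
}

scaling_panel <- function(n_cv, n_fano, n_cubic = 0, magnitude = 0.08) {
  mk <- function(kind, n, pre)
    probe_set(n, trend_spec("linear"),
              noise_spec(kind, magnitude, "divergence", divergence_sd = 0),
              pre)
  c(mk("cv_constant", n_cv, "cv"), mk("fano_constant", n_fano, "fa"),
    mk("cubic", n_cubic, "cu"))
}
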