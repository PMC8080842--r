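#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Cohorts may be
#' given as in-memory [meth_cohort()] objects or as
#' `list(beta = path, samples = path)` file pairs.
#'
#' @param primary cross-sectional cohort (object or path pair). Required.
#' @param secondary longitudinal cohort (object or path pair), or `NULL`
#'   for degraded single-dataset mode.
#' @param annotation probe annotation (data.frame or path), or `NULL` to
#'   skip enrichment.
#' @param cell_fractions cell-composition covariates (data.frame or
#'   path); when given, the whole analysis is repeated on shifted
#'   regression residuals and the report carries the beta/residual
#'   overlap flags.
#' @param alpha_primary,alpha_secondary BH-adjusted aVMP thresholds
#'   (0.001 / 0.05).
#' @param alpha_adavmp BH-adjusted variance threshold within the aDMP set.
#' @param alpha_scaling BH-adjusted threshold of the CV2/Fano age tests.
#' @param min_abs_slope,r2_percentile aDMP gates.
#' @param margin the 5% R-squared comparison margin.
#' @param epsilon,snr_cap SNR deviation floor and cap.
#' @param half_width sliding-window half width in years.
#' @param sexes strata to analyse.
#' @param seed echoed into the report (the pipeline itself is
#'   deterministic given its inputs).
#' @param output_dir directory for `probe_report.tsv`, `summary.json` and
#'   `run.log`, or `NULL` to skip writing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(primary, secondary = NULL, annotation = NULL,
                            cell_fractions = NULL,
                            alpha_primary = 0.001, alpha_secondary = 0.05,
                            alpha_adavmp = 0.001, alpha_scaling = 0.001,
                            min_abs_slope = 0.001, r2_percentile = 99,
                            margin = 0.05, epsilon = 1e-8, snr_cap = 1e6,
                            half_width = 5, sexes = c("male", "female"),
                            seed = 1, output_dir = NULL) {
  thr <- c(alpha_primary = alpha_primary, alpha_secondary = alpha_secondary,
           alpha_adavmp = alpha_adavmp, alpha_scaling = alpha_scaling,
           min_abs_slope = min_abs_slope, r2_percentile = r2_percentile,
           margin = margin, epsilon = epsilon, snr_cap = snr_cap,
           half_width = half_width)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(list(primary = primary, secondary = secondary,
                 annotation = annotation, cell_fractions = cell_fractions,
                 thresholds = as.list(thr), sexes = sexes,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; cohort
#' entries are maps with `beta` and `samples` paths.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.load_cohort_input <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "meth_cohort")) return(x)
  if (is.list(x) && !is.null(x$beta) && !is.null(x$samples))
    return(read_cohort(x$beta, x$samples))
  stop(what, " must be a meth_cohort or a list(beta=, samples=) of paths")
}

.load_table_input <- function(x, reader) {
  if (is.null(x) || is.data.frame(x)) return(x)
  reader(x)
}

# One full analysis pass (beta values or residuals). Returns the per-probe
# report rows plus stage tables and the exclusion ledger.
.run_one_analysis <- function(primary, secondary, ann, th, sexes, log) {
  avmp <- withCallingHandlers(
    select_avmps(primary, secondary, th$alpha_primary, th$alpha_secondary,
                 th$half_width, sexes),
    warning = function(w) {
      log(paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  admp <- select_admps(primary, th$min_abs_slope, th$r2_percentile, sexes)
  adav <- select_adavmps(primary, admp, th$alpha_adavmp, th$half_width, sexes)
  report <- merge(avmp[, c("probe_id", "sex", "q_primary", "q_secondary",
                           "avmp")],
                  admp[, c("probe_id", "sex", "slope", "r_squared", "admp")],
                  by = c("probe_id", "sex"), all = TRUE)
  report <- merge(report,
                  adav[, c("probe_id", "sex", "sigma2_slope", "q_sigma2",
                           "adavmp")],
                  by = c("probe_id", "sex"), all.x = TRUE)
  report$adavmp[is.na(report$adavmp) & report$admp %in% FALSE] <- FALSE
  enr <- NULL
  per_sex <- list()
  for (sx in sexes) {
    snr <- NULL
    ids_avmp <- avmp$probe_id[avmp$sex == sx & avmp$avmp]
    if (!is.null(secondary) && length(ids_avmp)) {
      co <- subset_cohort(secondary, secondary$samples$sex == sx,
                          probes = intersect(ids_avmp,
                                             rownames(secondary$beta)))
      snr <- snr_profiles(co, th$epsilon, th$snr_cap, th$half_width)
      snr$sex <- sx
      nsk <- length(attr(snr, "skipped_individuals"))
      psk <- length(attr(snr, "skipped_pairs"))
      log(sprintf("[%s] SNR: %d aVMPs; %d individuals skipped (M < 3), %d twin pairs skipped",
                  sx, nrow(snr), nsk, psk))
    }
    ids_adav <- adav$probe_id[adav$sex == sx & adav$adavmp]
    scal <- NULL
    if (length(ids_adav)) {
      cos <- subset_cohort(primary, primary$samples$sex == sx)
      bsl <- admp$slope[match(paste(ids_adav, sx),
                              paste(admp$probe_id, admp$sex))]
      ssl <- adav$sigma2_slope[match(paste(ids_adav, sx),
                                     paste(adav$probe_id, adav$sex))]
      scal <- infer_noise_scaling(cos, ids_adav, bsl, ssl,
                                  th$alpha_scaling, th$half_width)
      scal$sex <- sx
      scal$direction <- classify_direction(bsl, ssl)
      log(sprintf("[%s] scaling laws inferred for %d aDaVMPs (%d ties quadratic-first)",
                  sx, nrow(scal), sum(scal$tie)))
    }
    ids_admp <- admp$probe_id[admp$sex == sx & admp$admp]
    trend <- NULL
    if (length(ids_admp)) {
      cos <- subset_cohort(primary, primary$samples$sex == sx)
      trend <- fit_trend_models(cos, ids_admp, th$margin)
      trend$sex <- sx
    }
    if (!is.null(ann) && length(ids_avmp)) {
      e <- enrich_probe_list(intersect(ids_avmp, ann$probe_id),
                             rownames(primary$beta), ann)
      e$sex <- sx
      enr <- rbind(enr, e)
    }
    per_sex[[sx]] <- list(snr = snr, scaling = scal, trend = trend)
  }
  snr_all <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(per_sex, `[[`, "snr")))
  scal_all <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(per_sex, `[[`, "scaling")))
  trend_all <- do.call(rbind, Filter(Negate(is.null),
                                     lapply(per_sex, `[[`, "trend")))
  if (!is.null(snr_all))
    report <- merge(report, snr_all, by = c("probe_id", "sex"), all.x = TRUE)
  else
    report[c("snr_trajectories", "snr_twin_pairs", "snr_cloud",
             "log10_ratio", "call")] <- NA
  if (!is.null(scal_all))
    report <- merge(report,
                    scal_all[, c("probe_id", "sex", "orientation",
                                 "direction", "law")],
                    by = c("probe_id", "sex"), all.x = TRUE)
  else
    report[c("orientation", "direction", "law")] <- NA_character_
  if (!is.null(trend_all))
    report <- merge(report,
                    trend_all[, c("probe_id", "sex", "k", "alpha", "gamma",
                                  "r2_linear", "r2_pow", "r2_exp", "class")],
                    by = c("probe_id", "sex"), all.x = TRUE)
  else
    report[c("k", "alpha", "gamma", "r2_linear", "r2_pow", "r2_exp",
             "class")] <- NA
  list(report = report, enrichment = enr)
}

#' Run the full variability pipeline
#'
#' Stage order: (optional) cell-composition residualisation; aVMP
#' selection across the primary and secondary cohorts; SNR profiling and
#' deterministic/stochastic calls of the aVMPs on the longitudinal cohort;
#' aDMP and aDaVMP selection, direction classes and variance-mean scaling
#' laws on the cross-sectional cohort; linear/power/exponential trend
#' discrimination of the aDMPs; genomic-context enrichment of the aVMP
#' lists. Males and females are analysed separately throughout. When cell
#' fractions are supplied the whole analysis is repeated on residuals and
#' each probe list carries overlap flags (`"XX"` = in both the beta and
#' residual lists, `"X"` = in exactly one).
#'
#' @param config a [pipeline_config()].
#' @return list with `report` (per probe/sex data.frame), `summary`
#'   (nested counts/percentages, see [summarize_classes()]),
#'   `enrichment`, `log` (character vector) and `config`. Side effect:
#'   writes `probe_report.tsv`, `summary.json` and `run.log` when
#'   `config$output_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("methvar %s; seed %d; started %s",
              as.character(utils::packageVersion("methvar")), config$seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  primary <- .load_cohort_input(config$primary, "primary")
  secondary <- .load_cohort_input(config$secondary, "secondary")
  ann <- .load_table_input(config$annotation, read_probe_annotation)
  cf <- .load_table_input(config$cell_fractions, read_cell_fractions)
  th <- config$thresholds
  log(sprintf("primary: %d probes x %d samples; secondary: %s",
              nrow(primary$beta), ncol(primary$beta),
              if (is.null(secondary)) "none (single-dataset mode)"
              else sprintf("%d probes x %d samples",
                           nrow(secondary$beta), ncol(secondary$beta))))
  analyses <- list(beta = .run_one_analysis(primary, secondary, ann, th,
                                            config$sexes, log))
  if (!is.null(cf)) {
    log("residual analysis: regressing out cell fractions per sex")
    pr_res <- adjust_for_cell_composition(primary, cf)
    se_res <- if (!is.null(secondary))
      adjust_for_cell_composition(secondary, cf) else NULL
    analyses$residual <- .run_one_analysis(pr_res, se_res, ann, th,
                                           config$sexes, log)
  }
  report <- analyses$beta$report
  report$analysis <- "beta"
  if (!is.null(analyses$residual)) {
    res <- analyses$residual$report
    res$analysis <- "residual"
    key <- function(df) paste(df$probe_id, df$sex)
    for (flag in c("avmp", "admp", "adavmp")) {
      in_beta <- key(report)[report[[flag]] %in% TRUE]
      in_res <- key(res)[res[[flag]] %in% TRUE]
      mark <- function(df) {
        k <- key(df)
        ifelse(k %in% in_beta & k %in% in_res, "XX",
               ifelse(xor(k %in% in_beta, k %in% in_res), "X", ""))
      }
      report[[paste0(flag, "_overlap")]] <- mark(report)
      res[[paste0(flag, "_overlap")]] <- mark(res)
    }
    report <- rbind(report, res)
  }
  summary <- summarize_classes(report)
  out <- list(report = report, summary = summary,
              enrichment = analyses$beta$enrichment,
              log = log_lines, config = config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report,
                       file.path(config$output_dir, "probe_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    echo <- list(thresholds = th, sexes = config$sexes, seed = config$seed)
    jsonlite::write_json(list(config = echo, summary = summary),
                         file.path(config$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  out
}

.class_summary <- function(x, levels) {
  x <- x[!is.na(x)]
  n <- length(x)
  counts <- vapply(levels, function(lv) sum(x == lv), numeric(1))
  list(n = n, counts = as.list(counts),
       percentages = as.list(if (n > 0) 100 * counts / n else counts))
}

#' Summarise pipeline classifications
#'
#' Per sex (and analysis type), counts and percentages of the
#' deterministic/stochastic calls, the four direction classes, the three
#' scaling laws (age-dependent probes where both normalisations stay
#' age-dependent are the `unresolved` group) and the four trend classes.
#' Percentages within each taxonomy sum to 100.
#'
#' @param report the per-probe report from [run_pipeline()].
#' @return nested list keyed by analysis, then sex.
#' @export
summarize_classes <- function(report) {
  if (!"analysis" %in% names(report)) report$analysis <- "beta"
  out <- list()
  for (an in unique(report$analysis)) {
    ra <- report[report$analysis == an, ]
    for (sx in unique(ra$sex)) {
      r <- ra[ra$sex == sx, ]
      law <- ifelse(r$adavmp %in% TRUE & is.na(r$law), "unresolved", r$law)
      out[[an]][[sx]] <- list(
        n_probes = nrow(r),
        n_avmp = sum(r$avmp %in% TRUE),
        n_admp = sum(r$admp %in% TRUE),
        n_adavmp = sum(r$adavmp %in% TRUE),
        determinism = .class_summary(r$call,
                                     c("deterministic", "stochastic")),
        direction = .class_summary(r$direction,
                                   c("up_up", "down_down", "down_up",
                                     "up_down")),
        scaling_law = .class_summary(law,
                                     c("quadratic", "linear", "unresolved")),
        trend_class = .class_summary(r$class,
                                     c("linear", "weak_nonlinear",
                                       "nonlinear_power",
                                       "nonlinear_exponential")))
    }
  }
  out
}
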