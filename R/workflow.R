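#' End-to-end differential abundance and usage workflows
#'
#' Orchestrates the seven workflow stages — ingest, preprocessing,
#' normalization, peptidoform-level analysis, summarization to PTM level,
#' PTM-level analysis, results — in two flavours. DPA (differential
#' abundance) applies between-sample centering only; its `dpa-nonnorm`
#' variant skips even that (useful to demonstrate how loading differences
#' break unnormalized analyses). DPU (differential usage) additionally
#' subtracts the summarized parent-protein profile per sample before
#' summarization and modeling, so that changes driven by the parent protein
#' alone do not show up. Every intermediate assay is appended to the
#' experiment under a fixed name, never overwriting its input.
#'
#' @name workflow
NULL

#' Assemble a `ptm_experiment` from assays
#'
#' @param design Sample-annotation data frame with `sample_id`.
#' @param enriched Peptidoform `intensity_assay` (stored as
#'   `"peptidoforms"`).
#' @param global Optional non-enriched (global-profiling) assay, stored as
#'   `"global"`.
#' @return A `ptm_experiment`.
#' @export
build_experiment <- function(design, enriched, global = NULL) {
  x <- ptm_experiment(design)
  x <- add_assay(x, "peptidoforms", enriched)
  if (!is.null(global)) x <- add_assay(x, "global", global)
  x
}

#' Workflow configuration
#'
#' @param mode `"dpa"`, `"dpa-nonnorm"` (no centering) or `"dpu"`.
#' @param level `"ptm"` or `"peptidoform"`.
#' @param formula Fixed-effect model formula over design columns.
#' @param contrasts Character vector of contrast expressions for
#'   [make_contrast()]; `NULL` tests every non-intercept coefficient.
#' @param random Optional grouping column for a single random intercept.
#' @param robust Huber M-estimation in the per-feature models.
#' @param ridge Ridge shrinkage of non-intercept coefficients.
#' @param moderation Empirical-Bayes variance moderation.
#' @param protein_source `"global"` (recommended when a non-enriched run
#'   exists) or `"enriched"` (summaries from the PTM data itself).
#' @param center `"median"` or `"mean"` column centering.
#' @param min_samples Minimum observed samples per feature.
#' @param alpha BH significance level used by downstream summaries.
#' @param shared_policy Shared-peptide handling; see [summarize_proteins()].
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(mode = c("dpa", "dpa-nonnorm", "dpu"),
                            level = c("ptm", "peptidoform"),
                            formula = ~ condition, contrasts = NULL,
                            random = NULL, robust = FALSE, ridge = FALSE,
                            moderation = TRUE,
                            protein_source = c("global", "enriched"),
                            center = c("median", "mean"), min_samples = 2L,
                            alpha = 0.05,
                            shared_policy = c("exclude", "first")) {
  structure(list(mode = match.arg(mode), level = match.arg(level),
                 formula = formula, contrasts = contrasts, random = random,
                 robust = robust, ridge = ridge, moderation = moderation,
                 protein_source = match.arg(protein_source),
                 center = match.arg(center),
                 min_samples = as.integer(min_samples), alpha = alpha,
                 shared_policy = match.arg(shared_policy)),
            class = "workflow_config")
}

preprocess_stage <- function(assay, cfg, center) {
  log <- list()
  log$n_input <- nrow(assay$values)
  if (any(c("is_decoy", "is_contaminant") %in% names(assay$fdata)))
    assay <- remove_flagged(assay)
  log$n_after_flags <- nrow(assay$values)
  assay <- filter_min_observed(assay, cfg$min_samples)
  log$n_after_min_observed <- nrow(assay$values)
  if (assay$scale_tag == "raw") assay <- log2_transform(assay)
  if (center) assay <- center_columns(assay, cfg$center)
  list(assay = assay, log = log)
}

default_contrasts <- function(cfg, design) {
  coefs <- colnames(stats::model.matrix(cfg$formula, design))
  exprs <- cfg$contrasts
  if (is.null(exprs)) exprs <- paste(setdiff(coefs, "(Intercept)"), "= 0")
  lapply(exprs, make_contrast, coefficient_names = coefs)
}

finish_run <- function(x, assay, cfg, run_log) {
  fits <- fit_models(assay, x$samples, cfg$formula, random = cfg$random,
                     robust = cfg$robust, ridge = cfg$ridge)
  contrasts <- default_contrasts(cfg, x$samples)
  rows <- test_contrasts(fits, contrasts, moderation = cfg$moderation)
  run_log$n_tested <- sum(!is.na(rows$pval))
  run_log$n_no_fit <- sum(vapply(fits, function(f) f$status != "ok",
                                 logical(1)))
  list(results = rows, experiment = x, fits = fits, log = run_log)
}

#' Run the differential abundance (DPA) workflow
#'
#' Filter, log2-transform, center (unless `mode = "dpa-nonnorm"`), optionally
#' summarize to PTM level, fit the per-feature models, moderate, test the
#' contrasts and BH-adjust. Intermediate assays appended:
#' `"peptidoforms_processed"` and (at PTM level) `"ptm"` with its link.
#'
#' @param x A `ptm_experiment` with a `"peptidoforms"` assay.
#' @param cfg A [workflow_config()] with mode `"dpa"` or `"dpa-nonnorm"`.
#' @return List with `results` (inference rows), `experiment` (with appended
#'   assays), `fits` and a stage `log`.
#' @export
run_dpa <- function(x, cfg = workflow_config(mode = "dpa")) {
  stopifnot(inherits(x, "ptm_experiment"),
            cfg$mode %in% c("dpa", "dpa-nonnorm"))
  st <- preprocess_stage(get_assay(x, "peptidoforms"), cfg,
                         center = cfg$mode != "dpa-nonnorm")
  x <- add_assay(x, "peptidoforms_processed", st$assay)
  model_assay <- st$assay
  if (cfg$level == "ptm") {
    link <- expand_to_ptm(st$assay, "peptidoforms_processed", "ptm",
                          shared_policy = cfg$shared_policy)
    model_assay <- summarize_ptms(st$assay, link)
    x <- add_assay(x, "ptm", model_assay, link = link)
    st$log$n_ptms <- nrow(model_assay$values)
  }
  finish_run(x, model_assay, cfg, st$log)
}

#' Run the differential usage (DPU) workflow
#'
#' As [run_dpa()] with usage normalization inserted after centering: the
#' parent-protein profile (robust summary of the global-profiling assay when
#' `protein_source = "global"`, else of the processed enriched assay itself)
#' is subtracted from every peptidoform. Peptidoforms whose protein has no
#' summary cannot be normalized and are dropped (count in the run log).
#' Appended assays: `"peptidoforms_processed"`, `"protein_summary"`,
#' `"peptidoforms_usage"` and (at PTM level) `"ptm"`.
#'
#' @param x A `ptm_experiment`; `protein_source = "global"` requires a
#'   `"global"` assay.
#' @param cfg A [workflow_config()] with mode `"dpu"`.
#' @return As [run_dpa()].
#' @export
run_dpu <- function(x, cfg = workflow_config(mode = "dpu")) {
  stopifnot(inherits(x, "ptm_experiment"), cfg$mode == "dpu")
  st <- preprocess_stage(get_assay(x, "peptidoforms"), cfg, center = TRUE)
  x <- add_assay(x, "peptidoforms_processed", st$assay)

  if (cfg$protein_source == "global") {
    if (!"global" %in% names(x$assays))
      stop("protein_source = 'global' but no 'global' assay present")
    gst <- preprocess_stage(get_assay(x, "global"), cfg, center = TRUE)
    prot_sum <- summarize_proteins(gst$assay,
                                   shared_policy = cfg$shared_policy)
  } else {
    prot_sum <- summarize_proteins(st$assay,
                                   shared_policy = cfg$shared_policy)
  }
  x <- add_assay(x, "protein_summary", prot_sum)

  usage <- usage_normalize(st$assay, prot_sum,
                           shared_policy = cfg$shared_policy)
  st$log$n_not_normalized <- length(attr(usage, "dropped"))
  st$log$protein_source <- cfg$protein_source
  x <- add_assay(x, "peptidoforms_usage", usage,
                 link = feature_link("peptidoforms_processed",
                                     "peptidoforms_usage",
                                     data.frame(child_id = feature_ids(usage),
                                                parent_id = feature_ids(usage),
                                                stringsAsFactors = FALSE)))
  model_assay <- usage
  if (cfg$level == "ptm") {
    link <- expand_to_ptm(usage, "peptidoforms_usage", "ptm",
                          shared_policy = cfg$shared_policy)
    model_assay <- summarize_ptms(usage, link)
    x <- add_assay(x, "ptm", model_assay, link = link)
    st$log$n_ptms <- nrow(model_assay$values)
  }
  finish_run(x, model_assay, cfg, st$log)
}

#' Run the simulation benchmark
#'
#' Generates (or takes) a grid of benchmark datasets, runs DPU at PTM and
#' peptidoform level on each, and scores against the usage truth: confusion
#' metrics at the BH level and tpr-fdp curves.
#'
#' @param scenario 1 or 2; ignored when `datasets` is supplied.
#' @param datasets Optional list from [simulate_benchmark_grid()].
#' @param alpha BH significance level for the confusion metrics.
#' @param seed Base seed for dataset generation.
#' @param levels Analysis levels to run.
#' @param ... Further arguments to [simulate_benchmark_grid()] (grid axes,
#'   `n_ptms`, ...).
#' @return List with `metrics` (one row per dataset x level) and `curves`
#'   (named list of tpr-fdp curves).
#' @export
run_benchmark <- function(scenario = 1L, datasets = NULL, alpha = 0.05,
                          seed = 1L, levels = c("ptm", "peptidoform"), ...) {
  if (is.null(datasets))
    datasets <- simulate_benchmark_grid(scenario = scenario, seed = seed, ...)
  grid <- attr(datasets, "grid")
  metrics <- list(); curves <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    x <- build_experiment(d$design, d$enriched, d$global)
    for (lv in levels) {
      cfg <- workflow_config(mode = "dpu", level = lv, alpha = alpha)
      run <- run_dpu(x, cfg)
      truth <- if (lv == "ptm") d$truth$ptms else d$truth$peptidoforms
      rows <- run$results[run$results$contrast ==
                            run$results$contrast[1], , drop = FALSE]
      keep <- rows$feature_id %in%
        truth[[if (lv == "ptm") "ptm" else "pepform_id"]]
      rows <- rows[keep, , drop = FALSE]
      conf <- confusion_at_alpha(rows, truth, alpha = alpha)
      tag <- sprintf("dataset%02d_%s", i, lv)
      curves[[tag]] <- tpr_fdp_curve(rows, truth)
      metrics[[tag]] <- data.frame(
        dataset = i, level = lv,
        n_conditions = if (!is.null(grid)) grid$n_conditions[i] else NA,
        n_replicates = if (!is.null(grid)) grid$n_replicates[i] else NA,
        noise_sd = if (!is.null(grid)) grid$noise_sd[i] else NA,
        as.data.frame(conf), stringsAsFactors = FALSE)
    }
  }
  list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
       curves = curves)
}

#' Run the mock (null-calibration) pipeline
#'
#' Takes samples from a single condition, randomly relabels them into two
#' equal pseudo-groups, runs the DPU workflow testing mock vs control, and
#' checks the resulting p-values for uniformity; repeated `n_repeats` times
#' with distinct splits. Every discovery in a mock run is a false positive,
#' so uniform p-values indicate correct type I error control.
#'
#' @param x A `ptm_experiment` whose samples all come from one condition.
#' @param n_repeats Number of random relabelings.
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param level `"ptm"` or `"peptidoform"`.
#' @param robust,protein_source Passed to the workflow config.
#' @return List per repeat: the relabeling, p-values and the
#'   [pvalue_uniformity()] report.
#' @export
run_mock <- function(x, n_repeats = 5L, seed = 1L, level = "ptm",
                     robust = FALSE, protein_source = "global") {
  stopifnot(inherits(x, "ptm_experiment"))
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    lab <- mock_relabel(x$samples$sample_id, seed = seed + r)
    design <- x$samples
    design$mock_condition <- lab$mock_condition[match(design$sample_id,
                                                      lab$sample_id)]
    xr <- ptm_experiment(design)
    for (nm in names(x$assays)) xr <- add_assay(xr, nm, x$assays[[nm]])
    cfg <- workflow_config(mode = "dpu", level = level,
                           formula = ~ mock_condition, robust = robust,
                           protein_source = protein_source)
    run <- run_dpu(xr, cfg)
    pv <- run$results$pval[!is.na(run$results$pval)]
    out[[r]] <- list(relabeling = lab, pvals = pv,
                     uniformity = pvalue_uniformity(pv))
  }
  out
}
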