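#' Run the full screening pipeline
#'
#' Orchestrates the end-to-end analysis from one configuration: simulate a
#' synthetic cohort (or load user tables), call pre-operative plasma and
#' tumor-tissue mutations, subtract PBMC-detected variants, screen by MVFC,
#' classify MRD, and evaluate (log-rank on ctDNA MRD status, tissue
#' enrichment chi-square where tumor tissue is present, fixed-horizon ROC at
#' the early-recurrence horizon, time-dependent AUC for ctDNA/AFP/combined
#' markers). All intermediate tables are written to `out_dir`; a run
#' manifest records the configuration, the seed and per-stage record counts.
#' Re-running with the same configuration and seed reproduces byte-identical
#' outputs.
#'
#' @param config Either a path to a YAML configuration (see
#'   [read_config()]) or a list with elements `calling`, `simulation`,
#'   `input`, `evaluate`.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly. Elements: `seed`, `config`,
#'   `paths`, `counts`, `evaluation`.
#' @examples
#' \donttest{
#' cfg <- list(calling = calling_config(),
#'             simulation = simulation_config(seed = 1, n_patients = 5),
#'             evaluate = list(times = c(183, 365, 730)))
#' run_pipeline(cfg, tempfile("run"))
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  calling <- if (is.null(config$calling)) calling_config() else config$calling
  if (!inherits(calling, "calling_config")) {
    calling <- do.call(calling_config, as.list(calling))
  }
  times <- config$evaluate$times
  if (is.null(times)) times <- c(183, 365, 730)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # paths are kept relative to out_dir so run manifests are reproducible
  paths <- list()
  counts <- list()
  in_dir <- function(name) file.path(out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- stage: simulate or load ------------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    if (!inherits(sim_cfg, "simulation_config")) {
      sim_cfg <- do.call(simulation_config, as.list(sim_cfg))
    }
    seed <- sim_cfg$seed
    cohort <- stage("simulate", simulate_cohort(sim_cfg))
    pileup <- cohort$pileup
    manifest <- cohort$manifest
    paths$pileup <- "pileup.tsv"
    paths$manifest <- "manifest.tsv"
    paths$truth_patients <- "truth_patients.tsv"
    paths$truth_mutations <- "truth_mutations.tsv"
    write_pileup_table(pileup, in_dir(paths$pileup))
    write_patient_manifest(manifest, in_dir(paths$manifest))
    utils::write.table(cohort$truth$patients, in_dir(paths$truth_patients),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tm <- cohort$truth$mutations
    if (nrow(tm) > 0) {
      tm$vaf_pre_expected <- .fmt_num(tm$vaf_pre_expected)
      tm$vaf_post_expected <- .fmt_num(tm$vaf_post_expected)
    }
    utils::write.table(tm, in_dir(paths$truth_mutations),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(config$input$pileup) || is.null(config$input$manifest)) {
      stop("config must request simulation or provide input$pileup and input$manifest")
    }
    seed <- NA_integer_
    pileup <- stage("load", read_pileup_table(config$input$pileup))
    manifest <- stage("load", read_patient_manifest(config$input$manifest))
  }
  counts$sites_read <- nrow(pileup)
  counts$patients <- nrow(manifest)

  # --- stage: call -------------------------------------------------------
  pre <- pileup[pileup$sample_type == "pre_plasma", , drop = FALSE]
  pbmc <- pileup[pileup$sample_type == "pbmc", , drop = FALSE]
  tissue <- pileup[pileup$sample_type == "tumor", , drop = FALSE]
  pre_calls <- stage("call", call_sample_mutations(pre, calling))
  pre_calls <- stage("call", subtract_pbmc(pre_calls, pbmc, calling))
  tissue_calls <- stage("call", call_sample_mutations(tissue, calling))
  counts$pre_plasma_calls <- nrow(pre_calls)
  counts$tumor_tissue_calls <- nrow(tissue_calls)
  paths$calls <- "pre_plasma_calls.tsv"
  calls_out <- pre_calls
  if (nrow(calls_out) > 0) calls_out$vaf <- .fmt_num(calls_out$vaf)
  utils::write.table(calls_out, in_dir(paths$calls), sep = "\t",
                     quote = FALSE,
                     row.names = FALSE)

  # --- stage: screen -----------------------------------------------------
  screened <- stage("screen", screen_patient(pre_calls, pileup, calling))
  counts$screened <- nrow(screened)
  counts$tumor_class <- sum(screened$mvfc_class == "tumor")
  counts$nontumor_class <- sum(screened$mvfc_class == "nontumor")
  counts$unevaluable <- sum(screened$mvfc_class == "unevaluable")
  paths$screened <- "screened_mutations.tsv"
  write_screened_mutations(screened, in_dir(paths$screened))
  dist <- mvfc_distribution(screened, threshold = calling$mvfc_threshold)
  paths$mvfc_histogram <- "mvfc_histogram.tsv"
  utils::write.table(dist$histogram, in_dir(paths$mvfc_histogram),
                     sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- stage: mrd --------------------------------------------------------
  mrd <- stage("mrd", call_mrd(screened, manifest, calling))
  counts$mrd_positive <- sum(mrd$ctdna_positive)
  paths$mrd <- "mrd_calls.tsv"
  utils::write.table(mrd, in_dir(paths$mrd), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- stage: evaluate ---------------------------------------------------
  evaluation <- stage("evaluate", evaluate_cohort(
    mrd, manifest, tissue_calls = tissue_calls, screened = screened,
    config = calling, times = times
  ))
  paths$evaluation <- "evaluation.json"
  jsonlite::write_json(evaluation, in_dir(paths$evaluation),
                       auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(evaluation$km_curves)) {
    paths$km_curves <- "km_curves.tsv"
    utils::write.table(evaluation$km_curves, in_dir(paths$km_curves),
                       sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  run_manifest <- list(seed = seed, out_dir = out_dir,
                       config = list(calling = unclass(calling),
                                     times = times),
                       paths = paths, counts = counts,
                       evaluation = evaluation[setdiff(names(evaluation),
                                                       "km_curves")])
  # out_dir is kept out of the written manifest so identical runs into
  # different directories stay byte-identical
  jsonlite::write_json(run_manifest[setdiff(names(run_manifest), "out_dir")],
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  .log_msg(paste0(
    "run_pipeline: %d sites -> %d pre-plasma calls -> %d screened ",
    "(%d tumor-class) -> %d/%d MRD-positive"
  ), counts$sites_read, counts$pre_plasma_calls, counts$screened,
  counts$tumor_class, counts$mrd_positive, counts$patients)
  invisible(run_manifest)
}

#' Evaluate MRD calls against outcomes
#'
#' Computes the evaluation statistics on a cohort: log-rank test of
#' relapse-free survival by ctDNA MRD status, enrichment chi-square against
#' tumor-tissue calls (when available), fixed-horizon ROC at the
#' early-recurrence horizon, and time-dependent AUC for the ctDNA, AFP and
#' combined markers. Statistics whose preconditions fail on the given cohort
#' (e.g. a single-level grouping) are reported as NULL rather than erroring.
#'
#' @param mrd MRD calls from [call_mrd()].
#' @param manifest Patient manifest.
#' @param tissue_calls Optional tumor-tissue calls for the enrichment test.
#' @param screened Optional screened mutations (needed with `tissue_calls`).
#' @param config A [calling_config()].
#' @param times Horizons for the time-dependent AUC, days.
#' @return A list: `logrank_ctdna`, `enrichment`, `roc_early_recurrence`,
#'   `auc_timedep` (data.frame time x marker), `km_curves`.
#' @export
evaluate_cohort <- function(mrd, manifest, tissue_calls = NULL,
                            screened = NULL, config = calling_config(),
                            times = c(183, 365, 730)) {
  out <- list()
  if (nrow(mrd) == 0) return(out)
  d <- merge(manifest, mrd, by = "patient_id")
  d$time <- d$rfs_days
  d$event <- d$relapse_event
  try_or_null <- function(expr) {
    tryCatch(expr, error = function(e) NULL)
  }
  lr <- try_or_null(km_logrank(d$time, d$event, d$ctdna_positive))
  if (!is.null(lr)) {
    out$logrank_ctdna <- list(statistic = lr$statistic, df = lr$df,
                              p_value = lr$p_value)
    out$km_curves <- lr$curves
  }
  if (!is.null(tissue_calls) && !is.null(screened) &&
      nrow(tissue_calls) > 0) {
    tab <- enrichment_table(screened, tissue_calls)
    enr <- try_or_null(chi_square_enrichment(tab))
    if (!is.null(enr)) {
      out$enrichment <- list(statistic = enr$statistic, df = enr$df,
                             p_value = enr$p_value,
                             table = as.vector(t(tab)))
    }
  }
  roc <- try_or_null(fixed_horizon_roc(
    d$ctdna_positive, d$time, d$event, config$early_recurrence_days
  ))
  if (!is.null(roc)) {
    out$roc_early_recurrence <- list(auc = roc$estimate,
                                     n_cases = roc$n_cases,
                                     n_controls = roc$n_controls,
                                     horizon = config$early_recurrence_days)
  }
  markers <- list(ctdna = d$ctdna_positive,
                  afp = d$afp_positive,
                  combined = d$combined_positive)
  auc_td <- try_or_null({
    td <- lapply(names(markers), function(nm) {
      res <- time_dependent_roc(markers[[nm]], d$time, d$event, times)
      res$marker <- nm
      res
    })
    do.call(rbind, td)
  })
  if (!is.null(auc_td)) out$auc_timedep <- auc_td
  out
}
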