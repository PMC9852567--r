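#' Pipeline orchestration
#'
#' One call runs the whole analysis — simulate (or load) inputs, collapse
#' reads, quantify hotspot VAFs, calibrate or apply the calling threshold,
#' classify samples, and compute the diagnostic report — with every stage
#' writing a plain-TSV/JSON intermediate so stages are individually
#' re-runnable and diffable.
#'
#' @name cli_and_config
NULL

#' Build and validate a pipeline run configuration
#'
#' Exactly one score-rule must be active: either a fixed `threshold` or a
#' `calibration` specification (a list with `candidates` and
#' `target_specificity`, applied to the disease-free training-cohort
#' samples). Exactly one input source must be given: simulation parameters
#' (`sim`), a pre-computed site-count table (`counts_path` +
#' `sample_sheet_path`), or raw reads (`reads_path` + `sample_sheet_path`).
#'
#' @param out_dir output directory for stage artefacts.
#' @param panel a `hotspot_panel` (default [default_panel()]).
#' @param sim optional `sim_params`: simulate the cohort as input.
#' @param counts_path optional path to a site-counts TSV.
#' @param reads_path optional path to a read-records TSV.
#' @param sample_sheet_path sample sheet TSV (required with `counts_path`
#'   or `reads_path`).
#' @param threshold fixed calling threshold (fraction), or `NULL`.
#' @param calibration list(candidates=, target_specificity=), or `NULL`.
#' @param min_family_size consensus family-size rule (default 3).
#' @param min_baseq consensus base-quality filter (default 30).
#' @param excluded character keys excluded from the max-VAF statistic.
#' @param seed root seed for any simulation.
#' @param quiet suppress per-stage progress messages.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir, panel = default_panel(), sim = NULL,
                       counts_path = NULL, reads_path = NULL,
                       sample_sheet_path = NULL, threshold = NULL,
                       calibration = NULL, min_family_size = 3,
                       min_baseq = 30, excluded = character(),
                       seed = 1L, quiet = FALSE) {
  if (is.null(threshold) == is.null(calibration)) {
    stop_urovaf("exactly one of threshold / calibration must be given",
                "urovaf_config_error")
  }
  if (!is.null(calibration) &&
      !all(c("candidates", "target_specificity") %in% names(calibration))) {
    stop_urovaf("calibration needs candidates and target_specificity",
                "urovaf_config_error")
  }
  n_inputs <- (!is.null(sim)) + (!is.null(counts_path)) + (!is.null(reads_path))
  if (n_inputs != 1) {
    stop_urovaf("exactly one input source (sim, counts_path, reads_path) must be given",
                "urovaf_config_error")
  }
  if (is.null(sim) && is.null(sample_sheet_path)) {
    stop_urovaf("sample_sheet_path is required with counts_path/reads_path",
                "urovaf_config_error")
  }
  if (length(excluded) > 0) panel <- validate_panel(panel$hotspots,
                                                    union(panel$excluded, excluded))
  structure(
    list(out_dir = out_dir, panel = panel, sim = sim, counts_path = counts_path,
         reads_path = reads_path, sample_sheet_path = sample_sheet_path,
         threshold = threshold, calibration = calibration,
         min_family_size = min_family_size, min_baseq = min_baseq,
         seed = as.integer(seed), quiet = isTRUE(quiet)),
    class = "run_config"
  )
}

stage_log <- function(config, stage, ...) {
  if (!config$quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, urovaf_error = function(e) {
    e$message <- sprintf("stage %s: %s", stage, conditionMessage(e))
    stop(e)
  })
}

#' Run the end-to-end pipeline
#'
#' Executes input acquisition, (optional) consensus collapsing,
#' quantification, threshold calibration or fixed-threshold calling, and
#' reporting; writes each stage's output under `config$out_dir` and a run
#' manifest echoing every parameter. Deterministic given the seed: the
#' metrics JSON is byte-identical across re-runs with the same
#' configuration.
#'
#' @param config a `run_config`.
#' @return the manifest list, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  outputs <- character()

  ## stage 1: inputs
  if (!is.null(config$sim)) {
    stage_log(config, "simulate", "generating synthetic cohort (seed %d)", config$seed)
    sim <- with_stage("simulate",
                      simulate_cohort(config$panel, config$sim, seed = config$seed,
                                      cohort = "both"))
    samples <- sim$samples
    counts <- sim$counts
    write_sample_sheet(samples, out("samples.tsv"))
    write_site_counts(counts, out("site_counts.tsv"))
    outputs <- c(outputs, samples = "samples.tsv", counts = "site_counts.tsv")
  } else {
    stage_log(config, "load", "reading inputs")
    samples <- with_stage("load", load_sample_sheet(config$sample_sheet_path))
    if (!is.null(config$reads_path)) {
      reads <- with_stage("load", load_reads(config$reads_path))
      stage_log(config, "consensus", "collapsing %d reads", nrow(reads))
      calls <- with_stage("consensus",
                          collapse_reads(reads, min_family_size = config$min_family_size))
      counts <- NULL
    } else {
      counts <- with_stage("load", load_site_counts(config$counts_path))
    }
  }

  ## stage 2/3: quantification
  stage_log(config, "quantify", "computing VAF table")
  vaf_table <- with_stage("quantify", {
    if (is.null(counts)) {
      pileup_vaf(calls, config$panel, min_baseq = config$min_baseq)
    } else {
      pileup_vaf(counts, config$panel, min_baseq = config$min_baseq)
    }
  })
  mv <- with_stage("quantify", max_vaf(vaf_table, config$panel))
  write_vaf_table(vaf_table, out("vaf_table.tsv"))
  write_vaf_table(mv, out("max_vaf.tsv"))
  outputs <- c(outputs, vaf_table = "vaf_table.tsv", max_vaf = "max_vaf.tsv")

  idx <- match(mv$sample_id, samples$sample_id)
  if (anyNA(idx)) {
    stop_urovaf("samples present in counts but missing from sample sheet",
                "urovaf_config_error")
  }
  meta <- samples[idx, ]

  ## stage 4: threshold
  if (!is.null(config$calibration)) {
    train <- mv$max_vaf[meta$cohort == "haematuria_training" & !meta$bc_status]
    stage_log(config, "calibrate", "calibrating on %d training samples", length(train))
    calib <- with_stage("calibrate",
                        calibrate_threshold(train, config$calibration$candidates,
                                            config$calibration$target_specificity))
    threshold <- calib$selected
    jsonlite::write_json(
      list(candidates = calib$table$threshold,
           training_specificity = calib$table$specificity,
           selected = calib$selected,
           target_specificity = calib$target_specificity),
      out("calibration.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, calibration = "calibration.json")
  } else {
    threshold <- config$threshold
  }

  ## stage 5: calls
  stage_log(config, "call", "calling at threshold %.3g", threshold)
  calls_tbl <- with_stage("call", classify(mv, threshold))
  gene_calls <- with_stage("call", per_gene_calls(vaf_table, config$panel, threshold))
  write_vaf_table(calls_tbl, out("calls.tsv"))
  write_vaf_table(gene_calls, out("gene_calls.tsv"))
  outputs <- c(outputs, calls = "calls.tsv", gene_calls = "gene_calls.tsv")

  ## stage 6: report
  stage_log(config, "report", "computing diagnostic metrics")
  metrics <- with_stage("report",
                        pipeline_metrics(calls_tbl, gene_calls, mv, meta, threshold))
  jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  outputs <- c(outputs, metrics = "metrics.json")

  manifest <- list(
    package = "urovaf",
    version = as.character(utils::packageVersion("urovaf")),
    seed = config$seed,
    threshold = threshold,
    min_family_size = config$min_family_size,
    min_baseq = config$min_baseq,
    excluded_sites = config$panel$excluded,
    n_panel_sites = nrow(config$panel$hotspots),
    n_samples = nrow(meta),
    stage_outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

## assemble the per-cohort diagnostic report; pure function of its inputs so
## repeated runs write byte-identical JSON
pipeline_metrics <- function(calls_tbl, gene_calls, mv, meta, threshold) {
  metrics <- list(threshold = threshold)
  pos <- calls_tbl$positive

  ds_to_list <- function(ds) {
    list(tp = unname(ds$counts["tp"]), fn = unname(ds$counts["fn"]),
         fp = unname(ds$counts["fp"]), tn = unname(ds$counts["tn"]),
         sensitivity = ds$sensitivity_text, specificity = ds$specificity_text)
  }

  test_set <- meta$cohort == "haematuria_test"
  if (any(test_set) && length(unique(meta$bc_status[test_set])) == 2) {
    ds <- sens_spec(pos[test_set], meta$bc_status[test_set])
    roc <- roc_auc(mv$max_vaf[test_set], meta$bc_status[test_set])
    metrics$haematuria_test <- c(ds_to_list(ds), list(auc = roc$auc))
    nb <- !meta$bc_status & meta$cohort %in% c("haematuria_training", "haematuria_test")
    ab <- age_band_fpr(pos[nb], meta$age[nb])
    metrics$age_band_fpr <- list(band = ab$band, n = ab$n, fpr = ab$fpr)
    gc_cohort <- meta$cohort[match(gene_calls$sample_id, meta$sample_id)]
    st <- stratified_table(gene_calls[gc_cohort == "haematuria_test", ], meta)
    metrics$stratified_sensitivity <- as.list(st$sensitivity)
  }

  surv <- meta$cohort == "surveillance"
  if (any(surv) && length(unique(meta$bc_status[surv])) == 2) {
    ds <- sens_spec(pos[surv], meta$bc_status[surv])
    metrics$surveillance <- ds_to_list(ds)
    neg <- surv & !meta$bc_status & !is.na(meta$future_recurrence)
    if (any(neg & meta$future_recurrence) && any(neg & !meta$future_recurrence)) {
      a <- sum(pos[neg] & meta$future_recurrence[neg])
      b <- sum(pos[neg] & !meta$future_recurrence[neg])
      c_ <- sum(!pos[neg] & meta$future_recurrence[neg])
      d <- sum(!pos[neg] & !meta$future_recurrence[neg])
      if (a + b > 0 && c_ + d > 0 && a + c_ > 0) {
        rr <- relative_risk(a = a, b = b, c = c_, d = d)
        metrics$future_recurrence <- list(
          positive_recur = a, positive_no_recur = b,
          negative_recur = c_, negative_no_recur = d,
          rr = rr$rr, rr_ci = rr$ci, rr_ci_method = rr$ci_method)
      }
    }
  }
  metrics
}
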