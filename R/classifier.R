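#' Max-VAF classifier and threshold calibration
#'
#' A sample is called positive when its maximum hotspot VAF strictly exceeds
#' the calling threshold (a sample exactly at the threshold is negative).
#' The threshold is calibrated on a training set of disease-free samples:
#' for each candidate threshold the training specificity is the fraction of
#' training samples called negative, and the selected threshold is the
#' smallest candidate whose specificity meets the target — the smallest
#' qualifying threshold preserves sensitivity at the required specificity.
#' On the study's training data, thresholds of 1, 1.5 and 2% gave
#' specificities of 68, 86 and 90%, motivating a 2% operating point.
#'
#' @name classifier
NULL

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop_urovaf("threshold must be a single fraction in [0,1]", "urovaf_classifier_error")
  }
}

#' Training-set specificity at a threshold
#'
#' @param training_max_vafs numeric vector of max-VAF scores from disease-free
#'   training samples (or a [max_vaf()] tibble, from which `max_vaf` is taken).
#' @param threshold calling threshold as a fraction (e.g. 0.02 for 2% VAF).
#' @return the fraction of training samples with `max_vaf <= threshold`,
#'   i.e. called negative under the strict-> rule.
#' @export
#' @examples
#' training_specificity(c(0.001, 0.005, 0.03), 0.02)
training_specificity <- function(training_max_vafs, threshold) {
  x <- score_vector(training_max_vafs)
  if (length(x) == 0) {
    stop_urovaf("empty training set", "urovaf_classifier_error")
  }
  check_threshold(threshold)
  mean(x <= threshold)
}

score_vector <- function(x) {
  if (is.data.frame(x)) x <- x$max_vaf
  x <- as.numeric(x)
  if (anyNA(x)) stop_urovaf("max-VAF scores contain NA", "urovaf_classifier_error")
  x
}

#' Calibrate the calling threshold on a training set
#'
#' Evaluates the training specificity at each candidate threshold and
#' selects the smallest candidate meeting the target specificity.
#'
#' @inheritParams training_specificity
#' @param candidates numeric vector of candidate thresholds, fractions.
#' @param target_specificity required training specificity in [0,1].
#' @return an object of class `vaf_calibration`: a list with `table` (tibble
#'   of threshold and specificity for every candidate), `selected` (the
#'   chosen threshold) and `target_specificity`. If no candidate meets the
#'   target an error of class `urovaf_calibration_error` is raised carrying
#'   `best_threshold` and `best_specificity`.
#' @export
calibrate_threshold <- function(training_max_vafs, candidates, target_specificity) {
  if (length(candidates) == 0) {
    stop_urovaf("no candidate thresholds", "urovaf_classifier_error")
  }
  candidates <- sort(as.numeric(candidates))
  if (!is.numeric(target_specificity) || length(target_specificity) != 1 ||
      target_specificity < 0 || target_specificity > 1) {
    stop_urovaf("target specificity must be a fraction in [0,1]",
                "urovaf_classifier_error")
  }
  spec <- vapply(candidates, function(t) training_specificity(training_max_vafs, t),
                 numeric(1))
  ok <- which(spec >= target_specificity)
  if (length(ok) == 0) {
    best <- which.max(spec)
    stop_urovaf(
      sprintf("no candidate threshold reaches target specificity %.3f; best is %.3g (specificity %.3f)",
              target_specificity, candidates[best], spec[best]),
      "urovaf_calibration_error",
      data = list(best_threshold = candidates[best], best_specificity = spec[best])
    )
  }
  structure(
    list(
      table = tibble::tibble(threshold = candidates, specificity = spec),
      selected = candidates[ok[1]],
      target_specificity = target_specificity
    ),
    class = "vaf_calibration"
  )
}

#' @export
print.vaf_calibration <- function(x, ...) {
  cat("Max-VAF threshold calibration\n")
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  threshold %4.3g  training specificity %s%s\n",
                x$table$threshold[i], format_percent(x$table$specificity[i]),
                if (x$table$threshold[i] == x$selected) "  <- selected" else ""))
  }
  cat(sprintf("Target specificity: %s\n", format_percent(x$target_specificity)))
  invisible(x)
}

#' Classify samples by max VAF
#'
#' @param max_vafs a [max_vaf()] tibble or a named numeric vector of scores.
#' @param threshold calling threshold as a fraction; a sample is positive
#'   iff `max_vaf > threshold` (strictly).
#' @return tibble with columns `sample_id`, `max_vaf`, `positive` (logical)
#'   and `threshold`.
#' @export
classify <- function(max_vafs, threshold) {
  check_threshold(threshold)
  if (is.data.frame(max_vafs)) {
    ids <- max_vafs$sample_id
    x <- score_vector(max_vafs)
  } else {
    x <- score_vector(max_vafs)
    ids <- names(max_vafs) %||% paste0("sample", seq_along(x))
  }
  tibble::tibble(sample_id = ids, max_vaf = x, positive = x > threshold,
                 threshold = threshold)
}

#' Per-gene mutation calls
#'
#' A gene is called positive in a sample when any of its non-excluded
#' hotspots exceeds the threshold; the `any_gene` flag is the OR over genes
#' and always equals the sample-level max-VAF call.
#'
#' @param vaf_table VAF table from [pileup_vaf()].
#' @param panel the `hotspot_panel` (supplies gene assignment and the
#'   exclusion set).
#' @param threshold calling threshold, fraction.
#' @return tibble with one row per sample: `sample_id`, one logical column
#'   per panel gene, and `any_gene`.
#' @export
per_gene_calls <- function(vaf_table, panel, threshold) {
  check_threshold(threshold)
  genes <- unique(panel$hotspots$gene)
  usable <- setdiff(panel_keys(panel), panel$excluded)
  vt <- vaf_table[hotspot_key(vaf_table$chrom, vaf_table$pos, vaf_table$alt) %in% usable, ]
  samples <- unique(vaf_table$sample_id)
  pos_mat <- vapply(genes, function(g) {
    sub <- vt[vt$gene == g, ]
    hit <- sub$sample_id[!is.na(sub$vaf) & sub$vaf > threshold]
    samples %in% hit
  }, logical(length(samples)))
  pos_mat <- matrix(pos_mat, nrow = length(samples),
                    dimnames = list(NULL, genes))
  out <- tibble::tibble(sample_id = samples)
  for (g in genes) out[[g]] <- pos_mat[, g]
  out$any_gene <- apply(pos_mat, 1, any)
  out
}
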