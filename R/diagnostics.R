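#' Diagnostic accuracy statistics
#'
#' Sensitivity and specificity are reported with exact (Clopper-Pearson)
#' 95% confidence intervals computed from beta quantiles; this exact method
#' reproduces the conventional reporting for diagnostic accuracy studies and
#' is conservative (coverage at least nominal). Percentages are printed
#' rounded half away from zero to integer percent, or one decimal where a
#' sample-size calculation calls for it.
#'
#' @name diagnostics
NULL

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta quantiles: for k successes out of n, the
#' lower bound is the beta(k, n-k+1) quantile at alpha/2 (0 when k = 0) and
#' the upper bound the beta(k+1, n-k) quantile at 1-alpha/2 (1 when k = n).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return one-row tibble with columns `k`, `n`, `point`, `lower`, `upper`,
#'   `level`.
#' @export
#' @examples
#' exact_binomial_ci(109, 165)
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) || n < 1 ||
      k < 0 || k > n) {
    stop_urovaf("need 0 <= k <= n with n >= 1", "urovaf_ci_error")
  }
  alpha <- (1 - level) / 2
  lower <- if (k == 0) 0 else qbeta(alpha, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha, k + 1, n - k)
  tibble::tibble(k = as.integer(k), n = as.integer(n), point = k / n,
                 lower = lower, upper = upper, level = level)
}

#' Format an exact-CI tibble as a printed percentage interval
#'
#' Renders the interval as it would appear in a report: integer percent by
#' default, one decimal place in sample-size-calculation mode
#' (`digits = 1`). Rounding is half away from zero.
#'
#' @param ci a one-row tibble from [exact_binomial_ci()].
#' @param digits decimal places on the percentage scale (0 or 1).
#' @return string such as `"58-73%"`.
#' @export
format_proportion_ci <- function(ci, digits = 0) {
  format_ci(ci$lower, ci$upper, digits = digits)
}

#' Sensitivity and specificity with exact CIs from a 2x2 table
#'
#' @param tp,fn,fp,tn confusion-matrix counts: true/false positives and
#'   negatives of the disease call.
#' @param level confidence level for the exact intervals (default 0.95).
#' @return an object of class `diagnostic_summary`: a list with the 2x2
#'   counts, `sensitivity` and `specificity` exact-CI tibbles (NA entries
#'   with a `defined = FALSE` flag when a denominator is zero), and
#'   formatted percent strings as printed in a clinical report.
#' @export
#' @examples
#' diagnostic_summary(tp = 109, fn = 56, fp = 23, tn = 261)
diagnostic_summary <- function(tp, fn, fp, tn, level = 0.95) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop_urovaf("2x2 counts must be >= 0", "urovaf_ci_error")
  prop <- function(k, n) {
    if (n == 0) {
      list(ci = tibble::tibble(k = NA_integer_, n = 0L, point = NA_real_,
                               lower = NA_real_, upper = NA_real_, level = level),
           defined = FALSE, text = "undefined")
    } else {
      ci <- exact_binomial_ci(k, n, level)
      list(ci = ci, defined = TRUE,
           text = sprintf("%s (%d%% CI %s)", format_percent(ci$point),
                          round(100 * level), format_ci(ci$lower, ci$upper)))
    }
  }
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  structure(
    list(counts = counts,
         sensitivity = sens$ci, sensitivity_defined = sens$defined,
         specificity = spec$ci, specificity_defined = spec$defined,
         sensitivity_text = sens$text, specificity_text = spec$text,
         level = level),
    class = "diagnostic_summary"
  )
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("2x2: TP %d  FN %d  FP %d  TN %d\n",
              x$counts["tp"], x$counts["fn"], x$counts["fp"], x$counts["tn"]))
  cat("Sensitivity:", x$sensitivity_text, "\n")
  cat("Specificity:", x$specificity_text, "\n")
  invisible(x)
}

#' Sensitivity and specificity from per-sample calls and labels
#'
#' @param positive logical vector of sample calls (or a [classify()] tibble,
#'   from which `positive` is taken).
#' @param disease logical vector: disease present at collection, parallel
#'   to `positive`.
#' @param level confidence level.
#' @return a `diagnostic_summary` (see [diagnostic_summary()]).
#' @export
sens_spec <- function(positive, disease, level = 0.95) {
  if (is.data.frame(positive)) positive <- positive$positive
  if (length(positive) != length(disease)) {
    stop_urovaf("calls and labels differ in length", "urovaf_ci_error")
  }
  if (anyNA(positive) || anyNA(disease)) {
    stop_urovaf("calls/labels contain NA", "urovaf_ci_error")
  }
  diagnostic_summary(
    tp = sum(positive & disease), fn = sum(!positive & disease),
    fp = sum(positive & !disease), tn = sum(!positive & !disease),
    level = level
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the calling threshold over every distinct observed score (with the
#' strict-> calling rule) and traces (1 - specificity, sensitivity). The
#' trapezoidal AUC equals the Mann-Whitney rank statistic U / (n1 n2) with
#' tied score pairs given half credit. The AUC confidence interval is
#' computed by DeLong's method (labelled as such in the result).
#'
#' @param scores numeric vector of per-sample max-VAF scores.
#' @param disease logical vector, disease status parallel to `scores`.
#' @param level confidence level for the DeLong interval.
#' @return an object of class `roc_result`: list with `points` (tibble of
#'   threshold, fpr, sensitivity), `auc`, `auc_ci` (DeLong), `ci_method`,
#'   and class counts `n_disease`, `n_control`.
#' @export
roc_auc <- function(scores, disease, level = 0.95) {
  if (length(scores) != length(disease) || anyNA(scores) || anyNA(disease)) {
    stop_urovaf("scores/labels must be NA-free and equal length", "urovaf_roc_error")
  }
  disease <- as.logical(disease)
  n1 <- sum(disease); n0 <- sum(!disease)
  if (n1 == 0 || n0 == 0) {
    stop_urovaf("both classes must be present for a ROC curve", "urovaf_roc_error")
  }
  pos <- scores[disease]; neg <- scores[!disease]
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thresholds, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg > t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)

  ## DeLong variance from placement values
  v10 <- vapply(pos, function(x) mean(x > neg) + 0.5 * mean(x == neg), numeric(1))
  v01 <- vapply(neg, function(y) mean(pos > y) + 0.5 * mean(pos == y), numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(var_auc)))

  structure(
    list(points = tibble::tibble(threshold = thresholds, fpr = fpr,
                                 sensitivity = sens),
         auc = auc, auc_ci = ci, ci_method = "DeLong", level = level,
         n_disease = n1, n_control = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds (%d disease / %d control)\n",
              nrow(x$points), x$n_disease, x$n_control))
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f, %s)\n", x$auc,
              round(100 * x$level), x$auc_ci[1], x$auc_ci[2], x$ci_method))
  invisible(x)
}

#' Relative risk from a 2x2 exposure-by-event table
#'
#' Risk ratio of the event between exposed and unexposed groups, with a
#' Katz log-normal confidence interval (labelled in the result). With a
#' zero event cell the point estimate is infinite (or zero) and is flagged;
#' setting `correction = TRUE` applies a 0.5 continuity correction to every
#' cell, also flagged in the output.
#'
#' @param a exposed with event; `b` exposed without event; `c` unexposed
#'   with event; `d` unexposed without event.
#' @param b,c,d see `a`.
#' @param level confidence level.
#' @param correction apply a 0.5 continuity correction to all cells
#'   (default FALSE; only needed with zero cells).
#' @return an object of class `relative_risk`: list with `risk_exposed`,
#'   `risk_unexposed`, `rr`, `ci`, `ci_method` ("Katz log-normal"),
#'   `corrected` flag.
#' @export
#' @examples
#' relative_risk(a = 8, b = 31, c = 10, d = 215)
relative_risk <- function(a, b, c, d, level = 0.95, correction = FALSE) {
  if (any(c(a, b, c, d) < 0)) stop_urovaf("counts must be >= 0", "urovaf_rr_error")
  if (a + b == 0 || c + d == 0) {
    stop_urovaf("both exposure groups must be non-empty", "urovaf_rr_error")
  }
  cc <- if (correction) 0.5 else 0
  a2 <- a + cc; b2 <- b + cc; c2 <- c + cc; d2 <- d + cc
  risk_e <- a2 / (a2 + b2)
  risk_u <- c2 / (c2 + d2)
  rr <- if (risk_u == 0) Inf else risk_e / risk_u
  if (is.finite(rr) && rr > 0 && a2 > 0 && c2 > 0) {
    se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
    z <- qnorm(1 - (1 - level) / 2)
    ci <- exp(log(rr) + c(-1, 1) * z * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(
    list(risk_exposed = risk_e, risk_unexposed = risk_u, rr = rr, ci = ci,
         ci_method = "Katz log-normal", level = level, corrected = correction,
         degenerate = !is.finite(rr) || rr == 0),
    class = "relative_risk"
  )
}

#' @export
print.relative_risk <- function(x, ...) {
  cat(sprintf("Risk exposed %s vs unexposed %s\n",
              format_percent(x$risk_exposed), format_percent(x$risk_unexposed)))
  cat(sprintf("RR = %.2f (%d%% CI %.2f-%.2f, %s%s)\n", x$rr,
              round(100 * x$level), x$ci[1], x$ci[2], x$ci_method,
              if (x$corrected) ", 0.5 continuity correction" else ""))
  invisible(x)
}

#' False-positive rate by age band
#'
#' Among disease-free samples, the fraction called positive within each age
#' band. The default bands reflect the observed age dependence of clonal
#' APOBEC-hotspot signal in urine: below 50, 50-64, and 65 or over.
#'
#' @param positive logical calls for disease-free samples.
#' @param age numeric ages, parallel to `positive`.
#' @param breaks ascending band edges; bands are left-closed,
#'   right-open (default `c(0, 50, 65, Inf)`).
#' @return tibble with one row per band: `band`, `n`, `positives`, `fpr`
#'   (NA for empty bands).
#' @export
age_band_fpr <- function(positive, age, breaks = c(0, 50, 65, Inf)) {
  if (length(positive) != length(age)) {
    stop_urovaf("calls and ages differ in length", "urovaf_diagnostics_error")
  }
  labels <- vapply(seq_len(length(breaks) - 1), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    if (is.infinite(hi)) paste0(">=", lo) else paste0(lo, "-", hi - 1)
  }, character(1))
  band <- cut(age, breaks = breaks, labels = labels, right = FALSE,
              include.lowest = TRUE)
  n <- as.integer(table(band))
  pos <- as.integer(tapply(positive, band, sum, default = 0L))
  tibble::tibble(band = labels, n = n, positives = pos,
                 fpr = ifelse(n > 0, pos / n, NA_real_))
}

#' Compare max-VAF distributions between two groups
#'
#' Two-sided Mann-Whitney rank-sum test using the normal approximation with
#' tie correction, with group medians reported alongside (the medians never
#' depend on the test choice).
#'
#' @param values_a,values_b numeric score vectors for the two groups.
#' @return list with `median_a`, `median_b`, `p_value`, `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop_urovaf("both groups must be non-empty", "urovaf_diagnostics_error")
  }
  p <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = FALSE, correct = FALSE)$p.value
  )
  if (is.nan(p)) p <- 1  # all values tied: no evidence of a shift
  list(median_a = median(values_a), median_b = median(values_b),
       p_value = p,
       method = "Mann-Whitney rank-sum, normal approximation with tie correction")
}

#' Stage/grade stratum for reporting
#'
#' Maps stage and grade to the reporting strata G1pTa, G2pTa, G3pTa, G2pT1,
#' G3pT1, MIBC (stage T2 or higher) and Other BC (stage or grade unrecorded,
#' carcinoma in situ, or G1pT1).
#'
#' @param stage character vector of stages (Tis/Ta/T1/T2plus/nr).
#' @param grade character vector of grades (G1/G2/G3/nr).
#' @return character vector of stratum labels.
#' @export
stage_grade_stratum <- function(stage, grade) {
  out <- rep("Other BC", length(stage))
  out[stage == "T2plus"] <- "MIBC"
  out[stage == "Ta" & grade == "G1"] <- "G1pTa"
  out[stage == "Ta" & grade == "G2"] <- "G2pTa"
  out[stage == "Ta" & grade == "G3"] <- "G3pTa"
  out[stage == "T1" & grade == "G2"] <- "G2pT1"
  out[stage == "T1" & grade == "G3"] <- "G3pT1"
  out
}

BC_STRATA <- c("G1pTa", "G2pTa", "G3pTa", "G2pT1", "G3pT1", "MIBC", "Other BC")

#' Per-gene detection counts by stage/grade stratum
#'
#' Builds the detection table reported for incident disease: for each panel
#' gene and each stage/grade stratum, the number of samples in which a
#' mutation in that gene was detected above the threshold; plus an "Any"
#' row (mutation in at least one gene — identical to the sample-level call),
#' per-stratum totals, and per-stratum sensitivity. Disease-free samples,
#' when present, contribute a "Non-BC" column whose bottom row is the
#' specificity.
#'
#' @param gene_calls tibble from [per_gene_calls()].
#' @param meta sample sheet rows matching `gene_calls$sample_id` (needs
#'   `bc_status`, `stage`, `grade`).
#' @return list with `counts` (tibble: one row per gene plus "Any", one
#'   column per stratum plus "All BCs" and optionally "Non-BC"), `n` (named
#'   totals per column), `sensitivity` (percent per BC column, NA where a
#'   stratum is empty) and `specificity` (percent, NA when no disease-free
#'   samples).
#' @export
stratified_table <- function(gene_calls, meta) {
  idx <- match(gene_calls$sample_id, meta$sample_id)
  if (anyNA(idx)) {
    stop_urovaf("gene_calls contains samples missing from the sample sheet",
                "urovaf_diagnostics_error")
  }
  meta <- meta[idx, ]
  genes <- setdiff(names(gene_calls), c("sample_id", "any_gene"))
  is_bc <- meta$bc_status
  stratum <- ifelse(is_bc, stage_grade_stratum(meta$stage, meta$grade), "Non-BC")
  cols <- c(BC_STRATA, "All BCs", if (any(!is_bc)) "Non-BC")
  in_col <- function(colname) {
    if (colname == "All BCs") is_bc else stratum == colname
  }
  count_row <- function(flag) {
    vapply(cols, function(cn) sum(flag & in_col(cn)), integer(1))
  }
  counts <- do.call(rbind, lapply(genes, function(g) count_row(gene_calls[[g]])))
  counts <- rbind(counts, count_row(gene_calls$any_gene))
  n_col <- vapply(cols, function(cn) sum(in_col(cn)), integer(1))
  any_row <- counts[nrow(counts), ]
  sens <- ifelse(n_col > 0, round_half_up(100 * any_row / n_col), NA_real_)
  sens[cols == "Non-BC"] <- NA_real_
  specificity <- if ("Non-BC" %in% cols) {
    round_half_up(100 * (n_col[["Non-BC"]] - any_row[["Non-BC"]]) / n_col[["Non-BC"]])
  } else {
    NA_real_
  }
  tab <- tibble::as_tibble(as.data.frame(counts))
  names(tab) <- cols
  tab <- cbind(tibble::tibble(gene = c(genes, "Any")), tab)
  list(counts = tibble::as_tibble(tab), n = n_col, sensitivity = sens,
       specificity = specificity)
}
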