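test_that("exact binomial CI handles boundaries and matches binom.test", {
  ci0 <- exact_binomial_ci(0, 10)
  expect_equal(ci0$lower, 0)
  cin <- exact_binomial_ci(10, 10)
  expect_equal(cin$upper, 1)
  expect_true(all(with(exact_binomial_ci(5, 20),
                       lower <= point & point <= upper)))
  expect_error(exact_binomial_ci(5, 0), class = "urovaf_ci_error")
  expect_error(exact_binomial_ci(11, 10), class = "urovaf_ci_error")
  set.seed(71)
  for (i in 1:200) {
    n <- sample(1:400, 1)
    k <- sample(0:n, 1)
    ci <- exact_binomial_ci(k, n)
    ref <- stats::binom.test(k, n)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson coverage is at least nominal (conservatism)", {
  set.seed(72)
  n <- 50; p <- 0.7; reps <- 1e4
  k <- rbinom(reps, n, p)
  alpha <- 0.025
  lower <- ifelse(k == 0, 0, qbeta(alpha, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha, k + 1, n - k))
  coverage <- mean(lower <= p & p <= upper)
  expect_gte(coverage, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("sensitivity/specificity summaries print like a clinical report", {
  ds <- diagnostic_summary(tp = 109, fn = 56, fp = 23, tn = 261)
  expect_equal(ds$sensitivity_text, "66% (95% CI 58-73%)")
  expect_equal(ds$specificity_text, "92% (95% CI 88-95%)")
  perfect <- diagnostic_summary(tp = 20, fn = 0, fp = 0, tn = 10)
  expect_equal(perfect$sensitivity$point, 1)
  expect_equal(perfect$sensitivity$upper, 1)
  undef <- diagnostic_summary(tp = 0, fn = 0, fp = 2, tn = 8)
  expect_false(undef$sensitivity_defined)
  expect_equal(undef$sensitivity_text, "undefined")
})

test_that("sens_spec from calls equals the counts route", {
  set.seed(73)
  disease <- rep(c(TRUE, FALSE), c(40, 60))
  positive <- ifelse(disease, runif(100) < 0.7, runif(100) < 0.1)
  ds <- sens_spec(positive, disease)
  expect_equal(unname(ds$counts["tp"] + ds$counts["fn"]), 40)
  expect_equal(ds$sensitivity$point, mean(positive[disease]))
  expect_equal(ds$specificity$point, mean(!positive[!disease]))
})

test_that("AUC equals the pairwise rank oracle and handles separation", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 1)
  set.seed(74)
  for (i in 1:1000) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    scores <- c(sample(0:5, n1, replace = TRUE) / 5,
                sample(0:5, n0, replace = TRUE) / 5)
    disease <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(roc_auc(scores, disease)$auc, oracle_auc(scores, disease))
  }
})

test_that("AUC under label-independent scores is near 1/2", {
  set.seed(75)
  scores <- rlnorm(2000, log(0.01), 1)
  disease <- rep(c(TRUE, FALSE), each = 1000)
  auc <- roc_auc(scores, disease)$auc
  se_null <- sqrt((1000 + 1000 + 1) / (12 * 1000 * 1000))
  expect_lt(abs(auc - 0.5), 3 * se_null)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(76)
  scores <- rlnorm(60, log(0.02), 1)
  disease <- runif(60) < 0.4
  disease[1:2] <- c(TRUE, FALSE)
  a1 <- roc_auc(scores, disease)$auc
  expect_equal(roc_auc(log(scores), disease)$auc, a1)
  expect_equal(roc_auc(scores^3, disease)$auc, a1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- rlnorm(120, log(0.02), 1.2)
  disease <- runif(120) < 0.5
  disease[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(disease, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, disease)$auc, ref, tolerance = 1e-12)
})

test_that("ROC errors when one class is absent", {
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), class = "urovaf_roc_error")
})

test_that("relative risk is the risk ratio, 1 under equal rates", {
  rr <- relative_risk(a = 8, b = 31, c = 10, d = 215)
  expect_equal(rr$rr, (8 / 39) / (10 / 225))
  expect_equal(rr$ci_method, "Katz log-normal")
  expect_equal(relative_risk(5, 5, 10, 10)$rr, 1)
  set.seed(78)
  for (i in 1:1000) {
    x <- sample(1:50, 4, replace = TRUE)
    rr <- relative_risk(x[1], x[2], x[3], x[4])
    expect_equal(rr$rr, (x[1] / (x[1] + x[2])) / (x[3] / (x[3] + x[4])))
  }
  # equal event rates in both arms -> RR 1, whatever the table
  for (i in 1:200) {
    k <- sample(1:20, 1); m <- sample(1:20, 1)
    f <- sample(1:5, 1)
    expect_equal(relative_risk(k, m, f * k, f * m)$rr, 1)
  }
})

test_that("zero event cells are flagged or continuity-corrected", {
  rr <- relative_risk(3, 7, 0, 10)
  expect_true(rr$degenerate)
  expect_true(is.infinite(rr$rr))
  rrc <- relative_risk(3, 7, 0, 10, correction = TRUE)
  expect_true(is.finite(rrc$rr))
  expect_true(rrc$corrected)
})

test_that("age-band false-positive rates count per band", {
  ages <- c(rep(40, 5), rep(55, 22), rep(70, 10))
  pos <- c(rep(FALSE, 5), rep(c(TRUE, FALSE), c(2, 20)), rep(FALSE, 10))
  ab <- age_band_fpr(pos, ages)
  expect_equal(ab$band, c("0-49", "50-64", ">=65"))
  expect_equal(ab$n, c(5L, 22L, 10L))
  expect_equal(round_half_up(100 * ab$fpr), c(0, 9, 0))
  none <- age_band_fpr(logical(0), numeric(0))
  expect_true(all(is.na(none$fpr)))
  all_neg <- age_band_fpr(rep(FALSE, 30), rep(c(40, 55, 70), 10))
  expect_equal(all_neg$fpr, c(0, 0, 0))
})

test_that("group comparison reports medians and a rank-sum p-value", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$median_a, same$median_b)
  # exact enumeration oracle for a fully separated small case
  expect_equal(oracle_rank_sum_p(c(1, 2, 3), c(10, 11, 12)), 0.05)
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_lt(sep$p_value, 0.1)  # normal approximation of the 2*0.05 two-sided p
  set.seed(79)
  big <- compare_groups(rlnorm(200, log(0.06), 1), rlnorm(200, log(0.007), 1))
  expect_lt(big$p_value, 0.001)
  expect_gt(big$median_a, big$median_b)
})

test_that("stage/grade strata follow the reporting convention", {
  expect_equal(stage_grade_stratum(c("Ta", "Ta", "Ta", "T1", "T1", "T2plus"),
                                   c("G1", "G2", "G3", "G2", "G3", "G3")),
               c("G1pTa", "G2pTa", "G3pTa", "G2pT1", "G3pT1", "MIBC"))
  # unrecorded stage or grade, CIS and G1pT1 all route to Other BC
  expect_equal(stage_grade_stratum(c("nr", "Ta", "Tis", "T1"),
                                   c("G2", "nr", "G3", "G1")),
               rep("Other BC", 4))
})

test_that("stratified table matches the classifier and OR logic", {
  panel <- tiny_panel()
  n <- 60
  set.seed(80)
  counts <- tibble::tibble(
    sample_id = rep(sprintf("S%02d", 1:n), each = 3),
    chrom = rep(panel$hotspots$chrom, n), pos = rep(panel$hotspots$pos, n),
    alt = rep(panel$hotspots$alt, n), depth = 1000L,
    alt_count = as.integer(sample(0:50, 3 * n, replace = TRUE))
  )
  meta <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:n),
    cohort = "haematuria_test",
    bc_status = rep(c(TRUE, FALSE), c(40, 20)),
    age = 70, sex = "M",
    stage = c(sample(c("Ta", "T1", "T2plus", "nr"), 40, replace = TRUE),
              rep("nr", 20)),
    grade = c(sample(c("G1", "G2", "G3", "nr"), 40, replace = TRUE),
              rep("nr", 20)),
    future_recurrence = NA
  )
  vt <- pileup_vaf(counts, panel)
  gc <- per_gene_calls(vt, panel, 0.02)
  st <- stratified_table(gc, meta)
  # Any row equals the sample-level classifier, summed per column
  calls <- classify(max_vaf(vt, panel), 0.02)
  any_row <- unlist(st$counts[st$counts$gene == "Any", -1])
  expect_equal(unname(any_row["All BCs"]),
               sum(calls$positive & meta$bc_status))
  # gene rows can only exceed the Any row jointly (OR logic)
  gene_rows <- st$counts[st$counts$gene != "Any", -1]
  expect_true(all(apply(gene_rows, 2, max) <= unlist(any_row) |
                    unlist(any_row) == 0))
  expect_true(all(colSums(gene_rows) >= unlist(any_row)))
  # specificity column
  expect_equal(st$specificity,
               round_half_up(100 * mean(!calls$positive[!meta$bc_status])))
})

test_that("an all-positive stratum reports 100 and empty strata report NA", {
  panel <- tiny_panel()
  meta <- tibble::tibble(
    sample_id = c("A", "B"), cohort = "haematuria_test", bc_status = TRUE,
    age = 70, sex = "M", stage = "Ta", grade = "G3", future_recurrence = NA
  )
  counts <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 3),
    chrom = rep(panel$hotspots$chrom, 2), pos = rep(panel$hotspots$pos, 2),
    alt = rep(panel$hotspots$alt, 2), depth = 1000L,
    alt_count = rep(c(50L, 0L, 0L), 2)
  )
  gc <- per_gene_calls(pileup_vaf(counts, panel), panel, 0.02)
  st <- stratified_table(gc, meta)
  expect_equal(unname(st$sensitivity["G3pTa"]), 100)
  expect_true(is.na(st$sensitivity["G1pTa"]))
  expect_true(is.na(st$specificity) || length(st$specificity) == 0)
})
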