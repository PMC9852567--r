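#' Synthetic cohort and read simulator
#'
#' Generates urine cell-pellet DNA sequencing data with the statistical
#' structure the analysis assumes, so every pipeline stage is testable
#' without access to patient data. Background error is modelled per
#' consensus base (post error-suppression) because all analysis-level
#' quantities are consensus-level; raw read simulation exists to exercise
#' the consensus module. Disease-free urine carries, with an age-dependent
#' probability, a single clonal hotspot (clonal expansion of
#' APOBEC-mutated cells); tumour-bearing urine carries a mutated hotspot
#' with the tumour mutation prevalence, at VAFs drawn from a log-normal
#' around the cohort-appropriate median.
#'
#' @name synthetic_data
NULL

#' Simulation parameters
#'
#' All knobs of the synthetic cohort/read generator. Defaults reproduce the
#' study conditions: ~2,400x consensus depth from ~35,400x raw depth
#' (14.75 raw reads per consensus family), consensus-level substitution
#' error 1e-3 split evenly among the three alt bases, age-banded
#' probabilities of a detectable background clonal hotspot in disease-free
#' urine (<1% below age 50, 9% at 50-64, 14% at 65+) with clone VAFs
#' log-normal around a 3% median, 74% tumour mutation prevalence, and
#' tumour max-VAF medians of 6% (incident disease), 3.3% (recurrent
#' disease at collection) and 1.7% (pre-recurrence: cystoscopy-negative
#' samples from patients who recur at the next visit).
#'
#' @param seed root seed; all draws derive from it through named
#'   sub-streams, so adding samples never perturbs earlier ones.
#' @param n_non_bc,n_bc haematuria-cohort arm sizes (disease-free / incident
#'   disease).
#' @param n_surveillance_no_recur,n_surveillance_recur surveillance-cohort
#'   arm sizes (cystoscopy-negative / recurrence at collection).
#' @param training_fraction fraction of disease-free haematuria samples
#'   assigned to the calibration training set.
#' @param consensus_depth_mean expected quality-passing consensus depth per
#'   site (Poisson mean).
#' @param raw_per_consensus_mean expected raw reads per UMI family.
#' @param per_base_error consensus-level substitution probability per base,
#'   split evenly among the three non-reference bases.
#' @param raw_error_rate per-raw-read substitution probability (read-level
#'   simulation only).
#' @param low_qual_fraction fraction of consensus calls drawn below the
#'   quality-30 filter (read-level simulation only).
#' @param background_clonal_prob_by_age named vector of probabilities that a
#'   disease-free sample carries a detectable clonal hotspot, by age band
#'   `under50` / `age50to64` / `over65`.
#' @param background_clonal_vaf_median,background_clonal_vaf_logsd
#'   log-normal parameters of the background clone VAF.
#' @param multi_site_background if TRUE each site may independently carry a
#'   background clone (default FALSE: at most one clonal hotspot per
#'   sample).
#' @param tumour_mutation_prevalence probability an incident/recurrent
#'   tumour carries at least one panel hotspot mutation.
#' @param tumour_max_vaf_median,recurrence_max_vaf_median,pre_recurrence_max_vaf_median
#'   log-normal medians of the tumour-derived VAF for incident disease,
#'   recurrence at collection, and pre-recurrence samples.
#' @param tumour_vaf_logsd log-sd of the tumour VAF distribution.
#' @param pre_recurrence_fraction fraction of cystoscopy-negative
#'   surveillance samples whose patient recurs at the next visit.
#' @param site_error_overrides named numeric vector mapping
#'   `"chrom:pos:alt"` keys to an elevated per-base error (e.g. 0.003 for a
#'   germline-noise-prone site); empty by default.
#' @param age_mean_non_bc,age_mean_bc,age_mean_surveillance,age_sd
#'   demographics: normal age generator means and sd (rounded, truncated to
#'   18-95).
#' @param male_fraction_non_bc,male_fraction_bc,male_fraction_surveillance
#'   sex ratios.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_non_bc = 426L, n_bc = 165L,
                       n_surveillance_no_recur = 264L,
                       n_surveillance_recur = 29L,
                       training_fraction = 142 / 426,
                       consensus_depth_mean = 2400,
                       raw_per_consensus_mean = 14.75,
                       per_base_error = 1e-3,
                       raw_error_rate = 5e-3,
                       low_qual_fraction = 0.05,
                       background_clonal_prob_by_age =
                         c(under50 = 0.01, age50to64 = 0.09, over65 = 0.14),
                       background_clonal_vaf_median = 0.03,
                       background_clonal_vaf_logsd = 0.25,
                       multi_site_background = FALSE,
                       tumour_mutation_prevalence = 0.74,
                       tumour_max_vaf_median = 0.06,
                       recurrence_max_vaf_median = 0.033,
                       pre_recurrence_max_vaf_median = 0.017,
                       tumour_vaf_logsd = 1.0,
                       pre_recurrence_fraction = 18 / 264,
                       site_error_overrides = numeric(),
                       age_mean_non_bc = 59, age_mean_bc = 72,
                       age_mean_surveillance = 73, age_sd = 12,
                       male_fraction_non_bc = 0.52, male_fraction_bc = 0.80,
                       male_fraction_surveillance = 0.66) {
  p <- as.list(environment())
  probs <- c(p$per_base_error, p$raw_error_rate, p$low_qual_fraction,
             p$background_clonal_prob_by_age, p$tumour_mutation_prevalence,
             p$training_fraction, p$pre_recurrence_fraction,
             p$male_fraction_non_bc, p$male_fraction_bc,
             p$male_fraction_surveillance, p$site_error_overrides)
  if (any(probs < 0 | probs > 1)) {
    stop_urovaf("all probabilities must lie in [0,1]", "urovaf_sim_error")
  }
  if (p$consensus_depth_mean <= 0 || p$raw_per_consensus_mean <= 0) {
    stop_urovaf("depths must be > 0", "urovaf_sim_error")
  }
  medians <- c(p$background_clonal_vaf_median, p$tumour_max_vaf_median,
               p$recurrence_max_vaf_median, p$pre_recurrence_max_vaf_median)
  if (any(medians <= 0)) stop_urovaf("VAF medians must be > 0", "urovaf_sim_error")
  if (any(c(p$n_non_bc, p$n_bc, p$n_surveillance_no_recur,
            p$n_surveillance_recur) < 0)) {
    stop_urovaf("cohort sizes must be >= 0", "urovaf_sim_error")
  }
  if (!setequal(names(p$background_clonal_prob_by_age),
                c("under50", "age50to64", "over65"))) {
    stop_urovaf("background_clonal_prob_by_age needs bands under50/age50to64/over65",
                "urovaf_sim_error")
  }
  structure(p, class = "sim_params")
}

age_band_prob <- function(age, params) {
  p <- params$background_clonal_prob_by_age
  ifelse(age < 50, p[["under50"]], ifelse(age < 65, p[["age50to64"]], p[["over65"]]))
}

site_error <- function(panel, params) {
  err <- rep(params$per_base_error, nrow(panel$hotspots))
  if (length(params$site_error_overrides) > 0) {
    hit <- match(panel_keys(panel), names(params$site_error_overrides))
    err[!is.na(hit)] <- params$site_error_overrides[hit[!is.na(hit)]]
  }
  err
}

#' Simulate quality-filtered site counts for one sample
#'
#' Depth at each panel site is Poisson with mean `consensus_depth_mean`;
#' the alt count is binomial with success probability
#' `true_vaf + per_base_error/3 * (1 - true_vaf)` (one third of the
#' substitution error hits the specific alt base). Deterministic given the
#' seed.
#'
#' @param panel a `hotspot_panel`.
#' @param truth_vafs named numeric vector of true somatic VAFs keyed by
#'   `"chrom:pos:alt"`; sites absent from the vector have true VAF 0.
#' @param params a `sim_params` object.
#' @param seed integer seed (defaults to `params$seed`).
#' @param sample_id sample identifier attached to the output.
#' @return tibble of site counts (`sample_id`, `chrom`, `pos`, `alt`,
#'   `depth`, `alt_count`).
#' @export
simulate_counts <- function(panel, truth_vafs = numeric(), params = sim_params(),
                            seed = params$seed, sample_id = "sample") {
  keys <- panel_keys(panel)
  v <- rep(0, length(keys))
  if (length(truth_vafs) > 0) {
    if (any(truth_vafs < 0 | truth_vafs > 1)) {
      stop_urovaf("true VAFs must lie in [0,1]", "urovaf_sim_error")
    }
    hit <- match(names(truth_vafs), keys)
    if (anyNA(hit)) {
      stop_urovaf("truth_vafs keys must be panel sites", "urovaf_sim_error")
    }
    v[hit] <- truth_vafs
  }
  set.seed(seed)
  err <- site_error(panel, params)
  depth <- rpois(length(keys), params$consensus_depth_mean)
  p_alt <- v + err / 3 * (1 - v)
  n_alt <- rbinom(length(keys), depth, p_alt)
  tibble::tibble(
    sample_id = sample_id,
    chrom = panel$hotspots$chrom, pos = panel$hotspots$pos,
    alt = panel$hotspots$alt, depth = depth, alt_count = n_alt
  )
}

#' Simulate UMI-tagged raw reads for one sample
#'
#' Emits read records at each panel site: the number of UMI families is
#' Poisson with mean `n_families_mean`, family sizes are
#' `1 + Poisson(raw_per_consensus_mean - 1)`, each family's source molecule
#' carries the alt base with probability equal to the true VAF, raw reads
#' substitute away from the molecule base at `raw_error_rate`, and Phred
#' qualities fall below the quality-30 filter with probability
#' `low_qual_fraction`. Collapsing these reads with [collapse_reads()] and
#' quantifying with [pileup_vaf()] recovers the generating VAF within
#' binomial sampling error.
#'
#' @inheritParams simulate_counts
#' @param n_families_mean expected UMI families per site (defaults to the
#'   consensus depth mean).
#' @return tibble of read records.
#' @export
simulate_reads <- function(panel, truth_vafs = numeric(), params = sim_params(),
                           seed = params$seed, sample_id = "sample",
                           n_families_mean = params$consensus_depth_mean) {
  keys <- panel_keys(panel)
  v <- rep(0, length(keys))
  if (length(truth_vafs) > 0) {
    hit <- match(names(truth_vafs), keys)
    if (anyNA(hit)) stop_urovaf("truth_vafs keys must be panel sites", "urovaf_sim_error")
    v[hit] <- truth_vafs
  }
  set.seed(seed)
  sites <- panel$hotspots
  out <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    nf <- rpois(1, n_families_mean)
    if (nf == 0) next
    sizes <- 1L + rpois(nf, max(0, params$raw_per_consensus_mean - 1))
    mol_alt <- runif(nf) < v[s]
    mol_base <- ifelse(mol_alt, sites$alt[s], sites$ref[s])
    n_reads <- sum(sizes)
    fam <- rep(seq_len(nf), sizes)
    base <- rep(mol_base, sizes)
    err <- runif(n_reads) < params$raw_error_rate
    if (any(err)) {
      base[err] <- vapply(base[err], function(b) sample(setdiff(DNA_BASES, b), 1),
                          character(1))
    }
    qual <- ifelse(runif(n_reads) < params$low_qual_fraction, 25L, 37L)
    umis <- vapply(seq_len(nf), function(i) {
      paste(sample(DNA_BASES, 10, replace = TRUE), collapse = "")
    }, character(1))
    frag <- sites$pos[s] - sample.int(80L, nf, replace = TRUE)
    out[[s]] <- tibble::tibble(
      read_id = sprintf("%s_s%d_f%d_r%d", sample_id, s, fam,
                        sequence(sizes)),
      umi = umis[fam], chrom = sites$chrom[s], frag_start = frag[fam],
      pos = sites$pos[s], base = base, qual = qual
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(validate_reads(tibble::tibble(
      read_id = character(), umi = character(), chrom = character(),
      frag_start = integer(), pos = integer(), base = character(),
      qual = integer())))
  }
  do.call(rbind, out)
}

## draw the ground-truth VAF vector for one sample; returns a named numeric
## (possibly empty) keyed by hotspot key
draw_truth <- function(keys, kind, age, params) {
  if (kind %in% c("bc", "recurrence")) {
    if (runif(1) < params$tumour_mutation_prevalence) {
      med <- if (kind == "bc") params$tumour_max_vaf_median else params$recurrence_max_vaf_median
      vaf <- min(1, rlnorm(1, log(med), params$tumour_vaf_logsd))
      site <- sample.int(length(keys), 1)
      return(stats::setNames(vaf, keys[site]))
    }
    return(numeric())
  }
  if (kind == "pre_recurrence") {
    vaf <- min(1, rlnorm(1, log(params$pre_recurrence_max_vaf_median),
                         params$tumour_vaf_logsd))
    return(stats::setNames(vaf, keys[sample.int(length(keys), 1)]))
  }
  ## disease-free background: age-banded clonal expansion
  p <- age_band_prob(age, params)
  if (params$multi_site_background) {
    hit <- which(runif(length(keys)) < p)
    if (length(hit) == 0) return(numeric())
    vaf <- pmin(1, rlnorm(length(hit), log(params$background_clonal_vaf_median),
                          params$background_clonal_vaf_logsd))
    return(stats::setNames(vaf, keys[hit]))
  }
  if (runif(1) < p) {
    vaf <- min(1, rlnorm(1, log(params$background_clonal_vaf_median),
                         params$background_clonal_vaf_logsd))
    return(stats::setNames(vaf, keys[sample.int(length(keys), 1)]))
  }
  numeric()
}

draw_age <- function(mean, sd) {
  max(18, min(95, round(rnorm(1, mean, sd))))
}

## stage/grade strata frequencies for incident disease (reporting strata)
STRATUM_WEIGHTS <- c(G1pTa = 23, G2pTa = 42, G3pTa = 15, G2pT1 = 8,
                     G3pT1 = 24, MIBC = 36, "Other BC" = 17)
STRATUM_STAGE <- c(G1pTa = "Ta", G2pTa = "Ta", G3pTa = "Ta", G2pT1 = "T1",
                   G3pT1 = "T1", MIBC = "T2plus", "Other BC" = "nr")
STRATUM_GRADE <- c(G1pTa = "G1", G2pTa = "G2", G3pTa = "G3", G2pT1 = "G2",
                   G3pT1 = "G3", MIBC = "G3", "Other BC" = "nr")

#' Simulate a full synthetic cohort
#'
#' Generates a sample sheet, per-site counts and the generating ground
#' truth for a haematuria cohort (disease-free training/test arms plus
#' incident disease), a surveillance cohort (cystoscopy-negative samples,
#' a pre-recurrence subset, and recurrences at collection), or both.
#' Reproducible given the seed; each sample draws from its own derived
#' sub-seed so enlarging the cohort never changes earlier samples.
#'
#' @param panel a `hotspot_panel`.
#' @param params a `sim_params` object.
#' @param seed root seed (defaults to `params$seed`).
#' @param cohort which cohort(s) to generate: "haematuria", "surveillance"
#'   or "both".
#' @return list of class `sim_cohort` with elements `samples` (sample
#'   sheet tibble), `counts` (site-count tibble over all samples) and
#'   `truth` (tibble `sample_id`, `site_key`, `true_vaf` of nonzero somatic
#'   VAFs).
#' @export
simulate_cohort <- function(panel, params = sim_params(), seed = params$seed,
                            cohort = c("haematuria", "surveillance", "both")) {
  cohort <- match.arg(cohort)
  keys <- panel_keys(panel)
  spec <- list()
  if (cohort %in% c("haematuria", "both")) {
    n_train <- round(params$training_fraction * params$n_non_bc)
    spec <- c(spec, list(
      list(kind = "non_bc", n = n_train, cohort = "haematuria_training",
           age_mean = params$age_mean_non_bc, male = params$male_fraction_non_bc),
      list(kind = "non_bc", n = params$n_non_bc - n_train, cohort = "haematuria_test",
           age_mean = params$age_mean_non_bc, male = params$male_fraction_non_bc),
      list(kind = "bc", n = params$n_bc, cohort = "haematuria_test",
           age_mean = params$age_mean_bc, male = params$male_fraction_bc)
    ))
  }
  if (cohort %in% c("surveillance", "both")) {
    n_pre <- round(params$pre_recurrence_fraction * params$n_surveillance_no_recur)
    spec <- c(spec, list(
      list(kind = "pre_recurrence", n = n_pre, cohort = "surveillance",
           age_mean = params$age_mean_surveillance,
           male = params$male_fraction_surveillance),
      list(kind = "non_bc_surv", n = params$n_surveillance_no_recur - n_pre,
           cohort = "surveillance", age_mean = params$age_mean_surveillance,
           male = params$male_fraction_surveillance),
      list(kind = "recurrence", n = params$n_surveillance_recur,
           cohort = "surveillance", age_mean = params$age_mean_surveillance,
           male = params$male_fraction_surveillance)
    ))
  }
  n_total <- sum(vapply(spec, function(g) g$n, numeric(1)))
  if (n_total == 0) stop_urovaf("empty cohort requested", "urovaf_sim_error")

  n_sites <- length(keys)
  meta <- vector("list", n_total)
  depth_mat <- matrix(0L, nrow = n_total, ncol = n_sites)
  alt_mat <- matrix(0L, nrow = n_total, ncol = n_sites)
  truth_list <- vector("list", n_total)
  i <- 0L
  for (g in spec) {
    if (g$n == 0) next
    for (k in seq_len(g$n)) {
      i <- i + 1L
      sid <- sprintf("S%05d", i)
      set.seed(derive_seed(seed, "sample", i))
      age <- draw_age(g$age_mean, params$age_sd)
      sex <- if (runif(1) < g$male) "M" else "F"
      kind <- g$kind
      is_bc <- kind %in% c("bc", "recurrence")
      if (kind == "bc") {
        stratum <- sample(names(STRATUM_WEIGHTS), 1,
                          prob = STRATUM_WEIGHTS / sum(STRATUM_WEIGHTS))
        stage <- STRATUM_STAGE[[stratum]]
        grade <- STRATUM_GRADE[[stratum]]
      } else if (kind == "recurrence") {
        stage <- "Ta"; grade <- sample(c("G1", "G2", "G3"), 1)
      } else {
        stage <- "nr"; grade <- "nr"
      }
      truth_kind <- switch(kind, non_bc = , non_bc_surv = "non_bc", kind)
      tv <- draw_truth(keys, truth_kind, age, params)
      sc <- simulate_counts(panel, tv, params,
                            seed = derive_seed(seed, "counts", i),
                            sample_id = sid)
      depth_mat[i, ] <- sc$depth
      alt_mat[i, ] <- sc$alt_count
      meta[[i]] <- list(sample_id = sid, cohort = g$cohort, bc_status = is_bc,
                        age = age, sex = sex, stage = stage, grade = grade,
                        future_recurrence = switch(kind,
                          pre_recurrence = TRUE,
                          non_bc_surv = FALSE,
                          NA))
      if (length(tv) > 0) {
        truth_list[[i]] <- tibble::tibble(sample_id = sid, site_key = names(tv),
                                          true_vaf = unname(tv))
      }
    }
  }
  samples <- tibble::tibble(
    sample_id = vapply(meta, `[[`, character(1), "sample_id"),
    cohort = vapply(meta, `[[`, character(1), "cohort"),
    bc_status = vapply(meta, `[[`, logical(1), "bc_status"),
    age = vapply(meta, `[[`, numeric(1), "age"),
    sex = vapply(meta, `[[`, character(1), "sex"),
    stage = vapply(meta, `[[`, character(1), "stage"),
    grade = vapply(meta, `[[`, character(1), "grade"),
    future_recurrence = vapply(meta, `[[`, logical(1), "future_recurrence")
  )
  counts <- tibble::tibble(
    sample_id = rep(samples$sample_id, each = n_sites),
    chrom = rep(panel$hotspots$chrom, n_total),
    pos = rep(panel$hotspots$pos, n_total),
    alt = rep(panel$hotspots$alt, n_total),
    depth = as.integer(t(depth_mat)),
    alt_count = as.integer(t(alt_mat))
  )
  truth_list <- truth_list[!vapply(truth_list, is.null, logical(1))]
  truth <- if (length(truth_list) > 0) {
    do.call(rbind, truth_list)
  } else {
    tibble::tibble(sample_id = character(), site_key = character(),
                   true_vaf = numeric())
  }
  structure(list(samples = samples, counts = counts, truth = truth,
                 params = params, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%d disease-positive), %d panel sites\n",
              nrow(x$samples), sum(x$samples$bc_status),
              length(unique(paste(x$counts$chrom, x$counts$pos, x$counts$alt)))))
  print(table(x$samples$cohort, x$samples$bc_status))
  invisible(x)
}

#' Write a small complete demo cohort to disk
#'
#' Generates a reduced synthetic cohort and writes the sample sheet, site
#' counts and panel as TSV fixtures into a directory.
#'
#' @param dir output directory (created if needed).
#' @param panel a `hotspot_panel` (default [default_panel()]).
#' @param seed root seed.
#' @return named character vector of written paths, invisibly.
#' @export
write_demo_fixtures <- function(dir, panel = default_panel(), seed = 20260924) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- sim_params(seed = seed, n_non_bc = 45, n_bc = 25,
                       n_surveillance_no_recur = 40, n_surveillance_recur = 8)
  sim <- simulate_cohort(panel, params, cohort = "both")
  paths <- c(
    panel = file.path(dir, "panel.tsv"),
    samples = file.path(dir, "samples.tsv"),
    counts = file.path(dir, "site_counts.tsv")
  )
  write_panel(panel, paths["panel"])
  write_sample_sheet(sim$samples, paths["samples"])
  write_site_counts(sim$counts, paths["counts"])
  invisible(paths)
}
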