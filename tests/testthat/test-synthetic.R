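test_that("count simulation is deterministic and conserves alt <= depth", {
  panel <- tiny_panel()
  params <- sim_params(seed = 11)
  a <- simulate_counts(panel, c("chr10:96162368:T" = 0.05), params, seed = 99)
  b <- simulate_counts(panel, c("chr10:96162368:T" = 0.05), params, seed = 99)
  expect_identical(a, b)
  expect_true(all(a$alt_count <= a$depth))
  expect_true(all(a$alt_count >= 0))
})

test_that("no noise and no signal yields zero alt counts", {
  panel <- tiny_panel()
  params <- sim_params(per_base_error = 0)
  sc <- simulate_counts(panel, numeric(), params, seed = 5)
  expect_true(all(sc$alt_count == 0))
})

test_that("observed VAF falls in the exact binomial band around the truth", {
  panel <- tiny_panel()
  params <- sim_params(per_base_error = 0)
  v <- 0.05
  lo <- qbinom(5e-4, 2400, v)
  hi <- qbinom(1 - 5e-4, 2400, v)
  hits <- 0L
  for (s in 1:1000) {
    sc <- simulate_counts(panel, c("chr10:96162368:T" = v), params, seed = s)
    k <- sc$alt_count[sc$pos == 96162368]
    d <- sc$depth[sc$pos == 96162368]
    # rescale the band to the realised Poisson depth
    hits <- hits + (k >= qbinom(5e-4, d, v) && k <= qbinom(1 - 5e-4, d, v))
  }
  expect_gte(hits, 999L)
})

test_that("simulated reads collapse and quantify back to the generating VAF", {
  panel <- hotspot_panel(data.frame(gene = "TBC1D12", chrom = "chr10",
                                    pos = 96162368L, ref = "C", alt = "T"))
  params <- sim_params(raw_error_rate = 0.002, low_qual_fraction = 0.05)
  reads <- simulate_reads(panel, c("chr10:96162368:T" = 0.05), params,
                          seed = 21, n_families_mean = 2400)
  calls <- collapse_reads(reads, min_family_size = 3)
  expect_true(all(calls$family_size >= 3))
  vt <- pileup_vaf(calls, panel, min_baseq = 30)
  expect_lt(abs(vt$vaf - 0.05), 3 * sqrt(0.05 * 0.95 / 2400))
})

test_that("zero raw error and zero true VAF gives all-reference consensus", {
  panel <- tiny_panel()
  params <- sim_params(raw_error_rate = 0, low_qual_fraction = 0)
  reads <- simulate_reads(panel, numeric(), params, seed = 22,
                          n_families_mean = 50)
  calls <- collapse_reads(reads)
  ref_of <- panel$hotspots$ref[match(calls$pos, panel$hotspots$pos)]
  expect_true(all(calls$base == ref_of))
})

test_that("cohort simulation is reproducible and shaped like the study design", {
  panel <- tiny_panel()
  params <- sim_params(seed = 31, n_non_bc = 426, n_bc = 165,
                       consensus_depth_mean = 200)
  sim1 <- simulate_cohort(panel, params, cohort = "haematuria")
  sim2 <- simulate_cohort(panel, params, cohort = "haematuria")
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$samples, sim2$samples)
  tab <- table(sim1$samples$cohort, sim1$samples$bc_status)
  expect_equal(unname(tab["haematuria_training", "FALSE"]), 142)
  expect_equal(unname(tab["haematuria_test", "FALSE"]), 284)
  expect_equal(unname(tab["haematuria_test", "TRUE"]), 165)
})

test_that("enlarging the cohort never perturbs earlier samples", {
  panel <- tiny_panel()
  small <- simulate_cohort(panel, sim_params(seed = 32, n_non_bc = 20, n_bc = 0,
                                             consensus_depth_mean = 100),
                           cohort = "haematuria")
  # growing the BC arm appends samples; the first 20 non-BC draws are untouched
  big <- simulate_cohort(panel, sim_params(seed = 32, n_non_bc = 20, n_bc = 15,
                                           consensus_depth_mean = 100),
                         cohort = "haematuria")
  first <- small$samples$sample_id
  expect_identical(small$counts, big$counts[big$counts$sample_id %in% first, ])
  expect_identical(small$samples, big$samples[big$samples$sample_id %in% first, ])
})

test_that("an empty BC arm yields only disease-free samples", {
  panel <- tiny_panel()
  sim <- simulate_cohort(panel, sim_params(seed = 33, n_non_bc = 30, n_bc = 0,
                                           consensus_depth_mean = 100),
                         cohort = "haematuria")
  expect_false(any(sim$samples$bc_status))
  expect_error(simulate_cohort(panel, sim_params(seed = 33, n_non_bc = 0, n_bc = 0,
                                                 n_surveillance_no_recur = 0,
                                                 n_surveillance_recur = 0),
                               cohort = "both"),
               class = "urovaf_sim_error")
})

test_that("true VAFs live on panel sites and in [0,1]", {
  panel <- tiny_panel()
  sim <- simulate_cohort(panel, sim_params(seed = 34, n_non_bc = 50, n_bc = 50,
                                           consensus_depth_mean = 100),
                         cohort = "haematuria")
  expect_true(all(sim$truth$true_vaf >= 0 & sim$truth$true_vaf <= 1))
  expect_true(all(sim$truth$site_key %in%
                    paste(panel$hotspots$chrom, panel$hotspots$pos,
                          panel$hotspots$alt, sep = ":")))
  expect_error(simulate_counts(panel, c("chr10:96162368:T" = 1.5),
                               sim_params()),
               class = "urovaf_sim_error")
})

test_that("a per-site error override elevates background at that site only", {
  panel <- tiny_panel()
  params <- sim_params(site_error_overrides = c("chr11:62609254:A" = 0.003))
  alt_w <- 0; alt_o <- 0; dep_w <- 0; dep_o <- 0
  for (s in 1:80) {
    sc <- simulate_counts(panel, numeric(), params, seed = 1000 + s)
    wdr <- sc$pos == 62609254
    alt_w <- alt_w + sum(sc$alt_count[wdr]); dep_w <- dep_w + sum(sc$depth[wdr])
    alt_o <- alt_o + sum(sc$alt_count[!wdr]); dep_o <- dep_o + sum(sc$depth[!wdr])
  }
  # override implies a 3x higher per-alt error (0.3%/3 vs 0.1%/3)
  expect_gt(alt_w / dep_w, 2 * alt_o / dep_o)
})

test_that("sim parameter validation rejects out-of-range settings", {
  expect_error(sim_params(per_base_error = -0.1), class = "urovaf_sim_error")
  expect_error(sim_params(tumour_mutation_prevalence = 1.4), class = "urovaf_sim_error")
  expect_error(sim_params(consensus_depth_mean = 0), class = "urovaf_sim_error")
  expect_error(sim_params(background_clonal_vaf_median = 0), class = "urovaf_sim_error")
})
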