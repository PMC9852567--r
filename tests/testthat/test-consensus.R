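make_reads <- function(umi, frag_start, bases, quals = rep(35L, length(bases)),
                       chrom = "chr10", pos = 96162368L) {
  tibble::tibble(
    read_id = sprintf("r%d", seq_along(bases)), umi = umi, chrom = chrom,
    frag_start = frag_start, pos = pos, base = bases, qual = quals
  )
}

test_that("reads partition into families by (UMI, fragment start, chromosome)", {
  reads <- rbind(
    make_reads("AAAA", 100L, c("C", "C", "C")),
    make_reads("TTTT", 100L, c("C", "T", "C"))
  )
  fam <- group_families(reads)
  expect_equal(length(unique(fam$family_id)), 2)
  expect_equal(as.vector(table(fam$family_id)), c(3, 3))

  shifted <- rbind(make_reads("AAAA", 100L, "C"), make_reads("AAAA", 101L, "C"))
  expect_equal(length(unique(group_families(shifted)$family_id)), 2)

  empty <- group_families(reads[0, ])
  expect_equal(nrow(empty), 0)
  expect_true("family_id" %in% names(empty))
})

test_that("every read lands in exactly one family (random partitions)", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    reads <- make_reads(sample(c("ACGT", "TTGA", "GGCC"), n, replace = TRUE),
                        sample(100:102, n, replace = TRUE),
                        sample(c("C", "T"), n, replace = TRUE))
    fam <- group_families(reads)
    expect_equal(sum(table(fam$family_id)), n)
    # exhaustive key comparison: same family iff identical key
    key <- paste(reads$umi, reads$frag_start, reads$chrom)
    expect_equal(length(unique(fam$family_id)), length(unique(key)))
  }
})

test_that("consensus applies family-size, strict-majority and quality rules", {
  expect_null(call_consensus(c("C", "C"), c(35, 35)))
  cc <- call_consensus(c("C", "C", "C"), c(35, 35, 35))
  expect_equal(cc[c("base", "qual", "family_size")],
               list(base = "C", qual = 35L, family_size = 3L))
  expect_equal(call_consensus(c("C", "C", "T", "T"), rep(35, 4))$base, "N")
  expect_equal(call_consensus(c("C", "C", "C", "T"), rep(35, 4))$base, "C")
  # quality is mean of supporters, capped at 40
  expect_equal(call_consensus(c("C", "C", "C"), c(45, 45, 45))$qual, 40L)
  expect_equal(call_consensus(c("C", "C", "C", "T"), c(30, 31, 33, 45))$qual, 31L)
})

test_that("consensus caller matches the brute-force majority oracle", {
  set.seed(42)
  for (i in 1:2000) {
    f <- random_family()
    got <- call_consensus(f$bases, f$quals)
    want <- oracle_consensus(f$bases, f$quals)
    expect_identical(got, want)
  }
})

test_that("adding a read supporting the consensus never flips the call", {
  set.seed(43)
  for (i in 1:500) {
    f <- random_family()
    got <- call_consensus(f$bases, f$quals)
    if (is.null(got) || got$base == "N") next
    more <- call_consensus(c(f$bases, got$base), c(f$quals, 35))
    expect_equal(more$base, got$base)
  }
})

test_that("no consensus call derives from fewer than min_family_size reads", {
  set.seed(44)
  reads <- make_reads(sample(sprintf("U%02d", 1:30), 80, replace = TRUE), 100L,
                      sample(c("C", "T"), 80, replace = TRUE))
  calls <- collapse_reads(reads, min_family_size = 3)
  expect_true(all(calls$family_size >= 3))
  fam_sizes <- table(group_families(reads)$family_id)
  expect_equal(nrow(calls), sum(fam_sizes >= 3))
})

test_that("families below the size floor yield zero consensus depth", {
  reads <- rbind(
    make_reads("AAAA", 100L, c("C", "C")),
    make_reads("CCCC", 100L, "C"),
    make_reads("GGGG", 105L, c("T", "T"))
  )
  expect_equal(nrow(collapse_reads(reads)), 0)
})

test_that("Hamming-distance-1 UMI merge pools sequencing-error UMIs", {
  reads <- rbind(
    make_reads("AAAA", 100L, c("C", "C", "C")),
    make_reads("AAAT", 100L, "C")  # 1 error off the abundant UMI
  )
  expect_equal(length(unique(group_families(reads)$family_id)), 2)
  merged <- group_families(reads, umi_merge_distance = 1)
  expect_equal(length(unique(merged$family_id)), 1)
  # distance-2 UMIs stay separate
  far <- rbind(make_reads("AAAA", 100L, "C"), make_reads("AATT", 100L, "C"))
  expect_equal(length(unique(group_families(far, umi_merge_distance = 1)$family_id)), 2)
})

test_that("SAM text ingestion extracts panel-site bases with UMIs", {
  panel <- tiny_panel()
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr10\tLN:135534747",
    # 10M alignment covering chr10:96162368 at offset 4 (base T, qual 'I'=40)
    sprintf("r1:ACGTACGT\t0\tchr10\t%d\t60\t10M\t*\t0\t0\tAAATAAAAAA\tIIIIIIIIII",
            96162368 - 3),
    # RX-tagged read, ref base C at the site
    sprintf("r2\t0\tchr10\t%d\t60\t10M\t*\t0\t0\tCCCCCCCCCC\tIIIII5IIII\tRX:Z:GGGGTTTT",
            96162368 - 5),
    # soft-clipped alignment must be ignored
    sprintf("r3\t0\tchr10\t%d\t60\t2S8M\t*\t0\t0\tAACCCCCCCC\tIIIIIIIIII",
            96162368 - 5)
  )
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  recs <- read_sam_records(path, panel)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$umi, c("ACGTACGT", "GGGGTTTT"))
  expect_equal(recs$base, c("T", "C"))
  expect_equal(recs$pos, rep(96162368L, 2))
  expect_equal(recs$qual[1], 40L)
})
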