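#' UMI consensus collapsing
#'
#' Deep sequencing of urine cell-pellet DNA reaches raw depths around
#' 35,400x; at that depth PCR and sequencing errors swamp true low-frequency
#' variants. Reads carrying the same unique molecular identifier (UMI) and
#' fragment start derive from one original DNA molecule, so collapsing each
#' UMI family to a single consensus base call suppresses errors that appear
#' in only part of the family. Families with fewer than `min_family_size`
#' reads (default 3) are discarded outright; within a retained family the
#' consensus base is the most frequent member base provided it is carried by
#' a strict majority of the family, otherwise the call is `N` (never a
#' guess). The consensus quality is the mean quality of the supporting
#' reads, rounded and capped at 40.
#'
#' @name umi_consensus
NULL

validate_reads <- function(reads) {
  required <- c("read_id", "umi", "chrom", "frag_start", "pos", "base", "qual")
  missing <- setdiff(required, names(reads))
  if (length(missing) > 0) {
    stop_urovaf(paste0("read table missing column(s): ", paste(missing, collapse = ", ")),
                "urovaf_reads_error")
  }
  if (nrow(reads) > 0) {
    if (!all(reads$base %in% c(DNA_BASES, "N"))) {
      stop_urovaf("read bases must be A/C/G/T/N", "urovaf_reads_error")
    }
    if (any(reads$qual < 0) || any(reads$pos < 1)) {
      stop_urovaf("read qual must be >= 0 and pos >= 1", "urovaf_reads_error")
    }
  }
  tibble::as_tibble(reads)
}

#' Group reads into UMI families
#'
#' Partitions read records by the family key (UMI, fragment start,
#' chromosome). Each read belongs to exactly one family. Optionally, UMIs
#' within Hamming distance 1 of a more abundant UMI at the same fragment
#' start are merged into it before grouping (a simple directional merge for
#' UMI sequencing errors; the default is exact matching).
#'
#' @param reads tibble of read records with columns `read_id`, `umi`,
#'   `chrom`, `frag_start`, `pos`, `base`, `qual`.
#' @param umi_merge_distance 0 (exact UMI match, default) or 1 (merge UMIs at
#'   Hamming distance 1 into the most abundant neighbour).
#' @return the read tibble with an added `family_id` column.
#' @export
group_families <- function(reads, umi_merge_distance = 0) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) {
    reads$family_id <- character(0)
    return(reads)
  }
  if (umi_merge_distance > 0) {
    reads$umi <- merge_umis_within(reads)
  }
  reads$family_id <- paste(reads$umi, reads$frag_start, reads$chrom, sep = "|")
  reads
}

## directional Hamming-distance-1 merge: within each (chrom, frag_start)
## group, reassign each UMI to the most abundant UMI at distance <= 1
merge_umis_within <- function(reads) {
  key <- paste(reads$chrom, reads$frag_start, sep = "|")
  out <- reads$umi
  for (grp in split(seq_len(nrow(reads)), key)) {
    umis <- reads$umi[grp]
    counts <- sort(table(umis), decreasing = TRUE)
    canon <- names(counts)
    assign <- stats::setNames(canon, canon)
    if (length(canon) > 1) {
      mat <- do.call(rbind, strsplit(canon, ""))
      for (i in seq_along(canon)[-1]) {
        for (j in seq_len(i - 1)) {
          if (sum(mat[i, ] != mat[j, ]) <= 1) {
            assign[canon[i]] <- assign[canon[j]]
            break
          }
        }
      }
    }
    out[grp] <- unname(assign[umis])
  }
  out
}

#' Call the consensus base for one UMI family
#'
#' Applies the family-size and majority rules to the member base calls of a
#' single family at a single position.
#'
#' @param bases character vector of member base calls (A/C/G/T/N).
#' @param quals integer vector of member Phred qualities, parallel to
#'   `bases`.
#' @param min_family_size minimum number of raw reads required to emit a
#'   consensus (default 3); smaller families are discarded and yield `NULL`.
#' @param max_qual cap on the consensus quality (default 40).
#' @return `NULL` when the family is too small, otherwise a list with
#'   elements `base` (the strict-majority base, or `"N"` on a tie), `qual`
#'   (rounded mean quality of supporting reads, capped) and `family_size`.
#' @export
#' @examples
#' call_consensus(c("C", "C", "C", "T"), c(35, 35, 35, 30))
call_consensus <- function(bases, quals, min_family_size = 3, max_qual = 40) {
  n <- length(bases)
  if (n == 0) stop_urovaf("empty family", "urovaf_consensus_error")
  if (n < min_family_size) return(NULL)
  counts <- table(bases)
  top <- names(counts)[which.max(counts)]
  if (max(counts) * 2 > n) {
    base <- top
    qual <- min(max_qual, round_half_up(mean(quals[bases == top])))
  } else {
    base <- "N"
    qual <- 0
  }
  list(base = base, qual = as.integer(qual), family_size = n)
}

#' Collapse read records into consensus base calls
#'
#' Groups reads into UMI families and emits one consensus call per family
#' and position, applying [call_consensus()] rules throughout. This is the
#' error-suppression step that turns ~35,400x raw depth into ~2,400x
#' consensus depth.
#'
#' @inheritParams group_families
#' @inheritParams call_consensus
#' @param sample_id optional sample identifier attached to the output.
#' @return tibble of consensus calls with columns `sample_id`, `chrom`,
#'   `pos`, `base`, `qual`, `family_size`.
#' @export
collapse_reads <- function(reads, min_family_size = 3, umi_merge_distance = 0,
                           max_qual = 40, sample_id = "sample") {
  reads <- group_families(reads, umi_merge_distance = umi_merge_distance)
  if (nrow(reads) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), base = character(), qual = integer(),
                          family_size = integer()))
  }
  grp <- paste(reads$family_id, reads$pos, sep = "@")
  idx <- split(seq_len(nrow(reads)), grp)
  keep <- idx[lengths(idx) >= min_family_size]
  if (length(keep) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), base = character(), qual = integer(),
                          family_size = integer()))
  }
  calls <- lapply(keep, function(i) {
    cc <- call_consensus(reads$base[i], reads$qual[i],
                         min_family_size = min_family_size, max_qual = max_qual)
    c(chrom = reads$chrom[i[1]], pos = reads$pos[i[1]],
      base = cc$base, qual = cc$qual, family_size = cc$family_size)
  })
  m <- do.call(rbind, calls)
  out <- tibble::tibble(
    sample_id = sample_id,
    chrom = m[, "chrom"],
    pos = as.integer(m[, "pos"]),
    base = m[, "base"],
    qual = as.integer(m[, "qual"]),
    family_size = as.integer(m[, "family_size"])
  )
  out[order(out$chrom, out$pos), ]
}

#' Read records from a simplified read TSV
#'
#' Columns: `read_id`, `umi`, `chrom`, `frag_start`, `pos`, `base`, `qual`.
#'
#' @param path path to the TSV.
#' @return validated tibble of read records.
#' @export
load_reads <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(read_id = "character", umi = "character",
                                  chrom = "character", base = "character"))
  df$frag_start <- as.integer(df$frag_start)
  df$pos <- as.integer(df$pos)
  df$qual <- as.integer(df$qual)
  validate_reads(df)
}

#' Write read records to TSV
#' @param reads read tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  cols <- c("read_id", "umi", "chrom", "frag_start", "pos", "base", "qual")
  write.table(as.data.frame(reads)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Extract read records at panel sites from SAM text
#'
#' Minimal ingestion of aligned single-end SAM records: only fully-matching
#' alignments (CIGAR of the form `<n>M`, no soft clips or indels) are
#' accepted, and one read record is emitted per panel site the alignment
#' overlaps. The UMI is taken from the `RX:Z:` tag when present, otherwise
#' from the last `:`-delimited field of the query name. The fragment start
#' is the alignment POS.
#'
#' @param path path to a SAM text file.
#' @param panel a `hotspot_panel` giving the sites to extract.
#' @return tibble of read records suitable for [group_families()].
#' @export
read_sam_records <- function(path, panel) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sites <- panel$hotspots
  recs <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) next
    if (!grepl("^[0-9]+M$", f[6])) next
    pos0 <- as.integer(f[4])
    len <- as.integer(sub("M$", "", f[6]))
    rx <- grep("^RX:Z:", f[-(1:11)], value = TRUE)
    umi <- if (length(rx) > 0) {
      sub("^RX:Z:", "", rx[1])
    } else {
      parts <- strsplit(f[1], ":", fixed = TRUE)[[1]]
      parts[length(parts)]
    }
    hit <- which(sites$chrom == f[3] & sites$pos >= pos0 & sites$pos < pos0 + len)
    for (h in hit) {
      off <- sites$pos[h] - pos0 + 1L
      recs[[length(recs) + 1L]] <- tibble::tibble(
        read_id = f[1], umi = umi, chrom = f[3], frag_start = pos0,
        pos = sites$pos[h],
        base = toupper(substr(f[10], off, off)),
        qual = utf8ToInt(substr(f[11], off, off)) - 33L
      )
    }
  }
  if (length(recs) == 0) {
    return(validate_reads(tibble::tibble(
      read_id = character(), umi = character(), chrom = character(),
      frag_start = integer(), pos = integer(), base = character(),
      qual = integer())))
  }
  validate_reads(do.call(rbind, recs))
}
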