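#' Hotspot panels
#'
#' A hotspot panel is the set of recurrently mutated single-nucleotide
#' positions interrogated in urine cell-pellet DNA: here, non-coding sites in
#' ADGRG6, PLEKHS1, WDR74, TBC1D12 and LEPROTL1. Coordinates are 1-based,
#' inclusive and chromosome-scoped (hg19-style notation such as
#' "chr10:96162368"); the panel is self-describing and no reference FASTA is
#' needed. A panel may additionally carry a set of excluded sites: hotspots
#' retained in the VAF table but dropped from the per-sample maximum-VAF
#' statistic (used for germline-noise-prone sites such as WDR74
#' chr11:62609254 G/A).
#'
#' @name hotspot_panel
NULL

hotspot_key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

panel_keys <- function(panel) {
  hotspot_key(panel$hotspots$chrom, panel$hotspots$pos, panel$hotspots$alt)
}

validate_panel <- function(hotspots, excluded) {
  required <- c("gene", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(hotspots))
  if (length(missing) > 0) {
    stop_urovaf(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")),
                "urovaf_panel_error")
  }
  if (nrow(hotspots) == 0) {
    stop_urovaf("panel is empty", "urovaf_panel_error")
  }
  hotspots$pos <- as.integer(hotspots$pos)
  if (anyNA(hotspots$pos) || any(hotspots$pos < 1)) {
    stop_urovaf("panel positions must be integers >= 1", "urovaf_panel_error")
  }
  if (!all(hotspots$ref %in% DNA_BASES) || !all(hotspots$alt %in% DNA_BASES)) {
    stop_urovaf("panel ref/alt bases must be one of A/C/G/T", "urovaf_panel_error")
  }
  if (any(hotspots$ref == hotspots$alt)) {
    bad <- which(hotspots$ref == hotspots$alt)[1]
    stop_urovaf(sprintf("ref equals alt at %s:%d", hotspots$chrom[bad], hotspots$pos[bad]),
                "urovaf_panel_error")
  }
  keys <- hotspot_key(hotspots$chrom, hotspots$pos, hotspots$alt)
  if (anyDuplicated(keys)) {
    stop_urovaf(sprintf("duplicate panel site: %s", keys[duplicated(keys)][1]),
                "urovaf_panel_error")
  }
  excluded <- as.character(excluded)
  if (!all(excluded %in% keys)) {
    stop_urovaf(paste0("excluded site(s) not in panel: ",
                       paste(setdiff(excluded, keys), collapse = ", ")),
                "urovaf_panel_error")
  }
  structure(
    list(hotspots = tibble::as_tibble(hotspots[required]), excluded = excluded),
    class = "hotspot_panel"
  )
}

#' Construct a hotspot panel from a data frame
#'
#' @param hotspots data frame with columns `gene`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`. Row order is preserved and used downstream for tie-breaks.
#' @param excluded character vector of `"chrom:pos:alt"` keys to drop from the
#'   maximum-VAF statistic (must be a subset of the panel sites).
#' @return an object of class `hotspot_panel`.
#' @export
#' @examples
#' hotspot_panel(data.frame(
#'   gene = c("TBC1D12", "WDR74"), chrom = c("chr10", "chr11"),
#'   pos = c(96162368, 62609254), ref = c("C", "G"), alt = c("T", "A")
#' ))
hotspot_panel <- function(hotspots, excluded = character()) {
  validate_panel(as.data.frame(hotspots), excluded)
}

#' Read a hotspot panel from a TSV file
#'
#' Expects tab-separated columns `gene`, `chrom`, `pos`, `ref`, `alt`; lines
#' starting with `#` are comments. File order is preserved.
#'
#' @param path path to the panel TSV.
#' @inheritParams hotspot_panel
#' @return an object of class `hotspot_panel`.
#' @export
load_panel <- function(path, excluded = character()) {
  if (!file.exists(path)) {
    stop_urovaf(paste0("panel file not found: ", path), "urovaf_panel_error")
  }
  df <- tryCatch(
    read.delim(path, comment.char = "#", colClasses = "character",
               stringsAsFactors = FALSE),
    error = function(e) stop_urovaf(paste0("cannot parse panel file: ", conditionMessage(e)),
                                    "urovaf_panel_error")
  )
  if (nrow(df) == 0) stop_urovaf("panel file has no sites", "urovaf_panel_error")
  validate_panel(df, excluded)
}

#' Write a hotspot panel to TSV
#'
#' @param panel a `hotspot_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(panel$hotspots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export panel coordinates as BED intervals
#'
#' Converts the 1-based inclusive panel coordinates to 0-based half-open BED
#' (start = pos - 1, end = pos).
#'
#' @param panel a `hotspot_panel`.
#' @param path optional output path; when `NULL` the BED tibble is returned
#'   without writing.
#' @return tibble with columns chrom, start, end, name.
#' @export
panel_to_bed <- function(panel, path = NULL) {
  bed <- tibble::tibble(
    chrom = panel$hotspots$chrom,
    start = panel$hotspots$pos - 1L,
    end = panel$hotspots$pos,
    name = paste0(panel$hotspots$gene, "_", panel$hotspots$alt)
  )
  if (!is.null(path)) {
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  bed
}

#' Mark panel sites as excluded from the maximum-VAF statistic
#'
#' @param panel a `hotspot_panel`.
#' @param chrom,pos,alt coordinates of the site(s) to exclude.
#' @return the panel with the exclusion set extended.
#' @export
exclude_sites <- function(panel, chrom, pos, alt) {
  validate_panel(panel$hotspots,
                 union(panel$excluded, hotspot_key(chrom, pos, alt)))
}

#' @export
print.hotspot_panel <- function(x, ...) {
  cat(sprintf("Hotspot panel: %d sites in %d genes\n",
              nrow(x$hotspots), length(unique(x$hotspots$gene))))
  if (length(x$excluded) > 0) {
    cat("Excluded from max-VAF:", paste(x$excluded, collapse = ", "), "\n")
  }
  print(x$hotspots, ...)
  invisible(x)
}

#' The bundled demonstration panel
#'
#' Returns the panel shipped with the package: the two hotspot coordinates
#' with published positions (TBC1D12 chr10:96162368 C>T and WDR74
#' chr11:62609254 G>A) plus 17 placeholder sites with synthetic coordinates
#' distributed over the five hotspot genes, for a total of 19 sites. The
#' placeholder coordinates are clearly marked synthetic in the bundled file;
#' substitute the true panel coordinates for real analyses.
#'
#' @inheritParams hotspot_panel
#' @return an object of class `hotspot_panel` with 19 sites.
#' @export
default_panel <- function(excluded = character()) {
  load_panel(system.file("extdata", "hotspot_panel_synthetic.tsv",
                         package = "urovaf", mustWork = TRUE),
             excluded = excluded)
}

COHORTS <- c("haematuria_training", "haematuria_test", "surveillance",
             "germline", "qc")
STAGES <- c("Tis", "Ta", "T1", "T2plus", "nr")
GRADES <- c("G1", "G2", "G3", "nr")

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  x <- tolower(as.character(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

validate_sample_sheet <- function(df) {
  required <- c("sample_id", "cohort", "bc_status", "age", "sex", "stage",
                "grade", "future_recurrence")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_urovaf(paste0("sample sheet missing column(s): ", paste(missing, collapse = ", ")),
                "urovaf_sample_sheet_error")
  }
  if (anyNA(df$sample_id) || any(df$sample_id == "")) {
    stop_urovaf("sample sheet has missing sample_id", "urovaf_sample_sheet_error")
  }
  if (anyDuplicated(df$sample_id)) {
    stop_urovaf("sample sheet has duplicate sample_id", "urovaf_sample_sheet_error")
  }
  if (!all(df$cohort %in% COHORTS)) {
    stop_urovaf(paste0("unknown cohort: ", setdiff(df$cohort, COHORTS)[1]),
                "urovaf_sample_sheet_error")
  }
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || any(df$age < 0)) {
    stop_urovaf("sample ages must be numeric and >= 0", "urovaf_sample_sheet_error")
  }
  df$bc_status <- as_flag(df$bc_status)
  if (anyNA(df$bc_status)) {
    stop_urovaf("bc_status must be true/false", "urovaf_sample_sheet_error")
  }
  df$sex <- ifelse(df$sex %in% c("M", "F"), df$sex, "unknown")
  df$stage <- ifelse(df$stage %in% STAGES, df$stage, "nr")
  df$grade <- ifelse(df$grade %in% GRADES, df$grade, "nr")
  df$future_recurrence <- as_flag(df$future_recurrence)
  tibble::as_tibble(df[required])
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `cohort` (one of
#' haematuria_training / haematuria_test / surveillance / germline / qc),
#' `bc_status` (disease present at urine collection), `age`, `sex` (M/F),
#' `stage` (Tis/Ta/T1/T2plus; anything else is coded `nr`), `grade`
#' (G1/G2/G3; else `nr`) and `future_recurrence` (true/false, `n/a`
#' otherwise). Stage and grade are meaningful only for samples with
#' `bc_status` true.
#'
#' @param path path to the sample sheet TSV.
#' @return tibble with one validated row per sample.
#' @export
load_sample_sheet <- function(path) {
  df <- read.delim(path, comment.char = "#", colClasses = "character",
                   stringsAsFactors = FALSE, na.strings = c("NA", "n/a", ""))
  validate_sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param samples sample sheet tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- as.data.frame(samples)
  out$future_recurrence <- ifelse(is.na(out$future_recurrence), "n/a",
                                  tolower(out$future_recurrence))
  out$bc_status <- tolower(out$bc_status)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_site_counts <- function(df) {
  required <- c("sample_id", "chrom", "pos", "alt", "depth", "alt_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_urovaf(paste0("site counts missing column(s): ", paste(missing, collapse = ", ")),
                "urovaf_site_counts_error")
  }
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  df$alt_count <- as.integer(df$alt_count)
  if (any(df$depth < 0) || any(df$alt_count < 0) || any(df$alt_count > df$depth)) {
    stop_urovaf("site counts must satisfy 0 <= alt_count <= depth",
                "urovaf_site_counts_error")
  }
  tibble::as_tibble(df[required])
}

#' Read a per-site count table
#'
#' Quality-filtered consensus counts per sample and hotspot, tab-separated
#' with columns `sample_id`, `chrom`, `pos`, `alt`, `depth` (quality-passing
#' consensus calls at the site) and `alt_count` (those matching the alt
#' base).
#'
#' @param path path to the counts TSV.
#' @return validated tibble of site counts.
#' @export
load_site_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character", chrom = "character",
                                  alt = "character"))
  validate_site_counts(df)
}

#' Write a per-site count table to TSV
#' @param counts site counts tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
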