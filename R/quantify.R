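#' Hotspot VAF quantification
#'
#' Variant allele frequencies at panel hotspots are computed from
#' quality-filtered consensus base calls: only calls with Phred quality of
#' at least `min_baseq` (default 30) and a non-`N` base enter the depth, and
#' the VAF at a site is the fraction of those calls matching the panel alt
#' base. The denominator deliberately includes every quality-passing call at
#' the site (ref, alt, or other substitution), matching pileup-counting
#' semantics. A site with zero quality-passing depth has an undefined VAF
#' (`NA`) — missing coverage is never treated as VAF 0.
#'
#' @name hotspot_quant
NULL

empty_vaf_table <- function() {
  tibble::tibble(sample_id = character(), gene = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 depth = integer(), alt_count = integer(), vaf = numeric())
}

#' Compute a per-sample VAF table over the panel
#'
#' Accepts either consensus base calls (columns `base` and `qual`, one row
#' per consensus call, as produced by [collapse_reads()]) or pre-computed
#' per-site counts (columns `depth` and `alt_count`, assumed already
#' quality-filtered). Every panel site appears in the output for every
#' sample; sites with no quality-passing coverage get depth 0 and `NA` VAF.
#'
#' @param x tibble of consensus calls or site counts; a `sample_id` column
#'   is used when present.
#' @param panel a `hotspot_panel`.
#' @param min_baseq minimum Phred quality for a consensus call to be counted
#'   (default 30); applies only to consensus-call input.
#' @return VAF table tibble with columns `sample_id`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_count`, `vaf`.
#' @export
pileup_vaf <- function(x, panel, min_baseq = 30) {
  sites <- panel$hotspots
  from_calls <- all(c("base", "qual") %in% names(x))
  if (!from_calls && !all(c("depth", "alt_count") %in% names(x))) {
    stop_urovaf("input must have base/qual (consensus calls) or depth/alt_count (site counts)",
                "urovaf_quant_error")
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- "sample"
  samples <- unique(x$sample_id)
  if (length(samples) == 0) return(empty_vaf_table())

  grid <- tibble::tibble(
    sample_id = rep(samples, each = nrow(sites)),
    gene = rep(sites$gene, length(samples)),
    chrom = rep(sites$chrom, length(samples)),
    pos = rep(sites$pos, length(samples)),
    ref = rep(sites$ref, length(samples)),
    alt = rep(sites$alt, length(samples))
  )

  if (from_calls) {
    calls <- x[x$qual >= min_baseq & x$base != "N", , drop = FALSE]
    site_of_call <- match(paste(calls$chrom, calls$pos),
                          paste(sites$chrom, sites$pos))
    keep <- !is.na(site_of_call)
    calls <- calls[keep, , drop = FALSE]
    site_of_call <- site_of_call[keep]
    cell <- paste(calls$sample_id, calls$chrom, calls$pos)
    grid_cell <- paste(grid$sample_id, grid$chrom, grid$pos)
    depth_tab <- table(cell)
    is_alt <- calls$base == sites$alt[site_of_call]
    alt_tab <- table(cell[is_alt])
    grid$depth <- as.integer(depth_tab[grid_cell])
    grid$depth[is.na(grid$depth)] <- 0L
    grid$alt_count <- as.integer(alt_tab[grid_cell])
    grid$alt_count[is.na(grid$alt_count)] <- 0L
  } else {
    key_grid <- paste(grid$sample_id, grid$chrom, grid$pos, grid$alt)
    key_x <- paste(x$sample_id, x$chrom, x$pos, x$alt)
    hit <- match(key_grid, key_x)
    grid$depth <- ifelse(is.na(hit), 0L, as.integer(x$depth[hit]))
    grid$alt_count <- ifelse(is.na(hit), 0L, as.integer(x$alt_count[hit]))
  }
  grid$vaf <- ifelse(grid$depth > 0, grid$alt_count / grid$depth, NA_real_)
  grid
}

#' Per-sample maximum VAF over non-excluded panel sites
#'
#' The classifier score: the maximum of the defined VAFs across panel
#' hotspots, skipping sites in the panel's exclusion set and sites with
#' undefined (zero-depth) VAF. Ties are broken by panel order. A sample
#' whose non-excluded sites are all undefined is unevaluable and raises an
#' error rather than silently scoring 0.
#'
#' @param vaf_table VAF table from [pileup_vaf()].
#' @param panel the `hotspot_panel` used to build the table (supplies site
#'   order and the exclusion set).
#' @return tibble with one row per sample: `sample_id`, `max_vaf`, the
#'   argmax site (`gene`, `chrom`, `pos`, `alt`) and `n_sites_evaluated`.
#' @export
max_vaf <- function(vaf_table, panel) {
  keys <- panel_keys(panel)
  usable_keys <- setdiff(keys, panel$excluded)
  row_key <- hotspot_key(vaf_table$chrom, vaf_table$pos, vaf_table$alt)
  vt <- vaf_table[row_key %in% usable_keys, , drop = FALSE]
  ## order rows by panel position so which.max tie-breaks follow panel order
  vt <- vt[order(match(hotspot_key(vt$chrom, vt$pos, vt$alt), keys)), , drop = FALSE]
  out <- lapply(split(seq_len(nrow(vt)), factor(vt$sample_id, levels = unique(vt$sample_id))),
                function(i) {
    defined <- i[!is.na(vt$vaf[i])]
    if (length(defined) == 0) {
      stop_urovaf(sprintf("sample %s is unevaluable: no defined VAF at any non-excluded site",
                          vt$sample_id[i[1]]),
                  "urovaf_unevaluable_error",
                  data = list(sample_id = vt$sample_id[i[1]]))
    }
    best <- defined[which.max(vt$vaf[defined])]
    tibble::tibble(
      sample_id = vt$sample_id[best], max_vaf = vt$vaf[best],
      gene = vt$gene[best], chrom = vt$chrom[best], pos = vt$pos[best],
      alt = vt$alt[best], n_sites_evaluated = length(defined)
    )
  })
  do.call(rbind, out)
}

#' Write a VAF table or max-VAF table to TSV
#' @param x tibble from [pileup_vaf()] or [max_vaf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vaf_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
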