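#' Read a BED file of regions into a merged, sorted GRanges
#'
#' BED intervals (0-based half-open on disk) are returned as 1-based closed
#' `GRanges`, sorted, with overlapping and abutting intervals merged per
#' chromosome — coverage BEDs are run-length encodings, so `[10,20) + [20,30)`
#' is one region.
#'
#' @param path path to a BED3+ file
#' @param annotation_kind optional label stored in `metadata()$annotation_kind`
#' @return merged `GRanges`
#' @export
read_regions <- function(path, annotation_kind = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    fields <- strsplit(lines[idx], "\t| +")
    n <- lengths(fields)
    bad <- which(n < 3L)
    if (length(bad))
      abort("BED parse error at line %d: fewer than 3 columns", idx[bad[1]])
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      abort("BED parse error at line %d: non-numeric coordinates", idx[bad[1]])
    bad <- which(start >= end | start < 0)
    if (length(bad))
      abort("BED parse error at line %d: start >= end", idx[bad[1]])
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  if (!is.null(annotation_kind))
    S4Vectors::metadata(gr)$annotation_kind <- annotation_kind
  gr
}

#' Write regions to a BED file
#'
#' @param regions a `GRanges`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regions <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' Read gene/transcript/exon/CDS region sets from a GTF file
#'
#' Feature rows of type `gene`, `transcript`, `exon` and `CDS` are collected
#' into per-class merged interval sets, used downstream as evaluation strata.
#' Any other feature type is skipped with a message. Which annotation flavor
#' is supplied (collapsed vs full) determines what the strata contain; the
#' reader is agnostic.
#'
#' @param path path to a GTF file
#' @return a named list of merged `GRanges`: `gene`, `transcript`, `exon`,
#'   `cds`, plus `exons_by_tx` (unmerged exon `GRanges` with `gene_id` /
#'   `transcript_id` metadata columns, for boundary profiling)
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  known <- c("gene", "transcript", "exon", "CDS")
  n_skip <- sum(!type %in% known)
  if (n_skip > 0)
    message(sprintf("read_gene_model: skipped %d rows with unknown feature type", n_skip))
  out <- list(
    gene = GenomicRanges::reduce(GenomicRanges::sort(gr[type == "gene"])),
    transcript = GenomicRanges::reduce(GenomicRanges::sort(gr[type == "transcript"])),
    exon = GenomicRanges::reduce(GenomicRanges::sort(gr[type == "exon"])),
    cds = GenomicRanges::reduce(GenomicRanges::sort(gr[type == "CDS"]))
  )
  if (length(out$cds) == 0L)
    warning("read_gene_model: no CDS rows found; CDS stratum is empty", call. = FALSE)
  out$exons_by_tx <- gr[type == "exon"]
  out
}

# Intersect two region sets, returning merged GRanges (strand-agnostic).
intersect_regions <- function(a, b) {
  GenomicRanges::reduce(GenomicRanges::intersect(
    GenomicRanges::granges(a), GenomicRanges::granges(b), ignore.strand = TRUE))
}

# TRUE for each position (chrom, pos, both 1-based) inside `regions`.
pos_in_regions <- function(chrom, pos, regions) {
  if (length(chrom) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, regions, ignore.strand = TRUE)
}
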