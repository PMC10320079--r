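#' Construct a variant record table
#'
#' Variant records are plain `data.frame`s with one row per site:
#' `chrom`, `pos` (1-based), `ref`, `alt` (comma-separated for multi-allelic
#' sites), `gt` (unphased, e.g. `"0/1"`, `NA` for missing), `qual`, `gq`,
#' `dp`, `ad` (comma-separated depths, reference allele first).
#'
#' @param chrom,pos,ref,alt,gt,qual,gq,dp,ad per-record fields (recycled)
#' @return a `data.frame` of class `rnavc_variants`
#' @export
variant_records <- function(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            gt = NA_character_, qual = NA_real_,
                            gq = NA_real_, dp = NA_integer_,
                            ad = NA_character_) {
  n <- length(pos)
  r <- function(x) if (n == 0L) x[0] else rep_len(x, n)
  df <- data.frame(chrom = r(as.character(chrom)), pos = r(as.integer(pos)),
                   ref = r(toupper(as.character(ref))),
                   alt = r(toupper(as.character(alt))),
                   gt = r(as.character(gt)), qual = r(as.numeric(qual)),
                   gq = r(as.numeric(gq)), dp = r(as.integer(dp)),
                   ad = r(as.character(ad)), stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(nchar(df$ref) >= 1L), all(nzchar(df$alt)),
              all(df$pos >= 1L))
    if (any(mapply(function(r, a) r %in% strsplit(a, ",")[[1]], df$ref, df$alt)))
      abort("alt allele equal to ref allele")
  }
  class(df) <- c("rnavc_variants", "data.frame")
  df
}

#' Write variant records to a VCF 4.2 file
#'
#' Emits a single-sample VCF with FORMAT `GT:GQ:DP:AD:VAF`. VAF is the
#' alternate-allele read fraction `AD_alt / sum(AD)`, a display convenience
#' rounded to 3 decimals. Contigs must cover every record chromosome.
#'
#' @param records a variant record `data.frame` (see [variant_records()])
#' @param path output path
#' @param contigs named integer vector of contig lengths
#' @param sample_name sample column name
#' @return `path`, invisibly
#' @export
write_vcf <- function(records, path, contigs, sample_name = "SAMPLE") {
  stopifnot(!is.null(names(contigs)), all(nzchar(names(contigs))))
  if (nrow(records)) {
    missing_ctg <- setdiff(unique(records$chrom), names(contigs))
    if (length(missing_ctg))
      abort("contig(s) absent from header: %s", paste(missing_ctg, collapse = ","))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality (phred)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    "##FORMAT=<ID=VAF,Number=A,Type=Float,Description=\"Alternate allele read fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  body <- character(0)
  if (nrow(records)) {
    ord <- order(match(records$chrom, names(contigs)), records$pos)
    r <- records[ord, , drop = FALSE]
    vaf <- vapply(seq_len(nrow(r)), function(i) {
      ad <- suppressWarnings(as.numeric(strsplit(r$ad[i], ",")[[1]]))
      if (anyNA(ad) || sum(ad) == 0) return(".")
      paste(sprintf("%.3f", ad[-1] / sum(ad)), collapse = ",")
    }, "")
    fmt <- sprintf("%s:%s:%s:%s:%s",
                   ifelse(is.na(r$gt), "./.", r$gt),
                   ifelse(is.na(r$gq), ".", as.character(round(r$gq))),
                   ifelse(is.na(r$dp), ".", as.character(r$dp)),
                   ifelse(is.na(r$ad), ".", r$ad),
                   vaf)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:GQ:DP:AD:VAF\t%s",
                    r$chrom, r$pos, r$ref, r$alt,
                    ifelse(is.na(r$qual), ".", sprintf("%.1f", r$qual)),
                    fmt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a variant record table
#'
#' Parsed with `VariantAnnotation::readVcf`; the first sample's GT/GQ/DP/AD
#' are carried over when present.
#'
#' @param path path to a VCF file
#' @return a variant record `data.frame` (see [variant_records()])
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0L) return(variant_records())
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) paste(as.character(a), collapse = ","), "")
  g <- VariantAnnotation::geno(vcf)
  pick <- function(name, default) {
    if (name %in% names(g) && ncol(g[[name]]) >= 1L) g[[name]][, 1L] else rep(default, n)
  }
  gt <- as.character(pick("GT", NA_character_))
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  ad_raw <- if ("AD" %in% names(g)) g[["AD"]][, 1L] else NULL
  ad <- if (is.null(ad_raw)) rep(NA_character_, n) else
    vapply(ad_raw, function(x) if (all(is.na(x))) NA_character_ else
      paste(as.integer(x), collapse = ","), "")
  qual <- as.numeric(VariantAnnotation::qual(vcf))
  variant_records(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt, gt = gt, qual = qual,
    gq = suppressWarnings(as.numeric(pick("GQ", NA_real_))),
    dp = suppressWarnings(as.integer(pick("DP", NA_integer_))),
    ad = ad)
}

#' Read a table of A-to-I RNA-editing sites
#'
#' Tab-separated with header columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `strand`. A-to-I editing reads as A>G on the plus strand and T>C on the
#' minus strand (the reverse complement); any other base pair is rejected.
#'
#' @param path path to the TSV
#' @return `data.frame` with columns chrom, pos, ref, alt, strand
#' @export
read_editing_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")  # "T" must stay a base, not TRUE
  need <- c("chrom", "pos", "ref", "alt", "strand")
  if (!all(need %in% names(df)))
    abort("editing table must have header columns: %s", paste(need, collapse = ", "))
  df <- df[, need, drop = FALSE]
  if (nrow(df) == 0L) return(df)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  ok <- (df$ref == "A" & df$alt == "G" & df$strand == "+") |
        (df$ref == "T" & df$alt == "C" & df$strand == "-")
  if (any(!ok))
    abort("editing table row %d: %s>%s on strand %s is not an A-to-I pair",
          which(!ok)[1], df$ref[which(!ok)[1]], df$alt[which(!ok)[1]],
          df$strand[which(!ok)[1]])
  df
}

#' Write a table of RNA-editing sites
#'
#' @param sites `data.frame` with chrom, pos (1-based), ref, alt, strand
#'   (and optionally extra columns, e.g. per-site editing fraction)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_editing_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
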