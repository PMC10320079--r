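# Alignment I/O and the preprocessing stage: read filtering and splitting
# of spliced reads at SKIP (N) CIGAR operations.

SAM_FLAG <- c(unmapped = 4L, reverse = 16L, secondary = 256L,
              duplicate = 1024L, supplementary = 2048L)

#' Write aligned reads to a coordinate-sorted, indexed BAM
#'
#' Reads are serialized as SAM text and converted with Rsamtools. Segment
#' tables (from [split_skip_reads()]) carry their parent read name and
#' segment index in the `XP`/`XI` auxiliary tags.
#'
#' @param reads alignment `data.frame` (`qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, optionally `parent`, `segment_index`)
#' @param path output BAM path
#' @param contigs named integer vector of contig lengths
#' @return the BAM path, invisibly
#' @export
write_alignments <- function(reads, path, contigs) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  body <- character(0)
  if (nrow(reads)) {
    missing_ctg <- setdiff(unique(reads$chrom), names(contigs))
    if (length(missing_ctg))
      abort("contig(s) absent from header: %s", paste(missing_ctg, collapse = ","))
    r <- reads[order(match(reads$chrom, names(contigs)), reads$pos, reads$qname), ]
    tags <- if (all(c("parent", "segment_index") %in% names(r)))
      sprintf("\tXP:Z:%s\tXI:i:%d", r$parent, r$segment_index) else ""
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                    r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                    r$seq, r$qual, tags)
  }
  sam <- sub("\\.bam$", ".sam", path)
  if (identical(sam, path)) sam <- paste0(path, ".sam")
  writeLines(c(hdr, body), sam)
  on.exit(unlink(sam))
  tmp <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(tmp)
}

#' Read a BAM (or SAM-derived) file into an alignment data.frame
#'
#' @param path BAM path
#' @return alignment `data.frame` with `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual` (and `parent`/`segment_index` when the
#'   `XP`/`XI` tags are present)
#' @export
read_alignments <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("XP", "XI"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  df <- data.frame(qname = b$qname, flag = b$flag,
                   chrom = as.character(b$rname), pos = b$pos, mapq = b$mapq,
                   cigar = b$cigar, seq = as.character(b$seq),
                   qual = as.character(b$qual), stringsAsFactors = FALSE)
  if (!is.null(b$tag$XP) && !all(is.na(b$tag$XP))) {
    df$parent <- b$tag$XP
    df$segment_index <- b$tag$XI
  }
  df
}

#' Filter alignments before candidate discovery
#'
#' Drops unmapped, secondary, supplementary and duplicate-flagged reads and
#' reads below `min_mapq`; counts removed per reason are reported via
#' `message()`.
#'
#' @param reads alignment `data.frame`
#' @param min_mapq minimum mapping quality (default 1 excludes multimappers)
#' @return the retained reads
#' @export
filter_reads <- function(reads, min_mapq = 1L) {
  f <- reads$flag
  drop <- list(unmapped = bitwAnd(f, SAM_FLAG[["unmapped"]]) != 0L,
               secondary = bitwAnd(f, SAM_FLAG[["secondary"]]) != 0L,
               supplementary = bitwAnd(f, SAM_FLAG[["supplementary"]]) != 0L,
               duplicate = bitwAnd(f, SAM_FLAG[["duplicate"]]) != 0L,
               low_mapq = reads$mapq < min_mapq)
  any_drop <- Reduce(`|`, drop)
  counts <- vapply(drop, sum, 0L)
  if (any(counts > 0))
    message("filter_reads dropped: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  out <- reads[!any_drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split spliced reads into intron-free segments
#'
#' Each maximal N-free run of CIGAR operations becomes one segment; segment
#' k starts at the parent position plus the reference length consumed by all
#' prior operations including the skipped introns. Query bases and
#' qualities are partitioned without loss or duplication. Insertions at a
#' segment boundary attach to the left segment; deletions adjacent to an N
#' stay inside their segment. Segments with fewer than `min_segment_len`
#' aligned query bases are dropped (tiny exon overhangs carry no usable
#' variant context); the count is reported via `message()`. Reads without N
#' pass through as a single segment.
#'
#' @param reads alignment `data.frame` (post [filter_reads()])
#' @param min_segment_len minimum aligned query bases per kept segment
#' @return segment `data.frame`: parent fields plus `parent` (read name) and
#'   `segment_index`; `qname` becomes `"<parent>/<segment_index>"` for split
#'   reads and no segment CIGAR contains N
#' @export
split_skip_reads <- function(reads, min_segment_len = 15L) {
  if (nrow(reads) == 0L) {
    out <- reads; out$parent <- character(0); out$segment_index <- integer(0)
    return(out)
  }
  has_n <- grepl("N", reads$cigar, fixed = TRUE)
  plain <- reads[!has_n, , drop = FALSE]
  if (nrow(plain)) { plain$parent <- plain$qname; plain$segment_index <- 1L }
  spliced <- reads[has_n, , drop = FALSE]
  seg <- NULL
  n_dropped <- 0L
  if (nrow(spliced)) {
    ops_l <- GenomicAlignments::explodeCigarOps(spliced$cigar)
    len_l <- GenomicAlignments::explodeCigarOpLengths(spliced$cigar)
    nops <- lengths(ops_l)
    dt <- data.table(rid = rep(seq_len(nrow(spliced)), nops),
                     op = unlist(ops_l), len = unlist(len_l))
    core <- dt[!op %in% c("S", "H")]
    edge <- core[, .(first = op[1], last = op[.N]), by = rid]
    bad <- edge[first == "N" | last == "N", rid]
    if (length(bad))
      abort("malformed alignment %s: CIGAR begins or ends with N",
            spliced$qname[bad[1]])
    dt[, `:=`(qc = len * (op %in% c("M", "I", "S", "=", "X")),
              rc = len * (op %in% c("M", "D", "N", "=", "X")))]
    dt[, `:=`(qoff = cumsum(qc) - qc, roff = cumsum(rc) - rc,
              grp = cumsum(op == "N"),
              after_n = c(FALSE, op[-.N] == "N")), by = rid]
    # insertions opening a post-N group attach to the left segment
    dt[op == "I" & after_n, grp := grp - 1L]
    body <- dt[op != "N"]
    seg <- body[, .(pos = spliced$pos[rid[1]] + roff[1],
                    cigar = paste0(len, op, collapse = ""),
                    qlo = qoff[1] + 1L, qhi = qoff[.N] + qc[.N],
                    aligned = sum(len[op %in% c("M", "I", "=", "X")])),
                by = .(rid, grp)]
    n_dropped <- sum(seg$aligned < min_segment_len)
    seg <- seg[aligned >= min_segment_len]
    if (nrow(seg)) {
      seg[, segment_index := seq_len(.N), by = rid]
      seg <- data.frame(
        qname = sprintf("%s/%d", spliced$qname[seg$rid], seg$segment_index),
        flag = spliced$flag[seg$rid], chrom = spliced$chrom[seg$rid],
        pos = seg$pos, mapq = spliced$mapq[seg$rid], cigar = seg$cigar,
        seq = substring(spliced$seq[seg$rid], seg$qlo, seg$qhi),
        qual = substring(spliced$qual[seg$rid], seg$qlo, seg$qhi),
        parent = spliced$qname[seg$rid], segment_index = seg$segment_index,
        stringsAsFactors = FALSE)
    } else seg <- NULL
  }
  if (n_dropped > 0L)
    message(sprintf("split_skip_reads dropped %d segments shorter than %d aligned bases",
                    n_dropped, min_segment_len))
  common <- c("qname", "flag", "chrom", "pos", "mapq", "cigar", "seq", "qual",
              "parent", "segment_index")
  parts <- Filter(Negate(is.null), list(
    if (nrow(plain)) plain[, intersect(common, names(plain))] else NULL,
    if (!is.null(seg)) seg[, intersect(common, names(seg))] else NULL))
  if (!length(parts)) {
    out <- reads[0, , drop = FALSE]
    out$parent <- character(0); out$segment_index <- integer(0)
    return(out)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$pos, out$qname), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reference span (width) of each alignment from its CIGAR.
alignment_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}
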