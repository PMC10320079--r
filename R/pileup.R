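# Pileup construction over split (N-free) segments and candidate discovery.

# Expand segments into a per-base / per-indel event table.
#
# Returns a data.table with one row per aligned base ("base"), insertion
# ("ins", tallied at its left-anchor column), deletion allele ("del",
# tallied at the base preceding the deleted run) and deleted position
# ("delspan", counted in depth but carrying no allele). Columns: read_id,
# qname, chrom, pos, kind, base (allele string), qual, mapq, fwd, start.
segment_events <- function(segments) {
  n <- nrow(segments)
  empty <- data.table(read_id = integer(), qname = character(),
                      chrom = character(), pos = integer(), kind = character(),
                      base = character(), qual = integer(), mapq = integer(),
                      fwd = logical(), start = integer())
  if (n == 0L) return(empty)
  if (any(grepl("N", segments$cigar, fixed = TRUE)))
    abort("segment_events requires N-free segments; run split_skip_reads first")
  ops_l <- GenomicAlignments::explodeCigarOps(segments$cigar)
  len_l <- GenomicAlignments::explodeCigarOpLengths(segments$cigar)
  nops <- lengths(ops_l)
  dt <- data.table(rid = rep(seq_len(n), nops),
                   op = unlist(ops_l), len = unlist(len_l))
  dt[, `:=`(qc = len * (op %in% c("M", "I", "S", "=", "X")),
            rc = len * (op %in% c("M", "D", "=", "X")))]
  dt[, `:=`(qoff = cumsum(qc) - qc, roff = cumsum(rc) - rc), by = rid]
  allseq <- paste(segments$seq, collapse = "")
  seqoff <- cumsum(nchar(segments$seq)) - nchar(segments$seq)
  qraw <- as.integer(charToRaw(paste(segments$qual, collapse = ""))) - 33L
  rpos0 <- segments$pos
  fwd0 <- bitwAnd(segments$flag, SAM_FLAG[["reverse"]]) == 0L

  pieces <- list()
  m <- dt[op %in% c("M", "=", "X")]
  if (nrow(m)) {
    rid <- rep(m$rid, m$len)
    qpos <- rep(m$qoff, m$len) + sequence(m$len)
    gidx <- seqoff[rid] + qpos
    pieces$base <- data.table(
      read_id = rid,
      pos = rep(rpos0[m$rid] + m$roff, m$len) + sequence(m$len) - 1L,
      kind = "base",
      base = substring(allseq, gidx, gidx),
      qual = qraw[gidx])
  }
  i <- dt[op == "I" & roff > 0L]  # leading insertions have no anchor column
  if (nrow(i)) {
    gs <- seqoff[i$rid] + i$qoff
    pieces$ins <- data.table(
      read_id = i$rid,
      pos = rpos0[i$rid] + i$roff - 1L,
      kind = "ins",
      base = paste0("+", substring(allseq, gs + 1L, gs + i$len)),
      qual = qraw[gs + 1L])
  }
  d <- dt[op == "D" & roff > 0L]
  if (nrow(d)) {
    pieces$del <- data.table(
      read_id = d$rid,
      pos = rpos0[d$rid] + d$roff - 1L,
      kind = "del",
      base = paste0("-", d$len),
      qual = NA_integer_)
    pieces$delspan <- data.table(
      read_id = rep(d$rid, d$len),
      pos = rep(rpos0[d$rid] + d$roff, d$len) + sequence(d$len) - 1L,
      kind = "delspan", base = "*", qual = NA_integer_)
  }
  ev <- rbindlist(pieces)
  if (nrow(ev) == 0L) return(empty)
  ev[, `:=`(qname = segments$qname[read_id], chrom = segments$chrom[read_id],
            mapq = segments$mapq[read_id], fwd = fwd0[read_id],
            start = segments$pos[read_id])]
  setorder(ev, chrom, pos, read_id)
  ev[]
}

#' Build a pileup over split read segments
#'
#' Tallies, per reference column, every aligned base with quality at or
#' above `min_base_qual`, insertion alleles at their left-anchor column and
#' deletion alleles at the base preceding the deleted run. Depth counts
#' reads contributing an aligned base or a deletion span at the column,
#' regardless of base quality.
#'
#' @param segments N-free segment `data.frame` (see [split_skip_reads()])
#' @param reference `DNAStringSet` of the reference (for the `ref` column)
#' @param region optional `GRanges` restricting the scan
#' @param min_base_qual minimum base quality for allele tallies
#' @return `data.table` with one row per (column, allele): `chrom`, `pos`,
#'   `ref`, `allele`, `count`, `mean_qual`, `fwd`, `rev_`, `depth`
#' @export
build_pileup <- function(segments, reference, region = NULL,
                         min_base_qual = 10L) {
  ev <- segment_events(segments)
  if (!is.null(region)) {
    bad <- setdiff(unique(as.character(GenomeInfoDb::seqnames(region))),
                   names(reference))
    if (length(bad)) abort("region contig %s not in reference", bad[1])
    if (any(BiocGenerics::end(region) >
            Biostrings::width(reference)[match(
              as.character(GenomeInfoDb::seqnames(region)), names(reference))]))
      abort("region extends beyond contig end")
    if (nrow(ev)) {
      keep <- pos_in_regions(ev$chrom, ev$pos, region)
      ev <- ev[keep]
    }
  }
  if (nrow(ev) == 0L)
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      allele = character(), count = integer(),
                      mean_qual = numeric(), fwd = integer(), rev_ = integer(),
                      depth = integer()))
  # one base or delspan event per read per column, so depth is a row count
  depth_dt <- ev[kind %in% c("base", "delspan"), .(depth = .N),
                 by = .(chrom, pos)]
  al <- ev[(kind == "base" & qual >= min_base_qual) | kind %in% c("ins", "del")]
  out <- al[, .(count = .N, mean_qual = mean(qual, na.rm = TRUE),
                fwd = sum(fwd), rev_ = sum(!fwd)),
            by = .(chrom, pos, allele = base)]
  out <- merge(out, depth_dt, by = c("chrom", "pos"), all.x = TRUE)
  out[is.na(depth), depth := 0L]
  out[, ref := as.character(Biostrings::extractAt(
    reference[[chrom[1]]], IRanges::IRanges(pos, pos))), by = chrom]
  setorder(out, chrom, pos, -count, allele)
  out[, .(chrom, pos, ref, allele, count, mean_qual, fwd, rev_, depth)]
}

#' Propose candidate variant sites from a pileup
#'
#' An alternate allele becomes a candidate when it is supported by at least
#' `min_alt_count` reads (the core discovery rule: two or more bases
#' differing from the reference) and by at least `min_alt_fraction` of the
#' column depth — the fraction floor keeps two stray reads at very deep
#' RNA columns from flooding the classifier. At most two alternate alleles
#' are kept per column, by descending support (ties broken by allele
#' lexicographic order). SNP and indel candidates may coexist at one column.
#'
#' @param pileup from [build_pileup()]
#' @param reference `DNAStringSet` (for indel anchor/deleted bases)
#' @param min_alt_count minimum supporting reads (default 2)
#' @param min_alt_fraction minimum supporting fraction of depth (default 0.1)
#' @return candidate `data.frame`: `chrom`, `pos`, `ref`, `alt`, `kind`
#'   (SNP/INS/DEL), `alt_count`, `depth`, `mean_qual`, `fwd`, `rev_`
#' @export
find_candidates <- function(pileup, reference, min_alt_count = 2L,
                            min_alt_fraction = 0.1) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), kind = character(),
                      alt_count = integer(), depth = integer(),
                      mean_qual = numeric(), fwd = integer(), rev_ = integer())
  if (nrow(pileup) == 0L) return(empty)
  alt <- pileup[allele != ref & allele != "*" & depth > 0L &
                count >= min_alt_count & count / depth >= min_alt_fraction]
  if (nrow(alt) == 0L) return(empty)
  setorder(alt, chrom, pos, -count, allele)
  alt <- alt[, head(.SD, 2L), by = .(chrom, pos)]
  kind <- ifelse(startsWith(alt$allele, "+"), "INS",
          ifelse(startsWith(alt$allele, "-"), "DEL", "SNP"))
  ref_out <- alt$ref; alt_out <- alt$allele
  if (any(kind == "INS")) {
    k <- which(kind == "INS")
    alt_out[k] <- paste0(alt$ref[k], substring(alt$allele[k], 2L))
  }
  if (any(kind == "DEL")) {
    k <- which(kind == "DEL")
    dlen <- as.integer(substring(alt$allele[k], 2L))
    ref_out[k] <- vapply(seq_along(k), function(j)
      as.character(Biostrings::subseq(reference[[alt$chrom[k[j]]]],
                                      alt$pos[k[j]],
                                      alt$pos[k[j]] + dlen[j])), "")
    alt_out[k] <- alt$ref[k]
  }
  data.frame(chrom = alt$chrom, pos = alt$pos, ref = ref_out, alt = alt_out,
             kind = kind, alt_count = alt$count, depth = alt$depth,
             mean_qual = alt$mean_qual, fwd = alt$fwd, rev_ = alt$rev_,
             stringsAsFactors = FALSE)
}
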