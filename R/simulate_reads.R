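# Spliced read generation: per-gene haplotype transcripts -> aligned reads.

# Build one haplotype's transcript as parallel vectors: emitted base and the
# reference position it aligns to (NA for inserted bases). `epos` is the
# ascending vector of exonic reference positions of the gene; variants are
# the gene's truth records carried by this haplotype.
hap_transcript <- function(epos, ebase, variants) {
  key <- as.numeric(epos); refpos <- epos; base <- ebase
  drop <- logical(length(epos))
  ins_key <- numeric(0); ins_base <- character(0)
  if (nrow(variants)) for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
    j <- match(p, epos)
    if (is.na(j)) next
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      base[j] <- alt
    } else if (nchar(ref) > 1L) {            # deletion of ref positions p+1..p+L
      drop[epos > p & epos <= p + nchar(ref) - 1L] <- TRUE
    } else {                                  # insertion after anchor p
      ins <- strsplit(substring(alt, 2L), "")[[1]]
      ins_key <- c(ins_key, p + seq_along(ins) / (length(ins) + 1))
      ins_base <- c(ins_base, ins)
    }
  }
  key <- c(key[!drop], ins_key)
  refpos <- c(refpos[!drop], rep(NA_integer_, length(ins_key)))
  base <- c(base[!drop], ins_base)
  o <- order(key)
  list(refpos = refpos[o], base = base[o])
}

# CIGAR string for one read given its per-base reference positions (NA for
# inserted bases). `exon_ends` marks junction donors: a gap whose left
# flank is an exon end is an intron (N); any other gap is a deletion (D).
cigar_from_refpos <- function(rp, exon_ends) {
  n <- length(rp)
  if (!anyNA(rp)) {
    d <- diff(rp)
    br <- which(d > 1L)
    if (!length(br)) return(paste0(n, "M"))
    mlen <- diff(c(0L, br, n))
    gop <- ifelse(rp[br] %in% exon_ends, "N", "D")
    parts <- character(2L * length(br) + 1L)
    parts[seq(1L, by = 2L, length.out = length(mlen))] <- paste0(mlen, "M")
    parts[seq(2L, by = 2L, length.out = length(br))] <- paste0(d[br] - 1L, gop)
    return(paste(parts, collapse = ""))
  }
  ops <- character(0); lens <- integer(0)
  emit <- function(op, len) {
    k <- length(ops)
    if (k && ops[k] == op) lens[k] <<- lens[k] + len
    else { ops[k + 1L] <<- op; lens[k + 1L] <<- len }
  }
  prev <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(rp[i])) { emit("I", 1L); next }
    if (!is.na(prev)) {
      gap <- rp[i] - prev - 1L
      if (gap > 0L) emit(if (prev %in% exon_ends) "N" else "D", gap)
    }
    emit("M", 1L)
    prev <- rp[i]
  }
  paste0(lens, ops, collapse = "")
}

#' Simulate aligned spliced reads from a genome and truth set
#'
#' Reads are emitted pre-aligned at their generating locus: junction-spanning
#' reads carry N CIGAR operations whose lengths equal the skipped intron
#' lengths. Per-transcript depth is `mean_coverage * LogNormal(0,
#' expression_dispersion)`; at heterozygous sites the read's haplotype is
#' Bernoulli in the gene's ASE skew (haplotype 1 carries the alternate
#' allele); reads covering an editing site show the edited base with the
#' site's editing fraction; sequencing errors are i.i.d. at
#' `base_error_rate` with qualities Normal(quality_mean, quality_sd) clipped
#' to [2, 40]; duplicates copy an existing read and set the duplicate flag.
#'
#' @param genome from [make_genome()]
#' @param truth from [spike_truth()]
#' @param config a [sim_config()]
#' @return `data.frame` of aligned reads: `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, `gene_id`, coordinate-sorted
#' @export
simulate_reads <- function(genome, truth, config) {
  with_seed(derive_seed(config$seed, "reads"), {
    out <- list()
    for (gi in seq_along(genome$genes)) {
      g <- genome$genes[gi]
      gid <- g$gene_id
      chrom <- as.character(GenomeInfoDb::seqnames(g))
      ex <- genome$exons[genome$exons$gene_id == gid]
      ex <- ex[order(BiocGenerics::start(ex))]
      epos <- unlist(Map(seq.int, BiocGenerics::start(ex), BiocGenerics::end(ex)))
      ebase <- strsplit(as.character(Biostrings::subseq(
        genome$seqs[[chrom]], min(epos), max(epos))), "")[[1]][epos - min(epos) + 1L]
      exon_ends <- BiocGenerics::end(ex)[-length(ex)]
      vg <- truth$variants[truth$variants$chrom == chrom &
                           truth$variants$pos %in% epos, , drop = FALSE]
      hap <- list(
        hap_transcript(epos, ebase, vg[vg$gt %in% c("0/1", "1/1"), , drop = FALSE]),
        hap_transcript(epos, ebase, vg[vg$gt == "1/1", , drop = FALSE]))
      ed <- truth$editing[truth$editing$chrom == chrom &
                          truth$editing$pos %in% epos, , drop = FALSE]
      depth <- config$mean_coverage * rlnorm(1, 0, config$expression_dispersion)
      n_reads <- max(0L, as.integer(round(depth * length(epos) / config$read_length)))
      if (n_reads == 0L) next
      s <- truth$ase[[gid]]
      hap_of <- ifelse(runif(n_reads) < s, 1L, 2L)
      reads <- vector("list", n_reads)
      for (r in seq_len(n_reads)) {
        h <- hap[[hap_of[r]]]
        txlen <- length(h$base)
        L <- min(config$read_length, txlen)
        st <- sample.int(txlen - L + 1L, 1L)
        idx <- st:(st + L - 1L)
        rp <- h$refpos[idx]; bb <- h$base[idx]
        # trim inserted bases hanging off the read ends
        nn <- which(!is.na(rp))
        if (length(nn) == 0L) next
        if (nn[1] > 1L || nn[length(nn)] < length(rp)) {
          idx2 <- nn[1]:nn[length(nn)]
          rp <- rp[idx2]; bb <- bb[idx2]
        }
        # RNA editing: per covered site, edited with its fraction
        if (nrow(ed)) {
          hit <- match(ed$pos, rp)
          for (k in which(!is.na(hit)))
            if (runif(1) < ed$fraction[k]) bb[hit[k]] <- ed$alt[k]
        }
        # sequencing error
        if (config$base_error_rate > 0) {
          err <- which(runif(length(bb)) < config$base_error_rate)
          for (k in err) bb[k] <- sample(setdiff(c("A", "C", "G", "T"), bb[k]), 1L)
        }
        q <- as.integer(round(rnorm(length(bb), config$quality_mean, config$quality_sd)))
        q <- pmin(40L, pmax(2L, q))
        reads[[r]] <- list(pos = rp[1], cigar = cigar_from_refpos(rp, exon_ends),
                           seq = paste(bb, collapse = ""),
                           qual = rawToChar(as.raw(q + 33L)))
      }
      reads <- reads[!vapply(reads, is.null, TRUE)]
      if (!length(reads)) next
      out[[gid]] <- data.frame(
        chrom = chrom,
        pos = vapply(reads, `[[`, 0, "pos"),
        cigar = vapply(reads, `[[`, "", "cigar"),
        seq = vapply(reads, `[[`, "", "seq"),
        qual = vapply(reads, `[[`, "", "qual"),
        gene_id = gid, stringsAsFactors = FALSE)
    }
    if (!length(out)) {
      reads <- data.frame(qname = character(), flag = integer(),
                          chrom = character(), pos = integer(), mapq = integer(),
                          cigar = character(), seq = character(),
                          qual = character(), gene_id = character())
      return(reads)
    }
    reads <- do.call(rbind, out)
    n <- nrow(reads)
    reads$qname <- sprintf("r%07d", seq_len(n))
    reads$flag <- ifelse(runif(n) < 0.5, 16L, 0L)
    reads$mapq <- 60L
    # PCR duplicates: copy existing reads and set the duplicate flag
    ndup <- as.integer(round(config$duplication_rate * n))
    if (ndup > 0L) {
      di <- sample.int(n, ndup, replace = TRUE)
      dup <- reads[di, , drop = FALSE]
      dup$flag <- bitwOr(dup$flag, 1024L)
      dup$qname <- sprintf("%s.dup%d", dup$qname, seq_len(ndup))
      reads <- rbind(reads, dup)
    }
    reads <- reads[order(match(reads$chrom, names(genome$seqs)), reads$pos,
                         reads$qname), ]
    rownames(reads) <- NULL
    reads[, c("qname", "flag", "chrom", "pos", "mapq", "cigar", "seq", "qual",
              "gene_id")]
  })
}

#' Simulate a complete dataset to disk
#'
#' Runs [make_genome()], [spike_truth()] and [simulate_reads()] and writes
#' every artifact the pipeline consumes: reference FASTA, gene-model GTF,
#' coordinate-sorted indexed BAM, truth VCF, editing-site TSV,
#' confident-region BED, and the configuration as JSON.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if needed)
#' @return invisible list with the in-memory objects (`genome`, `truth`,
#'   `reads`) and all file `paths`
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(config)
  truth <- spike_truth(genome, config)
  reads <- simulate_reads(genome, truth, config)
  paths <- list(
    fasta = file.path(out_dir, "ref.fasta"),
    gtf = file.path(out_dir, "genes.gtf"),
    bam = file.path(out_dir, "reads.bam"),
    truth_vcf = file.path(out_dir, "truth.vcf"),
    editing = file.path(out_dir, "editing.tsv"),
    confident = file.path(out_dir, "confident.bed"),
    config = file.path(out_dir, "sim_config.json"))
  write_genome(genome, paths$fasta, paths$gtf)
  contigs <- setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  write_alignments(reads, paths$bam, contigs)
  write_vcf(truth$variants, paths$truth_vcf, contigs)
  write_editing_table(truth$editing, paths$editing)
  write_regions(truth$confident, paths$confident)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(genome = genome, truth = truth, reads = reads, paths = paths))
}
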