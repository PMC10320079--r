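#' Simulation configuration
#'
#' One object holds every knob of the spliced-read simulator: genome layout,
#' variant and editing rates, expression dispersion, allele-specific
#' expression (ASE) skew, base error and duplication. All randomness derives
#' from `seed`; identical configurations produce byte-identical outputs.
#'
#' Rates are per base pair. `expression_dispersion` is the log-normal sigma
#' of per-transcript depth around `mean_coverage`. `ase_skew` is the range
#' from which each gene's probability of sampling haplotype 1 (the haplotype
#' carrying the alternate allele at heterozygous sites) is drawn.
#' `editing_fraction` is the range of per-site A-to-I editing fractions.
#'
#' @param seed integer seed
#' @param n_genes number of genes
#' @param n_chroms number of chromosomes genes are distributed over
#' @param exons_per_gene integer range `c(min, max)`
#' @param exon_length,intron_length,intergenic_length bp ranges
#' @param utr_margin bp trimmed from the first/last exon to delimit the CDS
#' @param snp_rate,indel_rate per-bp rates over gene bodies
#' @param max_indel_len maximum inserted/deleted length
#' @param het_hom_ratio ratio of heterozygous to homozygous-alt genotypes
#' @param editing_site_rate per exonic-bp rate of A-to-I sites
#' @param editing_fraction range of per-site editing fractions in `[0,1]`
#' @param mean_coverage target mean exonic depth
#' @param expression_dispersion log-normal sigma of per-transcript depth
#' @param ase_skew range of per-gene haplotype-1 sampling probability
#' @param read_length read length in bp (>= 20)
#' @param base_error_rate i.i.d. substitution error rate
#' @param quality_mean,quality_sd base quality distribution, clipped to [2,40]
#' @param duplication_rate fraction of reads duplicated (flagged, not resequenced)
#' @return a validated list of class `rnavc_sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, n_chroms = 4L,
                       exons_per_gene = c(2L, 5L), exon_length = c(80L, 300L),
                       intron_length = c(60L, 400L),
                       intergenic_length = c(200L, 500L), utr_margin = 30L,
                       snp_rate = 0.002, indel_rate = 2e-4, max_indel_len = 6L,
                       het_hom_ratio = 2, editing_site_rate = 2e-4,
                       editing_fraction = c(0.2, 0.9), mean_coverage = 30,
                       expression_dispersion = 0.2, ase_skew = c(0.3, 0.7),
                       read_length = 100L, base_error_rate = 0.005,
                       quality_mean = 30, quality_sd = 4,
                       duplication_rate = 0.02) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chroms = as.integer(n_chroms),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_length = as.integer(intergenic_length),
              utr_margin = as.integer(utr_margin),
              snp_rate = snp_rate, indel_rate = indel_rate,
              max_indel_len = as.integer(max_indel_len),
              het_hom_ratio = het_hom_ratio,
              editing_site_rate = editing_site_rate,
              editing_fraction = editing_fraction,
              mean_coverage = mean_coverage,
              expression_dispersion = expression_dispersion,
              ase_skew = ase_skew, read_length = as.integer(read_length),
              base_error_rate = base_error_rate, quality_mean = quality_mean,
              quality_sd = quality_sd, duplication_rate = duplication_rate)
  rates <- c(cfg$snp_rate, cfg$indel_rate, cfg$editing_site_rate,
             cfg$base_error_rate, cfg$duplication_rate,
             cfg$editing_fraction, cfg$ase_skew)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (cfg$read_length < 20L) abort("read_length must be >= 20")
  if (cfg$mean_coverage <= 0) abort("mean_coverage must be > 0")
  for (f in c("exons_per_gene", "exon_length", "intron_length",
              "intergenic_length", "editing_fraction", "ase_skew")) {
    v <- cfg[[f]]
    if (length(v) != 2L || v[1] > v[2]) abort("infeasible range for %s", f)
  }
  if (cfg$exon_length[1] < 2L * cfg$max_indel_len + 8L)
    abort("exon_length minimum too small for max_indel_len")
  class(cfg) <- "rnavc_sim_config"
  cfg
}

# Uniform integer draw in [lo, hi] per element.
runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a random genome with gene models
#'
#' Genes are laid out sequentially on `n_chroms` chromosomes (`sim1`,
#' `sim2`, ...), each with one multi-exon transcript; the CDS is the exon
#' chain trimmed by `utr_margin` bp at each end, so CDS, exon, transcript
#' and gene intervals nest. Deterministic given the configuration seed.
#'
#' @param config a [sim_config()]
#' @return list of class `rnavc_genome`: `seqs` (`DNAStringSet`), `genes`,
#'   `transcripts`, `exons`, `cds` (`GRanges` with `gene_id`,
#'   `transcript_id`), `config`
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "rnavc_sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- paste0("sim", seq_len(config$n_chroms))
    cursor <- setNames(rep(0L, config$n_chroms), chroms)
    exon_rows <- list(); gene_rows <- list()
    if (config$n_genes > 0) for (g in seq_len(config$n_genes)) {
      chrom <- chroms[(g - 1L) %% config$n_chroms + 1L]
      n_ex <- runif_int(1L, config$exons_per_gene)
      ex_len <- runif_int(n_ex, config$exon_length)
      in_len <- if (n_ex > 1L) runif_int(n_ex - 1L, config$intron_length) else integer(0)
      gap <- runif_int(1L, config$intergenic_length)
      gstart <- cursor[chrom] + gap + 1L
      starts <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len - 1L
      strand <- sample(c("+", "-"), 1L)
      exon_rows[[g]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                   strand = strand, gene_id = sprintf("gene%04d", g),
                                   exon_number = seq_len(n_ex))
      gene_rows[[g]] <- data.frame(chrom = chrom, start = gstart,
                                   end = ends[n_ex], strand = strand,
                                   gene_id = sprintf("gene%04d", g))
      cursor[chrom] <- ends[n_ex]
    }
    chrom_len <- cursor + runif_int(config$n_chroms, config$intergenic_length)
    chrom_len <- pmax(chrom_len, 1000L)
    seqs <- Biostrings::DNAStringSet(vapply(chrom_len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""))
    names(seqs) <- chroms

    if (length(exon_rows)) {
      ex <- do.call(rbind, exon_rows)
      gn <- do.call(rbind, gene_rows)
      exons <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                                      strand = ex$strand, gene_id = ex$gene_id,
                                      transcript_id = paste0(ex$gene_id, ".t1"),
                                      exon_number = ex$exon_number)
      genes <- GenomicRanges::GRanges(gn$chrom, IRanges::IRanges(gn$start, gn$end),
                                      strand = gn$strand, gene_id = gn$gene_id)
      transcripts <- genes
      transcripts$transcript_id <- paste0(genes$gene_id, ".t1")
      # CDS: exon chain trimmed by utr_margin at the gene's two ends
      cds_list <- lapply(split(seq_along(exons), exons$gene_id), function(ii) {
        e <- exons[ii]
        lo <- min(BiocGenerics::start(e)) + config$utr_margin
        hi <- max(BiocGenerics::end(e)) - config$utr_margin
        win <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(e)[1],
                                      IRanges::IRanges(lo, hi))
        out <- suppressWarnings(IRanges::subsetByOverlaps(e, win, ignore.strand = TRUE))
        GenomicRanges::restrict(out, start = lo, end = hi)
      })
      cds <- unlist(GenomicRanges::GRangesList(cds_list), use.names = FALSE)
    } else {
      exons <- genes <- transcripts <- cds <- GenomicRanges::GRanges()
    }
    for (gr_name in c("genes", "transcripts", "exons", "cds")) {
      gr <- get(gr_name)
      GenomeInfoDb::seqlevels(gr) <- chroms
      GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_len)
      assign(gr_name, gr)
    }
    structure(list(seqs = seqs, genes = genes, transcripts = transcripts,
                   exons = exons, cds = cds, config = config),
              class = "rnavc_genome")
  })
}

#' Write a genome's reference FASTA and gene-model GTF
#'
#' @param genome from [make_genome()]
#' @param fasta_path,gtf_path output paths
#' @return invisible list of the two paths
#' @export
write_genome <- function(genome, fasta_path, gtf_path) {
  Biostrings::writeXStringSet(genome$seqs, fasta_path)
  rows <- list()
  g <- genome$genes
  if (length(g)) {
    add <- function(gr, type, tx_id = NA_character_) {
      df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                       start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                       strand = as.character(BiocGenerics::strand(gr)),
                       type = type, gene_id = gr$gene_id,
                       transcript_id = if (type == "gene") "" else
                         paste0(gr$gene_id, ".t1"))
      df
    }
    rows <- rbind(add(genome$genes, "gene"), add(genome$transcripts, "transcript"),
                  add(genome$exons, "exon"), add(genome$cds, "CDS"))
    rows <- rows[order(rows$chrom, rows$start,
                       match(rows$type, c("gene", "transcript", "exon", "CDS"))), ]
    attrs <- ifelse(rows$type == "gene",
                    sprintf("gene_id \"%s\";", rows$gene_id),
                    sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                            rows$gene_id, rows$transcript_id))
    lines <- sprintf("%s\trnavc_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     rows$chrom, rows$type, rows$start, rows$end, rows$strand, attrs)
  } else lines <- character(0)
  writeLines(lines, gtf_path)
  invisible(list(fasta = fasta_path, gtf = gtf_path))
}

#' Spike truth variants and editing sites into a genome
#'
#' SNPs and indels are placed over gene bodies at the configured per-bp
#' rates; genotypes are drawn from heterozygous (`0/1`) and homozygous-alt
#' (`1/1`) in the `het_hom_ratio` proportion (default 2:1). Indels are
#' left-anchored with one reference base and kept clear of exon boundaries.
#' A-to-I editing sites are placed only at exonic A (plus-strand genes) or T
#' (minus-strand genes) positions, disjoint from variants, each with an
#' editing fraction drawn from the configured range. Heterozygous alternate
#' alleles reside on haplotype 1. Per-gene ASE skews (probability a read
#' samples haplotype 1) are drawn here and stored with the truth set.
#'
#' @param genome from [make_genome()]
#' @param config a [sim_config()]
#' @return list of class `rnavc_truth`: `variants` (variant records),
#'   `editing` (data.frame with `fraction`), `confident` (`GRanges`),
#'   `ase` (named per-gene skew)
#' @export
spike_truth <- function(genome, config) {
  with_seed(derive_seed(config$seed, "truth"), {
    exons <- genome$exons
    variants <- variant_records()
    editing <- data.frame(chrom = character(), pos = integer(), ref = character(),
                          alt = character(), strand = character(),
                          fraction = numeric(), stringsAsFactors = FALSE)
    blocked <- NULL  # positions unavailable (variant footprints + margins)
    if (length(genome$genes) && (config$snp_rate > 0 || config$indel_rate > 0)) {
      vrows <- list()
      for (gi in seq_along(genome$genes)) {
        g <- genome$genes[gi]
        chrom <- as.character(GenomeInfoDb::seqnames(g))
        span <- BiocGenerics::start(g):BiocGenerics::end(g)
        n <- length(span)
        is_snp <- runif(n) < config$snp_rate
        is_ind <- !is_snp & runif(n) < config$indel_rate
        pos <- sort(span[is_snp | is_ind])
        if (!length(pos)) next
        snp_at <- span[is_snp]
        # enforce spacing > max_indel_len + 1 between consecutive variants
        keep <- rep(TRUE, length(pos))
        last <- -Inf
        for (k in seq_along(pos)) {
          if (pos[k] - last <= config$max_indel_len + 1L) keep[k] <- FALSE
          else last <- pos[k]
        }
        pos <- pos[keep]
        ex_g <- exons[exons$gene_id == g$gene_id]
        bnd <- sort(c(BiocGenerics::start(ex_g), BiocGenerics::end(ex_g)))
        refseq <- genome$seqs[[chrom]]
        for (p in pos) {
          gt <- if (runif(1) < config$het_hom_ratio / (config$het_hom_ratio + 1))
            "0/1" else "1/1"
          if (p %in% snp_at) {
            rb <- as.character(Biostrings::subseq(refseq, p, p))
            ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
            vrows[[length(vrows) + 1L]] <-
              data.frame(chrom = chrom, pos = p, ref = rb, alt = ab, gt = gt)
          } else {
            # indel: require the full footprint to stay away from exon
            # boundaries so read CIGARs decompose cleanly into M/I/D/N
            len <- runif_int(1L, c(1L, config$max_indel_len))
            if (min(abs(p - bnd)) <= config$max_indel_len + 2L) next
            anchor <- as.character(Biostrings::subseq(refseq, p, p))
            if (runif(1) < 0.5) {  # insertion
              ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = "")
              vrows[[length(vrows) + 1L]] <-
                data.frame(chrom = chrom, pos = p, ref = anchor,
                           alt = paste0(anchor, ins), gt = gt)
            } else {  # deletion
              if (p + len > length(refseq)) next
              del <- as.character(Biostrings::subseq(refseq, p, p + len))
              vrows[[length(vrows) + 1L]] <-
                data.frame(chrom = chrom, pos = p, ref = del, alt = anchor, gt = gt)
            }
          }
        }
      }
      if (length(vrows)) {
        v <- do.call(rbind, vrows)
        variants <- variant_records(chrom = v$chrom, pos = v$pos, ref = v$ref,
                                    alt = v$alt, gt = v$gt)
      }
    }
    if (nrow(variants)) {
      blocked <- GenomicRanges::GRanges(variants$chrom,
        IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L))
    }
    if (length(exons) && config$editing_site_rate > 0) {
      erows <- list()
      for (gi in seq_along(genome$genes)) {
        g <- genome$genes[gi]
        chrom <- as.character(GenomeInfoDb::seqnames(g))
        strand <- as.character(BiocGenerics::strand(g))
        want <- if (strand == "+") "A" else "T"
        ex_g <- exons[exons$gene_id == g$gene_id]
        epos <- unlist(lapply(seq_along(ex_g), function(i)
          BiocGenerics::start(ex_g)[i]:BiocGenerics::end(ex_g)[i]))
        bases <- strsplit(as.character(Biostrings::subseq(
          genome$seqs[[chrom]], min(epos), max(epos))), "")[[1]]
        at <- epos[bases[epos - min(epos) + 1L] == want]
        # ADAR motif: the transcribed-strand 5' neighbor is G-depleted, so
        # sites require a non-G 5' neighbor (genomic non-C 3' neighbor on
        # minus-strand genes)
        full <- strsplit(as.character(genome$seqs[[chrom]]), "")[[1]]
        at <- if (strand == "+") at[at > 1L & full[at - 1L] != "G"]
              else at[at < length(full) & full[at + 1L] != "C"]
        # rate is per exonic bp; sites land on qualifying (A/T) positions
        n_sites <- min(length(at), rbinom(1L, length(epos),
                                          config$editing_site_rate))
        at <- sort(sample(at, n_sites))
        if (!is.null(blocked) && length(at)) {
          q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(at, at))
          at <- at[!IRanges::overlapsAny(q, blocked)]
        }
        if (length(at))
          erows[[length(erows) + 1L]] <- data.frame(
            chrom = chrom, pos = at, ref = want,
            alt = if (strand == "+") "G" else "C", strand = strand,
            fraction = runif(length(at), config$editing_fraction[1],
                             config$editing_fraction[2]),
            gene_id = g$gene_id)
      }
      if (length(erows)) editing <- do.call(rbind, erows)
    }
    confident <- GenomicRanges::reduce(GenomicRanges::granges(exons) + 10L)
    confident <- GenomicRanges::restrict(confident, start = 1L)
    ase <- setNames(runif(length(genome$genes), config$ase_skew[1],
                          config$ase_skew[2]),
                    genome$genes$gene_id)
    structure(list(variants = variants, editing = editing,
                   confident = confident, ase = ase),
              class = "rnavc_truth")
  })
}
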