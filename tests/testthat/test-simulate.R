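test_that("identical configurations reproduce byte-identical artifacts", {
  cfg <- quick_cfg(seed = 9, n_genes = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("ref.fasta", "genes.gtf", "truth.vcf", "editing.tsv",
              "confident.bed", "reads.bam"))
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]], label = f)
  d3 <- withr::local_tempdir()
  simulate_dataset(quick_cfg(seed = 10, n_genes = 6), d3)
  expect_false(identical(tools::md5sum(file.path(d1, "truth.vcf"))[[1]],
                         tools::md5sum(file.path(d3, "truth.vcf"))[[1]]))
})

test_that("gene models nest (CDS in exon in transcript in gene) and honor ranges", {
  cfg <- quick_cfg(seed = 2, n_genes = 8, exons_per_gene = c(3L, 3L))
  g <- make_genome(cfg)
  expect_equal(unname(table(g$exons$gene_id)[g$genes$gene_id]),
               rep(3L, 8L), ignore_attr = TRUE)
  within <- function(a, b) all(IRanges::overlapsAny(
    a, b, type = "within", ignore.strand = TRUE))
  expect_true(within(g$cds, g$exons))
  expect_true(within(g$exons, g$transcripts))
  expect_true(within(g$transcripts, g$genes))
  # multi-exon transcripts throughout
  expect_true(all(table(g$exons$transcript_id) >= 2L))
})

test_that("zero genes still emits a reference and an empty gene set", {
  cfg <- quick_cfg(seed = 1, n_genes = 0)
  g <- make_genome(cfg)
  expect_length(g$genes, 0L)
  expect_gt(sum(Biostrings::width(g$seqs)), 0L)
  tr <- spike_truth(g, cfg)
  expect_equal(nrow(tr$variants), 0L)
})

test_that("zero rates yield empty truth artifacts", {
  cfg <- quick_cfg(seed = 4, n_genes = 6, snp_rate = 0, indel_rate = 0,
                   editing_site_rate = 0)
  tr <- spike_truth(make_genome(cfg), cfg)
  expect_equal(nrow(tr$variants), 0L)
  expect_equal(nrow(tr$editing), 0L)
})

test_that("editing sites sit on exonic A (+) / T (-) and avoid variants", {
  d <- quick_dataset(quick_cfg(seed = 7, n_genes = 15,
                               editing_site_rate = 2e-3))
  ed <- d$truth$editing
  expect_gt(nrow(ed), 0L)
  expect_true(all((ed$ref == "A" & ed$alt == "G" & ed$strand == "+") |
                  (ed$ref == "T" & ed$alt == "C" & ed$strand == "-")))
  for (i in seq_len(nrow(ed))) {
    b <- as.character(Biostrings::subseq(d$genome$seqs[[ed$chrom[i]]],
                                         ed$pos[i], ed$pos[i]))
    expect_equal(b, ed$ref[i])
  }
  expect_false(any(paste(ed$chrom, ed$pos) %in%
                   paste(d$truth$variants$chrom, d$truth$variants$pos)))
  expect_true(all(ed$fraction >= 0.2 & ed$fraction <= 0.9))
})

test_that("junction reads span introns: ref span = M spans + skipped lengths", {
  d <- quick_dataset()
  rd <- d$reads[grepl("N", d$reads$cigar), ]
  expect_gt(nrow(rd), 0L)
  ops <- GenomicAlignments::explodeCigarOps(rd$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rd$cigar)
  for (i in seq_len(nrow(rd))) {
    span <- GenomicAlignments::cigarWidthAlongReferenceSpace(rd$cigar[i])
    m <- sum(lens[[i]][ops[[i]] %in% c("M", "=", "X")])
    d_ <- sum(lens[[i]][ops[[i]] == "D"])
    nn <- sum(lens[[i]][ops[[i]] == "N"])
    expect_equal(span, m + d_ + nn)
    # every skipped run matches an intron of the generating gene
    ex <- d$genome$exons[d$genome$exons$gene_id == rd$gene_id[i]]
    ex <- ex[order(BiocGenerics::start(ex))]
    introns <- BiocGenerics::start(ex)[-1] - BiocGenerics::end(ex)[-length(ex)] - 1L
    expect_true(all(lens[[i]][ops[[i]] == "N"] %in% introns))
  }
})

test_that("mean exonic depth tracks mean_coverage at moderate dispersion", {
  cfg <- sim_config(seed = 13, n_genes = 50, n_chroms = 2, mean_coverage = 30,
                    expression_dispersion = 0.2)
  d <- quick_dataset(cfg)
  segs <- suppressMessages(split_skip_reads(filter_reads(d$reads)))
  gr <- GenomicRanges::GRanges(segs$chrom, IRanges::IRanges(
    segs$pos, width = GenomicAlignments::cigarWidthAlongReferenceSpace(segs$cigar)))
  cov <- GenomicRanges::coverage(gr, width = setNames(
    Biostrings::width(d$genome$seqs), names(d$genome$seqs)))
  ex <- GenomicRanges::reduce(GenomicRanges::granges(d$genome$exons))
  vals <- unlist(lapply(as.character(unique(GenomeInfoDb::seqnames(ex))), function(ch) {
    v <- cov[[ch]]
    unlist(lapply(which(as.character(GenomeInfoDb::seqnames(ex)) == ch), function(i)
      as.numeric(IRanges::Views(v, BiocGenerics::start(ex)[i],
                                BiocGenerics::end(ex)[i])[[1]])))
  }))
  expect_lt(abs(mean(vals) - 30) / 30, 0.15)
})

test_that("allele fractions reflect genotype, error rate and ASE skew", {
  cfg <- sim_config(seed = 21, n_genes = 40, n_chroms = 2, mean_coverage = 40,
                    base_error_rate = 0.005, ase_skew = c(0.5, 0.5),
                    duplication_rate = 0, editing_site_rate = 0)
  d <- quick_dataset(cfg)
  segs <- suppressMessages(split_skip_reads(filter_reads(d$reads)))
  pu <- build_pileup(segs, d$genome$seqs, min_base_qual = 0L)
  tv <- d$truth$variants
  snp <- tv[nchar(tv$ref) == 1L & nchar(tv$alt) == 1L, ]
  check_site <- function(row, expected) {
    col <- pu[pu$chrom == row$chrom & pu$pos == row$pos]
    n <- col$depth[1]
    if (is.na(n) || n < 10) return(NA)
    obs <- sum(col$count[col$allele == row$alt]) / n
    se <- sqrt(expected * (1 - expected) / n)
    abs(obs - expected) <= 3 * max(se, 1e-3)
  }
  hom <- snp[snp$gt == "1/1", ]
  ok_hom <- vapply(seq_len(nrow(hom)), function(i)
    check_site(hom[i, ], 1 - 0.005), NA)
  het <- snp[snp$gt == "0/1", ]
  ok_het <- vapply(seq_len(nrow(het)), function(i)
    check_site(het[i, ], 0.5), NA)
  # 3 SE covers ~99.7%; allow a small outlier margin across many sites
  expect_gt(mean(ok_hom, na.rm = TRUE), 0.9)
  expect_gt(mean(ok_het, na.rm = TRUE), 0.9)
})

test_that("noiseless reads carry only haplotype bases", {
  cfg <- noiseless_cfg(seed = 6, n_genes = 8)
  d <- quick_dataset(cfg)
  segs <- suppressMessages(split_skip_reads(filter_reads(d$reads)))
  pu <- build_pileup(segs, d$genome$seqs, min_base_qual = 0L)
  tv <- d$truth$variants
  offenders <- pu[pu$allele != pu$ref & pu$allele != "*" &
                  !paste(pu$chrom, pu$pos) %in% paste(tv$chrom, tv$pos)]
  expect_equal(nrow(offenders), 0L)
})

test_that("editing fraction 1 turns every covering read to the edited base", {
  cfg <- noiseless_cfg(seed = 8, n_genes = 8, editing_site_rate = 2e-3,
                       editing_fraction = c(1, 1))
  g <- make_genome(cfg); tr <- spike_truth(g, cfg)
  rd <- simulate_reads(g, tr, cfg)
  segs <- suppressMessages(split_skip_reads(filter_reads(rd)))
  pu <- build_pileup(segs, g$seqs, min_base_qual = 0L)
  expect_gt(nrow(tr$editing), 0L)
  for (i in seq_len(nrow(tr$editing))) {
    col <- pu[pu$chrom == tr$editing$chrom[i] & pu$pos == tr$editing$pos[i]]
    if (nrow(col) == 0L) next
    expect_equal(unique(col$allele), tr$editing$alt[i])
  }
})

test_that("duplicate reads are flagged copies of originals", {
  d <- quick_dataset(quick_cfg(seed = 3, n_genes = 8, duplication_rate = 0.1))
  dup <- d$reads[bitwAnd(d$reads$flag, 1024L) != 0L, ]
  expect_gt(nrow(dup), 0L)
  orig <- d$reads[bitwAnd(d$reads$flag, 1024L) == 0L, ]
  key <- paste(orig$chrom, orig$pos, orig$cigar, orig$seq)
  expect_true(all(paste(dup$chrom, dup$pos, dup$cigar, dup$seq) %in% key))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(read_length = 10), "read_length")
  expect_error(sim_config(snp_rate = 1.5), "rates")
  expect_error(sim_config(exons_per_gene = c(5, 2)), "infeasible")
  expect_error(sim_config(mean_coverage = 0), "mean_coverage")
})
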