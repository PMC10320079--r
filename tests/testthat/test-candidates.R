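# Reference: chrT = ACGT repeated; position p has base c("A","C","G","T")[(p-1)%%4+1]

test_that("pileup tallies bases, honors the quality floor, anchors indels", {
  ref <- toy_reference()
  rd <- do.call(rbind, lapply(1:10, function(i)
    toy_read(paste0("r", i), 1, "8M", "ACGTACGT")))
  pu <- build_pileup(rd, ref)
  col1 <- pu[pu$pos == 1]
  expect_equal(nrow(col1), 1L)
  expect_equal(col1$allele, "A")
  expect_equal(col1$count, 10L)
  expect_equal(col1$depth, 10L)

  # low-quality mismatch: excluded from allele counts, kept in depth
  rd2 <- rbind(rd, toy_read("lowq", 1, "8M", "CCGTACGT", qual = 5L))
  pu2 <- build_pileup(rd2, ref, min_base_qual = 10L)
  col1 <- pu2[pu2$pos == 1]
  expect_equal(sum(col1$count), 10L)
  expect_equal(col1$depth[1], 11L)

  # 2-bp insertion after the third aligned base anchors at column 3
  rd3 <- toy_read("ins", 1, "3M2I3M", "ACGTTTAC")
  pu3 <- build_pileup(rd3, ref, min_base_qual = 0L)
  ins <- pu3[startsWith(pu3$allele, "+")]
  expect_equal(ins$pos, 3L)
  expect_equal(ins$allele, "+TT")

  # deletion: allele at the anchor base, deleted span still in depth
  rd4 <- rbind(rd, toy_read("del", 1, "3M2D5M", "ACGACGTA"))
  pu4 <- build_pileup(rd4, ref, min_base_qual = 0L)
  del <- pu4[startsWith(pu4$allele, "-")]
  expect_equal(del$pos, 3L)
  expect_equal(del$allele, "-2")
  expect_equal(pu4[pu4$pos == 4]$depth[1], 11L)
})

test_that("the two-read support rule and the fraction floor gate candidates", {
  ref <- toy_reference()
  mk <- function(n_ref, n_alt) {
    alt_seq <- "ACGTTCGT"  # G>T at position 5... actually A>T at pos 5
    ref_seq <- "ACGTACGT"
    rbind(
      if (n_ref) do.call(rbind, lapply(seq_len(n_ref), function(i)
        toy_read(paste0("R", i), 1, "8M", ref_seq))),
      if (n_alt) do.call(rbind, lapply(seq_len(n_alt), function(i)
        toy_read(paste0("A", i), 1, "8M", alt_seq))))
  }
  cand <- function(reads, ...) {
    find_candidates(build_pileup(reads, ref), ref, ...)
  }
  # two alternate reads out of ten: candidate
  c1 <- cand(mk(8, 2), min_alt_fraction = 0.1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$pos, 5L)
  expect_equal(c1$ref, "A"); expect_equal(c1$alt, "T")
  expect_equal(c1$kind, "SNP")
  # a single alternate read is never enough
  expect_equal(nrow(cand(mk(9, 1), min_alt_fraction = 0.1)), 0L)
  # 2/100 fails a 10% fraction floor
  expect_equal(nrow(cand(mk(98, 2), min_alt_fraction = 0.1)), 0L)
  expect_equal(nrow(cand(mk(98, 2), min_alt_fraction = 0.01)), 1L)
})

test_that("at most two alts are kept, ordered by count then allele", {
  ref <- toy_reference()
  rd <- rbind(
    do.call(rbind, lapply(1:4, function(i) toy_read(paste0("c", i), 1, "4M", "CCGT"))),
    do.call(rbind, lapply(1:3, function(i) toy_read(paste0("g", i), 1, "4M", "GCGT"))),
    do.call(rbind, lapply(1:3, function(i) toy_read(paste0("t", i), 1, "4M", "TCGT"))),
    do.call(rbind, lapply(1:2, function(i) toy_read(paste0("r", i), 1, "4M", "ACGT"))))
  cc <- find_candidates(build_pileup(rd, ref), ref, min_alt_fraction = 0)
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$alt, c("C", "G"))  # 4 then tie 3/3 broken lexicographically
})

test_that("candidates match a brute-force recount on small instances", {
  cfg <- quick_cfg(seed = 17, n_genes = 4, mean_coverage = 12,
                   base_error_rate = 0.01)
  d <- quick_dataset(cfg)
  segs <- suppressMessages(split_skip_reads(filter_reads(d$reads)))
  # restrict to windows holding at most 50 reads
  g1 <- d$genome$genes[1]
  win <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(g1)),
                                IRanges::IRanges(BiocGenerics::start(g1),
                                                 BiocGenerics::end(g1)))
  ends <- segs$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(segs$cigar) - 1L
  keep <- segs$chrom == as.character(GenomeInfoDb::seqnames(g1)) &
    segs$pos <= BiocGenerics::end(g1) & ends >= BiocGenerics::start(g1)
  sub <- segs[keep, ][seq_len(min(50L, sum(keep))), ]
  got <- find_candidates(build_pileup(sub, d$genome$seqs, min_base_qual = 10L),
                         d$genome$seqs, min_alt_count = 2L,
                         min_alt_fraction = 0.1)
  got <- got[got$kind == "SNP", ]
  # independent recount from raw per-base maps
  maps <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    m <- brute_base_map(sub$pos[i], sub$cigar[i], sub$seq[i])
    # qualities re-derived independently per aligned base
    quals <- integer(0); qi <- 1L
    ops <- strsplit(gsub("([0-9]+)([A-Z])", "\\1\\2 ", sub$cigar[i]), " ")[[1]]
    qv <- as.integer(charToRaw(sub$qual[i])) - 33L
    for (tok in ops) {
      len <- as.integer(sub("[A-Z]$", "", tok)); op <- sub("^[0-9]+", "", tok)
      if (op %in% c("M", "=", "X")) { quals <- c(quals, qv[qi:(qi+len-1)]); qi <- qi + len }
      else if (op %in% c("I", "S")) qi <- qi + len
    }
    m$qual <- quals
    m
  }))
  chrom1 <- as.character(GenomeInfoDb::seqnames(g1))
  expected <- list()
  for (p in sort(unique(maps$refpos))) {
    at <- maps[maps$refpos == p, ]
    depth <- nrow(at)
    at <- at[at$qual >= 10L, ]
    rb <- as.character(Biostrings::subseq(d$genome$seqs[[chrom1]], p, p))
    tab <- table(at$base[at$base != rb])
    for (a in names(tab))
      if (tab[[a]] >= 2L && tab[[a]] / depth >= 0.1)
        expected[[length(expected) + 1L]] <- data.frame(pos = p, alt = a,
                                                        count = tab[[a]])
  }
  expected <- if (length(expected)) do.call(rbind, expected) else
    data.frame(pos = integer(), alt = character(), count = integer())
  # brute force keeps every qualifying alt; find_candidates caps at 2/site
  expect_gt(nrow(expected), 0L)
  expect_equal(got$pos, expected$pos)
  expect_equal(got$alt, expected$alt)
  expect_equal(got$alt_count, expected$count)
})

test_that("raising thresholds never adds a candidate", {
  d <- quick_dataset(quick_cfg(seed = 17, n_genes = 4, mean_coverage = 12,
                               base_error_rate = 0.01))
  segs <- suppressMessages(split_skip_reads(filter_reads(d$reads)))
  pu <- build_pileup(segs, d$genome$seqs)
  key <- function(cc) paste(cc$chrom, cc$pos, cc$alt)
  base <- find_candidates(pu, d$genome$seqs, 2L, 0.05)
  for (params in list(list(3L, 0.05), list(4L, 0.05), list(2L, 0.1),
                      list(2L, 0.2), list(3L, 0.2))) {
    tighter <- find_candidates(pu, d$genome$seqs, params[[1]], params[[2]])
    expect_true(all(key(tighter) %in% key(base)))
  }
})

test_that("every adequately supported truth SNP is proposed (noiseless limit)", {
  cfg <- noiseless_cfg(seed = 19, n_genes = 10)
  d <- quick_dataset(cfg)
  segs <- suppressMessages(split_skip_reads(filter_reads(d$reads)))
  pu <- build_pileup(segs, d$genome$seqs)
  cand <- find_candidates(pu, d$genome$seqs)
  tv <- d$truth$variants
  snp <- tv[nchar(tv$ref) == 1 & nchar(tv$alt) == 1, ]
  ckey <- paste(cand$chrom, cand$pos, cand$alt)
  n_checked <- 0L
  for (i in seq_len(nrow(snp))) {
    col <- pu[pu$chrom == snp$chrom[i] & pu$pos == snp$pos[i] &
              pu$allele == snp$alt[i]]
    support <- if (nrow(col)) col$count else 0L
    if (support >= 2L && support / col$depth[1] >= 0.1) {
      n_checked <- n_checked + 1L
      expect_true(paste(snp$chrom[i], snp$pos[i], snp$alt[i]) %in% ckey,
                  label = sprintf("truth SNP %s:%d", snp$chrom[i], snp$pos[i]))
    }
  }
  expect_gt(n_checked, 5L)
})

test_that("scanning a region beyond the contig errors", {
  ref <- toy_reference()
  rd <- toy_read("r", 1, "4M", "ACGT")
  bad <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 10000))
  expect_error(build_pileup(rd, ref, region = bad), "beyond contig")
  bad2 <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10))
  expect_error(build_pileup(rd, ref, region = bad2), "not in reference")
})
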