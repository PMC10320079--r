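# Shared fixtures: small seeded simulations and hand-built alignments.

quick_cfg <- function(seed = 5, n_genes = 12, ...) {
  args <- utils::modifyList(list(n_chroms = 2L, mean_coverage = 25),
                            list(...))
  do.call(sim_config, c(list(seed = seed, n_genes = n_genes), args))
}

noiseless_cfg <- function(seed = 5, n_genes = 12, ...) {
  args <- utils::modifyList(
    list(n_chroms = 2L, mean_coverage = 30, expression_dispersion = 0,
         base_error_rate = 0, quality_sd = 0, duplication_rate = 0,
         editing_site_rate = 0, ase_skew = c(0.5, 0.5)),
    list(...))
  do.call(sim_config, c(list(seed = seed, n_genes = n_genes), args))
}

# A tiny dataset shared across test files (built once per file sourcing).
quick_dataset <- local({
  cache <- new.env()
  function(cfg = quick_cfg()) {
    key <- paste(unlist(cfg), collapse = "|")
    if (is.null(cache[[key]])) {
      g <- make_genome(cfg)
      tr <- spike_truth(g, cfg)
      rd <- simulate_reads(g, tr, cfg)
      cache[[key]] <- list(genome = g, truth = tr, reads = rd, cfg = cfg)
    }
    cache[[key]]
  }
})

# Hand-built single-contig reference and plain (unspliced) reads.
toy_reference <- function(seq = strrep("ACGT", 50), name = "chrT") {
  r <- Biostrings::DNAStringSet(seq)
  names(r) <- name
  r
}

# One alignment row; qual given as integer phred values.
toy_read <- function(qname, pos, cigar, seq, qual = 30L, chrom = "chrT",
                     flag = 0L, mapq = 60L) {
  if (length(qual) == 1L) qual <- rep(qual, nchar(seq))
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = as.integer(pos),
             mapq = mapq, cigar = cigar, seq = seq,
             qual = rawToChar(as.raw(qual + 33L)), stringsAsFactors = FALSE)
}

toy_reads <- function(...) do.call(rbind, list(...))

# Independent per-base alignment map oracle: walks a CIGAR by hand and
# returns data.frame(refpos, base) for aligned (M) bases.
brute_base_map <- function(pos, cigar, seq) {
  ops <- strsplit(gsub("([0-9]+)([A-Z=])", "\\1\\2 ", cigar), " ")[[1]]
  r <- pos; q <- 1L
  out_pos <- integer(0); out_base <- character(0)
  for (tok in ops) {
    len <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^[0-9]+", "", tok)
    if (op %in% c("M", "=", "X")) {
      out_pos <- c(out_pos, r:(r + len - 1L))
      out_base <- c(out_base, strsplit(substring(seq, q, q + len - 1L), "")[[1]])
      r <- r + len; q <- q + len
    } else if (op %in% c("I", "S")) q <- q + len
    else if (op %in% c("D", "N")) r <- r + len
  }
  data.frame(refpos = out_pos, base = out_base, stringsAsFactors = FALSE)
}

# Memoised heavyweight benchmark shared by acceptance blocks.
acceptance_holdout <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- holdout_benchmark(seed = seed)
    cache[[key]]
  }
})
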