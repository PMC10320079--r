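# Genotype-level benchmarking: coverage regions, concordance counting,
# stratified reports, exon-boundary error profiles and threshold curves.

#' Regions attaining a minimum read depth
#'
#' Depth is computed from the supplied (already filtered/split) alignments'
#' reference spans; maximal runs with depth at or above `min_depth` are
#' returned as regions. `min_depth = 0` returns each contig's covered
#' extent in full.
#'
#' @param segments alignment/segment `data.frame`, or a BAM path
#' @param min_depth minimum depth (default 3)
#' @return `GRanges` of qualifying regions
#' @export
coverage_regions <- function(segments, min_depth = 3L) {
  if (is.character(segments)) segments <- read_alignments(segments)
  if (nrow(segments) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(segments$chrom,
    IRanges::IRanges(segments$pos,
                     width = alignment_ref_width(segments$cigar)))
  cov <- GenomicRanges::coverage(gr)
  out <- methods::as(IRanges::slice(cov, lower = min_depth, rangesOnly = TRUE),
                     "GRanges")
  GenomicRanges::reduce(GenomicRanges::sort(out))
}

# Decompose records into per-alt rows with alt copy number from GT.
decompose_records <- function(records) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    alts <- strsplit(records$alt[i], ",")[[1]]
    gta <- if (is.na(records$gt[i])) NA_integer_
           else as.integer(strsplit(records$gt[i], "[/|]")[[1]])
    for (ai in seq_along(alts)) {
      copies <- if (anyNA(gta)) NA_integer_ else sum(gta == ai)
      out[[length(out) + 1L]] <- data.frame(
        chrom = records$chrom[i], pos = records$pos[i], ref = records$ref[i],
        alt = alts[ai], copies = copies,
        gq = records$gq[i], qual = records$qual[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), copies = integer(), gq = numeric(),
                      qual = numeric()))
  do.call(rbind, out)
}

record_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")
}

#' Precision, recall and F1 from match counts
#'
#' Ratios with a zero denominator are reported as `NA` (missing), never 0.
#'
#' @param tp,fp,fn non-negative counts
#' @return one-row `data.frame`: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `fdr`
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
             f1 = f1, fdr = if (is.na(precision)) NA_real_ else 1 - precision)
}

#' Genotype concordance between call and truth VCF records
#'
#' Matching is normalized genotype concordance: a call is a true positive
#' when a truth record shares its chromosome, position, alleles (both in
#' minimal representation) and unordered genotype. A genotype mismatch at
#' matching alleles counts as one false positive and one false negative.
#' Records outside `regions` and homozygous-reference calls are ignored.
#' Multi-allelic records are decomposed per alternate.
#'
#' @param calls,truth variant-record `data.frame`s (truth must carry GT)
#' @param regions optional `GRanges`; records outside are ignored
#' @param kind `"SNP"` or `"INDEL"` (default: both)
#' @return list: `result` (one row, see [precision_recall_f1()]) and
#'   `records` (per-record outcomes TP/FP/FN with positions and scores)
#' @export
compare_calls <- function(calls, truth, regions = NULL,
                          kind = c("SNP", "INDEL")) {
  assert_normalized(calls); assert_normalized(truth)
  if (nrow(truth) && any(is.na(truth$gt)))
    abort("truth records lack genotypes")
  dc <- decompose_records(calls)
  dt_ <- decompose_records(truth)
  dc <- dc[!is.na(dc$copies) & dc$copies > 0L, , drop = FALSE]  # ignore hom-ref
  dt_ <- dt_[dt_$copies > 0L, , drop = FALSE]
  dc$kind <- record_kind(dc$ref, dc$alt)
  dt_$kind <- record_kind(dt_$ref, dt_$alt)
  dc <- dc[dc$kind %in% kind, , drop = FALSE]
  dt_ <- dt_[dt_$kind %in% kind, , drop = FALSE]
  if (!is.null(regions)) {
    if (nrow(dc)) dc <- dc[pos_in_regions(dc$chrom, dc$pos, regions), , drop = FALSE]
    if (nrow(dt_)) dt_ <- dt_[pos_in_regions(dt_$chrom, dt_$pos, regions), , drop = FALSE]
  }
  ckey <- paste(dc$chrom, dc$pos, dc$ref, dc$alt, dc$copies)
  tkey <- paste(dt_$chrom, dt_$pos, dt_$ref, dt_$alt, dt_$copies)
  c_match <- ckey %in% tkey
  t_match <- tkey %in% ckey
  recs <- rbind(
    if (nrow(dc)) data.frame(dc, outcome = ifelse(c_match, "TP", "FP")),
    if (nrow(dt_) && any(!t_match))
      data.frame(dt_[!t_match, , drop = FALSE], outcome = "FN"))
  if (is.null(recs))
    recs <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), copies = integer(), gq = numeric(),
                       qual = numeric(), kind = character(),
                       outcome = character())
  rownames(recs) <- NULL
  list(result = precision_recall_f1(sum(c_match), sum(!c_match), sum(!t_match)),
       records = recs)
}

#' Region- and kind-stratified evaluation report
#'
#' Evaluates calls against truth independently in each named stratum
#' (optionally intersected with a coverage region set) for each variant
#' kind.
#'
#' @param calls,truth variant-record `data.frame`s
#' @param strata named list of `GRanges`
#' @param coverage optional `GRanges` intersected into every stratum
#' @param kinds variant kinds to report
#' @return `data.frame` with one row per stratum x kind
#' @export
stratified_report <- function(calls, truth, strata, coverage = NULL,
                              kinds = c("SNP", "INDEL")) {
  if (is.null(names(strata)) || any(!nzchar(names(strata))))
    abort("strata must be a named list of GRanges")
  rows <- list()
  for (s in names(strata)) {
    reg <- strata[[s]]
    if (is.null(reg)) abort("unknown stratum: %s", s)
    if (!is.null(coverage)) reg <- intersect_regions(reg, coverage)
    for (k in kinds) {
      r <- compare_calls(calls, truth, regions = reg, kind = k)$result
      rows[[length(rows) + 1L]] <- data.frame(stratum = s, kind = k, r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed distance from a position to the nearest exon boundary
#'
#' Inside an exon the distance is non-negative: `min(pos - start, end -
#' pos)`, 0 on a terminal base. Outside, it is the negated distance in
#' bases to the nearest exon terminal base. Ties resolve to the smaller
#' absolute distance. Positions on chromosomes absent from the exon set
#' get `NA`.
#'
#' @param chrom,pos vectors of positions (1-based)
#' @param exons `GRanges` exon set (merged internally)
#' @return integer vector of signed distances
#' @export
signed_exon_distance <- function(chrom, pos, exons) {
  exons <- GenomicRanges::reduce(GenomicRanges::granges(exons),
                                 ignore.strand = TRUE)
  n <- length(pos)
  out <- rep(NA_integer_, n)
  if (n == 0L || length(exons) == 0L) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  known <- as.character(GenomeInfoDb::seqnames(q)) %in%
    as.character(GenomeInfoDb::seqnames(exons))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(q, exons, ignore.strand = TRUE))
  inside <- S4Vectors::queryHits(ov)
  ei <- S4Vectors::subjectHits(ov)
  out[inside] <- pmin(pos[inside] - BiocGenerics::start(exons)[ei],
                      BiocGenerics::end(exons)[ei] - pos[inside])
  outside <- which(known & is.na(out))
  if (length(outside)) {
    # distance to the nearest terminal base over both exon ends
    bnd <- c(BiocGenerics::start(exons), BiocGenerics::end(exons))
    bchr <- rep(as.character(GenomeInfoDb::seqnames(exons)), 2L)
    for (i in outside) {
      d <- abs(pos[i] - bnd[bchr == chrom[i]])
      out[i] <- -min(d)
    }
  }
  out
}

#' Average false-call counts by distance to the nearest exon boundary
#'
#' For each sample's FN and FP record sets, counts errors at each signed
#' exon distance in `[-window, window]` and averages the counts across
#' samples. Negative distances are outside exons, positive inside, 0 on a
#' boundary base.
#'
#' @param samples list (one element per sample) of outcome-record
#'   `data.frame`s as returned in `compare_calls()$records`
#' @param exons exon `GRanges`
#' @param window half-width in bp (default 50)
#' @return `data.frame`: `distance`, `fn_mean`, `fp_mean`
#' @export
boundary_profile <- function(samples, exons, window = 50L) {
  stopifnot(length(samples) >= 1L)
  ds <- if (window < 0L) integer(0) else (-window):window
  if (length(ds) == 0L)
    return(data.frame(distance = integer(), fn_mean = numeric(),
                      fp_mean = numeric()))
  acc <- matrix(0, nrow = length(ds), ncol = 2L,
                dimnames = list(NULL, c("fn", "fp")))
  for (s in samples) {
    for (oc in c("FN", "FP")) {
      r <- s[s$outcome == oc, , drop = FALSE]
      if (!nrow(r)) next
      d <- signed_exon_distance(r$chrom, r$pos, exons)
      tab <- table(factor(d[!is.na(d)], levels = ds))
      acc[, tolower(oc)] <- acc[, tolower(oc)] + as.integer(tab)
    }
  }
  data.frame(distance = ds, fn_mean = acc[, "fn"] / length(samples),
             fp_mean = acc[, "fp"] / length(samples))
}

#' FDR/TPR curve over integer score cutoffs
#'
#' For each cutoff t in `[0, cap]`, calls with the chosen score at or above
#' t are kept and TP/FP/FN recomputed; FDR = FP/(TP+FP) (missing when no
#' calls survive) and TPR = TP/(TP+FN).
#'
#' @param calls,truth variant-record `data.frame`s
#' @param regions optional `GRanges`
#' @param score `"GQ"` or `"QUAL"`
#' @param kind `"SNP"` or `"INDEL"`
#' @param cap maximum cutoff (default 99)
#' @return `data.frame`: `cutoff`, `tp`, `fp`, `fn`, `fdr`, `tpr`
#' @export
threshold_curve <- function(calls, truth, regions = NULL, score = c("GQ", "QUAL"),
                            kind = "SNP", cap = 99L) {
  score <- match.arg(score)
  cmp <- compare_calls(calls, truth, regions, kind)
  rec <- cmp$records
  s <- if (score == "GQ") rec$gq else rec$qual
  n_truth <- cmp$result$tp + cmp$result$fn
  cutoffs <- 0:cap
  tp <- vapply(cutoffs, function(t)
    sum(rec$outcome == "TP" & !is.na(s) & s >= t), 0L)
  fp <- vapply(cutoffs, function(t)
    sum(rec$outcome == "FP" & !is.na(s) & s >= t), 0L)
  fn <- n_truth - tp
  data.frame(cutoff = cutoffs, tp = tp, fp = fp, fn = fn,
             fdr = ifelse(tp + fp > 0, fp / (tp + fp), NA_real_),
             tpr = if (n_truth > 0) tp / n_truth else rep(0, length(tp)))
}

#' Select the smallest cutoff holding pooled FDR at or under a target
#'
#' Sums TP/FP across samples' curves at each cutoff and returns the
#' smallest cutoff whose pooled FDR is at or below `target_fdr` (default
#' 1.5%). If no cutoff qualifies, the cap is returned with attribute
#' `warning = TRUE`.
#'
#' @param curves one [threshold_curve()] `data.frame` or a list of them
#'   sharing the cutoff grid
#' @param target_fdr FDR target (default 0.015)
#' @return integer cutoff with attribute `warning`
#' @export
select_cutoff <- function(curves, target_fdr = 0.015) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (!length(curves)) abort("no threshold curves supplied")
  grid <- curves[[1]]$cutoff
  for (cv in curves) if (!identical(cv$cutoff, grid))
    abort("curves do not share a cutoff grid")
  tp <- Reduce(`+`, lapply(curves, `[[`, "tp"))
  fp <- Reduce(`+`, lapply(curves, `[[`, "fp"))
  fdr <- ifelse(tp + fp > 0, fp / (tp + fp), NA_real_)
  ok <- which(!is.na(fdr) & fdr <= target_fdr)
  if (length(ok)) structure(grid[min(ok)], warning = FALSE)
  else structure(grid[length(grid)], warning = TRUE)
}
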