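mk_truth <- function(pos, gt = "0/1", chrom = "c1", ref = "A", alt = "G") {
  variant_records(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  gt = rep(gt, length.out = length(pos)))
}
mk_calls <- function(pos, gt = "0/1", gq = 50, qual = 50, chrom = "c1",
                     ref = "A", alt = "G") {
  variant_records(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  gt = rep(gt, length.out = length(pos)),
                  gq = rep(gq, length.out = length(pos)),
                  qual = rep(qual, length.out = length(pos)))
}

test_that("concordance counting: exact matches, extras, misses", {
  truth <- mk_truth(c(10L, 20L, 30L))
  calls <- mk_calls(c(10L, 20L, 55L))
  r <- compare_calls(calls, truth)$result
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 1L, 1L))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$fdr, 1 - r$precision)
})

test_that("a genotype mismatch counts as both FP and FN", {
  truth <- mk_truth(10L, gt = "0/1")
  calls <- mk_calls(10L, gt = "1/1")
  r <- compare_calls(calls, truth)$result
  expect_equal(c(r$tp, r$fp, r$fn), c(0L, 1L, 1L))
})

test_that("empty calls yield FN = truth in regions; hom-ref calls are ignored", {
  truth <- mk_truth(c(10L, 20L))
  r <- compare_calls(mk_calls(integer(0)), truth)$result
  expect_equal(c(r$tp, r$fp, r$fn), c(0L, 0L, 2L))
  homref <- mk_calls(c(10L, 99L), gt = "0/0")
  r2 <- compare_calls(homref, truth)$result
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(0L, 0L, 2L))
})

test_that("records outside the region set are ignored", {
  reg <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 25))
  truth <- mk_truth(c(10L, 30L))
  calls <- mk_calls(c(10L, 30L))
  r <- compare_calls(calls, truth, regions = reg)$result
  expect_equal(c(r$tp, r$fp, r$fn), c(1L, 0L, 0L))
})

test_that("swapping calls and truth exchanges FP and FN with TP fixed", {
  truth <- mk_truth(c(10L, 20L, 30L))
  calls <- mk_calls(c(10L, 20L, 55L))
  a <- compare_calls(calls, truth)$result
  b <- compare_calls(truth, calls)$result
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
})

test_that("precision/recall/F1 formulas and missing-value handling", {
  r <- precision_recall_f1(9077L, 18L, 2145L)
  expect_equal(round(r$precision, 3), 0.998)
  r2 <- precision_recall_f1(86L, 1L, 83L)
  expect_equal(round(r2$precision, 3), 0.989)
  r3 <- precision_recall_f1(0L, 0L, 5L)
  expect_true(is.na(r3$precision))
  expect_equal(r3$recall, 0)
  r4 <- precision_recall_f1(0L, 0L, 0L)
  expect_true(is.na(r4$precision) && is.na(r4$recall) && is.na(r4$f1))
  expect_error(precision_recall_f1(-1L, 0L, 0L), "non-negative")
})

test_that("coverage regions are maximal runs at or above the depth floor", {
  rd <- toy_reads(toy_read("a", 1, "3M", "ACG"),
                  toy_read("b", 1, "4M", "ACGT"),
                  toy_read("c", 2, "3M", "CGT"))
  # depths at pos 1..4 are 2,3,3,2
  cov3 <- coverage_regions(rd, 3L)
  expect_equal(BiocGenerics::start(cov3), 2L)
  expect_equal(BiocGenerics::end(cov3), 3L)
  expect_length(coverage_regions(rd[0, ], 1L), 0L)
  cov0 <- coverage_regions(rd, 0L)
  expect_equal(BiocGenerics::width(cov0), 4L)
})

test_that("signed exon distances follow the boundary convention", {
  exons <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))
  # terminal base, outside by 3, inside by 20
  expect_equal(signed_exon_distance("c1", 101L, exons), 0L)
  expect_equal(signed_exon_distance("c1", 98L, exons), -3L)
  expect_equal(signed_exon_distance("c1", 121L, exons), 20L)
  expect_equal(signed_exon_distance("c1", 200L, exons), 0L)
  expect_true(is.na(signed_exon_distance("c9", 5L, exons)))
  # between two exons, ties resolve to the smaller distance
  two <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 21), c(10, 30)))
  expect_equal(signed_exon_distance("c1", 13L, two), -3L)
  expect_equal(signed_exon_distance("c1", 19L, two), -2L)
})

test_that("boundary profiles average error counts across samples", {
  exons <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))
  s1 <- data.frame(chrom = "c1", pos = c(101L, 106L, 106L), ref = "A",
                   alt = "G", copies = 1L, gq = NA, qual = NA, kind = "SNP",
                   outcome = c("FP", "FP", "FP"))
  s2 <- data.frame(chrom = "c1", pos = 95L, ref = "A", alt = "G",
                   copies = 1L, gq = NA, qual = NA, kind = "SNP",
                   outcome = "FN")
  bp <- boundary_profile(list(s1, s2), exons, window = 10L)
  expect_equal(bp$fp_mean[bp$distance == 0], 0.5)   # 1 FP in one of two samples
  expect_equal(bp$fp_mean[bp$distance == 5], 1.0)   # 2 and 0 across samples
  expect_equal(bp$fn_mean[bp$distance == -6], 0.5)
  expect_equal(sum(bp$fn_mean) + sum(bp$fp_mean), 2.0)
  empty <- boundary_profile(list(s1), exons, window = -1L)
  expect_equal(nrow(empty), 0L)
})

test_that("threshold curves recompute counts per cutoff", {
  truth <- mk_truth(c(10L, 20L))
  calls <- mk_calls(c(10L, 55L), gq = c(30, 5))
  cv <- threshold_curve(calls, truth, score = "GQ", kind = "SNP")
  at18 <- cv[cv$cutoff == 18L, ]
  expect_equal(at18$fdr, 0)
  expect_equal(at18$tpr, 0.5)
  at0 <- cv[cv$cutoff == 0L, ]
  plain <- compare_calls(calls, truth, kind = "SNP")$result
  expect_equal(c(at0$tp, at0$fp, at0$fn), c(plain$tp, plain$fp, plain$fn))
  beyond <- cv[cv$cutoff == 99L, ]
  expect_true(is.na(beyond$fdr))
  expect_equal(beyond$tpr, 0)
  expect_true(all(diff(cv$tp) <= 0) && all(diff(cv$fp) <= 0))
})

test_that("cutoff selection hits the smallest cutoff meeting the FDR target", {
  # pooled FDR first drops to the 1.5% target exactly at cutoff 18
  truth <- mk_truth(seq(10L, 10L + 190L * 5L, by = 5L))       # 191 variants
  tp_gq <- rep(60, 181)
  calls <- mk_calls(c(seq(10L, 10L + 180L * 5L, by = 5L), 1001L, 1002L, 1003L, 1004L),
                    gq = c(tp_gq, 17, 17, 17, 99))
  cv <- threshold_curve(calls, truth, score = "GQ", kind = "SNP")
  expect_gt(cv$fdr[cv$cutoff == 17L], 0.015)
  expect_lte(cv$fdr[cv$cutoff == 18L], 0.015)
  got <- select_cutoff(cv, target_fdr = 0.015)
  expect_equal(as.integer(got), 18L)
  expect_false(attr(got, "warning"))
  # all-TP calls select cutoff 0
  clean <- mk_calls(c(10L, 15L), gq = c(5, 40))
  cv2 <- threshold_curve(clean, mk_truth(c(10L, 15L)), score = "GQ")
  expect_equal(as.integer(select_cutoff(cv2)), 0L)
  # never below target: cap with warning flag
  bad <- mk_calls(1001L, gq = 50)
  cv3 <- threshold_curve(bad, mk_truth(10L), score = "GQ")
  got3 <- select_cutoff(cv3, target_fdr = 0.015)
  expect_equal(as.integer(got3), 99L)
  expect_true(attr(got3, "warning"))
  expect_error(select_cutoff(list()), "no threshold curves")
})

test_that("stratified reports respect containment and coverage intersection", {
  truth <- mk_truth(c(10L, 20L, 120L))
  calls <- mk_calls(c(10L, 120L, 300L))
  whole <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1000))
  cds <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 50))
  exon <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 150))
  rep_ <- stratified_report(calls, truth,
                            strata = list(genome = whole, cds = cds,
                                          exon = exon),
                            kinds = "SNP")
  direct <- compare_calls(calls, truth, regions = whole, kind = "SNP")$result
  expect_equal(rep_[rep_$stratum == "genome", c("tp", "fp", "fn")],
               direct[c("tp", "fp", "fn")], ignore_attr = TRUE)
  truth_in <- function(s) rep_[rep_$stratum == s, "tp"] + rep_[rep_$stratum == s, "fn"]
  expect_lte(truth_in("cds"), truth_in("exon"))   # CDS nested in exon
  # conservation: TP + FN equals truth inside each stratum
  expect_equal(truth_in("exon"), 3L)
  expect_equal(truth_in("cds"), 2L)
  expect_error(stratified_report(calls, truth, strata = list(whole)),
               "named")
})

test_that("chromosome-holdout strata exclude other chromosomes", {
  truth <- rbind(mk_truth(10L, chrom = "c1"), mk_truth(10L, chrom = "c2"))
  class(truth) <- c("rnavc_variants", "data.frame")
  calls <- mk_calls(10L, chrom = "c2")
  hold <- GenomicRanges::GRanges("c2", IRanges::IRanges(1, 1000))
  r <- compare_calls(calls, truth, regions = hold)$result
  expect_equal(c(r$tp, r$fp, r$fn), c(1L, 0L, 0L))
})
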