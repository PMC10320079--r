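# Standard desk-scale benchmark runs shared by the test suite and the
# acceptance script.

#' Held-out chromosome training benchmark
#'
#' Simulates a 4-chromosome genome, trains the logistic backend on
#' chromosomes 1-2 with chromosome 3 as the tune split, calls variants
#' with both the trained model and the Bayes baseline, and evaluates SNP
#' concordance on the held-out chromosome 4 restricted to CDS regions with
#' at least 3x coverage. Also reports false-positive counts at A-to-I
#' editing sites on the held-out chromosome for both backends, and the
#' GQ cutoff attaining a 1.5% target FDR on the tune chromosome.
#'
#' @param seed integer driving simulation and training
#' @param n_genes genome size (default 200)
#' @param mean_coverage,base_error_rate study conditions
#' @param target_fdr FDR target for the cutoff sweep
#' @return list: `logistic` / `bayes` (one-row SNP EvalResult each),
#'   `fp_editing_logistic`, `fp_editing_bayes`, `selected_gq_cutoff`,
#'   `n_truth_snps`, `model`, plus the simulated objects
#' @export
holdout_benchmark <- function(seed, n_genes = 200L, mean_coverage = 30,
                              base_error_rate = 0.005, target_fdr = 0.015) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, n_chroms = 4L,
                    mean_coverage = mean_coverage,
                    base_error_rate = base_error_rate)
  genome <- make_genome(cfg)
  truth <- spike_truth(genome, cfg)
  reads <- simulate_reads(genome, truth, cfg)
  ref <- genome$seqs
  segs <- suppressMessages(split_skip_reads(filter_reads(reads)))
  pu <- build_pileup(segs, ref)
  cand <- find_candidates(pu, ref)
  ex <- encode_examples(cand, segs, ref, keep_tensor = FALSE)
  lab <- make_labeled_examples(ex, truth$variants, truth$confident)
  split <- list(train = c("sim1", "sim2"), tune = "sim3")
  model <- train_genotyper(lab, "logistic", split = split, seed = seed)
  bayes <- train_genotyper(NULL, "bayes-baseline",
                           mean_base_error = base_error_rate)
  calls_log <- call_pipeline(reads, ref, model)
  calls_bay <- call_pipeline(reads, ref, bayes)
  chrom_region <- function(ch) GenomicRanges::GRanges(
    ch, IRanges::IRanges(1L, Biostrings::width(ref)[match(ch, names(ref))]))
  holdout <- chrom_region("sim4")
  stopifnot(!"sim4" %in% c(model$split$train, model$split$tune))  # no leakage
  cov3 <- coverage_regions(segs, 3L)
  cds_cov <- intersect_regions(genome$cds, cov3)
  hold_reg <- intersect_regions(cds_cov, holdout)
  r_log <- compare_calls(calls_log, truth$variants, hold_reg, kind = "SNP")
  r_bay <- compare_calls(calls_bay, truth$variants, hold_reg, kind = "SNP")
  ekey <- paste(truth$editing$chrom, truth$editing$pos)
  fp_edit <- function(cmp) {
    r <- cmp$records
    sum(r$outcome == "FP" & paste(r$chrom, r$pos) %in% ekey)
  }
  e_log <- compare_calls(calls_log, truth$variants, holdout, kind = "SNP")
  e_bay <- compare_calls(calls_bay, truth$variants, holdout, kind = "SNP")
  tune_reg <- intersect_regions(cds_cov, chrom_region("sim3"))
  cv <- threshold_curve(calls_log, truth$variants, tune_reg,
                        score = "GQ", kind = "SNP")
  cut <- select_cutoff(cv, target_fdr)
  list(logistic = r_log$result, bayes = r_bay$result,
       fp_editing_logistic = fp_edit(e_log), fp_editing_bayes = fp_edit(e_bay),
       selected_gq_cutoff = as.integer(cut),
       cutoff_warning = isTRUE(attr(cut, "warning")),
       n_truth_snps = r_log$result$tp + r_log$result$fn,
       model = model, genome = genome, truth = truth, calls = calls_log)
}

#' Noiseless-limit end-to-end benchmark
#'
#' Simulates an error-free, dispersion-free, duplicate-free dataset at 30x
#' and calls variants with the Bayes baseline; reports the fraction of
#' covered (>= 3 reads) exonic truth SNPs recovered with the exact
#' genotype, and the fraction of adequately supported truth SNPs proposed
#' as candidates.
#'
#' @param seed integer seed
#' @param n_genes genome size (default 30)
#' @return list: `gt_accuracy`, `candidate_completeness`, `n_sites`
#' @export
noiseless_benchmark <- function(seed, n_genes = 30L) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, n_chroms = 2L,
                    mean_coverage = 30, expression_dispersion = 0,
                    base_error_rate = 0, quality_sd = 0,
                    duplication_rate = 0, editing_site_rate = 0,
                    ase_skew = c(0.5, 0.5))
  genome <- make_genome(cfg)
  truth <- spike_truth(genome, cfg)
  reads <- simulate_reads(genome, truth, cfg)
  ref <- genome$seqs
  segs <- suppressMessages(split_skip_reads(filter_reads(reads)))
  pu <- build_pileup(segs, ref)
  cand <- find_candidates(pu, ref)
  bayes <- train_genotyper(NULL, "bayes-baseline", mean_base_error = 1e-3)
  calls <- call_pipeline(reads, ref, bayes)
  tv <- truth$variants
  snp <- tv[nchar(tv$ref) == 1L & nchar(tv$alt) == 1L, , drop = FALSE]
  ckey_cand <- paste(cand$chrom, cand$pos, cand$alt)
  ckey_call <- paste(calls$chrom, calls$pos, calls$alt, calls$gt)
  supported <- called <- logical(nrow(snp))
  n_eval <- 0L
  for (i in seq_len(nrow(snp))) {
    col <- pu[pu$chrom == snp$chrom[i] & pu$pos == snp$pos[i] &
              pu$allele == snp$alt[i]]
    dp_ok <- nrow(col) > 0 && col$depth[1] >= 3L && col$count >= 2L &&
      col$count / col$depth[1] >= 0.1
    if (!dp_ok) next
    n_eval <- n_eval + 1L
    supported[i] <- paste(snp$chrom[i], snp$pos[i], snp$alt[i]) %in% ckey_cand
    called[i] <- paste(snp$chrom[i], snp$pos[i], snp$alt[i], snp$gt[i]) %in%
      ckey_call
  }
  list(gt_accuracy = sum(called) / n_eval,
       candidate_completeness = sum(supported) / n_eval,
       n_sites = n_eval)
}
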