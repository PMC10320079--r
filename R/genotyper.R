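# Three-class genotype classification: model training, class probabilities,
# and conversion to genotype calls with GQ/QUAL.

GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Closed-form diploid genotype probabilities from allele counts
#'
#' The Bayesian baseline: with per-base error rate `e` and `n = ref_count +
#' alt_count`, the alternate count is Binomial(n, e) under hom-ref,
#' Binomial(n, 0.5) under het and Binomial(n, 1 - e) under hom-alt; a flat
#' prior over the three classes gives normalized posteriors. Zero depth
#' returns the uniform distribution. Serves both as a trainable-free
#' backend and as the reference oracle for classifier checks.
#'
#' @param ref_count,alt_count non-negative read counts (vectorized)
#' @param mean_base_error per-read base error rate
#' @return matrix with columns `p0`, `p1`, `p2` summing to 1 per row
#' @export
bayes_baseline_probs <- function(ref_count, alt_count, mean_base_error = 0.005) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0))
  n <- ref_count + alt_count
  e <- min(max(mean_base_error, 1e-6), 0.5)
  ll <- cbind(dbinom(alt_count, n, e, log = TRUE),
              dbinom(alt_count, n, 0.5, log = TRUE),
              dbinom(alt_count, n, 1 - e, log = TRUE))
  ll <- ll - apply(ll, 1L, max)
  p <- exp(ll)
  p <- p / rowSums(p)
  p[n == 0L, ] <- 1 / 3
  colnames(p) <- c("p0", "p1", "p2")
  p
}

#' Train a genotype classifier on labeled examples
#'
#' Backend `"logistic"` fits a multinomial logistic model (via
#' `nnet::multinom`) on the pooled per-example features; the fitted
#' coefficients are extracted so the model is a plain parameter list.
#' Backend `"bayes-baseline"` has no trainable parameters. When a
#' chromosome `split` is supplied, only examples on `split$train` are fit;
#' `split$tune` is used solely to pick the ridge penalty (`decay`) from a
#' small grid, and the split is recorded in the model so downstream
#' evaluation can refuse leakage. Deterministic given `seed`.
#'
#' @param examples labeled `rnavc_examples` (see [make_labeled_examples()])
#' @param backend `"logistic"` or `"bayes-baseline"`
#' @param split optional `list(train = chroms, tune = chroms)`
#' @param seed integer seed
#' @param decay_grid ridge penalties tried when a tune split is present
#'   (always > 0: rare base-change indicators otherwise quasi-separate)
#' @param mean_base_error error rate for the bayes backend
#' @return model list of class `rnavc_model`
#' @export
train_genotyper <- function(examples, backend = c("logistic", "bayes-baseline"),
                            split = NULL, seed = 1L,
                            decay_grid = c(0.01, 0.1, 1),
                            mean_base_error = 0.005) {
  backend <- match.arg(backend)
  m <- examples$meta
  if (backend == "bayes-baseline")
    return(structure(list(backend = backend, mean_base_error = mean_base_error,
                          split = split, seed = seed,
                          feature_names = NULL, coef = NULL),
                     class = "rnavc_model"))
  if (any(is.na(m$label))) abort("examples must be labeled before training")
  tr <- if (is.null(split)) rep(TRUE, nrow(m)) else m$chrom %in% split$train
  tu <- if (is.null(split) || is.null(split$tune)) rep(FALSE, nrow(m))
        else m$chrom %in% split$tune
  counts <- table(factor(m$label[tr], levels = 0:2))
  if (any(counts == 0L))
    abort("training split lacks class(es) %s (counts: %s)",
          paste(names(counts)[counts == 0L], collapse = ","),
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  X <- examples$features[tr, , drop = FALSE]
  y <- factor(m$label[tr], levels = 0:2)
  fit_one <- function(decay) {
    dat <- data.frame(y = y, X, check.names = FALSE)
    with_seed(seed, nnet::multinom(y ~ ., data = dat, decay = decay,
                                   maxit = 400, trace = FALSE))
  }
  if (any(tu) && length(decay_grid) > 1L) {
    acc <- vapply(decay_grid, function(d) {
      f <- fit_one(d)
      pred <- predict(f, newdata = data.frame(examples$features[tu, , drop = FALSE],
                                              check.names = FALSE))
      mean(as.integer(as.character(pred)) == m$label[tu])
    }, 0)
    decay <- decay_grid[which.max(acc)]
  } else decay <- decay_grid[1]
  fit <- fit_one(decay)
  cf <- coef(fit)  # rows: classes "1","2"; cols: (Intercept) + features
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L, dimnames = list("1", names(cf)))
  structure(list(backend = backend, coef = cf,
                 feature_names = colnames(examples$features),
                 split = split, seed = seed, decay = decay,
                 class_counts = as.integer(counts)),
            class = "rnavc_model")
}

#' Class probabilities for encoded examples
#'
#' @param model an `rnavc_model`
#' @param examples an `rnavc_examples` object
#' @return matrix with columns `p0`, `p1`, `p2` (one row per example)
#' @export
classify_examples <- function(model, examples) {
  m <- examples$meta
  if (model$backend == "bayes-baseline")
    return(bayes_baseline_probs(m$ref_count, m$alt_count_col,
                                model$mean_base_error))
  X <- examples$features
  if (!identical(colnames(X), model$feature_names))
    abort("example feature set does not match the model's feature spec")
  eta <- cbind(0, X %*% t(model$coef[, -1L, drop = FALSE]) +
                 matrix(model$coef[, 1L], nrow(X), nrow(model$coef),
                        byrow = TRUE))
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta); p <- p / rowSums(p)
  colnames(p) <- c("p0", "p1", "p2")
  p
}

#' Convert class probabilities into genotype calls
#'
#' The called class is the probability argmax (ties resolved to the lowest
#' class index, i.e. toward the reference). GQ is the phred-scaled
#' probability that the call is wrong, `min(cap, -10 log10(1 - p_called))`,
#' rounded to the nearest integer; QUAL is the phred-scaled probability
#' that the site is not a variant, `min(cap, -10 log10(p0))`, rounded to
#' one decimal.
#'
#' @param probs matrix from [classify_examples()]
#' @param meta candidate metadata (`chrom`, `pos`, `ref`, `alt`, `kind`,
#'   `depth`, `ref_count`, `alt_count_col`)
#' @param gq_cap cap for both scores (default 99)
#' @return variant-record `data.frame` with `gt`, `gq`, `qual`, `dp`, `ad`
#'   plus `p0`,`p1`,`p2`, `called_class` and `kind`
#' @export
call_genotype <- function(probs, meta, gq_cap = 99) {
  called <- max.col(probs, ties.method = "first") - 1L
  p_called <- probs[cbind(seq_len(nrow(probs)), called + 1L)]
  gq <- as.integer(round(phred(1 - p_called, gq_cap)))
  qual <- round(phred(probs[, "p0"], gq_cap), 1)
  out <- variant_records(chrom = meta$chrom, pos = meta$pos, ref = meta$ref,
                         alt = meta$alt, gt = GT_STRINGS[called + 1L],
                         qual = qual, gq = gq, dp = meta$depth,
                         ad = paste(meta$ref_count, meta$alt_count_col, sep = ","))
  out$p0 <- probs[, "p0"]; out$p1 <- probs[, "p1"]; out$p2 <- probs[, "p2"]
  out$called_class <- called
  out$kind <- ifelse(nchar(meta$ref) == 1L & nchar(meta$alt) == 1L,
                     "SNP", "INDEL")
  out
}

# Merge per-alt calls at one (chrom, pos, ref) into a single record with
# the highest-QUAL alt first.
merge_multiallelic <- function(calls) {
  if (nrow(calls) < 2L) return(calls)
  key <- paste(calls$chrom, calls$pos, calls$ref)
  if (!anyDuplicated(key)) return(calls)
  parts <- lapply(split(seq_len(nrow(calls)), key), function(ii) {
    if (length(ii) == 1L) return(calls[ii, , drop = FALSE])
    cc <- calls[ii[order(-calls$qual[ii], calls$alt[ii])], , drop = FALSE]
    rec <- cc[1L, , drop = FALSE]
    nonref <- cc[cc$called_class > 0L, , drop = FALSE]
    if (nrow(nonref) >= 2L) {
      rec <- nonref[1L, , drop = FALSE]
      rec$alt <- paste(nonref$alt, collapse = ",")
      rec$gt <- if (nonref$called_class[1L] == 2L) "1/1" else "1/2"
      rec$ad <- paste(c(strsplit(rec$ad, ",")[[1]][1],
                        vapply(strsplit(nonref$ad, ","), `[`, "", 2L)),
                      collapse = ",")
    }
    rec
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full calling pipeline on aligned reads
#'
#' filter -> split at SKIP operations -> pileup -> candidates -> encode ->
#' classify -> genotype calls. Homozygous-reference calls are suppressed
#' unless `emit_ref_calls`. Multi-allelic per-alt calls at one site are
#' merged with the highest-QUAL alternate first.
#'
#' @param reads alignment `data.frame` or a BAM path
#' @param reference `DNAStringSet` or FASTA path
#' @param model an `rnavc_model`
#' @param min_mapq,min_segment_len,min_base_qual,min_alt_count,min_alt_fraction
#'   stage parameters (see the stage functions)
#' @param encoder an [encoder_config()]
#' @param emit_ref_calls keep hom-ref records
#' @param region optional `GRanges` restriction
#' @return variant-record `data.frame` of calls
#' @export
call_pipeline <- function(reads, reference, model,
                          min_mapq = 1L, min_segment_len = 15L,
                          min_base_qual = 10L, min_alt_count = 2L,
                          min_alt_fraction = 0.1,
                          encoder = encoder_config(),
                          emit_ref_calls = FALSE, region = NULL) {
  if (is.character(reads)) reads <- read_alignments(reads)
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  if (nrow(reads)) {
    bad <- setdiff(unique(reads$chrom), names(reference))
    if (length(bad))
      abort("contig %s present in alignments but missing from reference", bad[1])
  }
  segs <- split_skip_reads(filter_reads(reads, min_mapq), min_segment_len)
  pu <- build_pileup(segs, reference, region, min_base_qual)
  cand <- find_candidates(pu, reference, min_alt_count, min_alt_fraction)
  if (nrow(cand) == 0L) return(call_genotype(bayes_baseline_probs(integer(0),
                                                                  integer(0)),
                                             cand[0, ]))
  ex <- encode_examples(cand, segs, reference, encoder,
                        keep_tensor = FALSE)
  probs <- classify_examples(model, ex)
  calls <- call_genotype(probs, ex$meta)
  calls <- merge_multiallelic(calls)
  if (!emit_ref_calls) calls <- calls[calls$gt != "0/0", , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Serialize a model to JSON / restore it
#'
#' @param model an `rnavc_model`
#' @param path JSON path
#' @return `path` invisibly for save; the model for load
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$coef <- if (!is.null(model$coef))
    list(values = as.vector(model$coef), nrow = nrow(model$coef),
         colnames = colnames(model$coef), rownames = rownames(model$coef))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$coef) && length(obj$coef)) {
    obj$coef <- matrix(obj$coef$values, nrow = obj$coef$nrow,
                       dimnames = list(obj$coef$rownames, obj$coef$colnames))
  } else obj$coef <- NULL
  structure(obj, class = "rnavc_model")
}
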