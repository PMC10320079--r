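# Fixed-shape multi-channel pileup encoding of candidate sites.

BASE_LEVELS <- c(A = 0.25, C = 0.50, G = 0.75, T = 1.00)

#' Encoder configuration
#'
#' Geometry and value conventions of the pileup example tensor. Width must
#' be odd so the candidate column sits exactly at `(width + 1) / 2`; height
#' counts the reference row plus up to `height - 1` read rows (excess reads
#' are downsampled uniformly under `seed`).
#'
#' @param width window width in columns (odd, default 221)
#' @param height max rows including the reference row (default 101)
#' @param base_qual_cap base qualities are clipped to this before scaling
#' @param mapq_cap mapping qualities are clipped to this before scaling
#' @param min_base_qual per-base quality floor for allele-count features
#' @param seed downsampling seed
#' @return list of class `rnavc_encoder_config`
#' @export
encoder_config <- function(width = 221L, height = 101L, base_qual_cap = 40L,
                           mapq_cap = 60L, min_base_qual = 10L, seed = 0L) {
  if (width %% 2L == 0L) abort("width must be odd")
  if (height < 2L) abort("height must be >= 2")
  structure(list(width = as.integer(width), height = as.integer(height),
                 base_qual_cap = base_qual_cap, mapq_cap = mapq_cap,
                 min_base_qual = as.integer(min_base_qual),
                 seed = as.integer(seed),
                 channels = c("base", "base_qual", "mapq", "strand",
                              "supports_alt", "differs_ref")),
            class = "rnavc_encoder_config")
}

example_feature_names <- function() {
  b <- names(BASE_LEVELS)
  g <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  c("depth_log", "alt_frac", "alt_frac_dev", "alt_count_log",
    "ll_het_ref", "ll_hom_het",
    "mean_alt_qual", "mean_ref_qual", "mean_mapq", "alt_fwd_frac",
    sort(paste0("chg_", g$ref, g$alt)), "chg_INS", "chg_DEL",
    "edit_signature", "edit_sig_x_frac", "edit_sig_x_dev")
}

# Allele string as tallied in the pileup for a candidate row.
candidate_allele <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, alt,
  ifelse(nchar(alt) > nchar(ref), paste0("+", substring(alt, 2L)),
         paste0("-", nchar(ref) - nchar(alt))))
}

#' Encode candidate sites as multi-channel pileup examples
#'
#' Every candidate becomes one example: a pooled feature vector always, and
#' optionally the full tensor of shape `height x width x 6` with channels
#' (1) base identity (A/C/G/T as 0.25/0.50/0.75/1.00, gap/other 0),
#' (2) base quality `min(q, cap)/cap`, (3) mapping quality, (4) strand
#' (forward 1.0, reverse 0.5, pad 0), (5) supports-alt (1.0 if the read
#' carries the scored alternate at the candidate column, else 0.5, pad 0),
#' (6) differs-from-reference. Row 1 is the reference track; reads are
#' sorted by (start, name) and downsampled uniformly to `height - 1` rows
#' under the configured seed. A candidate with no overlapping segment
#' yields an all-pad example below the reference row.
#'
#' @param candidates from [find_candidates()]
#' @param segments N-free segment `data.frame`
#' @param reference `DNAStringSet`
#' @param config an [encoder_config()]
#' @param keep_tensor build and keep full tensors (features are always kept;
#'   drop tensors when only summary-feature backends will consume the
#'   examples)
#' @return list of class `rnavc_examples`: `meta` (one row per example,
#'   including `ref_count`/`alt_count` at the candidate column and
#'   `label = NA`), `features` (matrix), `tensors` (list of arrays or
#'   `NULL`), `config`
#' @export
encode_examples <- function(candidates, segments, reference,
                            config = encoder_config(), keep_tensor = TRUE) {
  ev <- segment_events(segments)
  if (nrow(ev)) setkey(ev, chrom, pos)
  hw <- (config$width - 1L) %/% 2L
  nc <- nrow(candidates)
  fnames <- example_feature_names()
  feats <- matrix(0, nrow = nc, ncol = length(fnames),
                  dimnames = list(NULL, fnames))
  tensors <- if (keep_tensor) vector("list", nc) else NULL
  ref_count <- alt_count <- integer(nc)
  seg_start <- segments$pos
  for (i in seq_len(nc)) {
    cd <- candidates[i, ]
    lo <- cd$pos - hw; hi <- cd$pos + hw
    w <- if (nrow(ev))
      ev[data.table(chrom = cd$chrom, pos = lo:hi), nomatch = NULL,
         on = c("chrom", "pos")] else ev
    allele <- candidate_allele(cd$ref, cd$alt)
    atc <- w[pos == cd$pos]
    alt_reads <- unique(atc[base == allele &
                            (kind != "base" | qual >= config$min_base_qual),
                            read_id])
    ref_reads <- unique(atc[kind == "base" & base == cd$ref &
                            qual >= config$min_base_qual, read_id])
    ref_count[i] <- length(ref_reads); alt_count[i] <- length(alt_reads)
    dp <- if (nrow(atc)) length(unique(atc[kind %in% c("base", "delspan"),
                                           read_id])) else 0L
    alt_bq <- atc[read_id %in% alt_reads & kind == "base", qual]
    ref_bq <- atc[read_id %in% ref_reads & kind == "base", qual]
    rids <- unique(w[kind %in% c("base", "delspan"), read_id])
    mq <- if (length(rids)) mean(pmin(segments$mapq[rids], config$mapq_cap)) else 0
    alt_fwd <- atc[read_id %in% alt_reads & kind != "delspan",
                   mean(fwd[!duplicated(read_id)])]
    chg <- if (cd$kind == "SNP") paste0("chg_", cd$ref, cd$alt)
           else paste0("chg_", cd$kind)
    feats[i, "depth_log"] <- log1p(cd$depth)
    af <- if (cd$depth > 0) cd$alt_count / cd$depth else 0
    feats[i, "alt_frac"] <- af
    feats[i, "alt_frac_dev"] <- abs(af - 0.5)
    feats[i, "alt_count_log"] <- log1p(cd$alt_count)
    # genotype log-likelihood ratios: hom classes use a nominal base error;
    # the het class integrates the binomial over allele-specific expression
    # skews (alt fraction 0.25-0.75), the RNA-aware het model. Clipped and
    # scaled so the logistic backend sees a tame, near-linear feature.
    e0 <- 0.005
    n_rc <- ref_count[i] + alt_count[i]
    s_grid <- seq(0.25, 0.75, by = 0.025)
    ll_ref <- dbinom(alt_count[i], n_rc, e0, log = TRUE)
    ll_hom <- dbinom(alt_count[i], n_rc, 1 - e0, log = TRUE)
    ll_het <- log(mean(dbinom(alt_count[i], n_rc, s_grid)))
    feats[i, "ll_het_ref"] <- max(-10, min(10, (ll_het - ll_ref) / 10))
    feats[i, "ll_hom_het"] <- max(-10, min(10, (ll_hom - ll_het) / 10))
    feats[i, "mean_alt_qual"] <- if (length(alt_bq))
      mean(pmin(alt_bq, config$base_qual_cap)) / config$base_qual_cap else 0.5
    feats[i, "mean_ref_qual"] <- if (length(ref_bq))
      mean(pmin(ref_bq, config$base_qual_cap)) / config$base_qual_cap else 0.5
    feats[i, "mean_mapq"] <- mq / config$mapq_cap
    feats[i, "alt_fwd_frac"] <- if (length(alt_fwd) && !is.na(alt_fwd))
      alt_fwd else 0.5
    if (chg %in% fnames) feats[i, chg] <- 1
    # A-to-I editing signature: apparent A>G with a non-G 5' reference
    # neighbor, or its minus-strand mirror T>C with a non-C 3' neighbor
    # (the ADAR motif); interactions let suppression depend on allele
    # fraction, which separates editing fractions from ASE-skewed hets
    if (cd$kind == "SNP") {
      chromlen <- Biostrings::width(reference)[match(cd$chrom, names(reference))]
      nb <- function(at) if (at >= 1L && at <= chromlen)
        as.character(Biostrings::extractAt(reference[[cd$chrom]],
                                           IRanges::IRanges(at, at))) else ""
      sig <- (cd$ref == "A" && cd$alt == "G" && nb(cd$pos - 1L) != "G") ||
             (cd$ref == "T" && cd$alt == "C" && nb(cd$pos + 1L) != "C")
      if (sig) {
        feats[i, "edit_signature"] <- 1
        feats[i, "edit_sig_x_frac"] <- af
        feats[i, "edit_sig_x_dev"] <- abs(af - 0.5)
      }
    }
    if (keep_tensor)
      tensors[[i]] <- build_tensor(cd, allele, w, reference, config, alt_reads)
  }
  meta <- data.frame(candidates, ref_count = ref_count,
                     alt_count_col = alt_count, label = NA_integer_,
                     stringsAsFactors = FALSE)
  structure(list(meta = meta, features = feats, tensors = tensors,
                 config = config),
            class = "rnavc_examples")
}

# One example tensor: height x width x 6, values in [0, 1].
build_tensor <- function(cd, allele, w, reference, config, alt_reads) {
  H <- config$height; W <- config$width
  hw <- (W - 1L) %/% 2L
  lo <- cd$pos - hw
  tens <- array(0, dim = c(H, W, 6L))
  # reference row
  chromlen <- Biostrings::width(reference)[match(cd$chrom, names(reference))]
  cols <- pmax(1L, lo):pmin(chromlen, cd$pos + hw)
  refb <- strsplit(as.character(Biostrings::subseq(
    reference[[cd$chrom]], cols[1], cols[length(cols)])), "")[[1]]
  ridx <- cols - lo + 1L
  tens[1L, ridx, 1L] <- unname(BASE_LEVELS[refb])
  tens[1L, ridx, 2L] <- 1; tens[1L, ridx, 3L] <- 1; tens[1L, ridx, 4L] <- 1
  tens[1L, ridx, 5L] <- 0.5
  wb <- w[kind == "base"]
  if (nrow(wb) == 0L) return(tens)
  ord <- unique(wb[order(start, qname), read_id])
  if (length(ord) > H - 1L)
    ord <- with_seed(derive_seed(config$seed,
                                 sprintf("ds:%s:%d:%s", cd$chrom, cd$pos, allele)),
                     sort(sample(ord, H - 1L)))
  rowmap <- setNames(seq_along(ord) + 1L, ord)
  wb <- wb[read_id %in% ord]
  rr <- rowmap[as.character(wb$read_id)]
  cc <- wb$pos - lo + 1L
  refcol <- rep(NA_character_, W); refcol[ridx] <- refb
  idx <- cbind(rr, cc)
  tens[cbind(idx, 1L)] <- unname(BASE_LEVELS[wb$base])
  tens[cbind(idx, 2L)] <- pmin(wb$qual, config$base_qual_cap) / config$base_qual_cap
  tens[cbind(idx, 3L)] <- pmin(wb$mapq, config$mapq_cap) / config$mapq_cap
  tens[cbind(idx, 4L)] <- ifelse(wb$fwd, 1, 0.5)
  tens[cbind(idx, 5L)] <- ifelse(wb$read_id %in% alt_reads, 1, 0.5)
  tens[cbind(idx, 6L)] <- as.numeric(wb$base != refcol[cc])
  tens
}

#' Number of examples in an example set
#' @param x an `rnavc_examples` object
#' @return integer count
#' @export
n_examples <- function(x) nrow(x$meta)

#' Subset an example set by index
#' @param x an `rnavc_examples` object
#' @param i integer or logical index
#' @return the subset, an `rnavc_examples` object
#' @export
subset_examples <- function(x, i) {
  structure(list(meta = x$meta[i, , drop = FALSE],
                 features = x$features[i, , drop = FALSE],
                 tensors = if (!is.null(x$tensors)) x$tensors[i] else NULL,
                 config = x$config),
            class = "rnavc_examples")
}

# Error unless every record is in minimal (trimmed, anchored) representation.
assert_normalized <- function(records) {
  if (!nrow(records)) return(invisible(TRUE))
  for (i in seq_len(nrow(records))) {
    ref <- records$ref[i]
    for (alt in strsplit(records$alt[i], ",")[[1]]) {
      if (nchar(ref) > 1L && nchar(alt) > 1L &&
          substring(ref, nchar(ref)) == substring(alt, nchar(alt)))
        abort("un-normalized record at %s:%d (%s>%s): shared trailing base",
              records$chrom[i], records$pos[i], ref, alt)
      if (nchar(ref) > 1L && nchar(alt) > 1L)
        abort("un-normalized record at %s:%d (%s>%s): complex allele",
              records$chrom[i], records$pos[i], ref, alt)
    }
  }
  invisible(TRUE)
}

#' Label encoded examples against a truth set
#'
#' Silver-truth labeling: a candidate matching a truth variant (same
#' chromosome, position and alleles, both in minimal representation) takes
#' the truth genotype's copy number of the scored alternate as its class
#' (0 = hom-ref, 1 = het, 2 = hom-alt); a candidate inside the confident
#' regions with no truth match is labeled hom-ref; candidates outside the
#' confident regions are excluded.
#'
#' @param examples from [encode_examples()]
#' @param truth truth variant records with genotypes
#' @param confident_regions `GRanges` of high-confidence regions
#' @return the labeled, filtered `rnavc_examples`
#' @export
make_labeled_examples <- function(examples, truth, confident_regions) {
  if (nrow(truth) && any(is.na(truth$gt)))
    abort("truth records lack genotypes; labels require GT")
  assert_normalized(truth)
  m <- examples$meta
  if (nrow(m) == 0L) return(examples)
  inside <- pos_in_regions(m$chrom, m$pos, confident_regions)
  key <- paste(m$chrom, m$pos, m$ref, m$alt)
  lab <- rep(NA_integer_, nrow(m))
  if (nrow(truth)) {
    # decompose truth to per-alt copies
    tkey <- character(0); tcopies <- integer(0)
    for (i in seq_len(nrow(truth))) {
      alts <- strsplit(truth$alt[i], ",")[[1]]
      gta <- as.integer(strsplit(truth$gt[i], "[/|]")[[1]])
      for (ai in seq_along(alts)) {
        tkey <- c(tkey, paste(truth$chrom[i], truth$pos[i], truth$ref[i], alts[ai]))
        tcopies <- c(tcopies, sum(gta == ai))
      }
    }
    hit <- match(key, tkey)
    lab[!is.na(hit)] <- tcopies[hit[!is.na(hit)]]
  }
  lab[is.na(lab)] <- 0L
  out <- subset_examples(examples, inside)
  out$meta$label <- lab[inside]
  out
}
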