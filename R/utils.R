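#' @import methods
#' @importFrom stats dbinom rbinom rnorm rlnorm runif setNames predict coef
#' @importFrom utils head read.delim write.table
#' @importFrom data.table data.table rbindlist setkey setorder := .N .SD as.data.table
NULL

# Silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "allele", "alt", "chrom", "count", "depth", "fwd", "rev_", "is_alt",
  "mean_qual", "pos", "qual", "read_id", "ref", "strand", "n_reads", "qname",
  "base", "label", "outcome", "kind", "segment_index", "mapq", "parent"
))

#' Phred-scale a probability
#'
#' @param p probability in [0, 1]
#' @param cap maximum phred value returned
#' @return `min(cap, -10 * log10(p))`, with `p = 0` mapping to `cap`.
#' @keywords internal
phred <- function(p, cap = 99) {
  v <- -10 * log10(pmax(p, 0))
  pmin(cap, ifelse(is.finite(v), v, cap))
}

#' Derive a stage-specific seed from a global seed
#'
#' Multi-stage runs draw all randomness from one user seed; each stage mixes
#' in its name so that stages are decoupled but jointly reproducible.
#'
#' @param seed integer global seed
#' @param stage character stage label
#' @return integer seed in [0, 2^31 - 1)
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with sprintf formatting and no call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
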