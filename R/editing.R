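# RNA-editing annotation of evaluation outcomes and combinatorial
# genotype-by-edit codon isoform enumeration.

BASE_CHANGES <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(ref = b, alt = b, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  sort(paste0(g$ref, ">", g$alt))
}

#' Cross-tabulate SNP evaluation outcomes by base change and editing-site
#' membership
#'
#' Every SNP outcome record (TP/FP/FN) is assigned its `ref>alt` change and
#' whether its position appears in the editing-site table (exact
#' chromosome/position match; the base change is reported separately so
#' either view is recoverable). Indel records are excluded. A-to-I
#' artifacts surface as apparent A>G (plus strand) and T>C (minus strand)
#' changes concentrated in the `in_editing_db = "yes"` stratum.
#'
#' @param records outcome records from `compare_calls()$records`
#' @param editing_sites `data.frame` with `chrom`, `pos` (e.g. from
#'   [read_editing_table()])
#' @return `data.frame` counts over outcome x 12 base changes x membership,
#'   complete grid with zeros
#' @export
editing_crosstab <- function(records, editing_sites) {
  snp <- records[records$kind == "SNP", , drop = FALSE]
  key <- paste(snp$chrom, snp$pos)
  ekey <- if (nrow(editing_sites)) paste(editing_sites$chrom, editing_sites$pos)
          else character(0)
  df <- data.frame(
    outcome = factor(snp$outcome, levels = c("TP", "FP", "FN")),
    base_change = factor(paste0(snp$ref, ">", snp$alt), levels = BASE_CHANGES),
    in_editing_db = factor(ifelse(key %in% ekey, "yes", "no"),
                           levels = c("yes", "no")))
  out <- as.data.frame(table(df), responseName = "count",
                       stringsAsFactors = FALSE)
  out[order(out$outcome, out$base_change, out$in_editing_db), ]
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "*")

#' Describe one codon position for isoform enumeration
#'
#' @param ref reference base (sense-strand DNA)
#' @param genotype optional unphased DNA allele pair, e.g. `c("T", "C")`
#' @param edit optional editing event as `c(from, to)`; the edited and
#'   unedited base are both possible per molecule
#' @return list describing the position
#' @export
codon_position <- function(ref, genotype = NULL, edit = NULL) {
  chk <- function(x) {
    x <- toupper(x)
    if (any(!x %in% names(REVCOMP))) abort("invalid base: %s", paste(x, collapse = ","))
    x
  }
  list(ref = chk(ref), genotype = if (!is.null(genotype)) chk(genotype),
       edit = if (!is.null(edit)) chk(edit))
}

#' Enumerate mRNA codon and protein isoforms of a genotype-by-edit codon
#'
#' Each of the three codon positions contributes its possible DNA bases:
#' the unphased genotype alleles (or the reference base), plus the edited
#' base when an editing event is annotated — editing is treated as optional
#' per molecule, so both edited and unedited bases are enumerated. The
#' Cartesian product over the three positions is transcribed (minus-strand
#' contexts are reverse-complemented first) and translated with the
#' standard genetic code; stop codons get amino acid `*`. A heterozygous
#' T/C, an A-to-G edit and a fixed C jointly yield the four isoforms
#' UAC/Tyr, UGC/Cys, CAC/His and CGC/Arg.
#'
#' @param positions list of exactly three [codon_position()]s, in genomic
#'   order
#' @param strand `"+"` or `"-"` (gene strand)
#' @return `data.frame`: `codon_rna`, `aa`, `aa3`, one row per distinct
#'   (codon, amino acid) pair
#' @export
enumerate_isoforms <- function(positions, strand = "+") {
  stopifnot(length(positions) == 3L, strand %in% c("+", "-"))
  opts <- lapply(positions, function(p) {
    bases <- if (!is.null(p$genotype)) unique(p$genotype) else p$ref
    if (!is.null(p$edit)) bases <- unique(c(bases, p$edit[2L]))
    bases
  })
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  codons_dna <- apply(grid, 1L, paste, collapse = "")
  if (strand == "-")
    codons_dna <- vapply(strsplit(codons_dna, ""), function(x)
      paste(rev(unname(REVCOMP[x])), collapse = ""), "")
  aa <- unname(Biostrings::GENETIC_CODE[codons_dna])
  out <- unique(data.frame(codon_rna = gsub("T", "U", codons_dna), aa = aa,
                           aa3 = unname(AA3[aa]), stringsAsFactors = FALSE))
  out <- out[order(out$codon_rna), ]
  rownames(out) <- NULL
  out
}
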