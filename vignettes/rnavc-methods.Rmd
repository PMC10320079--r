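---
title: "Calling germline variants from spliced RNA-seq: models and design"
author: "rnavc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling germline variants from spliced RNA-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnavc)
```

## The problem

RNA-seq carries genotype information for free, but calling germline
variants from it faces error sources absent from DNA-seq: coverage follows
expression and ranges from zero to thousands-fold; spliced alignments
carry SKIP (N) CIGAR operations that standard callers handle poorly;
allele-specific expression (ASE) skews heterozygous allele fractions away
from 50%; A-to-I RNA editing creates apparent A>G (plus strand) and T>C
(minus strand) variants that are not in the DNA; PCR amplification and
reverse transcription add further noise. `rnavc` implements a desk-scale
variant-calling pipeline built around these problems, together with the
evaluation machinery (region-stratified concordance, exon-boundary error
profiles, FDR-targeted score thresholding, editing cross-tabulation) and a
spliced-read simulator so that every stage is testable without external
data.

## Pipeline

1. **Read preparation** (`filter_reads`, `split_skip_reads`). Unmapped,
   secondary, supplementary, duplicate-flagged and low-MAPQ reads are
   dropped. Spliced reads are then split at every N operation into
   intron-free segments: segment *k* starts at the parent position plus
   the reference length consumed by all prior operations including the
   skipped introns, and query bases/qualities are partitioned without loss
   or duplication. Two partition rules the CIGAR grammar leaves open are
   fixed deterministically: insertions at a segment boundary attach to the
   left segment, and deletions adjacent to an N stay inside their segment.
   Segments with fewer than `min_segment_len = 15` aligned bases are
   dropped — tiny exon overhangs carry no usable variant context; the
   threshold is configurable and logged.
2. **Candidate discovery** (`build_pileup`, `find_candidates`). Columns
   tally aligned bases with quality at or above `min_base_qual = 10`,
   insertion alleles at their left-anchor column and deletion alleles at
   the base preceding the run; depth counts reads with an aligned base or
   deletion span regardless of quality. An alternate allele becomes a
   candidate with at least `min_alt_count = 2` supporting reads — the
   two-mismatch discovery rule — and at least `min_alt_fraction = 0.10` of
   depth. The fraction floor is our addition: RNA coverage can exceed
   10,000x, where two stray reads are noise; the count rule alone would
   flood the classifier. At most two alternates are kept per column
   (descending support, ties lexicographic).
3. **Example encoding** (`encode_examples`). Each candidate becomes a
   fixed-shape pileup image of `height x width x 6` channels (base
   identity, base quality, mapping quality, strand, supports-alt,
   differs-from-reference), reference row first, reads sorted by (start,
   name) and downsampled under a seed when they exceed the height. The
   channel set and numeric conventions are ours; defaults `width = 221`,
   `height = 101` keep memory trivial at desk scale. Alongside the tensor,
   a pooled feature vector is always computed: depth, alternate fraction
   and its deviation from 1/2, genotype log-likelihood ratios in which the
   homozygous classes use a nominal 0.5% base error and the heterozygous
   class integrates the binomial over ASE skews 0.25-0.75 (the RNA-aware
   het model; it linearizes the depth-by-fraction decision boundary for
   the linear backend and keeps strongly skewed heterozygotes away from
   the homozygous calls), mean alternate/reference base quality, mean
   mapping quality, alternate-read strand balance, indicator features for
   the twelve base changes plus insertion/deletion, and an A-to-I
   editing-signature indicator (apparent A>G with a non-G 5-prime
   reference neighbor, or the strand mirror T>C with a non-C 3-prime
   neighbor) with allele-fraction interactions — the pooled-feature
   rendering of the sequence context a pileup-image model would read off
   the reference row.
4. **Genotype classification** (`train_genotyper`, `classify_examples`).
   Three classes: homozygous-reference, heterozygous, homozygous-
   alternate. Backends: `logistic`, a multinomial logistic model on the
   pooled features (the default; its coefficients are extracted into a
   plain JSON-serializable parameter list), and `bayes-baseline`, the
   closed-form binomial model with flat class prior, which doubles as the
   reference oracle in tests. A convolutional backend on the full tensor
   is a natural extension we did not include; at desk scale the pooled
   features already expose the signal a small CNN could use, and the
   training set sizes here (hundreds of examples) would not support one.
   Labels are silver truth: candidates matching a truth variant (same
   position and alleles, minimal representation) take the truth genotype's
   copy number of the scored alternate; unmatched candidates inside the
   confident regions are labeled homozygous-reference; candidates outside
   are excluded. Training respects a chromosome partition (train / tune /
   holdout, mirroring the chr1-19 / chr21-22 / chr20 style of partition);
   the tune chromosomes are used only to select the ridge penalty, and the
   split is recorded in the model so downstream evaluation can refuse
   leakage. The ridge grid deliberately excludes zero: rare base-change
   indicators quasi-separate on small training sets and produce confident
   nonsense without shrinkage.
5. **Calls, GQ and QUAL** (`call_genotype`, `call_pipeline`). The called
   class is the probability argmax, ties toward the reference. GQ is the
   phred-scaled probability the call is wrong, `-10 log10(1 - p_called)`,
   rounded to an integer; QUAL is the phred-scaled probability the site is
   not a variant, `-10 log10(p0)`, one decimal; both capped at 99. These
   phred forms implement the verbal definitions of the two scores; the
   upstream implementation does not publish its exact formulas, so the
   caps and rounding are VCF convention. Per-alternate calls at one site
   are merged with the highest-QUAL alternate first. Homozygous-reference
   records are suppressed unless requested.
6. **Thresholding** (`threshold_curve`, `select_cutoff`). For integer
   cutoffs 0..99 the calls with score at or above the cutoff are rescored
   to an (FDR, TPR) curve; `select_cutoff` returns the smallest cutoff
   whose pooled FDR across samples is at or below the target (default
   1.5%), the production-pipeline operating point. If the target is
   unattainable the cap is returned with a warning flag.

## Evaluation model

Matching is *normalized genotype concordance*: a call is a true positive
when a truth record shares chromosome, position, alleles (both minimal
representation) and unordered genotype. A genotype mismatch counts one FP
and one FN — symmetric and conservative. This deliberately is not
haplotype-resolved matching (vcfeval-style): complex representation
differences are out of scope, and concordance is exact on simulator output
because the simulator emits normalized truth. Metrics with zero
denominators are reported missing, never zero. Coverage stratification
computes maximal intervals of depth >= 3 from the *filtered, split*
alignments, then intersects them into every stratum (CDS, exon,
transcript, gene, arbitrary named regions), which applies the depth filter
to calls and truth uniformly. The exon-boundary profile uses a signed
distance: non-negative inside an exon (0 on a terminal base), negative
outside (distance to the nearest terminal base); any fixed anchoring
convention yields the same profile shape, so we state ours and keep it.

The editing cross-tab classifies SNP outcomes (TP/FP/FN) by base change
and by presence in an editing-site table matched on position alone; the
base change is reported as its own margin, so a membership-plus-allele
view remains recoverable.

Codon isoform enumeration treats unphased genotypes and editing events
combinatorially: each position contributes its genotype alleles, plus the
edited base when an edit is annotated (editing is optional per molecule,
so the unedited base stays enumerable); the Cartesian product is
transcribed (minus-strand contexts reverse-complemented first) and
translated with the standard genetic code. A heterozygous T/C beside an
A-to-G edit and a fixed C yields UAC/Tyr, UGC/Cys, CAC/His, CGC/Arg —
four protein isoforms from one codon.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions: ~50-200 genes of 2-5
exons (80-300 bp) with 60-400 bp introns on 4 chromosomes; SNPs at
2e-3/bp and indels at 2e-4/bp over gene bodies with heterozygous to
homozygous-alternate genotypes at 2:1; per-transcript depth
`mean_coverage * LogNormal(0, 0.2)` around 30x; per-gene ASE skew uniform
in [0.3, 0.7] (the probability a read samples the alternate-bearing
haplotype); A-to-I sites at 2e-4 per exonic bp placed on exonic A/T of
the transcribed strand carrying the ADAR motif (the transcribed-strand 5-prime
neighbor is never G), with per-site editing fractions uniform in
[0.2, 0.9]; i.i.d. base errors at 5e-3 with qualities Normal(30, 4)
clipped to [2, 40]; 2% flagged PCR duplicates. Reads are emitted
pre-aligned at their true locus, so caller behavior is isolated from
aligner behavior, and junction reads carry N operations whose lengths are
exactly the intron lengths.

Where no external value fixes a knob we chose once: the ASE and
editing-fraction ranges follow the stated conventions above; the editing
*density* is set so that the editing-artifact burden is a few percent of
the true-variant count, matching the relative scale at which editing
false positives appear against thousands of true SNPs in exome-restricted
RNA calling — at much higher densities an A>G candidate is a priori more
likely edited than germline, and no classifier confined to per-site
features can separate the two. Indels are kept at least
`max_indel_len + 2` bp clear of exon boundaries so each within-read
reference gap is unambiguously a deletion (intra-exon) or an intron
(junction); junction-adjacent indel CIGARs are otherwise ill-defined.
Confident regions default to exons padded by 10 bp.

Not emulated: fragment/insert-size structure (single-end reads only, the
duplicate flag stands in for resequenced duplicates), sequencer-specific
error profiles, softclips, fusion transcripts, degradation (RIN) effects,
intron-retention isoforms, and clustered editing (real A-to-I sites
aggregate in inverted repeats; ours are independent). Passing tests
therefore demonstrate correctness of the mechanics and calibration under
this generative model, not performance on real tissue RNA.

## Numerical and degenerate-input choices

Probability ties break toward the lower class index (the reference).
Zero-depth examples classify as the uniform simplex. The bayes backend
clamps its error rate to [1e-6, 0.5] and works in log space. Empty inputs
propagate as empty, typed results (header-only VCFs, zero-row tables).
All multi-stage randomness derives from one seed via a documented
stage-name hash (`derive_seed`), so any stage can be reproduced in
isolation; read downsampling in the encoder additionally mixes in the
candidate's coordinates so one crowded window cannot perturb another.

## Benchmark problem sizes

The bundled checks run at sizes chosen for a laptop CPU: unit fixtures use
6-20 genes; the calibration and recovery benchmarks use a 200-gene,
4-chromosome genome (~45,000 reads), trained on two chromosomes, tuned on
a third (ridge penalty and the FDR-targeted GQ cutoff are both selected
there) and scored on the held-out fourth. At these sizes the full
pipeline runs in about two minutes. Held-out F1 is reported at the
pipeline's selected operating point (GQ cutoff at 1.5% target FDR),
which is how the method is meant to be run in production; unthresholded
F1 is a seed-noisy quantity at this scale because a handful of
low-confidence editing false positives can dominate the count.

## Known limitations

The logistic backend sees pooled per-example features only; signals that
need the spatial structure of the pileup (strand-of-gene context,
clustered edits, proximal indel shadows) are invisible to it. Genotype
concordance cannot credit representationally different but equivalent
complex calls. The coverage BED derives from split segments, so a
deletion inside a segment still counts toward depth. Multi-allelic
genotypes beyond two alternates are not modeled. The editing-avoidance
behavior is learned, and therefore only as strong as the editing burden
present in training data.
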