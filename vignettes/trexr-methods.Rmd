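---
title: "Methods behind the trexr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the trexr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trexr)
```

trexr detects and genotypes tandem repeat (TR) expansions from long-read
genome alignments in two stages: a genome-wide **scan** that needs no
prior locus annotation, and a targeted **genotype** stage that sizes the
repeat in every informative read and clusters read sizes into alleles.
This vignette describes the methods each stage rests on, plus the
simulator and the benchmarking utilities used to validate them.

## Repeat detection: wraparound dynamic programming

The repeat finder at the core of both stages is a local alignment of a
sequence against a *circularised* motif: a dynamic-programming matrix
with one column per motif position, where the transition from the last
motif position wraps back to the first. A tandem array of any number of
copies therefore aligns as one continuous local alignment, and the motif
never has to be pre-multiplied to the tract length. Scoring is
`+1` match, `-1` mismatch, `-2` indel, and a tract is reported when the
best local score reaches `min_repeat_score` (8, i.e. at least ~8
consistent bases net of noise). The implementation (`wrap_align()`) is
in C++; the test suite checks it cell-for-cell against a plain-R
re-implementation.

```{r wrap}
wrap_align(paste0("TTTT", strrep("CAG", 10), "AA"), "CAG")
```

`find_repeats()` turns this aligner into a motif search. Short
sequences (`exhaustive_max_len`, 64 bp) are searched exhaustively over
every substring motif of 2 to `motif_len_max` bases; longer sequences
are first screened with a lag autocorrelation profile (positions where
`seq[i] == seq[i + lag]` cluster at the repeat period), and only dense
candidate regions are aligned. The density threshold
(`min_region_density`, 0.4) is deliberately permissive: at a 12%,
indel-heavy error rate the lag profile of long-unit repeats (e.g. a
12 bp VNTR) degrades quickly, because a single indel shifts the phase of
every following position; at 0.4 such tracts still form candidate
regions, while the wraparound alignment that follows cheaply rejects the
extra false candidates the low threshold admits. Candidate motifs are reduced to their
primitive root and canonical form — the lexicographically smallest
rotation over both strands — so `CAG`, `GCA` and `CTG` all report as
`AGC`:

```{r canon}
canonical_motif("CTG")
find_repeats(paste0("ACGT", strrep("CAG", 8), "ACGT"))
```

Overlapping candidates are ranked by a *parsimony-adjusted* score
(alignment score minus motif length). This lets the primitive unit beat
two kinds of impostor that plain score ranking admits: long "verbatim
chunk" motifs cut straight out of a noisy tract (they outscore the true
unit because the errors are baked into the motif), and low-scoring
degenerate near-motifs. A candidate is then dropped only if it overlaps
an accepted hit of the same motif *family* (`motifs_match()`): exact
canonical equality for short units, or — when one unit is a harmonic of
the other or both are VNTR-scale — an identity/coverage test of the
longer unit aligned against a tandem array of the shorter.

## Scan stage: expansion discovery from alignments

An expansion longer than the sequenced reference allele appears in a
read alignment in one of two ways, and `genome_scan()` harvests both:

1. **CIGAR insertions** (`insertions_from_cigar()`): a single alignment
   with an `I` operation of at least `min_ins_size` (100 bp).
2. **Split alignments** (`insertions_from_splits()`): very large
   expansions break the alignment in two; the unaligned read sequence
   between a primary/supplementary pair on the same strand, with
   compatible read and reference geometry, is recovered as one insertion
   event.

Events from all reads are merged by single-linkage clustering within
`merge_window` (50 bp) of reference position. Each cluster must reach
`min_support` events, and the inserted sequence must be at least
`insertion_purity_min` (70%) covered by a single canonical motif —
everything else is discarded as alignment noise.

For each surviving cluster, `delineate_locus()` re-examines the
*reference* around the insertion anchor, finds the repeat tract matching
the inserted motif, trims the alignment-optimal segment to its outermost
exact double motif copies (local alignment happily extends a few
net-positive bases into flank), and finally extends the boundaries to
the maximal run of the period. The result is a precise reference locus
that feeds directly into the genotype stage.

## Genotype stage: read sizing and allele calling

For each target locus, every overlapping read is sized
(`call_read()`) by one of two routes:

- **Spanning reads** (`extract_read_tract()`): the locus boundaries are
  mapped through the read's aligned blocks. The read segment between
  them contains the full repeat, including any insertions, and the read
  must carry at least `min_flank_anchor` (50 bp) of aligned sequence on
  both sides.
- **Clip rescue** (`rescue_clipped()`): long expansions often end the
  alignment inside the repeat, leaving the rest of the repeat and the
  far flank in a soft clip. The missing boundary is recovered by
  locally aligning `rescue_flank_len` (80 bp) of reference sequence from
  the far side of the locus into the clipped bases; a unique, high
  identity placement re-anchors the read.

The extracted segment is then measured with the wraparound aligner
against the locus motif, giving a repeat size in bases and in copies.

Per-read sizes at a locus are clustered into alleles by
`fit_genotype()`, which behaves like a classic R modelling function: it
returns a classed object (`tr_genotype`) with `print()` and `summary()`
methods. One-dimensional Gaussian mixtures with 1 to `max_alleles`
components (via **mclust**, unequal variances) are compared by AIC; two
exactly-repeated size values are handled as a zero-variance mixture
analytically. Components closer than `allele_merge_gap` are merged and
alleles with fewer than `min_support` reads are dropped, so the reported
`k` is the number of *supported* alleles.

```{r genotype}
set.seed(1)
sizes <- c(round(rnorm(10, 60, 3)), round(rnorm(10, 417, 8)))
calls <- data.frame(read_id = sprintf("r%02d", 1:20), repeat_size = sizes,
                    copy_number = sizes / 3, read_tract_start = 0L,
                    method = "spanning")
fit_genotype(calls, tr_params())
```

## Simulator

`simulate_reads()` generates noisy long reads from haplotype sequences
built by `build_haplotype()` (a reference with the locus tract replaced
by any copy number). Errors follow a per-base model with independent
substitution, insertion and deletion rates (defaults total 12%), and
every simulated error is logged so tests can replay it. Each read
carries a parseable identifier and a *truth alignment*: the CIGAR the
read would have against the reference, including expansion insertions
and — for reads whose expansion exceeds the aligner's tolerance — split
primary/supplementary pairs with soft clips. `write_sam()` emits
standard SAM that round-trips through `read_alignments()` (Rsamtools).

`make_experiment()` packages three designs: `het17` (17 catalogued
disease loci, heterozygous reference/expanded at ~30X), `resolve_grid`
(bi-allelic samples over a grid of base sizes and allele separations)
and `mosaic_series` (premutation/full-mutation mixtures at varying
fractions, replicated).

## Benchmarking

- `classify_support_reads()` partitions a call's supporting reads
  against the set of truth spanning reads (at least
  `truth_overlap_min` = 50 bp aligned on both sides of the expansion)
  into true/false positives and false negatives.
- `assembly_tr_size()` sizes a repeat in an assembled haplotype by
  placing two `flank_probe_len` (500 bp) reference probes around the
  locus and measuring the distance between their inner ends, with
  motif and purity checks and a reason code for failures.
- `match_genotype()` pairs called against truth alleles (nearest-first)
  and scores each within `match_abs_tol` (20 bp) **or**
  `match_rel_tol` (10%) of the truth size.
- `ks_compare()` wraps `stats::ks.test()` to compare two read-level size
  distributions, e.g. the supporting reads of two alleles.

```{r match}
match_genotype(c(60, 417), c(60, 420), tr_params())
```

## Parameters

All thresholds live in one validated object:

```{r params}
tr_params()
```
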