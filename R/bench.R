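# Evaluation utilities: compare pipeline output against simulation truth or
# against an assembly-derived tract size, classify supporting reads, and
# test read-size distributions for allele-specific differences.

#' Classify called supporting reads against truth
#'
#' @param called character vector of read ids reported as supporting a locus.
#' @param truth character vector of ground-truth spanning read ids
#'   (e.g. from [truth_spanning_reads()]).
#' @return List: `tp`, `fp`, `fn` (read id vectors), `n_tp`, `n_fp`, `n_fn`,
#'   `sensitivity` and `precision` (percent; `NA` for empty denominators).
#' @export
classify_support_reads <- function(called, truth) {
  called <- unique(as.character(called))
  truth <- unique(as.character(truth))
  tp <- intersect(called, truth)
  fp <- setdiff(called, truth)
  fn <- setdiff(truth, called)
  list(tp = tp, fp = fp, fn = fn,
       n_tp = length(tp), n_fp = length(fp), n_fn = length(fn),
       sensitivity = if (length(truth)) 100 * length(tp) / length(truth)
                     else NA_real_,
       precision = if (length(called)) 100 * length(tp) / length(called)
                   else NA_real_)
}

#' Measure a TR tract in an assembled sequence by flank anchoring
#'
#' Anchors `flank_probe_len` (500 bp) of reference sequence from each side of
#' the locus in the assembly by local alignment.  Both probes must place
#' end-to-end (coverage at least `probe_min_cov`) and unambiguously; the
#' tract is the assembly interval between them and must consist of at least
#' `genomic_tract_purity_min` (80\%) of a single TR whose motif matches one
#' of the locus motifs.  This gives an orthogonal, alignment-free size
#' estimate for validating genotype calls.
#'
#' @param assembly assembled sequence (single DNA string) containing the
#'   locus region.
#' @param reference reference genome (see [ref_fetch()]).
#' @param locus one-row `tr_loci` data frame.
#' @param params [tr_params()].
#' @return List: `size` (bp; `NA` when the probes do not place cleanly or the
#'   interval is not a matching TR tract), `start`, `end` (0-based half-open
#'   in `assembly`), `motif`, `purity`, `reason` (why `NA`, else `"ok"`).
#' @export
assembly_tr_size <- function(assembly, reference, locus,
                             params = tr_params()) {
  params <- as_params(params)
  fail <- function(reason) list(size = NA_real_, start = NA_integer_,
                                end = NA_integer_, motif = NA_character_,
                                purity = NA_real_, reason = reason)
  fp <- params$flank_probe_len
  left <- ref_fetch(reference, locus$chrom, locus$start - fp, locus$start)
  right <- ref_fetch(reference, locus$chrom, locus$end, locus$end + fp)
  if (nchar(left) < fp || nchar(right) < fp)
    return(fail("locus too close to a reference edge for flank probes"))
  hl <- local_probe(left, assembly, unique_check = TRUE)
  hr <- local_probe(right, assembly, unique_check = TRUE)
  if (is.null(hl) || is.null(hr)) return(fail("flank probe not found"))
  if (hl$ambiguous || hr$ambiguous) return(fail("flank probe ambiguous"))
  if (hl$coverage < params$probe_min_cov || hr$coverage < params$probe_min_cov)
    return(fail("flank probe placed partially"))
  s <- hl$sub_end
  e <- hr$sub_start
  if (e <= s) return(fail("flank probes overlap or are inverted"))
  tract <- substr(assembly, s + 1L, e)
  hits <- find_repeats(tract, params)
  if (!nrow(hits)) return(fail("no repeat in anchored interval"))
  by_motif <- vapply(unique(hits$motif), function(m)
    tract_purity(tract, hits[hits$motif == m, , drop = FALSE]), 0)
  best <- names(by_motif)[which.max(by_motif)]
  if (max(by_motif) < params$genomic_tract_purity_min)
    return(fail("anchored interval below tract purity threshold"))
  target_ok <- any(vapply(locus_motifs(locus), function(m)
    motifs_match(best, m, params), TRUE))
  if (!target_ok) return(fail("repeat motif does not match locus"))
  list(size = e - s, start = s, end = e, motif = best,
       purity = unname(max(by_motif)), reason = "ok")
}

#' Compare a called genotype against truth allele sizes
#'
#' Both size vectors are sorted ascending and paired by rank; a pair matches
#' when the absolute difference is within `match_abs_tol` (20 bp) or within
#' `match_rel_tol` (10\%) of the truth size.  When the call has fewer alleles
#' than the truth (e.g. a homozygous call against a heterozygous truth), each
#' truth allele is compared against its nearest call, so `one_match` reports
#' whether at least one truth allele was recovered.
#'
#' @param called numeric vector of called allele sizes (bp).
#' @param truth numeric vector of true allele sizes (bp).
#' @param params [tr_params()].
#' @return An object of class `tr_match`: list with `pairs` (data frame
#'   `truth`, `called`, `delta`, `matched`), `n_called`, `n_truth`,
#'   `all_matched`, `one_match`.
#' @export
match_genotype <- function(called, truth, params = tr_params()) {
  params <- as_params(params)
  called <- sort(as.numeric(called))
  truth <- sort(as.numeric(truth))
  if (!length(truth)) stop("truth must contain at least one allele size")
  within_tol <- function(c_, t_)
    !is.na(c_) & (abs(c_ - t_) <= params$match_abs_tol |
                    abs(c_ - t_) <= params$match_rel_tol * t_)
  if (length(called) >= length(truth)) {
    # rank pairing; surplus calls pair with NA truth and count as mismatches
    cal <- called[seq_along(truth)]
    pairs <- data.frame(truth = truth, called = cal, delta = cal - truth)
    pairs$matched <- within_tol(pairs$called, pairs$truth)
    extra <- length(called) - length(truth)
    all_matched <- all(pairs$matched) && extra == 0L
  } else {
    # fewer calls than truth alleles: nearest call per truth allele
    cal <- vapply(truth, function(t_) {
      if (!length(called)) NA_real_
      else called[which.min(abs(called - t_))]
    }, 0)
    pairs <- data.frame(truth = truth, called = cal, delta = cal - truth)
    pairs$matched <- within_tol(pairs$called, pairs$truth)
    all_matched <- FALSE
  }
  structure(list(pairs = pairs, n_called = length(called),
                 n_truth = length(truth), all_matched = all_matched,
                 one_match = any(pairs$matched)),
            class = "tr_match")
}

#' @export
print.tr_match <- function(x, ...) {
  cat(sprintf("Genotype match: %d called vs %d truth allele(s); %s\n",
              x$n_called, x$n_truth,
              if (x$all_matched) "all matched"
              else if (x$one_match) "partial match" else "no match"))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of read size distributions
#'
#' Thin wrapper around [stats::ks.test()] (asymptotic p-value; ties are
#' expected in integer repeat sizes, so the exact method is disabled and its
#' tie warnings suppressed).  Used to ask whether the supporting reads of two
#' alleles (or two samples) were drawn from distinguishable size
#' distributions.
#'
#' @param x,y numeric vectors of read-level repeat sizes.
#' @param alpha significance level for the `significant` flag.
#' @return List: `statistic` (D), `p_value`, `significant`.
#' @export
ks_compare <- function(x, y, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L)
    stop("ks_compare needs at least two observations per sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value < alpha)
}
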