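# Native tandem repeat detection.  Replaces an external TRF/BLASTN dependency
# with a fixed, testable contract: candidate repeat periods come from a
# self-match lag profile, boundaries/copy number/purity from wraparound
# dynamic programming against the inferred motif (+1/-1/-2 scoring, report
# threshold 8).  Sequences up to `exhaustive_max_len` are searched
# exhaustively over all substring motifs, which doubles as the brute-force
# reference behaviour for small inputs.

#' Canonical form of a repeat motif
#'
#' The lexicographically smallest string among all rotations of the motif
#' and, when `use_revcomp`, all rotations of its reverse complement.  Reads
#' may align to either genomic strand, so strand-normalised comparison is the
#' default.  Idempotent.
#'
#' @param motif DNA string (ACGT).
#' @param use_revcomp also consider the reverse complement (default TRUE).
#' @return The canonical motif string.
#' @examples
#' canonical_motif("CAG")          # "AGC"
#' canonical_motif("CTG")          # "AGC" (revcomp rotation)
#' canonical_motif("CTG", FALSE)   # "CTG"
#' @export
canonical_motif <- function(motif, use_revcomp = TRUE) {
  motif <- toupper(motif)
  if (!nzchar(motif) || !grepl("^[ACGT]+$", motif))
    stop("motif must be a non-empty ACGT string")
  cands <- rotations(motif)
  if (use_revcomp) cands <- c(cands, rotations(revcomp(motif)))
  min(cands)
}

rotations <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(x)
  d <- paste0(x, x)
  vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), "")
}

# smallest repeating unit of a motif ("ACAC" -> "AC")
primitive_root <- function(x) {
  n <- nchar(x)
  for (d in seq_len(n)) {
    if (n %% d != 0L) next
    if (strrep(substr(x, 1L, d), n %/% d) == x) return(substr(x, 1L, d))
  }
  x
}

#' Detect tandem repeat tracts in a sequence
#'
#' Reports maximal, mutually non-redundant tandem repeat tracts with motif
#' lengths in `[motif_len_min, motif_len_max]`.  Each tract is scored by
#' wraparound local alignment against its motif; tracts with fewer than two
#' copies or score below `min_repeat_score` are not reported.  Tolerates the
#' indel-dominated error profile of long reads (a planted tract of >= 3
#' copies, >= 20 bp, with per-base error up to ~15\% is recovered with the
#' correct canonical motif and boundaries within one motif length).
#'
#' @param seq DNA string.
#' @param params [tr_params()].
#' @return A data frame of repeat hits: `motif` (canonical,
#'   strand-normalised), `start`, `end` (0-based half-open in `seq`),
#'   `copy_number` (`(end-start)/nchar(motif)`), `purity` (matched /
#'   aligned columns), `score`.
#' @examples
#' find_repeats("ACACACACACAC")
#' @export
find_repeats <- function(seq, params = tr_params()) {
  params <- as_params(params)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), copy_number = numeric(0),
                      purity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2L * params$motif_len_min) return(empty)
  cands <- if (n <= params$exhaustive_max_len)
    repeat_candidates_exhaustive(seq, params)
  else
    repeat_candidates_profile(seq, params)
  if (!nrow(cands)) return(empty)
  select_hits(cands, params)
}

# score one candidate (region, motif) by wraparound alignment; NULL when it
# does not qualify as a repeat tract
score_candidate <- function(seq, motif, region_start, region_end, params) {
  sub <- substr(seq, region_start + 1L, region_end)
  p <- nchar(motif)
  al <- wrap_align_cpp(sub, motif, params$wrap_match, params$wrap_mismatch,
                       params$wrap_indel)
  if (al$score < params$min_repeat_score || al$cols == 0L) return(NULL)
  start <- region_start + al$start
  end <- region_start + al$end
  if (end - start < 2L * p) return(NULL)
  data.frame(motif = canonical_motif(motif), start = start, end = end,
             copy_number = (end - start) / p,
             purity = al$matches / al$cols, score = al$score,
             stringsAsFactors = FALSE)
}

repeat_candidates_exhaustive <- function(seq, params) {
  n <- nchar(seq)
  pmax_ <- min(params$motif_len_max, n %/% 2L)
  seen <- character(0)
  out <- list()
  for (p in params$motif_len_min:pmax_) {
    for (i in seq_len(n - p + 1L)) {
      motif <- substr(seq, i, i + p - 1L)
      if (!grepl("^[ACGT]+$", motif)) next
      root <- primitive_root(motif)
      if (nchar(root) < p) next  # evaluated at its own period
      key <- canonical_motif(motif, use_revcomp = FALSE)
      if (key %in% seen) next    # rotation-invariant score
      seen <- c(seen, key)
      hit <- score_candidate(seq, motif, 0L, n, params)
      if (!is.null(hit)) out[[length(out) + 1L]] <- hit
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

repeat_candidates_profile <- function(seq, params) {
  n <- nchar(seq)
  pmax_ <- min(params$motif_len_max, n %/% 2L)
  out <- list()
  for (p in params$motif_len_min:pmax_) {
    eq <- lag_profile_cpp(seq, p)
    m <- length(eq)
    w <- min(max(2L * p, 16L), m)
    if (w < 4L) next
    cs <- cumsum(c(0L, as.integer(eq)))
    dens <- (cs[(w + 1L):(m + 1L)] - cs[1L:(m - w + 1L)]) / w
    hot <- which(dens >= params$min_region_density)
    if (!length(hot)) next
    # merge window starts closer than one window into regions
    breaks <- which(diff(hot) > w)
    reg_start <- hot[c(1L, breaks + 1L)]
    reg_end <- hot[c(breaks, length(hot))] + w  # eq coords, half-open-ish
    for (r in seq_along(reg_start)) {
      a <- reg_start[r] - 1L       # 0-based in seq
      b <- min(n, reg_end[r] + p)  # include the lagged copy
      # motif: cleanest copy = window of p consecutive lag matches
      i0 <- best_motif_offset(eq, a, min(b - p, m), p)
      motif <- substr(seq, i0 + 1L, i0 + p)
      if (!grepl("^[ACGT]+$", motif)) next
      root <- primitive_root(motif)
      if (nchar(root) < params$motif_len_min) next
      motif <- root
      ext <- p + 4L
      hit <- score_candidate(seq, motif, max(0L, a - ext), min(n, b + ext),
                             params)
      if (!is.null(hit)) out[[length(out) + 1L]] <- hit
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

# offset (0-based) within [a, b) maximising the number of lag matches over
# the next p positions, i.e. the most internally consistent motif copy
best_motif_offset <- function(eq, a, b, p) {
  lo <- a + 1L
  hi <- max(lo, b)
  hi <- min(hi, length(eq) - p + 1L)
  if (hi < lo) return(a)
  cs <- cumsum(c(0L, as.integer(eq)))
  sums <- cs[(lo + p):(hi + p)] - cs[lo:hi]
  lo - 1L + which.max(sums) - 1L
}

# greedy selection of maximal non-redundant tracts: order by
# parsimony-adjusted score (alignment score minus motif length; ties:
# shorter motif, then lexicographic canonical form, then start).  A hit is
# redundant -- and dropped -- only against an accepted hit of the same motif
# family ([motifs_match()]): same motif with any overlap, or a matching
# motif overlapping by >= 50% of the shorter tract.  Overlapping repeats of
# unrelated periods (e.g. a short STR inside a longer spurious unit) are
# both reported; downstream consumers pick by motif.
select_hits <- function(cands, params) {
  # parsimony-adjusted ranking (score minus motif length): within a family
  # the primitive unit must claim the tract both ahead of longer "harmonic"
  # units (verbatim chunks of a noisy tract outscore the true unit because
  # they bake the errors into the motif) and ahead of low-scoring degenerate
  # near-motifs; the length penalty charges each candidate for the
  # description length of its unit
  ord <- order(-(cands$score - nchar(cands$motif)), nchar(cands$motif),
               cands$motif, cands$start)
  cands <- cands[ord, , drop = FALSE]
  kept <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in which(kept)) {
      ov <- interval_overlap(cands$start[i], cands$end[i],
                             cands$start[j], cands$end[j])
      if (ov <= 0) next
      if (cands$motif[j] == cands$motif[i]) { ok <- FALSE; break }
      shorter <- min(cands$end[i] - cands$start[i],
                     cands$end[j] - cands$start[j])
      if (ov >= 0.5 * shorter &&
          motifs_match(cands$motif[i], cands$motif[j], params)) {
        ok <- FALSE; break
      }
    }
    kept[i] <- ok
  }
  res <- cands[kept, , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Single-motif purity of a sequence
#'
#' Fraction of the sequence covered by tandem repeat tracts of one (canonical)
#' motif, maximised over motifs: the screen used to keep only insertions
#' composed of at least 70\% of a single TR.
#'
#' @param seq DNA string (or its length).
#' @param hits repeat hits from [find_repeats()] on `seq`.
#' @return A fraction in `[0, 1]` (0 when no hits).
#' @export
tract_purity <- function(seq, hits) {
  len <- if (is.character(seq)) nchar(seq) else as.integer(seq)
  if (is.null(hits) || !nrow(hits) || len == 0L) return(0)
  cov <- vapply(split(seq_len(nrow(hits)), hits$motif), function(idx) {
    covered <- rep(FALSE, len)
    for (i in idx) {
      s <- max(0L, hits$start[i]); e <- min(len, hits$end[i])
      if (e > s) covered[(s + 1L):e] <- TRUE
    }
    sum(covered)
  }, 0L)
  max(cov) / len
}

#' Do two repeat motifs match?
#'
#' Exact path: equal canonical (rotation/strand-normalised) forms.
#' Approximate path (taken only when either motif exceeds 6 bp, or the
#' longer is at least twice the shorter): a wraparound local alignment of
#' the longer motif against a tandem array of the shorter must reach
#' `motif_match_min_identity` identity over `motif_match_min_cov` of the
#' longer motif.  This covers VNTR units that noisy reads rarely yield
#' exactly, and "harmonic" motifs -- a long unit that is itself essentially
#' a tandem array of a short one (e.g. AACAC over an AC tract) describes the
#' same repeat.  Short STR motifs of similar length are compared exactly
#' only (so e.g. CAG and CGG, or unrelated 5 bp and 6 bp units, never
#' match).  Symmetric in its arguments.
#'
#' @param detected,target DNA motif strings.
#' @param params [tr_params()].
#' @return TRUE or FALSE.
#' @examples
#' motifs_match("GCA", "CAG")  # rotation
#' motifs_match("CAG", "CGG")  # FALSE
#' @export
motifs_match <- function(detected, target, params = tr_params()) {
  params <- as_params(params)
  detected <- toupper(detected); target <- toupper(target)
  if (!grepl("^[ACGT]+$", detected) || !grepl("^[ACGT]+$", target))
    stop("motifs must be ACGT strings")
  if (canonical_motif(detected) == canonical_motif(target)) return(TRUE)
  n1 <- nchar(detected); n2 <- nchar(target)
  if (max(n1, n2) <= 6L && max(n1, n2) < 2L * min(n1, n2)) return(FALSE)
  shorter <- if (nchar(detected) <= nchar(target)) detected else target
  longer <- if (nchar(detected) <= nchar(target)) target else detected
  for (cand in c(shorter, revcomp(shorter))) {
    al <- wrap_align_cpp(longer, cand, params$wrap_match,
                         params$wrap_mismatch, params$wrap_indel)
    if (al$cols == 0L) next
    identity <- al$matches / al$cols
    coverage <- (al$end - al$start) / nchar(longer)
    if (identity >= params$motif_match_min_identity &&
        coverage >= params$motif_match_min_cov) return(TRUE)
  }
  FALSE
}
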