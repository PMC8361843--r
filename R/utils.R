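# Low-level sequence, CIGAR and reference helpers shared across modules.

CIGAR_RE <- "\\d+[MIDNSHP=X]"
READ_OPS <- c("M", "=", "X", "I", "S")
REF_OPS <- c("M", "=", "X", "D", "N")
ALN_OPS <- c("M", "=", "X")

#' Parse a CIGAR string into op/length runs
#'
#' @param cigar a single CIGAR string (e.g. `"5S20M3I10M2H"`).
#' @return A list with character vector `op` and integer vector `len`.
#' @examples
#' cigar_ops("5S20M3I10M2H")
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(list(op = character(0), len = integer(0)))
  toks <- regmatches(cigar, gregexpr(CIGAR_RE, cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

cigar_runs_to_string <- function(op, len) {
  keep <- len > 0L
  paste0(len[keep], op[keep], collapse = "")
}

# summary statistics for a vector of CIGAR strings
cigar_stats <- function(cigars) {
  n <- length(cigars)
  out <- data.frame(read_consumed = integer(n), ref_consumed = integer(n),
                    left_clip = integer(n), right_clip = integer(n),
                    read_len = integer(n))
  for (i in seq_len(n)) {
    co <- cigar_ops(cigars[i])
    op <- co$op; len <- co$len
    k <- length(op)
    lc <- 0L; rc <- 0L
    j <- 1L
    while (j <= k && op[j] %in% c("S", "H")) { lc <- lc + len[j]; j <- j + 1L }
    j <- k
    while (j >= 1L && op[j] %in% c("S", "H")) { rc <- rc + len[j]; j <- j - 1L }
    if (k >= 2L && all(op %in% c("S", "H"))) { rc <- 0L }  # degenerate
    out$read_consumed[i] <- sum(len[op %in% READ_OPS])
    out$ref_consumed[i] <- sum(len[op %in% REF_OPS])
    out$left_clip[i] <- lc
    out$right_clip[i] <- rc
    # total read length including hard clips
    out$read_len[i] <- sum(len[op %in% READ_OPS]) + sum(len[op == "H"])
  }
  out
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' Uniform i.i.d. bases; uses the current RNG state.
#'
#' @param n length in bp.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Fetch a reference subsequence
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or a path
#' to a FASTA file.  Coordinates are 0-based half-open.
#'
#' @param reference reference genome in any of the accepted forms.
#' @param chrom sequence name.
#' @param start,end 0-based half-open interval; clamped to the sequence.
#' @return The subsequence as an upper-case character string.
#' @export
ref_fetch <- function(reference, chrom, start, end) {
  seqs <- as_reference(reference)
  if (!chrom %in% names(seqs))
    stop("sequence not found in reference: ", chrom)
  s <- seqs[[chrom]]
  L <- nchar(s)
  start <- max(0L, as.integer(start))
  end <- min(L, as.integer(end))
  if (end <= start) return("")
  toupper(substr(s, start + 1L, end))
}

# normalise any accepted reference form to a named character vector
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(setNames(as.character(ss), names(ss)))
  }
  if (inherits(reference, "DNAStringSet"))
    return(setNames(as.character(reference), names(reference)))
  if (is.character(reference)) {
    if (is.null(names(reference)))
      stop("character reference must be named by sequence")
    return(reference)
  }
  stop("unsupported reference type: ", class(reference)[1])
}

reference_lengths <- function(reference) {
  seqs <- as_reference(reference)
  setNames(nchar(seqs), names(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Wraparound repeat alignment
#'
#' Locally aligns `seq` against an unbounded tandem concatenation of `motif`
#' (wraparound dynamic programming), the scoring primitive behind
#' [find_repeats()].  Scores default to +1 match, -1 mismatch, -2 indel.
#'
#' @param seq query DNA string.
#' @param motif repeat unit.
#' @param params [tr_params()] (supplies the scores).
#' @return A list with `start`, `end` (0-based half-open in `seq`), `score`,
#'   `matches` and `cols` (aligned columns); `purity = matches / cols`.
#' @examples
#' wrap_align("TTACACACACTT", "AC")
#' @export
wrap_align <- function(seq, motif, params = tr_params()) {
  params <- as_params(params)
  wrap_align_cpp(toupper(seq), toupper(motif),
                 params$wrap_match, params$wrap_mismatch, params$wrap_indel)
}

# local alignment of a short probe inside a subject; returns NULL when the
# subject is empty, otherwise score/identity/coverage and subject coordinates
# (0-based half-open).  `unique_check` re-aligns with the best placement
# masked and reports whether an equally good second placement exists.
local_probe <- function(probe, subject, unique_check = FALSE) {
  if (nchar(subject) == 0L || nchar(probe) == 0L) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(pattern = probe, subject = subject,
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 2, gapExtension = 1)
  al_len <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  pr <- pa@pattern@range
  sr <- pa@subject@range
  res <- list(
    score = Biostrings::score(pa),
    identity = if (al_len > 0) nm / al_len else 0,
    coverage = (BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1) /
      nchar(probe),
    sub_start = BiocGenerics::start(sr) - 1L,
    sub_end = BiocGenerics::end(sr),
    pat_start = BiocGenerics::start(pr) - 1L,
    pat_end = BiocGenerics::end(pr),
    ambiguous = FALSE
  )
  if (unique_check && res$score > 0) {
    masked <- subject
    substr(masked, res$sub_start + 1L, res$sub_end) <-
      strrep("N", res$sub_end - res$sub_start)
    pa2 <- Biostrings::pairwiseAlignment(pattern = probe, subject = masked,
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1)
    if (Biostrings::score(pa2) >= res$score) res$ambiguous <- TRUE
  }
  res
}

# 0-based half-open interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
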