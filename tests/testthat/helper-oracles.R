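# Independent re-implementations used as oracles.  They deliberately share
# no code with the package: the wraparound aligner is re-done in plain R,
# insertion extraction walks an expanded per-base op string, and the error
# log replayer reconstructs a mutated read from the clean read.

# plain-R wraparound local alignment (same contract as wrap_align_cpp:
# +match/-mismatch/-indel, local, ties toward earliest start then end)
r_wrap_align <- function(seq, motif, match = 1, mismatch = -1, indel = -2) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  n <- length(s); p <- length(m)
  if (n == 0L || p == 0L)
    return(list(start = 0L, end = 0L, score = 0L, matches = 0L, cols = 0L))
  mk <- function(sc, st, ma, co) list(s = sc, start = st, match = ma, cols = co)
  prev <- replicate(p, mk(0L, 0L, 0L, 0L), simplify = FALSE)
  best <- mk(0L, 0L, 0L, 0L); best_end <- 0L
  for (i in seq_len(n)) {
    cur <- vector("list", p)
    for (j in seq_len(p)) {
      jw <- if (j == 1L) p else j - 1L
      is_match <- s[i] == m[j] && s[i] %in% c("A", "C", "G", "T")
      cand <- mk(0L, i, 0L, 0L)  # empty cell: segment would begin at offset i
      d <- prev[[jw]]
      v <- d$s + (if (is_match) match else mismatch)
      if (v > cand$s) cand <- mk(v, d$start, d$match + is_match, d$cols + 1L)
      u <- prev[[j]]
      if (u$s + indel > cand$s) cand <- mk(u$s + indel, u$start, u$match, u$cols + 1L)
      if (j > 1L) {
        l <- cur[[j - 1L]]
        if (l$s + indel > cand$s) cand <- mk(l$s + indel, l$start, l$match, l$cols + 1L)
      }
      cur[[j]] <- cand
    }
    for (sweep in 1:2) {
      for (j in seq_len(p)) {
        jw <- if (j == 1L) p else j - 1L
        l <- cur[[jw]]
        if (l$s + indel > cur[[j]]$s)
          cur[[j]] <- mk(l$s + indel, l$start, l$match, l$cols + 1L)
      }
    }
    for (j in seq_len(p)) {
      if (cur[[j]]$s > best$s) { best <- cur[[j]]; best_end <- i }
    }
    prev <- cur
  }
  list(start = best$start, end = best_end, score = best$s,
       matches = best$match, cols = best$cols)
}

# exhaustive repeat search oracle for short strings: every substring motif,
# rotation-deduplicated, primitive units only, scored by r_wrap_align over
# the whole string; same acceptance thresholds and the same published
# redundancy contract, re-coded independently
oracle_find_repeats <- function(seq, params = trexr::tr_params()) {
  n <- nchar(seq)
  hits <- list()
  seen <- character(0)
  for (p in params$motif_len_min:min(params$motif_len_max, n %/% 2L)) {
    for (i in seq_len(n - p + 1L)) {
      motif <- substr(seq, i, i + p - 1L)
      if (!grepl("^[ACGT]+$", motif)) next
      # primitive unit only
      is_primitive <- TRUE
      for (d in seq_len(p - 1L)) {
        if (p %% d == 0L && strrep(substr(motif, 1L, d), p %/% d) == motif) {
          is_primitive <- FALSE; break
        }
      }
      if (!is_primitive) next
      rots <- vapply(seq_len(p), function(k)
        substr(paste0(motif, motif), k, k + p - 1L), "")
      key <- min(rots)
      if (key %in% seen) next
      seen <- c(seen, key)
      al <- r_wrap_align(seq, motif, params$wrap_match, params$wrap_mismatch,
                         params$wrap_indel)
      if (al$score < params$min_repeat_score) next
      if (al$end - al$start < 2L * p) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif = trexr::canonical_motif(motif), start = al$start, end = al$end,
        copy_number = (al$end - al$start) / p,
        purity = al$matches / al$cols, score = al$score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), copy_number = numeric(0),
                      purity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  cands <- do.call(rbind, hits)
  ord <- order(-(cands$score - nchar(cands$motif)), nchar(cands$motif),
               cands$motif, cands$start)
  cands <- cands[ord, , drop = FALSE]
  kept <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in which(kept)) {
      ov <- max(0, min(cands$end[i], cands$end[j]) -
                  max(cands$start[i], cands$start[j]))
      if (ov <= 0) next
      if (cands$motif[j] == cands$motif[i]) { ok <- FALSE; break }
      shorter <- min(cands$end[i] - cands$start[i],
                     cands$end[j] - cands$start[j])
      if (ov >= 0.5 * shorter &&
          trexr::motifs_match(cands$motif[i], cands$motif[j], params)) {
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

# expand a CIGAR into one op character per column and walk it to find
# insertions (independent of the package's run-based walker)
oracle_cigar_insertions <- function(ref_start, cigar, seq, min_len) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ops <- unlist(lapply(toks, function(t) {
    rep(substr(t, nchar(t), nchar(t)), as.integer(substr(t, 1, nchar(t) - 1L)))
  }))
  read_pos <- 0L; ref_pos <- ref_start
  out <- list()
  k <- 1L
  while (k <= length(ops)) {
    op <- ops[k]
    j <- k
    while (j < length(ops) && ops[j + 1L] == op) j <- j + 1L
    len <- j - k + 1L
    if (op == "I" && len >= min_len) {
      out[[length(out) + 1L]] <- list(
        ref_pos = ref_pos,
        ins_seq = substr(seq, read_pos + 1L, read_pos + len),
        read_start = read_pos, read_end = read_pos + len)
    }
    if (op %in% c("M", "=", "X", "I", "S")) read_pos <- read_pos + len
    if (op %in% c("M", "=", "X", "D", "N")) ref_pos <- ref_pos + len
    k <- j + 1L
  }
  out
}

# replay an error log onto the clean read (offsets are original-read
# coordinates; "del" drops the base, "ins" keeps it and appends `base`,
# "sub" replaces it with `base`)
apply_error_log <- function(read0, log) {
  bases <- strsplit(read0, "")[[1]]
  out <- vector("list", length(bases))
  for (i in seq_along(bases)) out[[i]] <- bases[i]
  for (i in seq_len(nrow(log))) {
    off <- log$offset[i] + 1L
    if (log$op[i] == "del") out[[off]] <- character(0)
    else if (log$op[i] == "ins") out[[off]] <- c(bases[off], log$base[i])
    else if (log$op[i] == "sub") out[[off]] <- log$base[i]
  }
  paste(unlist(out), collapse = "")
}

# reconstruct the reference-consistent check of an alignment record: every
# M column of the CIGAR must match the reference base when the read was
# simulated without errors
check_record_against_ref <- function(rec, reference) {
  ref <- trexr::ref_fetch(reference, rec$ref_name, rec$ref_start,
                          rec$ref_start + 10^9)
  toks <- regmatches(rec$cigar, gregexpr("\\d+[MIDNSHP=X]", rec$cigar))[[1]]
  read_pos <- 0L; ref_pos <- 0L
  for (t in toks) {
    op <- substr(t, nchar(t), nchar(t))
    len <- as.integer(substr(t, 1, nchar(t) - 1L))
    if (op %in% c("M", "=", "X")) {
      if (substr(rec$seq, read_pos + 1L, read_pos + len) !=
          substr(ref, ref_pos + 1L, ref_pos + len)) return(FALSE)
      read_pos <- read_pos + len; ref_pos <- ref_pos + len
    } else if (op %in% c("I", "S")) {
      read_pos <- read_pos + len
    } else if (op %in% c("D", "N")) {
      ref_pos <- ref_pos + len
    }
  }
  TRUE
}

# small toy single-locus bundle used across tests
toy_locus_bundle <- function(motif = "CAG", ref_copies = 20L, flank = 3000L,
                             contig = "ctg") {
  ref <- setNames(paste0(trexr::random_dna(flank), strrep(motif, ref_copies),
                         trexr::random_dna(flank)), contig)
  locus <- trexr:::tr_loci_frame(
    chrom = contig, start = flank,
    end = flank + nchar(motif) * ref_copies, motifs = motif,
    source = "annotation")
  list(reference = ref, locus = locus, motif = motif)
}

# simple independent per-base mutator (sub/ins/del equally likely at `rate`)
mutate_dna_simple <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (b in bases) {
    u <- runif(1)
    if (u < rate / 3) next                                  # deletion
    if (u < 2 * rate / 3) {                                 # insertion
      out <- c(out, b, sample(c("A", "C", "G", "T"), 1))
    } else if (u < rate) {                                  # substitution
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), b), 1))
    } else out <- c(out, b)
  }
  paste(out, collapse = "")
}
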