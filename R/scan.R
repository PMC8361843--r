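# Genome-scan stage: extract large insertions from single alignments (CIGAR
# I ops) and from split alignments (paired records close on the reference,
# far apart on the read), merge nearby events, keep clusters whose insertion
# sequences are predominantly one tandem repeat, and delineate the reference
# TR locus around each cluster.

#' Insertions encoded in one alignment's CIGAR
#'
#' One candidate event per `I` op of length `>= min_ins_size`.  The event is
#' anchored at the reference coordinate immediately left of the insertion.
#'
#' @param rec one alignment record (a one-row data frame or list with
#'   `read_id`, `ref_name`, `ref_start`, `cigar`, `seq`).
#' @param params [tr_params()].
#' @return Data frame of insertion events: `read_id`, `ref_name`, `ref_pos`,
#'   `ins_seq`, `source = "cigar"`, `read_start`, `read_end` (0-based
#'   half-open coordinates in the stored read sequence).
#' @export
insertions_from_cigar <- function(rec, params = tr_params()) {
  params <- as_params(params)
  if (is.na(rec$seq)) stop("record has no sequence; cannot extract insertions")
  co <- cigar_ops(rec$cigar)
  op <- co$op; len <- co$len
  read_adv <- ifelse(op %in% READ_OPS, len, 0L)
  ref_adv <- ifelse(op %in% REF_OPS, len, 0L)
  read_off <- cumsum(c(0L, read_adv))[seq_along(op)]
  ref_off <- cumsum(c(0L, ref_adv))[seq_along(op)]
  idx <- which(op == "I" & len >= params$min_ins_size)
  if (!length(idx)) return(events_frame())
  events_frame(
    read_id = rep(rec$read_id, length(idx)),
    ref_name = rep(rec$ref_name, length(idx)),
    ref_pos = rec$ref_start + ref_off[idx],
    ins_seq = substring(rec$seq, read_off[idx] + 1L, read_off[idx] + len[idx]),
    source = rep("cigar", length(idx)),
    read_start = read_off[idx],
    read_end = read_off[idx] + len[idx]
  )
}

events_frame <- function(read_id = character(0), ref_name = character(0),
                         ref_pos = integer(0), ins_seq = character(0),
                         source = character(0), read_start = integer(0),
                         read_end = integer(0)) {
  data.frame(read_id = read_id, ref_name = ref_name,
             ref_pos = as.integer(ref_pos), ins_seq = ins_seq,
             source = source, read_start = as.integer(read_start),
             read_end = as.integer(read_end), stringsAsFactors = FALSE)
}

# read-space span of a record on the original read strand, plus aligned
# reference span (0-based half-open)
split_geometry <- function(recs) {
  cs <- cigar_stats(recs$cigar)
  aligned <- mapply(function(cig) {
    co <- cigar_ops(cig)
    sum(co$len[co$op %in% c("M", "=", "X", "I")])
  }, recs$cigar)
  total <- cs$read_len
  stored_start <- cs$left_clip
  read_start <- ifelse(recs$strand == "+", stored_start,
                       total - (stored_start + aligned))
  data.frame(read_start = as.integer(read_start),
             read_end = as.integer(read_start + aligned),
             stored_start = as.integer(stored_start),
             stored_end = as.integer(stored_start + aligned),
             total = as.integer(total))
}

#' Insertions implied by split alignments of one read
#'
#' Adjacent (in read order) same-chromosome, same-strand alignment pairs
#' whose reference positions are close (`|gap| <= split_max_ref_gap`) while
#' their read positions are far apart indicate an insertion the aligner did
#' not represent in a single record.  The event length is
#' `read_gap - max(ref_gap, 0)`, anchored at the earlier alignment's
#' reference end (the left-hand reference breakpoint).
#'
#' @param recs alignment records of one read (data frame; all rows share
#'   `read_id`).
#' @param params [tr_params()].
#' @return Data frame of insertion events with `source = "split"`.
#' @export
insertions_from_splits <- function(recs, params = tr_params()) {
  params <- as_params(params)
  if (length(unique(recs$read_id)) > 1L)
    stop("records from multiple reads passed to insertions_from_splits")
  if (nrow(recs) < 2L) return(events_frame())
  geo <- split_geometry(recs)
  if (length(unique(geo$total)) > 1L)
    stop("inconsistent read lengths across split records of one read: ",
         recs$read_id[1])
  ord <- order(geo$read_start)
  recs <- recs[ord, , drop = FALSE]
  geo <- geo[ord, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(recs) - 1L)) {
    a <- i; b <- i + 1L
    if (recs$ref_name[a] != recs$ref_name[b]) next
    if (recs$strand[a] != recs$strand[b]) next
    fwd <- recs$strand[a] == "+"
    g <- if (fwd) recs$ref_start[b] - recs$ref_end[a]
         else recs$ref_start[a] - recs$ref_end[b]
    d <- geo$read_start[b] - geo$read_end[a]
    if (abs(g) > params$split_max_ref_gap) next
    if (d - g < params$min_ins_size) next
    len <- d - max(g, 0)
    anchor <- if (fwd) recs$ref_end[a] else recs$ref_end[b]
    ins <- extract_split_insertion(recs, geo, a, b, len)
    out[[length(out) + 1L]] <- events_frame(
      read_id = recs$read_id[1], ref_name = recs$ref_name[a],
      ref_pos = anchor, ins_seq = ins$seq, source = "split",
      read_start = ins$start, read_end = ins$start + nchar(ins$seq))
  }
  if (!length(out)) return(events_frame())
  do.call(rbind, out)
}

# pull the inserted bases (stored orientation) for a split pair; any record
# of the read whose stored sequence covers the gap will do
extract_split_insertion <- function(recs, geo, a, b, len) {
  o_start <- geo$read_end[a]            # original-strand coords
  o_end <- o_start + len
  for (i in c(a, b)) {
    if (is.na(recs$seq[i])) next
    tot <- geo$total[i]
    if (nchar(recs$seq[i]) != tot) next  # hard-clipped partial sequence
    if (recs$strand[i] == "+") {
      s <- o_start; e <- o_end
    } else {
      s <- tot - o_end; e <- tot - o_start
    }
    return(list(seq = substr(recs$seq[i], s + 1L, e), start = s))
  }
  list(seq = strrep("N", len), start = NA_integer_)
}

#' Merge nearby insertion events into clusters
#'
#' Single-linkage clustering on the reference anchor with gap
#' `<= merge_window`; within a cluster each read contributes its largest
#' event; clusters supported by fewer than `min_support` distinct reads are
#' dropped.
#'
#' @param events event data frame (rows as produced by
#'   [insertions_from_cigar()] / [insertions_from_splits()]).
#' @param params [tr_params()].
#' @return A list of event data frames (one per retained cluster), ordered
#'   by position.
#' @export
merge_events <- function(events, params = tr_params()) {
  params <- as_params(params)
  if (is.null(events) || !nrow(events)) return(list())
  events <- events[order(events$ref_name, events$ref_pos), , drop = FALSE]
  newc <- c(TRUE, events$ref_name[-1] != events$ref_name[-nrow(events)] |
              diff(events$ref_pos) > params$merge_window)
  cl <- cumsum(newc)
  out <- lapply(split(events, cl), function(df) {
    # one event per read: keep the largest insertion
    df <- df[order(-nchar(df$ins_seq)), , drop = FALSE]
    df <- df[!duplicated(df$read_id), , drop = FALSE]
    df[order(df$ref_pos), , drop = FALSE]
  })
  out <- out[vapply(out, function(df)
    length(unique(df$read_id)) >= params$min_support, TRUE)]
  names(out) <- NULL
  out
}

#' Tandem-repeat purity filter for an event cluster
#'
#' Runs [find_repeats()] + [tract_purity()] on every insertion sequence;
#' events pass when a single motif covers at least `insertion_purity_min` of
#' the insertion.  The cluster survives when at least `min_support` passing
#' events agree on a matching motif ([motifs_match()]); the majority
#' canonical motif is returned with the surviving events.
#'
#' @param cluster event data frame (one cluster from [merge_events()]).
#' @param params [tr_params()].
#' @return `list(events, motif)` or NULL when the cluster is dropped.
#' @export
filter_by_purity <- function(cluster, params = tr_params()) {
  params <- as_params(params)
  if (is.null(cluster) || !nrow(cluster)) return(NULL)
  motifs <- character(nrow(cluster))
  pur <- numeric(nrow(cluster))
  for (i in seq_len(nrow(cluster))) {
    hits <- find_repeats(cluster$ins_seq[i], params)
    if (!nrow(hits)) next
    cov <- vapply(split(seq_len(nrow(hits)), hits$motif), function(idx)
      sum(hits$end[idx] - hits$start[idx]), 0)
    best <- names(cov)[which.max(cov)]
    motifs[i] <- best
    pur[i] <- tract_purity(cluster$ins_seq[i],
                           hits[hits$motif == best, , drop = FALSE])
  }
  pass <- pur >= params$insertion_purity_min & nzchar(motifs)
  if (sum(pass) < params$min_support) return(NULL)
  pm <- motifs[pass]
  # majority canonical motif among passing events (ties: most frequent, then
  # lexicographic)
  tab <- sort(table(pm), decreasing = TRUE)
  major <- names(tab)[1]
  agree <- pass
  agree[pass] <- vapply(pm, function(m) motifs_match(m, major, params), TRUE)
  if (sum(agree) < params$min_support) return(NULL)
  list(events = cluster[agree, , drop = FALSE], motif = major)
}

#' Delineate the reference TR locus behind an insertion cluster
#'
#' Runs [find_repeats()] on the reference neighbourhood (`scan_window` bp
#' each side of the anchor) and returns the tract overlapping -- or, failing
#' that, nearest to -- the anchor whose motif matches the insertion motif.
#' When no reference tract matches, the cluster has no locus (reference
#' motif concordance is required) and NULL is returned.
#'
#' @param chrom,anchor_pos reference anchor of the cluster.
#' @param motif insertion motif (canonical or not).
#' @param reference reference genome (see [ref_fetch()]).
#' @param params [tr_params()].
#' @return A one-row `tr_loci` data frame, or NULL.
#' @export
delineate_locus <- function(chrom, anchor_pos, motif, reference,
                            params = tr_params()) {
  params <- as_params(params)
  lens <- reference_lengths(reference)
  if (!chrom %in% names(lens)) stop("unknown reference sequence: ", chrom)
  if (anchor_pos < 0 || anchor_pos > lens[[chrom]])
    stop("anchor outside reference bounds: ", chrom, ":", anchor_pos)
  w0 <- max(0L, anchor_pos - params$scan_window)
  w1 <- min(lens[[chrom]], anchor_pos + params$scan_window)
  win <- ref_fetch(reference, chrom, w0, w1)
  hits <- find_repeats(win, params)
  if (!nrow(hits)) return(NULL)
  ok <- vapply(hits$motif, function(m) motifs_match(m, motif, params), TRUE)
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  gs <- w0 + hits$start
  ge <- w0 + hits$end
  dist <- ifelse(anchor_pos >= gs & anchor_pos <= ge, 0L,
                 pmin(abs(anchor_pos - gs), abs(anchor_pos - ge)))
  i <- which.min(dist)
  # trim to the outermost exact motif copies: the local alignment may extend
  # a few score-neutral-or-better bases into flanking sequence, but the
  # reference tract boundary is defined by the exact copies
  tb <- trim_to_exact_copies(substr(win, hits$start[i] + 1L, hits$end[i]),
                             hits$motif[i])
  if (is.null(tb)) return(NULL)
  # the double-copy anchors can stop one partial copy short of the true
  # tract boundary; extend to the maximal run of the period so the locus
  # covers the whole reference tract (expansion insertions in spanning
  # reads anchor at the tract edge, which must fall inside the locus)
  ext <- extend_period_run(reference, chrom, lens[[chrom]],
                           gs[i] + tb[1], gs[i] + tb[2],
                           nchar(hits$motif[i]))
  tr_loci_frame(chrom = chrom, start = ext[1], end = ext[2],
                motifs = canonical_motif(motif), source = "scan",
                support_events = NA_integer_)
}

# [start, end) of the region from the first to the last exact double copy
# (two tandem copies, so chance occurrences in flanking sequence are rare)
# of any rotation of `motif` (either strand) in `seq`; NULL when none occurs
trim_to_exact_copies <- function(seq, motif) {
  p <- nchar(motif)
  d <- paste0(motif, motif)
  rots <- unique(vapply(seq_len(p), function(k) substr(d, k, k + p - 1L), ""))
  rots <- unique(c(rots, revcomp(rots)))
  first <- Inf; last <- -Inf
  for (r in rots) {
    m <- gregexpr(strrep(r, 2L), seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    first <- min(first, m[1] - 1L)
    last <- max(last, m[length(m)] - 1L + 2L * p)
  }
  if (!is.finite(first)) return(NULL)
  c(as.integer(first), as.integer(last))
}

# extend [start, end) (0-based, global) outward while the reference keeps
# repeating with period p (base at i equals base at i - p); extension is
# capped -- chance continuations into flanking sequence die off geometrically
extend_period_run <- function(reference, chrom, contig_len, start, end, p,
                              cap = 4L * p + 16L) {
  pad_lo <- max(0L, start - cap - p)
  pad_hi <- min(contig_len, end + cap)
  s <- ref_fetch(reference, chrom, pad_lo, pad_hi)
  b <- function(i) substr(s, i - pad_lo + 1L, i - pad_lo + 1L)  # 0-based base
  e0 <- end
  while (end < pad_hi && end - e0 < cap && b(end) == b(end - p))
    end <- end + 1L
  s0 <- start
  while (start > pad_lo + p && s0 - start < cap &&
         b(start - 1L) == b(start - 1L + p))
    start <- start - 1L
  c(as.integer(start), as.integer(end))
}

#' Genome-scan for candidate TR expansion loci
#'
#' Full scan stage: extract insertion events from all alignments (CIGAR and
#' split), skip events anchored in `exclude_regions`, merge, filter by
#' tandem-repeat purity, and delineate the reference locus of every
#' surviving cluster.  Output loci are deduplicated (overlapping loci: most
#' supporting events wins, ties to the leftmost) and sorted; they feed
#' directly into [genotype_loci()].
#'
#' @param alignments alignment record data frame (from [read_alignments()])
#'   or a SAM/BAM path.
#' @param reference reference genome (see [ref_fetch()]).
#' @param exclude_regions optional data frame `chrom`,`start`,`end`
#'   (0-based half-open) of regions to bypass.
#' @param params [tr_params()].
#' @return A `tr_loci` data frame with `source = "scan"` and
#'   `support_events` filled in.
#' @export
genome_scan <- function(alignments, reference, exclude_regions = NULL,
                        params = tr_params()) {
  params <- as_params(params)
  if (is.character(alignments))
    alignments <- read_alignments(alignments, params = params)
  ev <- list()
  with_seq <- which(!is.na(alignments$seq))
  for (i in with_seq) {
    e <- insertions_from_cigar(alignments[i, , drop = FALSE], params)
    if (nrow(e)) ev[[length(ev) + 1L]] <- e
  }
  multi <- names(which(table(alignments$read_id) > 1L))
  for (rid in multi) {
    recs <- alignments[alignments$read_id == rid, , drop = FALSE]
    e <- insertions_from_splits(recs, params)
    if (nrow(e)) ev[[length(ev) + 1L]] <- e
  }
  events <- if (length(ev)) do.call(rbind, ev) else events_frame()
  if (!is.null(exclude_regions) && nrow(events)) {
    drop <- rep(FALSE, nrow(events))
    for (j in seq_len(nrow(exclude_regions))) {
      drop <- drop | (events$ref_name == exclude_regions$chrom[j] &
                        events$ref_pos >= exclude_regions$start[j] &
                        events$ref_pos < exclude_regions$end[j])
    }
    events <- events[!drop, , drop = FALSE]
  }
  clusters <- merge_events(events, params)
  loci <- list()
  for (cl in clusters) {
    fp <- filter_by_purity(cl, params)
    if (is.null(fp)) next
    anchor <- as.integer(round(median(fp$events$ref_pos)))
    loc <- delineate_locus(cl$ref_name[1], anchor, fp$motif, reference,
                           params)
    if (is.null(loc)) next
    loc$support_events <- nrow(fp$events)
    loci[[length(loci) + 1L]] <- loc
  }
  if (!length(loci)) return(tr_loci_frame())
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
  # deduplicate overlapping loci: keep the better-supported, ties leftmost
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(loci))) {
      if (i == j || !keep[j]) next
      if (loci$chrom[i] != loci$chrom[j]) next
      if (interval_overlap(loci$start[i], loci$end[i],
                           loci$start[j], loci$end[j]) > 0L) {
        si <- loci$support_events[i]; sj <- loci$support_events[j]
        if (sj > si || (sj == si && j < i)) keep[i] <- FALSE
      }
    }
  }
  loci <- loci[keep, , drop = FALSE]
  rownames(loci) <- NULL
  class(loci) <- c("tr_loci", "data.frame")
  loci
}
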