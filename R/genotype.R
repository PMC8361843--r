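# Genotyping stage: per-read repeat tract extraction at target loci (CIGAR
# walk between the flanking nucleotides, with flank rescue of clipped reads),
# repeat sizing via find_repeats, and allele clustering by 1-D Gaussian
# mixture with AIC model selection.

# per-run summary of aligned (M/=/X) blocks of a record, in reference and
# stored-read coordinates (both 0-based half-open)
aligned_blocks <- function(rec) {
  co <- cigar_ops(rec$cigar)
  op <- co$op; len <- co$len
  read_adv <- ifelse(op %in% READ_OPS, len, 0L)
  ref_adv <- ifelse(op %in% REF_OPS, len, 0L)
  read_off <- cumsum(c(0L, read_adv))
  ref_off <- cumsum(c(0L, ref_adv))
  i <- which(op %in% ALN_OPS)
  data.frame(ref_start = rec$ref_start + ref_off[i],
             ref_end = rec$ref_start + ref_off[i] + len[i],
             read_start = read_off[i],
             read_end = read_off[i] + len[i])
}

#' Read-coordinate interval of a locus within a spanning read
#'
#' Maps the locus boundaries to read coordinates through the CIGAR: the
#' interval runs from the base following the last aligned base left of the
#' locus start to the first aligned base at or beyond the locus end, so any
#' insertion inside the locus is included.  Both flanks must be anchored by
#' at least `min_flank_anchor` aligned bases; otherwise NULL is returned and
#' the read is a candidate for clip rescue.
#'
#' @param rec one alignment record.
#' @param locus one-row `tr_loci` data frame (or list with `start`, `end`).
#' @param params [tr_params()].
#' @return `c(start, end)` (0-based half-open in the stored read sequence)
#'   or NULL.
#' @export
extract_read_tract <- function(rec, locus, params = tr_params()) {
  params <- as_params(params)
  if (is.na(rec$seq)) return(NULL)
  ab <- aligned_blocks(rec)
  if (!nrow(ab)) return(NULL)
  left_anchor <- sum(interval_overlap(ab$ref_start, ab$ref_end,
                                      -Inf, locus$start))
  right_anchor <- sum(interval_overlap(ab$ref_start, ab$ref_end,
                                       locus$end, Inf))
  if (left_anchor < params$min_flank_anchor ||
      right_anchor < params$min_flank_anchor) return(NULL)
  lb <- ab[ab$ref_start < locus$start, , drop = FALSE]
  r_left <- max(lb$read_start + pmin(lb$ref_end, locus$start) - lb$ref_start)
  rb <- ab[ab$ref_end > locus$end, , drop = FALSE]
  r_right <- min(rb$read_start + pmax(locus$end - rb$ref_start, 0L))
  if (r_right < r_left) return(NULL)
  c(start = as.integer(r_left), end = as.integer(r_right))
}

#' Rescue a repeat boundary from a clipped read
#'
#' When a read's alignment stops at one side of the locus (the repeat and the
#' far flank live in the soft clip, as happens with long expansions and split
#' alignments), the missing boundary is recovered by locally aligning a short
#' stretch (`rescue_flank_len`, 80 bp) of reference sequence immediately
#' up- or downstream of the locus into the clipped read sequence.  Success
#' requires a unique best placement with at least `rescue_min_identity`
#' identity over `rescue_min_cov` of the flank; the CIGAR-anchored side must
#' still satisfy `min_flank_anchor`.
#'
#' @param rec one alignment record (clipped on the side facing the locus).
#' @param locus one-row `tr_loci` data frame.
#' @param reference reference genome (see [ref_fetch()]).
#' @param params [tr_params()].
#' @return `c(start, end)` read interval, or NULL when rescue fails.
#' @export
rescue_clipped <- function(rec, locus, reference, params = tr_params()) {
  params <- as_params(params)
  if (is.na(rec$seq)) return(NULL)
  ab <- aligned_blocks(rec)
  if (!nrow(ab)) return(NULL)
  left_anchor <- sum(interval_overlap(ab$ref_start, ab$ref_end,
                                      -Inf, locus$start))
  right_anchor <- sum(interval_overlap(ab$ref_start, ab$ref_end,
                                       locus$end, Inf))
  fl <- params$rescue_flank_len
  seq_len_ <- nchar(rec$seq)
  soft_left <- min(rec$left_clip, seq_len_)    # hard clips have no bases
  soft_right <- min(rec$right_clip, seq_len_)

  if (left_anchor >= params$min_flank_anchor &&
      right_anchor < params$min_flank_anchor && soft_right > 0L) {
    # repeat continues into the right clip; find downstream flank inside it
    lb <- ab[ab$ref_start < locus$start, , drop = FALSE]
    if (!nrow(lb)) return(NULL)
    r_left <- max(lb$read_start + pmin(lb$ref_end, locus$start) - lb$ref_start)
    clip0 <- seq_len_ - soft_right
    clip <- substr(rec$seq, clip0 + 1L, seq_len_)
    probe <- ref_fetch(reference, locus$chrom, locus$end, locus$end + fl)
    hit <- rescue_hit(probe, clip, params)
    if (is.null(hit)) return(NULL)
    r_right <- clip0 + hit$sub_start
    if (r_right < r_left) return(NULL)
    return(c(start = as.integer(r_left), end = as.integer(r_right)))
  }
  if (right_anchor >= params$min_flank_anchor &&
      left_anchor < params$min_flank_anchor && soft_left > 0L) {
    rb <- ab[ab$ref_end > locus$end, , drop = FALSE]
    if (!nrow(rb)) return(NULL)
    r_right <- min(rb$read_start + pmax(locus$end - rb$ref_start, 0L))
    clip <- substr(rec$seq, 1L, soft_left)
    probe <- ref_fetch(reference, locus$chrom,
                       max(0L, locus$start - fl), locus$start)
    hit <- rescue_hit(probe, clip, params)
    if (is.null(hit)) return(NULL)
    r_left <- hit$sub_end
    if (r_right < r_left) return(NULL)
    return(c(start = as.integer(r_left), end = as.integer(r_right)))
  }
  NULL
}

rescue_hit <- function(probe, clip, params) {
  if (!nzchar(probe) || !nzchar(clip)) return(NULL)
  hit <- local_probe(probe, clip, unique_check = TRUE)
  if (is.null(hit) || hit$ambiguous ||
      hit$identity < params$rescue_min_identity ||
      hit$coverage < params$rescue_min_cov) return(NULL)
  hit
}

#' Size the repeat in one extracted read sequence
#'
#' The target motif is known at the genotyping stage, so the tract is sized
#' directly: a wraparound local alignment of the extracted sequence against
#' each target motif (both strands) finds the repeat array, and the repeat
#' size is the aligned span of the best-scoring motif.  The alignment must
#' reach `min_repeat_score` and span at least two motif copies; otherwise
#' NULL is returned (no genotyping result for this read).
#'
#' @param seq extracted read sequence (DNA string).
#' @param motifs character vector of target motifs.
#' @param params [tr_params()].
#' @param offset read coordinate of `seq`'s first base (for reporting).
#' @return A list (`repeat_size`, `copy_number`, `motif`, `purity`,
#'   `read_tract_start`) or NULL.
#' @export
call_read <- function(seq, motifs, params = tr_params(), offset = 0L) {
  params <- as_params(params)
  if (!nzchar(seq)) return(NULL)
  best <- NULL
  for (m in toupper(motifs)) {
    for (mm in unique(c(m, revcomp(m)))) {
      al <- wrap_align_cpp(seq, mm, params$wrap_match, params$wrap_mismatch,
                           params$wrap_indel)
      if (al$score < params$min_repeat_score) next
      if (al$end - al$start < 2L * nchar(mm)) next
      if (is.null(best) || al$score > best$al$score)
        best <- list(al = al, motif = m)
    }
  }
  if (is.null(best)) return(NULL)
  size <- best$al$end - best$al$start
  list(repeat_size = size,
       copy_number = size / nchar(best$motif),
       motif = best$motif,
       purity = best$al$matches / max(1L, best$al$cols),
       read_tract_start = as.integer(offset + best$al$start))
}

#' Fit a genotype from per-read repeat sizes
#'
#' Clusters per-read repeat sizes (bp) with one-dimensional Gaussian
#' mixtures for k = 1..`max_alleles` components and keeps the k with the
#' smallest AIC (ties toward fewer alleles).  Each read is assigned to its
#' maximum-responsibility component; components supported by fewer than
#' `min_support` reads are dropped, components whose means differ by less
#' than `allele_merge_gap` bp are merged, and each allele is reported as the
#' exact median of its members' sizes (and copy numbers), sorted ascending.
#'
#' @param calls data frame of read calls: `read_id`, `repeat_size`,
#'   `copy_number`, `read_tract_start`, `method`.
#' @param params [tr_params()].
#' @param locus,motif locus metadata attached to the result.
#' @return An object of class `tr_genotype`: list with `locus`, `motif`,
#'   `alleles` (size, copy_number, support), `reads` (calls plus allele
#'   assignment), `total_reads`, `k`, `aic`.
#' @export
fit_genotype <- function(calls, params = tr_params(), locus = NULL,
                         motif = NA_character_) {
  params <- as_params(params)
  if (is.null(calls) || !nrow(calls)) stop("no read calls to genotype")
  x <- calls$repeat_size
  n <- length(x)
  kmax <- min(params$max_alleles, n)
  aic <- rep(NA_real_, kmax)
  fits <- vector("list", kmax)
  # k = 1 in closed form (Gaussian MLE)
  mu <- mean(x); s2 <- sum((x - mu)^2) / n
  aic[1] <- if (s2 > 0) 2 * 2 - 2 * sum(dnorm(x, mu, sqrt(s2), log = TRUE))
            else -Inf  # degenerate: all sizes identical, one allele
  fits[[1]] <- list(classification = rep(1L, n), mean = mu)
  # u distinct values with u <= kmax: the u-component mixture is degenerate
  # (zero within-component variance, unbounded likelihood), so it wins
  # outright; components at near-identical sizes are re-merged below
  ux <- sort(unique(x))
  u <- length(ux)
  if (u >= 2L && u <= kmax) {
    aic[u] <- -Inf
    fits[[u]] <- list(classification = match(x, ux), mean = ux)
  }
  if (kmax >= 2L && s2 > 0 && u > kmax) {
    # Mclust() resolves mclustBIC in the calling frame; bind it here
    mclustBIC <- mclust::mclustBIC
    for (k in 2:kmax) {
      fit <- tryCatch(
        suppressWarnings(mclust::Mclust(x, G = k, modelNames = "V",
                                        verbose = FALSE)),
        error = function(e) NULL)
      if (is.null(fit) || is.na(fit$loglik) || !is.finite(fit$loglik)) next
      aic[k] <- 2 * fit$df - 2 * fit$loglik
      fits[[k]] <- list(classification = as.integer(fit$classification),
                        mean = as.numeric(fit$parameters$mean))
    }
  }
  k <- which.min(aic)  # ties and NA: earliest (fewest alleles) wins
  cls <- fits[[k]]$classification
  # merge components with nearly identical means
  means <- tapply(x, cls, mean)
  ord <- order(means)
  grp <- integer(length(ord)); g <- 0L
  for (i in seq_along(ord)) {
    if (i == 1L || means[ord[i]] - means[ord[i - 1L]] >= params$allele_merge_gap)
      g <- g + 1L
    grp[ord[i]] <- g
  }
  comp <- grp[match(cls, as.integer(names(means)))]
  support <- table(comp)
  retained <- as.integer(names(support))[support >= params$min_support]
  allele <- match(comp, sort(retained))  # NA for dropped components
  # order alleles ascending by median size
  med <- vapply(sort(retained), function(cc) median(x[comp == cc]), 0)
  ord2 <- order(med)
  allele <- match(allele, ord2)
  alleles <- data.frame(
    size = vapply(ord2, function(i) median(x[comp == sort(retained)[i]]), 0),
    copy_number = vapply(ord2, function(i)
      median(calls$copy_number[comp == sort(retained)[i]]), 0),
    support = vapply(ord2, function(i)
      sum(comp == sort(retained)[i]), 0L))
  reads <- calls
  reads$allele <- allele
  structure(list(locus = locus, motif = motif, alleles = alleles,
                 reads = reads, total_reads = n, k = length(retained),
                 aic = aic),
            class = "tr_genotype")
}

#' @export
print.tr_genotype <- function(x, ...) {
  loc <- if (!is.null(x$locus))
    sprintf("%s:%d-%d", x$locus$chrom, x$locus$start, x$locus$end)
  else "(no locus)"
  cat(sprintf("TR genotype at %s  motif %s  (%d reads)\n",
              loc, x$motif, x$total_reads))
  if (nrow(x$alleles)) {
    a <- x$alleles
    for (i in seq_len(nrow(a)))
      cat(sprintf("  allele %d: %.1f bp  (%.1f copies, %d reads)\n",
                  i, a$size[i], a$copy_number[i], a$support[i]))
  } else cat("  no allele passed the support filter\n")
  invisible(x)
}

#' @export
summary.tr_genotype <- function(object, ...) {
  print(object)
  cat("AIC by component count:",
      paste(sprintf("%.1f", object$aic), collapse = ", "), "\n")
  invisible(object)
}

#' @export
as.data.frame.tr_genotype <- function(x, ...) genotype_rows(x)

#' Genotype a set of target TR loci
#'
#' For every locus: collect spanning reads ([extract_read_tract()]) and
#' clip-rescued reads ([rescue_clipped()]), size the repeat in each
#' ([call_read()]), and fit the genotype ([fit_genotype()]).  One call per
#' read (the spanning call is preferred over a rescued one).  Loci with no
#' matching read call produce no output.  Reference-sized (unexpanded)
#' alleles are genotyped like any other, so alleles smaller than those found
#' by the scan stage are captured.
#'
#' @param alignments alignment record data frame or SAM/BAM path.
#' @param reference reference genome (see [ref_fetch()]).
#' @param loci `tr_loci` data frame (from [load_loci_bed()] or
#'   [genome_scan()]).
#' @param params [tr_params()].
#' @return An object of class `tr_genotype_set`: a named list of
#'   `tr_genotype`, one per genotyped locus.
#' @export
genotype_loci <- function(alignments, reference, loci,
                          params = tr_params()) {
  params <- as_params(params)
  if (is.character(alignments))
    alignments <- read_alignments(alignments, params = params)
  out <- list()
  for (li in seq_len(nrow(loci))) {
    locus <- loci[li, , drop = FALSE]
    cand <- alignments[alignments$ref_name == locus$chrom &
                         alignments$ref_start <= locus$end &
                         alignments$ref_end >= locus$start, , drop = FALSE]
    if (!nrow(cand)) next
    motifs <- locus_motifs(locus)
    calls <- list()
    for (ri in seq_len(nrow(cand))) {
      rec <- cand[ri, , drop = FALSE]
      iv <- extract_read_tract(rec, locus, params)
      method <- "spanning"
      if (is.null(iv) && (rec$left_clip > 0L || rec$right_clip > 0L)) {
        iv <- rescue_clipped(rec, locus, reference, params)
        method <- "rescued"
      }
      if (is.null(iv)) next
      seq <- substr(rec$seq, iv[["start"]] + 1L, iv[["end"]])
      cr <- call_read(seq, motifs, params, offset = iv[["start"]])
      if (is.null(cr)) next
      calls[[length(calls) + 1L]] <- data.frame(
        read_id = rec$read_id, repeat_size = cr$repeat_size,
        copy_number = cr$copy_number,
        read_tract_start = cr$read_tract_start, method = method,
        stringsAsFactors = FALSE)
    }
    if (!length(calls)) next
    calls <- do.call(rbind, calls)
    # one call per read: spanning preferred, then larger size, then order
    calls <- calls[order(calls$method != "spanning", -calls$repeat_size), ,
                   drop = FALSE]
    calls <- calls[!duplicated(calls$read_id), , drop = FALSE]
    calls <- calls[order(calls$read_id), , drop = FALSE]
    rownames(calls) <- NULL
    g <- fit_genotype(calls, params, locus = as.list(locus),
                      motif = motifs[1])
    out[[sprintf("%s:%d-%d", locus$chrom, locus$start, locus$end)]] <- g
  }
  structure(out, class = "tr_genotype_set")
}

#' @export
print.tr_genotype_set <- function(x, ...) {
  cat(sprintf("TR genotypes at %d locus/loci\n", length(x)))
  for (g in x) print(g)
  invisible(x)
}

#' @export
as.data.frame.tr_genotype_set <- function(x, ...) {
  genotype_rows(unclass(x))
}
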