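# Native long-read simulator for TR expansion experiments: builds modified
# haplotypes (reference TR tract replaced by a chosen number of motif
# copies), emits noisy reads with truth alignments (including split records
# for very long insertions) and truth-encoded read names, so the whole
# pipeline can be evaluated without an external read simulator or aligner.

#' Catalogue of disease-associated STR loci used by the simulation designs
#'
#' Seventeen well-known repeat expansion loci (gene symbol, repeat motif and
#' reference tract length derived from the hg38 coordinates of each locus).
#' The toy references built by [make_experiment()] embed each tract, at its
#' reference length, in random flanking sequence on a contig named after the
#' gene.
#'
#' @return Data frame: `gene`, `motif`, `hg38_chrom`, `hg38_start`,
#'   `hg38_end`, `ref_len` (bp), `ref_copies`.
#' @export
disease_loci <- function() {
  df <- data.frame(
    gene = c("HOXD13", "ATXN7", "HTT", "PPP2R2B", "ATXN1", "HOXA13", "FXN",
             "CBL", "ATXN2", "ATXN8", "ATXN3", "JPH3", "DMPK", "NOP56",
             "CSTB", "ATXN10", "FMR1"),
    motif = c("GGC", "CAG", "CAG", "CTG", "CTG", "CGC", "GAA", "CGG", "CTG",
              "CTG", "CTG", "CTG", "CAG", "GGCCTG", "CGCGGGGCGGGG", "ATTCT",
              "CGG"),
    hg38_chrom = c("chr2", "chr3", "chr4", "chr5", "chr6", "chr7", "chr9",
                   "chr11", "chr12", "chr13", "chr14", "chr16", "chr19",
                   "chr20", "chr21", "chr22", "chrX"),
    hg38_start = c(176093057L, 63912685L, 3074876L, 146878728L, 16327635L,
                   27199924L, 69037286L, 119206289L, 111598950L, 70139383L,
                   92071010L, 87604287L, 45770204L, 2652733L, 43776443L,
                   45795354L, 147912050L),
    hg38_end = c(176093099L, 63912715L, 3074933L, 146878758L, 16327722L,
                 27199966L, 69037304L, 119206322L, 111599019L, 70139428L,
                 92071034L, 87604329L, 45770264L, 2652775L, 43776479L,
                 45795424L, 147912110L),
    stringsAsFactors = FALSE
  )
  df$ref_len <- df$hg38_end - df$hg38_start
  df$ref_copies <- as.integer(round(df$ref_len / nchar(df$motif)))
  df
}

#' Build a modified haplotype sequence
#'
#' Replaces the TR tract at `locus` with `copies` tandem copies of `motif`,
#' recording the coordinate bookkeeping needed to emit truth alignments
#' against the unmodified reference.
#'
#' @param reference reference genome (see [ref_fetch()]).
#' @param locus one-row `tr_loci` data frame (0-based half-open tract).
#' @param motif repeat unit to plant.
#' @param copies number of copies (`>= 0`); `copies * nchar(motif)` is the
#'   haplotype allele size.
#' @return An object of class `tr_haplotype`.
#' @export
build_haplotype <- function(reference, locus, motif, copies) {
  stopifnot(copies >= 0)
  lens <- reference_lengths(reference)
  if (!locus$chrom %in% names(lens) || locus$start < 0 ||
      locus$end > lens[[locus$chrom]] || locus$start >= locus$end)
    stop("locus outside reference bounds")
  L <- lens[[locus$chrom]]
  pre <- ref_fetch(reference, locus$chrom, 0L, locus$start)
  post <- ref_fetch(reference, locus$chrom, locus$end, L)
  tract <- strrep(toupper(motif), copies)
  structure(list(
    name = NULL,
    seq = paste0(pre, tract, post),
    chrom = locus$chrom,
    tract_start = as.integer(locus$start),
    tract_len = nchar(tract),
    ref_tract_start = as.integer(locus$start),
    ref_tract_len = as.integer(locus$end - locus$start),
    motif = toupper(motif),
    copies = as.integer(copies)
  ), class = "tr_haplotype")
}

# ---- truth alignment construction -----------------------------------------

# op runs + POS for an error-free read covering haplotype interval [s, e)
truth_alignment <- function(hap, s, e) {
  A <- hap$tract_start
  Lm <- hap$tract_len
  Lr <- hap$ref_tract_len
  Lmin <- min(Lm, Lr)
  b1 <- A; b2 <- A + Lmin; b3 <- A + Lm
  op <- character(0); len <- integer(0)
  add <- function(o, l) {
    if (l > 0L) { op <<- c(op, o); len <<- c(len, as.integer(l)) }
  }
  add("M", min(e, b1) - min(max(s, 0L), b1))           # left flank
  add("M", max(0L, min(e, b2) - max(s, b1)))           # shared tract prefix
  add("I", max(0L, min(e, b3) - max(s, b2)))           # expansion surplus
  if (Lm < Lr && s < b3 && e > b3) add("D", Lr - Lm)   # contraction
  add("M", max(0L, e - max(s, b3)))                    # right flank
  if (!any(op == "M")) return(NULL)                    # unmappable read
  pos <- if (s < b2) s else if (s < b3) A + Lr else s - (Lm - Lr)
  list(op = op, len = len, pos = as.integer(pos))
}

# tidy op runs: merge equal neighbours, trim terminal deletions (adjusting
# POS), soft-clip terminal insertions
normalize_runs <- function(op, len, pos) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  repeat {
    changed <- FALSE
    # merge adjacent identical ops
    if (length(op) > 1L) {
      same <- c(FALSE, op[-1] == op[-length(op)])
      if (any(same)) {
        grp <- cumsum(!same)
        len <- as.integer(tapply(len, grp, sum))
        op <- op[!same]
        changed <- TRUE
      }
    }
    # leading D / trailing D
    if (length(op) && op[1] %in% c("D", "N")) {
      pos <- pos + len[1]; op <- op[-1]; len <- len[-1]; changed <- TRUE
    }
    if (length(op) && op[length(op)] %in% c("D", "N")) {
      op <- op[-length(op)]; len <- len[-length(len)]; changed <- TRUE
    }
    # I before the first M (possibly after an S) or after the last M -> S
    m <- which(op == "M")
    if (length(m)) {
      pre <- seq_len(m[1] - 1L)
      post <- if (m[length(m)] < length(op))
        (m[length(m)] + 1L):length(op) else integer(0)
      conv <- c(pre[op[pre] == "I"], post[op[post] == "I"])
      if (length(conv)) { op[conv] <- "S"; changed <- TRUE }
    }
    if (!changed) break
  }
  list(op = op, len = len, pos = as.integer(pos))
}

#' Simulate noisy long reads from one or more haplotypes
#'
#' Read starts are uniform over each haplotype (in proportion to `weights`),
#' lengths log-normal (median `params$read_len_median`, truncated at the
#' sequence ends), and per-base errors i.i.d. at the given substitution /
#' insertion / deletion rates.  Truth SAM records give the exact alignment to
#' the unmodified reference implied by the haplotype's coordinate map and the
#' error log: reads crossing an expanded tract carry an `I` op of the
#' expansion size (plus or minus local errors); when that insertion exceeds
#' `params$split_emit_threshold` the read is emitted as two soft-clipped
#' records (primary + supplementary) to exercise the split-alignment path.
#' Reads falling entirely inside an insertion are unmappable: they appear in
#' the truth table and FASTA but produce no alignment record.
#'
#' @param haplotypes list of `tr_haplotype` (all on the same contig when
#'   they are to be mixed); names are used as haplotype labels.
#' @param weights mixing weights (default equal; must sum to 1).
#' @param depth target coverage (total, split across haplotypes by weight).
#' @param n_reads exact read count (scalar: per haplotype when `weights` is
#'   NULL, otherwise total split by weight; vector: per haplotype).
#' @param params [tr_params()] (error rates, read-length model, split
#'   threshold).
#' @param seed optional seed (`set.seed` is called when non-NULL).
#' @param spanning_only draw only reads that span the tract, with flanks
#'   uniform in `spanning_flanks` (emulates selecting locus-spanning reads).
#' @param spanning_flanks `c(min, max)` flank lengths for `spanning_only`.
#' @param error_rates optional `c(sub, ins, del)` override.
#' @param id_prefix prefix namespace for read indices.
#' @return An object of class `tr_sim`: list with `records` (truth alignment
#'   records), `truth` (read table), `reads` (named original-strand
#'   sequences), `reads0` (error-free reads), `logs` (per-read error logs),
#'   `ref_lengths`.
#' @export
simulate_reads <- function(haplotypes, weights = NULL, depth = 30,
                           n_reads = NULL, params = tr_params(), seed = NULL,
                           spanning_only = FALSE,
                           spanning_flanks = c(1000L, 3000L),
                           error_rates = NULL, id_prefix = "r") {
  params <- as_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(haplotypes, "tr_haplotype")) haplotypes <- list(haplotypes)
  nh <- length(haplotypes)
  if (is.null(error_rates))
    error_rates <- c(params$error_sub, params$error_ins, params$error_del)
  if (any(error_rates < 0) || sum(error_rates) >= 1)
    stop("invalid error rates (must be non-negative and sum below 1)")
  if (is.null(weights) && is.null(n_reads)) weights <- rep(1 / nh, nh)
  if (!is.null(weights)) {
    if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
    if (depth <= 0) stop("depth must be positive")
  }
  hap_names <- names(haplotypes)
  if (is.null(hap_names)) hap_names <- paste0("h", seq_len(nh))
  hap_names[!nzchar(hap_names)] <- paste0("h", which(!nzchar(hap_names)))
  counts <- NULL
  if (!is.null(n_reads)) {
    counts <- if (length(n_reads) == nh) as.integer(n_reads)
    else if (!is.null(weights)) {
      ct <- as.integer(round(n_reads * weights))
      ct[1] <- as.integer(n_reads) - sum(ct[-1])
      ct
    } else rep(as.integer(n_reads), nh)
  }
  mean_len <- params$read_len_median * exp(params$read_len_sdlog^2 / 2)

  recs <- list(); truth <- list(); reads <- character(0)
  reads0 <- character(0); logs <- list()
  idx <- 0L
  for (hi in seq_len(nh)) {
    hap <- haplotypes[[hi]]
    L <- nchar(hap$seq)
    target_bases <- if (is.null(counts)) depth * weights[hi] * L else NA
    emitted_bases <- 0
    emitted <- 0L
    repeat {
      if (!is.null(counts)) {
        if (emitted >= counts[hi]) break
      } else if (emitted_bases >= target_bases) break
      if (spanning_only) {
        fl <- sample(spanning_flanks[1]:spanning_flanks[2], 1L)
        fr <- sample(spanning_flanks[1]:spanning_flanks[2], 1L)
        s <- max(0L, hap$tract_start - fl)
        e <- min(L, hap$tract_start + hap$tract_len + fr)
      } else {
        rl <- max(300L, as.integer(round(
          rlnorm(1, log(params$read_len_median), params$read_len_sdlog))))
        s <- sample.int(L, 1L) - 1L
        e <- min(L, s + rl)
        if (e - s < 300L) s <- max(0L, e - 300L)
      }
      idx <- idx + 1L
      emitted <- emitted + 1L
      emitted_bases <- emitted_bases + (e - s)
      strand <- if (runif(1) < 0.5) "+" else "-"
      read0 <- substr(hap$seq, s + 1L, e)
      ta <- truth_alignment(hap, s, e)
      mappable <- !is.null(ta)
      rid <- sprintf("%s_%d_%s_%s%d_%s_%d_%d", hap$chrom, s,
                     if (mappable) "aligned" else "unaligned",
                     id_prefix, idx, hap_names[hi], hap$tract_len, e - s)
      # apply sequencing errors to the reference-oriented read
      if (sum(error_rates) > 0) {
        ops0 <- if (mappable) paste(strrep(ta$op, ta$len), collapse = "")
                else strrep("S", nchar(read0))
        mut <- mutate_read_cpp(read0, ops0, error_rates[1], error_rates[2],
                               error_rates[3])
        read <- mut$seq
        ops <- mut$ops
        logs[[rid]] <- mut$log
      } else {
        read <- read0
        ops <- if (mappable) paste(strrep(ta$op, ta$len), collapse = "")
               else strrep("S", nchar(read0))
        logs[[rid]] <- data.frame(offset = integer(0), op = character(0),
                                  base = character(0),
                                  stringsAsFactors = FALSE)
      }
      reads0[rid] <- read0
      reads[rid] <- if (strand == "-") revcomp(read) else read
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = rid, chrom = hap$chrom, hap = hap_names[hi],
        start = s, end = e, strand = strand, mappable = mappable,
        allele = hap$tract_len, stringsAsFactors = FALSE)
      if (!mappable) next
      r <- rle(strsplit(ops, "", fixed = TRUE)[[1]])
      nr <- normalize_runs(r$values, r$lengths, ta$pos)
      recs <- c(recs, emit_records(nr, read, rid, hap$chrom, strand, params))
    }
  }
  ref_lengths <- vapply(haplotypes, function(h)
    nchar(h$seq) - h$tract_len + h$ref_tract_len, 0L)
  names(ref_lengths) <- vapply(haplotypes, `[[`, "", "chrom")
  ref_lengths <- ref_lengths[!duplicated(names(ref_lengths))]
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(read_id = character(0), flag = integer(0),
               ref_name = character(0), ref_start = integer(0),
               mapq = integer(0), cigar = character(0), seq = character(0),
               stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records,
                 truth = do.call(rbind, truth),
                 reads = reads, reads0 = reads0, logs = logs,
                 ref_lengths = ref_lengths),
            class = "tr_sim")
}

# one or two (split) SAM-style records from normalized truth runs
emit_records <- function(nr, read, rid, chrom, strand, params) {
  base_flag <- if (strand == "-") 16L else 0L
  mk <- function(op, len, pos, flag) {
    data.frame(read_id = rid, flag = flag, ref_name = chrom,
               ref_start = as.integer(pos), mapq = 60L,
               cigar = cigar_runs_to_string(op, len), seq = read,
               stringsAsFactors = FALSE)
  }
  big <- which(nr$op == "I" & nr$len > params$split_emit_threshold)
  if (!length(big)) return(list(mk(nr$op, nr$len, nr$pos, base_flag)))
  k0 <- big[which.max(nr$len[big])]
  read_len <- nchar(read)
  rc <- ifelse(nr$op %in% READ_OPS, nr$len, 0L)
  r1 <- sum(rc[seq_len(k0 - 1L)])
  r2 <- r1 + nr$len[k0]
  refc <- ifelse(nr$op %in% REF_OPS, nr$len, 0L)
  p_mid <- nr$pos + sum(refc[seq_len(k0 - 1L)])
  left <- normalize_runs(c(nr$op[seq_len(k0 - 1L)], "S"),
                         c(nr$len[seq_len(k0 - 1L)], read_len - r1), nr$pos)
  right <- normalize_runs(c("S", nr$op[(k0 + 1L):length(nr$op)]),
                          c(r2, nr$len[(k0 + 1L):length(nr$op)]), p_mid)
  list(mk(left$op, left$len, left$pos, base_flag),
       mk(right$op, right$len, right$pos, base_flag + 2048L))
}

#' Alignment-record table of a simulation, in [read_alignments()] form
#'
#' Adds the derived columns (`ref_end`, clips, `read_len`,
#' `is_supplementary`) so a `tr_sim` can feed [genome_scan()] /
#' [genotype_loci()] directly without a SAM round trip.
#'
#' @param sim `tr_sim` object.
#' @return Alignment record data frame.
#' @export
sim_alignments <- function(sim) {
  df <- sim$records
  cs <- cigar_stats(df$cigar)
  df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
  df$is_supplementary <- bitwAnd(df$flag, 2048L) > 0L
  df$ref_end <- df$ref_start + cs$ref_consumed
  df$left_clip <- cs$left_clip
  df$right_clip <- cs$right_clip
  df$read_len <- cs$read_len
  df
}

#' Decode truth-encoded read names
#'
#' Read names carry underscore-separated fields: contig, 0-based haplotype
#' start, mappability, read index, haplotype label, haplotype allele size
#' (bp) and aligned length.
#'
#' @param ids character vector of read names.
#' @return Data frame: `read_id`, `chrom`, `start`, `mappable`, `hap`,
#'   `allele`, `aligned_length`, `end`.
#' @export
decode_read_id <- function(ids) {
  f <- strsplit(ids, "_", fixed = TRUE)
  if (any(vapply(f, length, 1L) != 7L))
    stop("read name does not have 7 underscore-separated fields")
  df <- data.frame(
    read_id = ids,
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 2L)),
    mappable = vapply(f, `[[`, "", 3L) == "aligned",
    hap = vapply(f, `[[`, "", 5L),
    allele = as.integer(vapply(f, `[[`, "", 6L)),
    aligned_length = as.integer(vapply(f, `[[`, "", 7L)),
    stringsAsFactors = FALSE)
  df$end <- df$start + df$aligned_length
  df
}

#' Ground-truth locus-spanning reads
#'
#' Reads whose (haplotype-coordinate) interval covers the expanded tract with
#' at least `truth_overlap_min` (50 bp) on both sides and that are flagged
#' mappable.  Each read's own haplotype allele size (from the truth table or
#' decoded read name) defines its expanded interval; `expansion_size` is the
#' fallback added size when per-read allele sizes are unavailable.
#'
#' @param truth truth table of a `tr_sim` (or a vector of read names).
#' @param locus one-row `tr_loci` data frame (reference tract).
#' @param expansion_size added size (bp) relative to the reference tract,
#'   used only when `truth` lacks an `allele` column.
#' @param params [tr_params()].
#' @return Character vector of read ids.
#' @export
truth_spanning_reads <- function(truth, locus, expansion_size = NULL,
                                 params = tr_params()) {
  params <- as_params(params)
  if (is.character(truth)) truth <- decode_read_id(truth)
  t <- params$truth_overlap_min
  allele <- if ("allele" %in% names(truth) && !anyNA(truth$allele))
    truth$allele
  else (locus$end - locus$start) +
    (if (is.null(expansion_size)) 0L else expansion_size)
  ok <- truth$mappable &
    truth$chrom == locus$chrom &
    truth$start <= locus$start - t &
    truth$end >= locus$start + allele + t
  unique(truth$read_id[ok])
}

# ---- experiment designs ----------------------------------------------------

#' Build a complete simulation experiment
#'
#' Three designs mirror the package's evaluation set-ups:
#' \describe{
#'   \item{het17}{17 disease loci ([disease_loci()] motifs), each on its own
#'     contig (tract embedded in random flanks), heterozygous for the
#'     reference allele and an expanded allele of `allele_size` bp total, at
#'     combined coverage `depth` (~30X).}
#'   \item{resolve_grid}{bi- or tri-allelic samples over base allele sizes
#'     `base_sizes` x allele separations `separations`, with
#'     `reads_per_allele` spanning reads per allele at each of the 17 loci.}
#'   \item{mosaic_series}{FMR1-like CGG locus; samples of `n_reads` spanning
#'     reads mixing a premutation (150-copy) and a full-mutation (500-copy)
#'     allele at every composition in `fractions` (fraction full-mutation),
#'     `replicates` times each.}
#' }
#'
#' @param design one of `"het17"`, `"resolve_grid"`, `"mosaic_series"`.
#' @param params [tr_params()].
#' @param seed integer seed governing reference construction and reads.
#' @param ... design arguments, see Details above (`allele_size = 500`,
#'   `depth = 30`, `flank = 20000` for het17; `base_sizes`, `separations`,
#'   `n_alleles = 2`, `reads_per_allele = 10`, `flank = 4000` for
#'   resolve_grid; `fractions`, `replicates = 10`, `n_reads = 30`,
#'   `pm_copies = 150`, `fm_copies = 500`, `flank = 4000` for mosaic_series).
#' @return A list bundle with `reference`, `loci` and design-specific
#'   simulation objects (see each design's element docs in the vignette).
#' @export
make_experiment <- function(design = c("het17", "resolve_grid",
                                       "mosaic_series"),
                            params = tr_params(), seed = 1L, ...) {
  design <- match.arg(design)
  params <- as_params(params)
  set.seed(seed)
  args <- list(...)
  switch(design,
         het17 = experiment_het17(params, args),
         resolve_grid = experiment_resolve_grid(params, args),
         mosaic_series = experiment_mosaic(params, args))
}

arg_or <- function(args, name, default)
  if (!is.null(args[[name]])) args[[name]] else default

# one contig per locus: [flank][ref tract][flank]
toy_reference <- function(loci_cat, flank) {
  ref <- character(0)
  for (i in seq_len(nrow(loci_cat))) {
    tract <- strrep(loci_cat$motif[i], loci_cat$ref_copies[i])
    ref[loci_cat$gene[i]] <- paste0(random_dna(flank), tract,
                                    random_dna(flank))
  }
  ref
}

toy_loci <- function(loci_cat, flank) {
  tr_loci_frame(chrom = loci_cat$gene, start = flank,
                end = flank + nchar(loci_cat$motif) * loci_cat$ref_copies,
                motifs = loci_cat$motif, source = "annotation")
}

experiment_het17 <- function(params, args) {
  allele_size <- arg_or(args, "allele_size", 500L)
  depth <- arg_or(args, "depth", 30)
  flank <- arg_or(args, "flank", 20000L)
  cat <- disease_loci()
  reference <- toy_reference(cat, flank)
  loci <- toy_loci(cat, flank)
  sims <- vector("list", nrow(cat))
  for (i in seq_len(nrow(cat))) {
    locus <- loci[i, , drop = FALSE]
    exp_copies <- as.integer(round(allele_size / nchar(cat$motif[i])))
    haps <- list(ref = build_haplotype(reference, locus, cat$motif[i],
                                       cat$ref_copies[i]),
                 exp = build_haplotype(reference, locus, cat$motif[i],
                                       exp_copies))
    sims[[i]] <- simulate_reads(haps, weights = c(0.5, 0.5), depth = depth,
                                params = params,
                                id_prefix = paste0("L", i, "n"))
  }
  sim <- combine_sims(sims)
  list(design = "het17", reference = reference, loci = loci, sim = sim,
       allele_size = allele_size)
}

experiment_resolve_grid <- function(params, args) {
  base_sizes <- arg_or(args, "base_sizes", c(100L, 500L, 1000L, 2000L))
  separations <- arg_or(args, "separations", c(100L, 200L))
  n_alleles <- arg_or(args, "n_alleles", 2L)
  reads_per_allele <- arg_or(args, "reads_per_allele", 10L)
  flank <- arg_or(args, "flank", 4000L)
  cat <- disease_loci()
  reference <- toy_reference(cat, flank)
  loci <- toy_loci(cat, flank)
  samples <- list()
  for (b in base_sizes) for (sp in separations) {
    sims <- vector("list", nrow(cat))
    sizes <- b + (seq_len(n_alleles) - 1L) * sp
    for (i in seq_len(nrow(cat))) {
      locus <- loci[i, , drop = FALSE]
      ml <- nchar(cat$motif[i])
      haps <- lapply(sizes, function(sz)
        build_haplotype(reference, locus, cat$motif[i],
                        as.integer(round(sz / ml))))
      names(haps) <- paste0("a", seq_along(haps))
      sims[[i]] <- simulate_reads(
        haps, n_reads = rep(reads_per_allele, n_alleles), params = params,
        spanning_only = TRUE,
        spanning_flanks = c(1000L, min(3000L, flank - 100L)),
        id_prefix = sprintf("b%ds%dL%dn", b, sp, i))
    }
    key <- sprintf("b%d_s%d", b, sp)
    samples[[key]] <- list(sim = combine_sims(sims), base = b, sep = sp,
                           target_sizes = sizes)
  }
  list(design = "resolve_grid", reference = reference, loci = loci,
       samples = samples)
}

experiment_mosaic <- function(params, args) {
  fractions <- arg_or(args, "fractions", seq(0, 1, 0.1))
  replicates <- arg_or(args, "replicates", 10L)
  n_reads <- arg_or(args, "n_reads", 30L)
  pm_copies <- arg_or(args, "pm_copies", 150L)
  fm_copies <- arg_or(args, "fm_copies", 500L)
  flank <- arg_or(args, "flank", 4000L)
  cat <- disease_loci()
  cat <- cat[cat$gene == "FMR1", , drop = FALSE]
  reference <- toy_reference(cat, flank)
  loci <- toy_loci(cat, flank)
  locus <- loci[1, , drop = FALSE]
  haps <- list(pm = build_haplotype(reference, locus, cat$motif, pm_copies),
               fm = build_haplotype(reference, locus, cat$motif, fm_copies))
  samples <- list()
  for (f in fractions) {
    n_fm <- as.integer(round(n_reads * f))
    key <- sprintf("fm%d", as.integer(round(100 * f)))
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      reps[[r]] <- simulate_reads(
        haps, n_reads = c(n_reads - n_fm, n_fm), params = params,
        spanning_only = TRUE,
        spanning_flanks = c(1000L, min(3000L, flank - 100L)),
        id_prefix = sprintf("f%dr%dn", as.integer(round(100 * f)), r))
    }
    samples[[key]] <- list(sims = reps, n_pm = n_reads - n_fm, n_fm = n_fm,
                           fraction_fm = f)
  }
  list(design = "mosaic_series", reference = reference, loci = loci,
       samples = samples, pm_copies = pm_copies, fm_copies = fm_copies,
       pm_size = pm_copies * nchar(cat$motif),
       fm_size = fm_copies * nchar(cat$motif))
}

# merge per-locus simulations (distinct contigs) into one bundle
combine_sims <- function(sims) {
  sims <- unname(sims)  # outer names would leak into element names via c()
  structure(list(
    records = do.call(rbind, lapply(sims, `[[`, "records")),
    truth = do.call(rbind, lapply(sims, `[[`, "truth")),
    reads = do.call(c, lapply(sims, `[[`, "reads")),
    reads0 = do.call(c, lapply(sims, `[[`, "reads0")),
    logs = do.call(c, lapply(sims, `[[`, "logs")),
    ref_lengths = local({
      rl <- do.call(c, lapply(sims, `[[`, "ref_lengths"))
      rl[!duplicated(names(rl))]
    })
  ), class = "tr_sim")
}
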