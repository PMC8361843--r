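# Alignment, locus and table I/O: SAM/BAM in via Rsamtools, BED loci in,
# genotype TSV and SAM out.  Internal coordinates are 0-based half-open
# everywhere; conversion to/from SAM's 1-based POS happens only here.

#' Read long-read alignments from SAM or BAM
#'
#' Parses genomic alignments into a flat record table.  Unmapped records are
#' skipped; secondary alignments are skipped unless `params$use_secondary`.
#' Hard-clipped records keep their clip lengths but have `seq = NA`.
#'
#' @param path SAM or BAM file.
#' @param region optional `list(chrom, start, end)` (0-based half-open); only
#'   overlapping records are returned (the file is sorted/indexed into a
#'   temporary BAM as needed).
#' @param params [tr_params()].
#' @return A data frame with one row per alignment record: `read_id`,
#'   `ref_name`, `ref_start`/`ref_end` (0-based half-open reference span),
#'   `strand`, `mapq`, `flag`, `cigar`, `seq` (as stored, reference strand),
#'   `is_supplementary`, `left_clip`, `right_clip`, `read_len` (including
#'   hard-clipped bases).
#' @export
read_alignments <- function(path, region = NULL, params = tr_params()) {
  params <- as_params(params)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  sbp_flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  if (is.null(region)) {
    sbp <- Rsamtools::ScanBamParam(flag = sbp_flag, what = what)
  } else {
    sorted <- Rsamtools::sortBam(bam, tempfile(fileext = ""))
    Rsamtools::indexBam(sorted)
    bam <- sorted
    which <- IRanges::IRangesList(IRanges::IRanges(region$start + 1L,
                                                   region$end))
    names(which) <- region$chrom
    sbp <- Rsamtools::ScanBamParam(flag = sbp_flag, what = what,
                                   which = which)
  }
  res <- Rsamtools::scanBam(bam, param = sbp)
  res <- lapply(names(res[[1]]), function(f)
    do.call(c, unname(lapply(res, `[[`, f))))
  names(res) <- what
  n <- length(res$qname)
  seqs <- as.character(res$seq)
  seqs[!nzchar(seqs)] <- NA_character_
  df <- data.frame(
    read_id = res$qname,
    ref_name = as.character(res$rname),
    ref_start = res$pos - 1L,
    strand = as.character(res$strand),
    mapq = as.integer(res$mapq),
    flag = as.integer(res$flag),
    cigar = res$cigar,
    seq = seqs,
    stringsAsFactors = FALSE
  )
  df$is_supplementary <- bitwAnd(df$flag, 2048L) > 0L
  df$is_secondary <- bitwAnd(df$flag, 256L) > 0L
  cs <- tryCatch(cigar_stats(df$cigar), error = function(e) {
    stop("CIGAR parse error (", conditionMessage(e), ")")
  })
  df$ref_end <- df$ref_start + cs$ref_consumed
  df$left_clip <- cs$left_clip
  df$right_clip <- cs$right_clip
  df$read_len <- cs$read_len
  bad <- !is.na(df$seq) &
    nchar(df$seq) != cs$read_consumed
  if (any(bad))
    stop("CIGAR/SEQ length mismatch for record(s): ",
         paste(head(df$read_id[bad], 3), collapse = ", "))
  if (!params$use_secondary) df <- df[!df$is_secondary, , drop = FALSE]
  df <- df[df$mapq >= params$min_mapq, , drop = FALSE]
  df$is_secondary <- NULL
  rownames(df) <- NULL
  df
}

#' Load target TR loci from BED
#'
#' Expects at least four columns: chrom, start, end, motif(s); multiple
#' motifs for one locus are comma-separated.  Coordinates are BED-style
#' 0-based half-open.
#'
#' @param path BED file.
#' @param params [tr_params()]; motif lengths outside
#'   `[motif_len_min, motif_len_max]` are rejected when `strict`.
#' @param strict reject out-of-range motif lengths (default TRUE).
#' @return A `tr_loci` data frame: `chrom`, `start`, `end`, `motifs`
#'   (comma-separated, upper case), `source`.
#' @export
load_loci_bed <- function(path, params = tr_params(), strict = TRUE) {
  params <- as_params(params)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(tr_loci_frame())
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad))
    stop("BED line ", bad[1], " has fewer than 4 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  motifs <- toupper(vapply(fields, `[[`, "", 4L))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinates")
  if (any(start >= end))
    stop("BED line ", which(start >= end)[1], ": start >= end")
  for (i in seq_along(motifs)) {
    ms <- strsplit(motifs[i], ",", fixed = TRUE)[[1]]
    if (!length(ms) || any(!grepl("^[ACGT]+$", ms)))
      stop("BED line ", i, ": motif must be ACGT (comma-separated)")
    if (strict && any(nchar(ms) < params$motif_len_min |
                        nchar(ms) > params$motif_len_max))
      stop("BED line ", i, ": motif length outside [",
           params$motif_len_min, ", ", params$motif_len_max, "]")
  }
  tr_loci_frame(chrom = chrom, start = start, end = end, motifs = motifs,
                source = "annotation")
}

tr_loci_frame <- function(chrom = character(0), start = integer(0),
                          end = integer(0), motifs = character(0),
                          source = character(0),
                          support_events = rep(NA_integer_, length(chrom))) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), motifs = motifs,
                   source = if (length(source)) source else
                     rep("annotation", length(chrom)),
                   support_events = support_events,
                   stringsAsFactors = FALSE)
  class(df) <- c("tr_loci", "data.frame")
  df
}

locus_motifs <- function(locus) {
  strsplit(locus$motifs, ",", fixed = TRUE)[[1]]
}

#' Write per-read genotype calls to TSV
#'
#' One row per supporting read, alleles sorted ascending by size, with a
#' `#`-prefixed header.  Columns: chrom, start, end, motif, allele_index,
#' allele_size_bp, allele_copy_number, allele_support, read_id, read_size_bp,
#' read_copy_number, read_tract_start.
#'
#' @param genotypes a `tr_genotype`, a `tr_genotype_set`, or a list of
#'   `tr_genotype` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  df <- genotype_rows(genotypes)
  header <- paste0("#", paste(colnames(df), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

genotype_rows <- function(genotypes) {
  if (inherits(genotypes, "tr_genotype")) genotypes <- list(genotypes)
  rows <- lapply(genotypes, function(g) {
    if (is.null(g) || !nrow(g$alleles)) return(NULL)
    reads <- g$reads[!is.na(g$reads$allele), , drop = FALSE]
    if (!nrow(reads)) return(NULL)
    a <- g$alleles[reads$allele, , drop = FALSE]
    data.frame(chrom = g$locus$chrom, start = g$locus$start,
               end = g$locus$end, motif = g$motif,
               allele_index = reads$allele,
               allele_size_bp = a$size,
               allele_copy_number = a$copy_number,
               allele_support = a$support,
               read_id = reads$read_id,
               read_size_bp = reads$repeat_size,
               read_copy_number = reads$copy_number,
               read_tract_start = reads$read_tract_start,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      allele_index = integer(0), allele_size_bp = numeric(0),
                      allele_copy_number = numeric(0),
                      allele_support = integer(0), read_id = character(0),
                      read_size_bp = numeric(0), read_copy_number = numeric(0),
                      read_tract_start = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read a genotype TSV written by [write_genotype_tsv()]
#'
#' @param path TSV file.
#' @return Data frame with the per-read call columns.
#' @export
read_genotype_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = cols, stringsAsFactors = FALSE)
  df
}

#' Write scan loci to a BED-compatible TSV
#'
#' Columns: chrom, start, end, motif(s), support_events.
#'
#' @param loci `tr_loci` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  df <- as.data.frame(loci)[, c("chrom", "start", "end", "motifs",
                                "support_events")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tmotifs\tsupport_events", con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Write alignment records to SAM
#'
#' Writes the record table produced by the simulator (or by
#' [read_alignments()]) as headered SAM text.
#'
#' @param records alignment record data frame with `read_id`, `flag`,
#'   `ref_name`, `ref_start` (0-based), `mapq`, `cigar`, `seq`.
#' @param ref_lengths named integer vector of reference sequence lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(ref_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(ref_lengths[[nm]])),
               con)
  if (nrow(records)) {
    seqf <- ifelse(is.na(records$seq), "*", records$seq)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     records$read_id, records$flag, records$ref_name,
                     records$ref_start + 1L, records$mapq, records$cigar,
                     seqf)
    writeLines(lines, con)
  }
  invisible(path)
}
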