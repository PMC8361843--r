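#' Pipeline parameters
#'
#' Bundles every tunable threshold of the scan/genotype/simulate/bench
#' pipeline into one validated list.  Call with no arguments for the
#' defaults; override individual values by name.
#'
#' Core thresholds (units in brackets):
#' \describe{
#'   \item{min_ins_size}{minimum insertion size considered by the scan stage
#'     (bp, 100).}
#'   \item{insertion_purity_min}{minimum fraction of an insertion covered by a
#'     single tandem repeat motif for it to be kept (0.70).}
#'   \item{genomic_tract_purity_min}{minimum single-repeat purity of an
#'     assembly tract sized by flank probes (0.80).}
#'   \item{flank_probe_len}{reference flank probe length for assembly sizing
#'     (bp, 500).}
#'   \item{rescue_flank_len}{reference flank length aligned into clipped read
#'     sequence to rescue a missing repeat boundary (bp, 80).}
#'   \item{truth_overlap_min}{overlap required on both sides of an expansion
#'     for a simulated read to count as ground truth (bp, 50).}
#'   \item{match_abs_tol, match_rel_tol}{allele match criterion: within 20 bp
#'     or within 10\% of the truth allele.}
#'   \item{max_alleles}{maximum number of Gaussian mixture components tried
#'     (2).}
#'   \item{motif_len_min, motif_len_max}{admissible motif sizes (bp, 2-100).}
#'   \item{min_support}{minimum reads supporting a cluster or allele (2).}
#'   \item{merge_window}{single-linkage gap for merging insertion events
#'     (bp, 50).}
#'   \item{split_max_ref_gap}{maximum reference gap between paired split
#'     alignments (bp, 50).}
#'   \item{min_flank_anchor}{aligned bases required on each flank for a read
#'     to be called spanning (bp, 50); mirrors the ground-truth spanning
#'     definition (50 bp on both sides of the expansion).}
#'   \item{ks_alpha}{significance level for KS comparisons (0.05).}
#' }
#'
#' Repeat-finder internals: `wrap_match`/`wrap_mismatch`/`wrap_indel`
#' (+1/-1/-2 wraparound alignment scores), `min_repeat_score` (report
#' threshold 8), `min_region_density` (lag-profile screen, 0.4),
#' `exhaustive_max_len` (sequences up to 64 bp are searched exhaustively).
#' Rescue/matching: `rescue_min_identity` (0.85), `rescue_min_cov` (0.90),
#' `motif_match_min_identity`/`motif_match_min_cov` (0.80/0.80),
#' `probe_min_cov` (0.99, end-to-end probe requirement).
#' Scan: `scan_window` (reference neighbourhood for locus delineation, 1000),
#' `min_mapq` (0), `use_secondary` (FALSE).  Genotype: `allele_merge_gap`
#' (alleles with means < 2 bp apart are merged).  Simulator:
#' `error_sub`/`error_ins`/`error_del` (0.03/0.04/0.05), `read_len_median`
#' (5000), `read_len_sdlog` (0.35), `split_emit_threshold` (insertions above
#' 1000 bp are emitted as split alignments), `random_seed`.
#'
#' @param ... named overrides of the defaults described above.
#' @return An object of class `tr_params` (a named list).
#' @examples
#' p <- tr_params(min_ins_size = 200)
#' p$min_ins_size
#' @export
tr_params <- function(...) {
  p <- list(
    min_ins_size = 100L,
    insertion_purity_min = 0.70,
    genomic_tract_purity_min = 0.80,
    flank_probe_len = 500L,
    rescue_flank_len = 80L,
    truth_overlap_min = 50L,
    match_abs_tol = 20,
    match_rel_tol = 0.10,
    max_alleles = 2L,
    ks_alpha = 0.05,
    motif_len_min = 2L,
    motif_len_max = 100L,
    min_support = 2L,
    merge_window = 50L,
    split_max_ref_gap = 50L,
    min_flank_anchor = 50L,
    random_seed = 1L,
    # scan internals
    scan_window = 1000L,
    min_mapq = 0L,
    use_secondary = FALSE,
    # repeat finder
    wrap_match = 1L,
    wrap_mismatch = -1L,
    wrap_indel = -2L,
    min_repeat_score = 8L,
    min_region_density = 0.4,
    exhaustive_max_len = 64L,
    # rescue / motif matching / probes
    rescue_min_identity = 0.85,
    rescue_min_cov = 0.90,
    motif_match_min_identity = 0.80,
    motif_match_min_cov = 0.80,
    probe_min_cov = 0.99,
    # genotype
    allele_merge_gap = 2,
    # simulator
    error_sub = 0.03,
    error_ins = 0.04,
    error_del = 0.05,
    read_len_median = 5000,
    read_len_sdlog = 0.35,
    split_emit_threshold = 1000L
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(
    p$insertion_purity_min > 0, p$insertion_purity_min <= 1,
    p$genomic_tract_purity_min > 0, p$genomic_tract_purity_min <= 1,
    p$motif_len_min >= 1, p$motif_len_max >= p$motif_len_min,
    p$max_alleles >= 1, p$min_support >= 1,
    p$min_ins_size >= 1, p$merge_window >= 0,
    p$error_sub >= 0, p$error_ins >= 0, p$error_del >= 0,
    p$error_sub + p$error_ins + p$error_del < 1
  )
  structure(p, class = "tr_params")
}

#' @export
print.tr_params <- function(x, ...) {
  cat("trexr parameters:\n")
  nm <- names(x)
  for (i in seq_along(x))
    cat(sprintf("  %-26s %s\n", nm[i], format(x[[i]])))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "tr_params")) return(params)
  if (is.null(params)) return(tr_params())
  stop("`params` must be created by tr_params()")
}
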