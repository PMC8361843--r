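test_that("build_haplotype swaps the tract and keeps the bookkeeping", {
  set.seed(41)
  tb <- toy_locus_bundle(motif = "CAG", ref_copies = 20L, flank = 500L)
  hap <- build_haplotype(tb$reference, tb$locus, "CAG", 100)
  expect_s3_class(hap, "tr_haplotype")
  expect_equal(nchar(hap$seq), 1000L + 300L)
  expect_equal(hap$tract_start, 500L)
  expect_equal(hap$tract_len, 300L)
  expect_equal(hap$ref_tract_len, 60L)
  expect_equal(substr(hap$seq, 501L, 800L), strrep("CAG", 100))
  # flanks are untouched
  expect_equal(substr(hap$seq, 1L, 500L),
               substr(tb$reference[["ctg"]], 1L, 500L))
  expect_equal(substr(hap$seq, 801L, 1300L),
               substr(tb$reference[["ctg"]], 561L, 1060L))
  # zero copies: contraction to nothing
  hap0 <- build_haplotype(tb$reference, tb$locus, "CAG", 0)
  expect_equal(nchar(hap0$seq), 1000L)
  expect_error(build_haplotype(tb$reference,
                               trexr:::tr_loci_frame("nope", 0L, 10L, "CAG",
                                                     "annotation"),
                               "CAG", 5), "bounds")
})

test_that("error-free reads align exactly and recover planted sizes", {
  set.seed(42)
  tb <- toy_locus_bundle()
  p0 <- tr_params(error_sub = 0, error_ins = 0, error_del = 0)
  for (copies in c(20L, 60L, 150L)) {
    hap <- build_haplotype(tb$reference, tb$locus, "CAG", copies)
    sim <- simulate_reads(list(h = hap), n_reads = 6L, params = p0,
                          spanning_only = TRUE,
                          spanning_flanks = c(500L, 1500L))
    # every M column of every record matches the reference exactly
    for (i in seq_len(nrow(sim$records))) {
      rec <- sim$records[i, , drop = FALSE]
      expect_true(check_record_against_ref(rec, tb$reference),
                  info = rec$cigar)
    }
    # genotyping the error-free reads recovers the planted size exactly
    gts <- genotype_loci(sim_alignments(sim), tb$reference, tb$locus,
                         params = p0)
    g <- gts[[1]]
    expect_equal(g$k, 1L)
    expect_equal(g$alleles$size, 3 * copies)
    expect_equal(g$alleles$support, 6L)
  }
})

test_that("depth mode targets total bases; n_reads mode is exact", {
  set.seed(43)
  tb <- toy_locus_bundle(flank = 2000L)
  hapA <- build_haplotype(tb$reference, tb$locus, "CAG", 20)
  hapB <- build_haplotype(tb$reference, tb$locus, "CAG", 100)
  sim <- simulate_reads(list(a = hapA, b = hapB), weights = c(0.5, 0.5),
                        depth = 20)
  bases <- sum(nchar(sim$reads0))
  target <- 20 * 0.5 * (nchar(hapA$seq) + nchar(hapB$seq))
  expect_lt(abs(bases - target) / target, 0.10)

  sim2 <- simulate_reads(list(a = hapA, b = hapB), n_reads = c(7L, 3L),
                         spanning_only = TRUE,
                         spanning_flanks = c(300L, 800L))
  expect_equal(as.integer(table(sim2$truth$hap)[c("a", "b")]), c(7L, 3L))
  # scalar n_reads with weights is split by weight and totals exactly
  sim3 <- simulate_reads(list(a = hapA, b = hapB), weights = c(0.7, 0.3),
                         n_reads = 10L, spanning_only = TRUE,
                         spanning_flanks = c(300L, 800L))
  expect_equal(nrow(sim3$truth), 10L)
  expect_equal(sum(sim3$truth$hap == "a"), 7L)

  expect_error(simulate_reads(list(a = hapA), weights = c(0.4)),
               "sum to 1")
  expect_error(simulate_reads(list(a = hapA), error_rates = c(0.5, 0.4, 0.3)),
               "error rates")
})

test_that("very long insertions are emitted as split record pairs", {
  set.seed(44)
  tb <- toy_locus_bundle()
  p0 <- tr_params(error_sub = 0, error_ins = 0, error_del = 0)
  hap <- build_haplotype(tb$reference, tb$locus, "CAG", 500)  # 1500 bp ins
  sim <- simulate_reads(list(h = hap), n_reads = 4L, params = p0,
                        spanning_only = TRUE,
                        spanning_flanks = c(500L, 1500L))
  expect_equal(nrow(sim$records), 8L)  # two records per read
  for (rid in unique(sim$records$read_id)) {
    pair <- sim$records[sim$records$read_id == rid, , drop = FALSE]
    pair <- pair[order(pair$ref_start), , drop = FALSE]
    expect_equal(bitwAnd(pair$flag, 2048L) > 0L, c(FALSE, TRUE))
    expect_equal(pair$seq[1], pair$seq[2])
    co1 <- cigar_ops(pair$cigar[1]); co2 <- cigar_ops(pair$cigar[2])
    expect_equal(co1$op[length(co1$op)], "S")
    expect_equal(co2$op[1], "S")
    # the supplementary resumes where the primary's reference span ended
    # (the shared tract prefix aligns as M, so the break sits at locus end)
    expect_equal(pair$ref_start[2],
                 pair$ref_start[1] + sum(co1$len[co1$op %in% c("M", "D")]))
  }
  # the scan-side split extractor recovers the insertion from the pair
  ev <- insertions_from_splits(
    sim_alignments(sim)[sim$records$read_id == sim$records$read_id[1], ,
                        drop = FALSE], p0)
  expect_equal(nrow(ev), 1L)
  # insertion size = expansion surplus (shared prefix aligns as M)
  expect_equal(nchar(ev$ins_seq), hap$tract_len - hap$ref_tract_len)
})

test_that("minus-strand reads store the reverse complement", {
  set.seed(45)
  tb <- toy_locus_bundle()
  hap <- build_haplotype(tb$reference, tb$locus, "CAG", 40)
  p0 <- tr_params(error_sub = 0, error_ins = 0, error_del = 0)
  sim <- simulate_reads(list(h = hap), n_reads = 20L, params = p0,
                        spanning_only = TRUE,
                        spanning_flanks = c(400L, 900L))
  minus <- sim$truth$read_id[sim$truth$strand == "-"]
  plus <- sim$truth$read_id[sim$truth$strand == "+"]
  expect_gt(length(minus), 0L)
  expect_gt(length(plus), 0L)
  for (rid in minus)
    expect_equal(revcomp(sim$reads[[rid]]), sim$reads0[[rid]])
  for (rid in plus)
    expect_equal(sim$reads[[rid]], sim$reads0[[rid]])
  # SAM records always store the reference-oriented sequence
  expect_equal(unname(sim$records$seq),
               unname(sim$reads0[sim$records$read_id]))
})

test_that("error logs replay the clean read into the emitted read", {
  set.seed(46)
  tb <- toy_locus_bundle()
  hap <- build_haplotype(tb$reference, tb$locus, "CAG", 60)
  sim <- simulate_reads(list(h = hap), n_reads = 10L,
                        spanning_only = TRUE,
                        spanning_flanks = c(400L, 900L))
  for (rid in names(sim$reads0)) {
    replayed <- apply_error_log(sim$reads0[[rid]], sim$logs[[rid]])
    stored <- sim$reads[[rid]]
    if (sim$truth$strand[sim$truth$read_id == rid] == "-")
      stored <- revcomp(stored)
    expect_equal(replayed, stored, info = rid)
  }
  # with 12% total error the logs are non-trivial
  expect_gt(sum(vapply(sim$logs, nrow, 1L)), 0L)
})

test_that("decode_read_id round trips the truth table", {
  set.seed(47)
  tb <- toy_locus_bundle()
  hap <- build_haplotype(tb$reference, tb$locus, "CAG", 30)
  sim <- simulate_reads(list(myhap = hap), n_reads = 5L,
                        spanning_only = TRUE,
                        spanning_flanks = c(400L, 900L))
  dec <- decode_read_id(sim$truth$read_id)
  expect_equal(dec$chrom, sim$truth$chrom)
  expect_equal(dec$start, sim$truth$start)
  expect_equal(dec$end, sim$truth$end)
  expect_equal(dec$mappable, sim$truth$mappable)
  expect_equal(dec$hap, sim$truth$hap)
  expect_equal(dec$allele, sim$truth$allele)
  expect_error(decode_read_id("just_three_fields"), "7")
})

test_that("truth_spanning_reads applies the 50 bp overlap boundary exactly", {
  p <- tr_params()
  locus <- trexr:::tr_loci_frame("ctg", 1000L, 1060L, "CAG", "annotation")
  # allele 300: expanded interval is [1000, 1300) in haplotype coordinates
  truth <- data.frame(
    read_id = c("span", "left_exact", "left_short", "right_exact",
                "right_short", "unmapped", "other_chrom"),
    chrom = c(rep("ctg", 6), "ctg2"),
    hap = "h",
    start = c(100L, 950L, 951L, 100L, 100L, 100L, 100L),
    end = c(2000L, 2000L, 2000L, 1350L, 1349L, 2000L, 2000L),
    strand = "+",
    mappable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    allele = 300L, stringsAsFactors = FALSE)
  got <- truth_spanning_reads(truth, locus, params = p)
  expect_equal(sort(got), c("left_exact", "right_exact", "span"))
  # without an allele column, expansion_size supplies the added length
  truth2 <- truth[, setdiff(names(truth), "allele")]
  got2 <- truth_spanning_reads(truth2, locus, expansion_size = 240L,
                               params = p)
  expect_equal(sort(got2), c("left_exact", "right_exact", "span"))
})

test_that("unmappable inside-insertion reads appear only in the truth table", {
  set.seed(48)
  tb <- toy_locus_bundle(flank = 1000L)
  # 9 kb tract dwarfing the flanks: random-start reads often fall inside it
  hap <- build_haplotype(tb$reference, tb$locus, "CAG", 3000)
  p <- tr_params(read_len_median = 600, read_len_sdlog = 0.1)
  sim <- simulate_reads(list(h = hap), n_reads = 60L, params = p)
  inside <- !sim$truth$mappable
  expect_gt(sum(inside), 0L)
  expect_false(any(sim$records$read_id %in% sim$truth$read_id[inside]))
  expect_true(all(sim$truth$read_id[inside] %in% names(sim$reads)))
  expect_true(all(grepl("_unaligned_", sim$truth$read_id[inside])))
})

test_that("make_experiment designs have the advertised shape and determinism", {
  p <- tr_params()
  ex <- make_experiment("resolve_grid", params = p, seed = 7L,
                        base_sizes = 100L, separations = 200L,
                        reads_per_allele = 3L, flank = 1500L)
  expect_equal(ex$design, "resolve_grid")
  expect_equal(length(ex$reference), 17L)
  expect_equal(nrow(ex$loci), 17L)
  expect_equal(names(ex$samples), "b100_s200")
  s <- ex$samples[["b100_s200"]]
  expect_equal(s$target_sizes, c(100L, 300L))
  expect_equal(nrow(s$sim$truth), 17L * 6L)

  ex2 <- make_experiment("resolve_grid", params = p, seed = 7L,
                         base_sizes = 100L, separations = 200L,
                         reads_per_allele = 3L, flank = 1500L)
  expect_identical(ex$reference, ex2$reference)
  expect_identical(ex$samples[["b100_s200"]]$sim$records,
                   ex2$samples[["b100_s200"]]$sim$records)

  ex3 <- make_experiment("mosaic_series", params = p, seed = 8L,
                         fractions = c(0, 0.5), replicates = 2L,
                         n_reads = 6L, flank = 1500L)
  expect_equal(names(ex3$samples), c("fm0", "fm50"))
  expect_equal(ex3$samples$fm50$n_fm, 3L)
  expect_equal(ex3$pm_size, 450L)
  expect_equal(ex3$fm_size, 1500L)
  expect_equal(nrow(ex3$loci), 1L)
  expect_equal(length(ex3$samples$fm0$sims), 2L)
  expect_true(all(ex3$samples$fm0$sims[[1]]$truth$hap == "pm"))
})

test_that("disease_loci catalogue is consistent", {
  cat <- disease_loci()
  expect_equal(nrow(cat), 17L)
  expect_equal(anyDuplicated(cat$gene), 0L)
  expect_true(all(grepl("^[ACGT]+$", cat$motif)))
  expect_equal(cat$ref_len, cat$hg38_end - cat$hg38_start)
  expect_true(all(cat$ref_copies >= 2L))
  expect_equal(cat$motif[cat$gene == "FMR1"], "CGG")
})
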