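make_rec <- function(read_id = "r", ref_name = "ctg", ref_start = 0L,
                     strand = "+", cigar = "10M", seq = strrep("A", 10)) {
  cs <- trexr:::cigar_stats(cigar)
  data.frame(read_id = read_id, ref_name = ref_name,
             ref_start = as.integer(ref_start), strand = strand,
             mapq = 60L, flag = if (strand == "-") 16L else 0L,
             cigar = cigar, seq = seq, is_supplementary = FALSE,
             ref_end = as.integer(ref_start) + cs$ref_consumed,
             left_clip = cs$left_clip, right_clip = cs$right_clip,
             read_len = cs$read_len, stringsAsFactors = FALSE)
}

test_that("insertions_from_cigar equals the expanded-op oracle on toy records", {
  p <- tr_params(min_ins_size = 10L)
  set.seed(21)
  for (i in 1:25) {
    # random well-formed toy cigar over a <=200 bp read: optional terminal
    # soft clips, alternating interior M/I/D runs (no adjacent equal ops)
    n_ops <- sample(3:8, 1)
    ops <- character(n_ops)
    ops[1] <- "M"
    for (k in seq_len(n_ops)[-1])
      ops[k] <- sample(setdiff(c("M", "I", "D"), ops[k - 1L]), 1)
    if (runif(1) < 0.5) ops <- c("S", ops)
    if (runif(1) < 0.5) ops <- c(ops, "S")
    cigar <- paste0(sample(3:30, length(ops), replace = TRUE), ops,
                    collapse = "")
    cs <- trexr:::cigar_stats(cigar)
    seq <- random_dna(cs$read_consumed)
    rec <- make_rec(ref_start = sample(0:100, 1), cigar = cigar, seq = seq)
    got <- insertions_from_cigar(rec, p)
    want <- oracle_cigar_insertions(rec$ref_start, cigar, seq, 10L)
    expect_equal(nrow(got), length(want), info = cigar)
    for (j in seq_along(want)) {
      expect_equal(got$ref_pos[j], want[[j]]$ref_pos, info = cigar)
      expect_equal(got$ins_seq[j], want[[j]]$ins_seq, info = cigar)
      expect_equal(got$read_start[j], want[[j]]$read_start, info = cigar)
    }
  }
})

test_that("insertions_from_cigar thresholds and errors", {
  p <- tr_params()
  rec <- make_rec(cigar = "50M99I50M", seq = random_dna(199))
  expect_equal(nrow(insertions_from_cigar(rec, p)), 0L)  # 99 < 100
  rec2 <- make_rec(cigar = "50M100I50M", seq = random_dna(200))
  ev <- insertions_from_cigar(rec2, p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ref_pos, 50L)
  rec3 <- make_rec(cigar = "50M100I50M", seq = NA_character_)
  expect_error(insertions_from_cigar(rec3, p), "no sequence")
})

test_that("insertions_from_splits detects the read/reference gap signature", {
  p <- tr_params()
  # read: 200 bp left flank | 300 bp insertion | 200 bp right flank
  seq <- paste0(random_dna(200), strrep("CAG", 100), random_dna(200))
  recs <- rbind(
    make_rec("r", ref_start = 1000L, cigar = "200M500S", seq = seq),
    make_rec("r", ref_start = 1200L, cigar = "500S200M", seq = seq))
  ev <- insertions_from_splits(recs, p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ref_pos, 1200L)
  expect_equal(nchar(ev$ins_seq), 300L)
  expect_equal(ev$ins_seq, strrep("CAG", 100))
  expect_equal(ev$source, "split")

  # minus strand: SAM stores the reverse-complemented read, so the record
  # geometry in reference orientation is unchanged; only the flag differs
  recs_m <- rbind(
    make_rec("r", ref_start = 1000L, strand = "-", cigar = "200M500S", seq = seq),
    make_rec("r", ref_start = 1200L, strand = "-", cigar = "500S200M", seq = seq))
  ev_m <- insertions_from_splits(recs_m, p)
  expect_equal(nrow(ev_m), 1L)
  expect_equal(ev_m$ref_pos, 1200L)
  expect_equal(nchar(ev_m$ins_seq), 300L)

  # reference gap too large -> no event
  recs2 <- rbind(
    make_rec("r", ref_start = 1000L, cigar = "200M500S", seq = seq),
    make_rec("r", ref_start = 1300L, cigar = "500S200M", seq = seq))
  expect_equal(nrow(insertions_from_splits(recs2, p)), 0L)

  # read gap too small -> no event
  seq3 <- random_dna(450)
  recs3 <- rbind(
    make_rec("r", ref_start = 1000L, cigar = "200M250S", seq = seq3),
    make_rec("r", ref_start = 1200L, cigar = "250S200M", seq = seq3))
  expect_equal(nrow(insertions_from_splits(recs3, p)), 0L)

  expect_error(insertions_from_splits(rbind(make_rec("a"), make_rec("b")), p),
               "multiple reads")
})

test_that("merge_events clusters by position and enforces support", {
  p <- tr_params()
  ev <- trexr:::events_frame(
    read_id = c("r1", "r2", "r2", "r3"),
    ref_name = "ctg",
    ref_pos = c(1000L, 1030L, 1010L, 5000L),
    ins_seq = c(strrep("A", 120), strrep("A", 150), strrep("A", 110),
                strrep("A", 200)),
    source = "cigar",
    read_start = 0L, read_end = 1L)
  cl <- merge_events(ev, p)
  expect_equal(length(cl), 1L)             # the singleton at 5000 is dropped
  expect_equal(nrow(cl[[1]]), 2L)          # r2 deduplicated to largest event
  expect_equal(sort(cl[[1]]$read_id), c("r1", "r2"))
  expect_equal(nchar(cl[[1]]$ins_seq[cl[[1]]$read_id == "r2"]), 150L)
  expect_equal(merge_events(trexr:::events_frame(), p), list())
})

test_that("filter_by_purity keeps repeat insertions and drops random ones", {
  p <- tr_params()
  set.seed(22)
  pure <- trexr:::events_frame(
    read_id = c("r1", "r2", "r3"), ref_name = "ctg", ref_pos = 1000L,
    ins_seq = c(strrep("CAG", 50), strrep("CAG", 52), random_dna(150)),
    source = "cigar", read_start = 0L, read_end = 1L)
  fp <- filter_by_purity(pure, p)
  expect_false(is.null(fp))
  expect_equal(fp$motif, "AGC")
  expect_equal(sort(fp$events$read_id), c("r1", "r2"))

  junk <- pure
  junk$ins_seq <- vapply(1:3, function(i) random_dna(150), "")
  expect_null(filter_by_purity(junk, p))
})

test_that("delineate_locus finds the concordant reference tract", {
  p <- tr_params()
  set.seed(23)
  tb <- toy_locus_bundle(motif = "CAG", ref_copies = 20L)
  loc <- delineate_locus("ctg", tb$locus$end, "AGC", tb$reference, p)
  expect_false(is.null(loc))
  expect_equal(loc$chrom, "ctg")
  expect_lte(abs(loc$start - tb$locus$start), 24)
  expect_lte(abs(loc$end - tb$locus$end), 24)
  expect_equal(loc$source, "scan")
  # discordant motif: no reference tract
  expect_null(delineate_locus("ctg", tb$locus$end, "ATTCT", tb$reference, p))
  expect_error(delineate_locus("nope", 10L, "AGC", tb$reference, p),
               "unknown reference")
  expect_error(delineate_locus("ctg", 10^7, "AGC", tb$reference, p),
               "bounds")
})

test_that("genome_scan discovers the expanded locus and honours exclusions", {
  p <- tr_params()
  set.seed(24)
  tb <- toy_locus_bundle(motif = "CAG", ref_copies = 20L)
  haps <- list(ref = build_haplotype(tb$reference, tb$locus, "CAG", 20),
               exp = build_haplotype(tb$reference, tb$locus, "CAG", 120))
  sim <- simulate_reads(haps, n_reads = c(6L, 6L), spanning_only = TRUE,
                        spanning_flanks = c(500L, 1500L))
  aln <- sim_alignments(sim)
  loci <- genome_scan(aln, tb$reference, params = p)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motifs, "AGC")
  expect_lte(abs(loci$start - tb$locus$start), 24)
  expect_lte(abs(loci$end - tb$locus$end), 24)
  expect_gte(loci$support_events, p$min_support)

  excl <- data.frame(chrom = "ctg", start = tb$locus$start - 200L,
                     end = tb$locus$end + 200L)
  loci2 <- genome_scan(aln, tb$reference, exclude_regions = excl, params = p)
  expect_equal(nrow(loci2), 0L)
})
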