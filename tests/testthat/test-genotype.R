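gt_rec <- function(read_id = "r", ref_start = 0L, cigar = "10M",
                   seq = strrep("A", 10), strand = "+") {
  cs <- trexr:::cigar_stats(cigar)
  data.frame(read_id = read_id, ref_name = "ctg",
             ref_start = as.integer(ref_start), strand = strand,
             mapq = 60L, flag = 0L, cigar = cigar, seq = seq,
             is_supplementary = FALSE,
             ref_end = as.integer(ref_start) + cs$ref_consumed,
             left_clip = cs$left_clip, right_clip = cs$right_clip,
             read_len = cs$read_len, stringsAsFactors = FALSE)
}

gt_locus <- function(start, end, motifs = "CAG") {
  trexr:::tr_loci_frame("ctg", start, end, motifs, "annotation")
}

test_that("extract_read_tract maps locus boundaries through the CIGAR", {
  p <- tr_params()
  # plain match: read covers ref [100, 400), locus [200, 260)
  rec <- gt_rec(ref_start = 100L, cigar = "300M", seq = random_dna(300))
  iv <- extract_read_tract(rec, gt_locus(200L, 260L), p)
  expect_equal(unname(iv), c(100L, 160L))

  # insertion inside the locus is included in the interval
  rec2 <- gt_rec(ref_start = 100L, cigar = "130M90I170M",
                 seq = random_dna(390))
  iv2 <- extract_read_tract(rec2, gt_locus(200L, 260L), p)
  expect_equal(unname(iv2), c(100L, 250L))

  # soft clip shifts read coordinates
  rec3 <- gt_rec(ref_start = 100L, cigar = "20S300M", seq = random_dna(320))
  iv3 <- extract_read_tract(rec3, gt_locus(200L, 260L), p)
  expect_equal(unname(iv3), c(120L, 180L))

  # deletion straddling the locus start: boundary clamps to the deletion
  rec4 <- gt_rec(ref_start = 100L, cigar = "90M20D190M",
                 seq = random_dna(280))
  iv4 <- extract_read_tract(rec4, gt_locus(200L, 260L), p)
  expect_equal(unname(iv4), c(90L, 140L))

  # insufficient flank anchor -> NULL
  rec5 <- gt_rec(ref_start = 170L, cigar = "130M", seq = random_dna(130))
  expect_null(extract_read_tract(rec5, gt_locus(200L, 260L), p))
  expect_null(extract_read_tract(gt_rec(seq = NA_character_),
                                 gt_locus(2L, 8L), p))
})

test_that("rescue_clipped recovers the boundary from the soft clip", {
  p <- tr_params()
  set.seed(31)
  tb <- toy_locus_bundle(motif = "CAG", ref_copies = 20L)
  locus <- tb$locus
  hap <- build_haplotype(tb$reference, locus, "CAG", 400)  # 1200 bp tract
  # read spans, but the alignment stops at the locus start: right side clipped
  s <- locus$start - 400L
  e <- locus$start + hap$tract_len + 400L
  read <- substr(hap$seq, s + 1L, e)
  n <- nchar(read)
  rec <- gt_rec(read_id = "clip", ref_start = s,
                cigar = sprintf("%dM%dS", 400L, n - 400L), seq = read)
  iv <- rescue_clipped(rec, locus, tb$reference, p)
  expect_false(is.null(iv))
  expect_equal(unname(iv), c(400L, 400L + hap$tract_len))

  # mirrored: left side clipped, right side anchored
  rec2 <- gt_rec(read_id = "clip2", ref_start = locus$end,
                 cigar = sprintf("%dS%dM", n - 400L, 400L), seq = read)
  iv2 <- rescue_clipped(rec2, locus, tb$reference, p)
  expect_equal(unname(iv2), c(400L, 400L + hap$tract_len))

  # scrambled clip: flank probe cannot place -> NULL
  bad <- paste0(substr(read, 1, 400), random_dna(n - 400L))
  rec3 <- gt_rec(read_id = "bad", ref_start = s,
                 cigar = sprintf("%dM%dS", 400L, n - 400L), seq = bad)
  expect_null(rescue_clipped(rec3, locus, tb$reference, p))
})

test_that("call_read sizes the tract against the known motif", {
  p <- tr_params()
  cr <- call_read(strrep("CAG", 50), "CAG", p)
  expect_equal(cr$repeat_size, 150L)
  expect_equal(cr$copy_number, 50)
  expect_equal(cr$motif, "CAG")
  expect_equal(cr$purity, 1)
  expect_equal(cr$read_tract_start, 0L)
  # reverse-complement strand of the motif
  cr2 <- call_read(strrep("CTG", 50), "CAG", p)
  expect_equal(cr2$repeat_size, 150L)
  # offset reporting
  cr3 <- call_read(paste0("TTTT", strrep("CAG", 50)), "CAG", p, offset = 10L)
  expect_equal(cr3$read_tract_start, 14L)
  # unrelated sequence: no call
  set.seed(32)
  expect_null(call_read(random_dna(40), "CAG", p))
  expect_null(call_read("", "CAG", p))
  # noisy tract sized within a motif length or two
  set.seed(33)
  noisy <- mutate_dna_simple(strrep("CAG", 100), 0.12)
  cr4 <- call_read(noisy, "CAG", p)
  expect_lt(abs(cr4$repeat_size - nchar(noisy)), 15)
})

test_that("fit_genotype selects k by AIC and reports exact medians", {
  p <- tr_params()
  mk_calls <- function(sizes) data.frame(
    read_id = sprintf("r%d", seq_along(sizes)), repeat_size = sizes,
    copy_number = sizes / 3, read_tract_start = 0L, method = "spanning",
    stringsAsFactors = FALSE)

  g2 <- fit_genotype(mk_calls(c(58, 60, 60, 62, 64, 488, 490, 492, 494, 500)),
                     p)
  expect_s3_class(g2, "tr_genotype")
  expect_equal(g2$k, 2L)
  expect_equal(g2$alleles$size, c(60, 492))
  expect_equal(g2$alleles$support, c(5L, 5L))
  expect_equal(g2$alleles$copy_number, c(20, 164))
  expect_equal(g2$reads$allele,
               c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))

  g1 <- fit_genotype(mk_calls(c(59, 60, 60, 61, 62, 60, 58, 61)), p)
  expect_equal(g1$k, 1L)
  expect_equal(g1$alleles$size, 60)

  # all identical sizes: degenerate single allele
  g0 <- fit_genotype(mk_calls(rep(60, 6)), p)
  expect_equal(g0$k, 1L)
  expect_equal(g0$alleles$size, 60)

  # a singleton outlier component is dropped by min_support
  g3 <- fit_genotype(mk_calls(c(60, 60, 60, 900)), p)
  expect_equal(g3$k, 1L)
  expect_equal(g3$alleles$size, 60)
  expect_true(is.na(g3$reads$allele[4]))

  # exact two-valued data (error-free reads) splits without mixture noise
  g4 <- fit_genotype(mk_calls(c(75, 75, 75, 540, 540)), p)
  expect_equal(g4$k, 2L)
  expect_equal(g4$alleles$size, c(75, 540))
  expect_equal(g4$alleles$support, c(3L, 2L))

  expect_error(fit_genotype(data.frame(), p), "no read calls")
})

test_that("GMM allele recovery over seeded replicates", {
  p <- tr_params()
  set.seed(34)
  ok <- 0L
  for (i in 1:100) {
    a <- round(rnorm(12, 150, 5))
    b <- round(rnorm(12, 450, 10))  # separation 300 >> 4 sd
    calls <- data.frame(read_id = sprintf("r%d", 1:24),
                        repeat_size = c(a, b), copy_number = c(a, b) / 3,
                        read_tract_start = 0L, method = "spanning",
                        stringsAsFactors = FALSE)
    g <- fit_genotype(calls, p)
    if (g$k == 2L &&
        abs(g$alleles$size[1] - 150) < 20 &&
        abs(g$alleles$size[2] - 450) < 45 &&
        all(g$alleles$support == c(12L, 12L))) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("genotype_loci deduplicates reads and prefers spanning calls", {
  p <- tr_params()
  set.seed(35)
  tb <- toy_locus_bundle()
  haps <- list(a = build_haplotype(tb$reference, tb$locus, "CAG", 20),
               b = build_haplotype(tb$reference, tb$locus, "CAG", 150))
  sim <- simulate_reads(haps, n_reads = c(6L, 6L), spanning_only = TRUE,
                        spanning_flanks = c(500L, 1500L))
  gts <- genotype_loci(sim_alignments(sim), tb$reference, tb$locus,
                       params = p)
  expect_s3_class(gts, "tr_genotype_set")
  g <- gts[[1]]
  expect_equal(anyDuplicated(g$reads$read_id), 0L)
  expect_equal(g$k, 2L)
  expect_lte(abs(g$alleles$size[1] - 60), 20)
  expect_lte(abs(g$alleles$size[2] - 450), 45)
  df <- as.data.frame(gts)
  expect_equal(nrow(df), sum(g$alleles$support))
  expect_output(print(gts), "TR genotype")
  expect_output(summary(g), "AIC")
})

test_that("loci with no usable reads produce no genotype", {
  p <- tr_params()
  set.seed(36)
  tb <- toy_locus_bundle()
  far <- gt_locus(10L, 70L)  # no reads near contig start
  rec <- gt_rec(ref_start = 2000L, cigar = "500M", seq = random_dna(500))
  gts <- genotype_loci(rec, tb$reference, far, params = p)
  expect_equal(length(gts), 0L)
})
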