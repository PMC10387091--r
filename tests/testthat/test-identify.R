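test_that("germline-specific regions require full testis cover, no kidney reads, 500 bp", {
  t1 <- c(rep(1L, 600), rep(0L, 100))
  k1 <- rep(0L, 700)
  r <- germline_specific_regions(list(s = t1), list(s = k1))
  expect_equal(r, tibble::tibble(scaffold = "s", start = 0L, end = 600L))

  t2 <- c(rep(1L, 400), rep(0L, 300))
  expect_equal(nrow(germline_specific_regions(list(s = t2), list(s = rep(0L, 700)))), 0)

  # one kidney read base splits a 1,200-bp testis block into 300 + 899
  t3 <- rep(2L, 1200)
  k3 <- rep(0L, 1200); k3[301] <- 1L
  r3 <- germline_specific_regions(list(s = t3), list(s = k3))
  expect_equal(r3$start, 301L)
  expect_equal(r3$end, 1200L)

  expect_error(germline_specific_regions(list(s = t1), list(s = rep(0L, 10))),
               "length mismatch")
})

test_that("region detection equals the per-base brute-force oracle", {
  withr::local_seed(5)
  for (i in 1:25) {
    L <- 5000L
    tv <- sample(0:2, L, TRUE, prob = c(0.3, 0.4, 0.3))
    kv <- sample(0:1, L, TRUE, prob = c(0.95, 0.05))
    # implant a few long clean stretches so regions exist
    for (j in 1:3) {
      st <- sample(L - 1500, 1)
      tv[st:(st + 800)] <- 1L
      kv[st:(st + 800)] <- 0L
    }
    got <- germline_specific_regions(list(s = tv), list(s = kv), min_len = 500)
    oracle <- grcfinder:::cpp_scan_germline_runs(tv, kv, 500L)
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
  }
})

test_that("read overlap selection honours the 10-bp boundary and barcode absence", {
  regions <- tibble::tibble(scaffold = "s", start = 500L, end = 1100L)
  aln <- dplyr::bind_rows(
    aln_row("in140", "s", 490, 150, 150),   # overlap 140
    aln_row("in10", "s", 390, 120, 120),    # ends at 510: overlap exactly 10
    aln_row("out9", "s", 391, 118, 118),    # ends at 509: overlap 9
    aln_row("nobc", "s", 600, 100, 100))
  reads <- tibble::tibble(
    read_id = c("in140", "in10", "out9", "nobc"),
    barcode = c("B1", "B2", "B3", NA))
  sel <- reads_overlapping(regions, aln, reads, min_overlap = 10)
  expect_setequal(sel$barcode, c("B1", "B2"))
  expect_equal(attr(sel, "n_no_barcode"), 1L)
  expect_true(all(sel$channel == "region"))
})

test_that("pileup caller needs two alt reads in one sample and skips N sites", {
  ref <- c(s = "AAAAAAAAAA")
  mk_reads <- function(n, seq, prefix, sample, tissue) {
    tibble::tibble(read_id = paste0(prefix, seq_len(n)), sequence = seq,
                   sample = sample, tissue = tissue)
  }
  # 5 alt reads (C at position 4), 5 ref reads in testis sample T1
  reads <- dplyr::bind_rows(
    mk_reads(5, "AAACAAAAAA", "alt", "T1", "testis"),
    mk_reads(5, "AAAAAAAAAA", "ref", "T1", "testis"))
  aln <- dplyr::bind_rows(lapply(reads$read_id, function(id)
    aln_row(id, "s", 0, 10, 10)))
  calls <- call_variants_pileup(aln, reads, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 3L)
  expect_equal(calls$alt, "C")
  expect_equal(calls$alt_count, 5L)
  expect_equal(calls$depth, 10L)

  # a single alt-supporting read is below the threshold
  reads1 <- dplyr::bind_rows(
    mk_reads(1, "AAACAAAAAA", "alt", "T1", "testis"),
    mk_reads(9, "AAAAAAAAAA", "ref", "T1", "testis"))
  aln1 <- dplyr::bind_rows(lapply(reads1$read_id, function(id)
    aln_row(id, "s", 0, 10, 10)))
  expect_equal(nrow(call_variants_pileup(aln1, reads1, ref)), 0L)

  # all-reference pileup calls nothing
  expect_equal(nrow(call_variants_pileup(aln1[2:10, ], reads1[2:10, ], ref)), 0L)

  # N in the reference masks the site
  refN <- c(s = "AAANAAAAAA")
  expect_equal(nrow(call_variants_pileup(aln, reads, refN)), 0L)
})

test_that("germline-specific SNP filter demands all-testis support and kidney absence", {
  base <- tidyr::expand_grid(
    scaffold = "s", pos = 10L, ref = "A", alt = "G",
    sample = c("T1", "T2", "T3", "K1", "K2", "K3"))
  base$tissue <- ifelse(grepl("^T", base$sample), "testis", "kidney")
  base$depth <- 10L

  ok <- dplyr::mutate(base, alt_count = ifelse(tissue == "testis", 4L, 0L))
  expect_equal(nrow(germline_specific_snps(ok)), 1L)

  two_of_three <- dplyr::mutate(base, alt_count = dplyr::case_when(
    sample == "T3" ~ 0L, tissue == "testis" ~ 4L, .default = 0L))
  expect_equal(nrow(germline_specific_snps(two_of_three)), 0L)

  kidney_leak <- dplyr::mutate(base, alt_count = ifelse(tissue == "testis", 4L, 0L))
  kidney_leak$alt_count[kidney_leak$sample == "K2"] <- 1L
  expect_equal(nrow(germline_specific_snps(kidney_leak)), 0L)
})

test_that("snp_to_kmers yields min(k, pos+1, L-pos) windows, all carrying the alt", {
  ref <- c(ctg = fixture_seq(200, seed = 3))
  km <- snp_to_kmers("ctg", 100L, "A", ref, k = 29)
  expect_length(km, 29)
  expect_true(all(nchar(km) == 29))

  km10 <- snp_to_kmers("ctg", 10L, "A", ref, k = 29)
  expect_length(km10, 11)

  # invariant across positions, and exactly one substitution per kmer
  for (pos in c(0L, 5L, 28L, 100L, 171L, 199L)) {
    refbase <- substr(ref[["ctg"]], pos + 1, pos + 1)
    alt <- setdiff(c("A", "C", "G", "T"), refbase)[1]
    kk <- snp_to_kmers("ctg", pos, alt, ref, k = 29)
    expect_length(kk, min(29, pos + 1, 200 - pos))
    for (w in seq_along(kk)) {
      start <- max(0, pos - 29 + 1) + w - 1
      refwin <- substr(ref[["ctg"]], start + 1, start + 29)
      expect_equal(sum(strsplit(kk[w], "")[[1]] != strsplit(refwin, "")[[1]]), 1L)
    }
  }
})

test_that("soma filtering removes kmers present on either strand of kidney reads", {
  km <- c(a = "ACGTACGTACG", b = "TTTTGGGGCCA", c = "GATCGATCGAT")
  kidney <- tibble::tibble(sequence = c(
    paste0("AAAA", km[["a"]], "AAAA"),          # verbatim
    paste0("GG", revcomp_seq(km[["b"]]), "TT")  # reverse complement
  ))
  surv <- filter_kmers_against_soma(unname(km), kidney)
  expect_equal(surv, km[["c"]])
})

test_that("kmer matching selects barcodes of reads containing surviving kmers", {
  km <- "ACGTACGTACGTACGTACGTACGTACGTA"
  reads <- tibble::tibble(
    read_id = c("hit", "rc_hit", "miss"),
    sequence = c(paste0("TTTT", km, "GGGG"),
                 paste0("CCAA", revcomp_seq(km), "AATT"),
                 fixture_seq(60, seed = 12)),
    barcode = c("B1", "B2", "B3"))
  sel <- match_kmers(km, reads)
  expect_setequal(sel$barcode, c("B1", "B2"))
  expect_true(all(sel$channel == "snp_kmer"))
  expect_equal(nrow(match_kmers(character(), reads)), 0L)
})

test_that("repeat channel applies the 100-bp / 90% identity thresholds", {
  reads <- tibble::tibble(read_id = c("good", "low_id", "short"),
                          sequence = "N", barcode = c("B1", "B2", "B3"))
  aln <- dplyr::bind_rows(
    aln_row("good", "rep", 0, 120, 114),   # identity 0.95
    aln_row("low_id", "rep", 0, 120, 102), # identity 0.85
    aln_row("short", "rep", 0, 90, 90))    # identity 1.0 but 90 bp
  sel <- repeat_reads("ACGT", reads, alignments = aln)
  expect_equal(sel$barcode, "B1")
  expect_true(all(sel$channel == "repeat"))
  expect_error(repeat_reads("", reads), "empty repeat consensus")
})

test_that("barcode expansion recruits exactly the reads sharing selected barcodes", {
  reads <- tibble::tibble(read_id = paste0("r", 1:4),
                          barcode = c("A", "A", "B", NA))
  sel <- tibble::tibble(barcode = "A", channel = "region")
  expect_equal(expand_barcodes(sel, reads)$read_id, c("r1", "r2"))
  expect_equal(nrow(expand_barcodes(sel[0, ], reads)), 0L)
  all_sel <- tibble::tibble(barcode = c("A", "B"), channel = "region")
  expect_equal(expand_barcodes(all_sel, reads)$read_id, c("r1", "r2", "r3"))
})
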