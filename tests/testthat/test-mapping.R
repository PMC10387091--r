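test_that("seed index counts every forward k-mer position", {
  idx <- seed_index(c(s1 = "ACGTACGT"), k = 4)
  expect_equal(index_n_seeds(idx), 5L)
  # the palindromic-context seed appears once per occurrence
  hits <- index_lookup(idx, "ACGT")
  expect_equal(hits$pos, c(0L, 4L))
  expect_equal(nrow(index_lookup(idx, "TTTT")), 0L)
  expect_error(seed_index(c(s1 = "ACG"), k = 11), "shortest scaffold")
})

test_that("error-free reads map uniquely with full-length matches", {
  ref <- c(chr = fixture_seq(5000))
  idx <- seed_index(ref, k = 15)
  reads <- tibble::tibble(read_id = "r1",
                          sequence = substr(ref[["chr"]], 1001, 1100))
  a <- map_reads(reads, idx)
  expect_equal(nrow(a), 1L)
  expect_equal(a$target_start, 1000L)
  expect_equal(a$matches, 100L)
  expect_true(a$unique)
  # reverse-complement read maps to the same locus on the minus strand
  rc <- tibble::tibble(read_id = "r2", sequence = revcomp_seq(reads$sequence))
  b <- map_reads(rc, idx)
  expect_equal(b$target_start, 1000L)
  expect_equal(b$strand, "-")
})

test_that("reads from identical two-copy repeats are flagged non-unique", {
  unit <- fixture_seq(400, seed = 7)
  ref <- c(chr = paste0(fixture_seq(500, seed = 8), unit,
                        fixture_seq(600, seed = 9), unit,
                        fixture_seq(500, seed = 10)))
  idx <- seed_index(ref, k = 15)
  reads <- tibble::tibble(read_id = "r", sequence = substr(unit, 101, 200))
  a <- map_reads(reads, idx)
  expect_gte(nrow(a), 2L)
  expect_true(all(!a$unique))
  expect_equal(length(unique(a$matches)), 1L)
  # placements are reported in deterministic (scaffold, position) order
  expect_equal(a$target_start, sort(a$target_start))
})

test_that("mapper equals the brute-force Hamming oracle on mutated reads", {
  withr::local_seed(11)
  ref <- c(s1 = fixture_seq(20000, seed = 21), s2 = fixture_seq(10000, seed = 22))
  idx <- seed_index(ref, k = 15)
  for (i in 1:40) {
    src <- sample(names(ref), 1)
    pos <- sample(nchar(ref[[src]]) - 100, 1)
    seq <- substr(ref[[src]], pos, pos + 99)
    n_mut <- sample(0:3, 1)
    if (n_mut > 0) {
      at <- sample(100, n_mut)
      for (p in at) {
        b <- substr(seq, p, p)
        substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }
    }
    if (runif(1) < 0.5) seq <- revcomp_seq(seq)
    a <- map_reads(tibble::tibble(read_id = "r", sequence = seq), idx,
                   best_only = TRUE)
    oracle <- hamming_scan(ref, seq)
    expect_equal(a$block_len[1] - a$matches[1], attr(oracle, "mismatches"))
    expect_equal(nrow(a), nrow(oracle))
    expect_setequal(paste(a$target, a$target_start, a$strand),
                    paste(oracle$target, oracle$target_start, oracle$strand))
  }
})

test_that("two planted mismatches give a best alignment with two mismatches", {
  ref <- c(chr = fixture_seq(8000, seed = 31))
  idx <- seed_index(ref, k = 15)
  seq <- substr(ref[["chr"]], 3001, 3100)
  substr(seq, 20, 20) <- if (substr(seq, 20, 20) == "A") "C" else "A"
  substr(seq, 80, 80) <- if (substr(seq, 80, 80) == "G") "T" else "G"
  a <- map_reads(tibble::tibble(read_id = "r", sequence = seq), idx,
                 best_only = TRUE)
  expect_equal(a$block_len - a$matches, 2L)
  expect_equal(a$target_start, 3000L)
})

test_that("barcode voting resolves ties toward the molecule's unique scaffold", {
  aln <- dplyr::bind_rows(
    # r1: tied between chrA and grc
    dplyr::mutate(aln_row("r1", "chrA", 100, 100, 100), unique = FALSE),
    dplyr::mutate(aln_row("r1", "grc", 500, 100, 100), unique = FALSE),
    # r2 (same barcode): unique on grc
    aln_row("r2", "grc", 700, 100, 100),
    # r3 (other barcode): unique on chrA
    aln_row("r3", "chrA", 900, 100, 100),
    # r4 (r3's molecule): tied
    dplyr::mutate(aln_row("r4", "chrA", 950, 100, 100), unique = FALSE),
    dplyr::mutate(aln_row("r4", "grc", 10, 100, 100), unique = FALSE))
  reads <- tibble::tibble(read_id = paste0("r", 1:4),
                          barcode = c("m1", "m1", "m2", "m2"))
  res <- barcode_aware_primary(aln, reads, prefer = "grc")
  expect_equal(nrow(res), 4L)
  expect_equal(res$target[res$query_id == "r1"], "grc")
  expect_equal(res$target[res$query_id == "r4"], "chrA")
})

test_that("tiled mapping recovers the source interval of long queries", {
  ref <- c(chr = fixture_seq(30000, seed = 41))
  idx <- seed_index(ref, k = 15)
  q <- c(scafX = substr(ref[["chr"]], 5001, 9000))
  a <- map_tiles(q, idx, tile = 500)
  expect_true(all(a$target_start == 5000 + a$query_start))
  expect_equal(sum(a$block_len[!duplicated(a$query_start)]), 4000)
})
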