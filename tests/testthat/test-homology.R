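test_that("interval merging follows the gap rule and is idempotent", {
  iv <- tibble::tibble(start = c(0L, 5000L), end = c(100L, 5100L))
  m <- merge_within_gap(iv, gap = 10000)
  expect_equal(m, tibble::tibble(start = 0L, end = 5100L))

  touching <- tibble::tibble(start = c(0L, 10L), end = c(10L, 20L))
  expect_equal(merge_within_gap(touching, gap = 0),
               tibble::tibble(start = 0L, end = 20L))

  # beyond the gap stays split
  far <- tibble::tibble(start = c(0L, 20000L), end = c(100L, 20100L))
  expect_equal(nrow(merge_within_gap(far, gap = 10000)), 2L)

  m2 <- merge_within_gap(m, gap = 10000)
  expect_equal(m, m2)
})

test_that("merging equals the transitive-closure oracle on random interval sets", {
  withr::local_seed(13)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    start <- sample(0:20000, n, TRUE)
    end <- start + sample(1:3000, n, TRUE)
    gap <- sample(c(0L, 100L, 1000L, 5000L), 1)
    got <- merge_within_gap(tibble::tibble(start = start, end = end), gap = gap)
    # order invariance
    perm <- sample(n)
    got_perm <- merge_within_gap(tibble::tibble(start = start[perm],
                                                end = end[perm]), gap = gap)
    expect_equal(got, got_perm)
    oracle <- merge_oracle(start, end, gap)
    expect_equal(got$start, unname(oracle[, 1]))
    expect_equal(got$end, unname(oracle[, 2]))
  }
})

test_that("homology labels partition the GRC and respect planted structure", {
  # species A GRC: scaffold sA (3 kb shared + 2 kb 'potential' + 1 kb specific)
  grc_lengths <- c(sA = 6000L)
  # direct cross-alignment covers [0, 3000)
  cross <- aln_row("sA", "other_grc_scaf", 0, 3000, 2950)
  cross$query_start <- 0L; cross$query_end <- 3000L
  # genome placements: shared part -> chr1[0,3000); potential part ->
  # chr2[0,2000); specific part -> chr3[0,1000)
  gs <- dplyr::bind_rows(
    dplyr::mutate(aln_row("sA", "chr1", 0, 3000, 2950), query_start = 0L, query_end = 3000L),
    dplyr::mutate(aln_row("sA", "chr2", 0, 2000, 1980), query_start = 3000L, query_end = 5000L),
    dplyr::mutate(aln_row("sA", "chr3", 0, 1000, 990), query_start = 5000L, query_end = 6000L))
  # other species' GRC maps to chr1 (same region) and chr2[6000,8000):
  # within 10 kb of chr2[0,2000) so footprints merge -> potential
  go <- dplyr::bind_rows(
    dplyr::mutate(aln_row("sB", "chr1", 0, 3000, 2900), query_start = 0L, query_end = 3000L),
    dplyr::mutate(aln_row("sB", "chr2", 6000, 2000, 1980), query_start = 3000L, query_end = 5000L))
  cls <- classify_homology(grc_lengths, cross, gs, go)
  expect_equal(sum(cls$end - cls$start), 6000L)
  lab <- function(l) sum(cls$end[cls$label == l] - cls$start[cls$label == l])
  expect_equal(lab("homologous"), 3000L)
  expect_equal(lab("potentially_homologous"), 2000L)
  expect_equal(lab("species_specific"), 1000L)
  # no overlapping labels
  o <- cls[order(cls$start), ]
  expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
})

test_that("weak or short cross-alignments do not count as homologous", {
  grc_lengths <- c(sA = 2000L)
  weak <- dplyr::mutate(aln_row("sA", "sB", 0, 1000, 850),  # identity 0.85
                        query_start = 0L, query_end = 1000L)
  short <- dplyr::mutate(aln_row("sA", "sB", 0, 400, 400),
                         query_start = 1000L, query_end = 1400L)
  cls <- classify_homology(grc_lengths, dplyr::bind_rows(weak, short),
                           empty_aln(), empty_aln())
  expect_true(all(cls$label == "species_specific"))
})

test_that("origin attribution weights by copy number and breaks ties by block length", {
  chrom <- tibble::tibble(scaffold = c("c1", "c2", "c3"),
                          chromosome = c("chr1", "chr2", "chr3"),
                          length = c(60L, 30L, 10L))
  # expected proportions follow chromosome sizes
  aln <- dplyr::bind_rows(
    dplyr::mutate(aln_row("g1", "c2", 0, 1000, 990), query_start = 0L, query_end = 1000L),
    dplyr::mutate(aln_row("g2", "c2", 0, 500, 480), query_start = 0L, query_end = 500L))
  res <- origin_attribution(aln, chrom)
  expect_equal(res$proportions$expected, c(0.6, 0.3, 0.1))
  expect_equal(res$proportions$observed[res$proportions$chromosome == "chr2"], 1)

  # equal matches, longer block wins
  tie <- dplyr::bind_rows(
    dplyr::mutate(aln_row("g1", "c1", 0, 900, 800), query_start = 0L, query_end = 900L),
    dplyr::mutate(aln_row("g1", "c2", 0, 850, 800), query_start = 0L, query_end = 900L))
  res2 <- origin_attribution(tie, chrom)
  expect_equal(res2$attributions$chromosome, "chr1")

  # copy-number weighting doubles a duplicated scaffold's contribution
  two <- dplyr::bind_rows(
    dplyr::mutate(aln_row("dup", "c1", 0, 1000, 990), query_start = 0L, query_end = 1000L),
    dplyr::mutate(aln_row("single", "c2", 0, 1000, 990), query_start = 0L, query_end = 1000L))
  cn <- tibble::tibble(scaffold = c("dup", "single"), copy_number = c(3, 1))
  res3 <- origin_attribution(two, chrom, cn)
  obs <- res3$proportions$observed
  expect_equal(obs[res3$proportions$chromosome == "chr1"], 0.75)
  expect_equal(sum(res3$proportions$observed), 1, tolerance = 1e-9)
})

test_that("divergence polarity signs regions and drops ties", {
  a1 <- dplyr::bind_rows(
    dplyr::mutate(aln_row("r1", "chr1", 0, 1000, 990), query_start = 0L, query_end = 1000L),
    dplyr::mutate(aln_row("r2", "chr1", 0, 1000, 980), query_start = 0L, query_end = 1000L),
    dplyr::mutate(aln_row("only1", "chr1", 0, 1000, 999), query_start = 0L, query_end = 1000L))
  a2 <- dplyr::bind_rows(
    dplyr::mutate(aln_row("r1", "chr1b", 0, 1000, 980), query_start = 0L, query_end = 1000L),
    dplyr::mutate(aln_row("r2", "chr1b", 0, 1000, 980), query_start = 0L, query_end = 1000L))
  d <- divergence_polarity(a1, a2)
  # r1: 1% vs 2% mismatches -> closer to species 1
  expect_equal(d$d[d$scaffold == "r1"], -0.01)
  # r2 equally divergent -> removed
  expect_false("r2" %in% d$scaffold)
  expect_equal(attr(d, "n_equal"), 1L)
  expect_equal(attr(d, "n_single_side"), 1L)
})

test_that("homology summary reports raw and copy-weighted totals", {
  cls <- tibble::tibble(scaffold = c("s1", "s1", "s2"),
                        start = c(0L, 500L, 0L), end = c(500L, 800L, 1000L),
                        label = c("homologous", "species_specific", "homologous"))
  cn <- tibble::tibble(scaffold = c("s1", "s2"), copy_number = c(1, 3))
  s <- homology_summary(cls, cn)
  expect_equal(s$bp[s$label == "homologous"], 1500L)
  expect_equal(s$weighted_bp[s$label == "homologous"], 500 + 3000)
})
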