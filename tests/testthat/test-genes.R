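test_that("overlapping same-strand hits merge into exons; opposite strands stay apart", {
  mk_hit <- function(gene, s_start, s_end, strand = "+", bits = 200,
                     q_start = 0L, q_end = s_end - s_start) {
    tibble::tibble(query_id = gene, subject_id = "scafG", pident = 95,
                   length = (s_end - s_start) %/% 3L, mismatch = 0L, gapopen = 0L,
                   q_start = q_start, q_end = q_end,
                   s_start = s_start, s_end = s_end, strand = strand,
                   evalue = 1e-30, bitscore = bits, frame = 1L)
  }
  h <- dplyr::bind_rows(mk_hit("gX", 100L, 400L), mk_hit("gX", 300L, 600L))
  e <- annotate_exons(h)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$start, e$end), c(100L, 600L))

  h2 <- dplyr::bind_rows(mk_hit("gX", 100L, 400L),
                         mk_hit("gX", 300L, 600L, strand = "-"))
  expect_equal(nrow(annotate_exons(h2)), 2L)

  # merged exon goes to the top bitscore gene
  h3 <- dplyr::bind_rows(mk_hit("gX", 100L, 400L, bits = 200),
                         mk_hit("gY", 300L, 600L, bits = 180))
  e3 <- annotate_exons(h3)
  expect_equal(e3$gene_id, "gX")

  # hits above the e-value cut-off are discarded
  weak <- dplyr::mutate(mk_hit("gX", 100L, 400L), evalue = 1e-3)
  expect_equal(nrow(annotate_exons(weak)), 0L)
})

test_that("completeness reproduces the floored-normalization worked examples", {
  expect_equal(completeness(0.80, 0.80), 1.0)
  expect_equal(completeness(0.05, 0.05), 0.05 / 0.75)
  expect_equal(round(100 * completeness(0.05, 0.05), 1), 6.7)
  expect_equal(completeness(0.75, 0.20), 1.0)
})

test_that("completeness is monotone and bounded on a grid", {
  g <- seq(0, 1, by = 0.05)
  for (pg in g) {
    vals <- completeness(g, pg)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) >= 0))   # nondecreasing in raw proportion
  }
  for (raw in g) {
    vals <- completeness(raw, g)
    expect_true(all(diff(vals) <= 1e-12))  # nonincreasing in genome proportion
  }
})

test_that("gene inclusion keeps genes with >= 25% in at least one species", {
  expect_true(include_gene(0.30, 0.00))
  expect_false(include_gene(0.24, 0.24))
  expect_true(include_gene(0.25, NA))
  expect_equal(include_gene(c(0.3, 0.24, 0.25), c(0, 0.24, NA)),
               c(TRUE, FALSE, TRUE))
})

test_that("premature-stop rule agrees with the translation oracle on random exons", {
  withr::local_seed(17)
  n_checked <- 0
  for (i in 1:300) {
    L <- sample(30:400, 1)
    seq <- fixture_seq(L, seed = 1000 + i)
    expect_equal(premature_stop(seq),
                 longest_open_oracle(seq) < 0.95 * L)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("the 95% boundary is inclusive and minus strands are handled", {
  # 60-bp exon engineered so frame 1 is capped at 56 bp (stop at base 1),
  # frame 2 at 52 bp (stop at base 5), and frame 0 carries the deciding stop
  make_exon <- function(frame0_stop_at) {
    v <- character(60)
    v[1] <- "C"; v[2:4] <- c("T", "A", "A")       # frame-1 stop
    v[5] <- "C"; v[6:8] <- c("T", "G", "A")       # frame-2 stop
    v[9] <- "C"
    v[10:57] <- rep(c("G", "C", "C"), 16)         # stop-free filler
    v[58:60] <- c("G", "C", "C")
    v[(frame0_stop_at + 1):(frame0_stop_at + 3)] <- c("T", "A", "A")
    paste(v, collapse = "")
  }
  at_boundary <- make_exon(57)   # frame-0 open stretch exactly 57 = 0.95 * 60
  expect_equal(longest_open_oracle(at_boundary), 57)
  expect_false(premature_stop(at_boundary))
  below <- make_exon(54)         # best frame now reaches only 56 bp
  expect_equal(longest_open_oracle(below), 56)
  expect_true(premature_stop(below))
  # minus-strand exon is reverse-complemented before scanning
  expect_false(premature_stop(revcomp_seq(strrep("GCT", 30)), strand = "-"))
  expect_error(premature_stop("AC"), "codon")
})

test_that("gene copy number is the exon-length-weighted scaffold mean", {
  exons <- tibble::tibble(gene_id = c("g", "g"), scaffold = c("s1", "s2"),
                          start = c(0L, 0L), end = c(300L, 100L))
  cn <- tibble::tibble(scaffold = c("s1", "s2"), sample = "i1",
                       copy_number = c(1, 5))
  g <- gene_copy_number(exons, cn)
  expect_equal(g$copy_number, (300 * 1 + 100 * 5) / 400)
  one <- gene_copy_number(exons[1, ], cn)
  expect_equal(one$copy_number, 1)
})

test_that("sharing categories and completeness bands follow the definitions", {
  expect_equal(sharing_category(TRUE, TRUE, "species_specific"), "both_unambiguous")
  expect_equal(sharing_category(TRUE, FALSE, "potentially_homologous"),
               "potentially_shared")
  expect_equal(sharing_category(TRUE, FALSE, "species_specific"), "species_specific")

  b <- completeness_band(c(0, 0.1, 0.5, 0.51, 0.75, 0.76, 0.95, 0.96, 1))
  expect_equal(as.character(b),
               c("none", ">0%", ">0%", ">50%", ">50%", ">75%", ">75%", ">95%", ">95%"))
  # band counts are nested by construction
  x <- runif(200)
  counts <- vapply(c(0, 0.5, 0.75, 0.95), function(th) sum(x > th), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("FPKM arithmetic and the completeness-expression fit behave", {
  expect_equal(fpkm(100, 2, 10), 5)
  expect_error(fpkm(10, 0, 1), "exon_kbp")

  withr::local_seed(23)
  n <- 150
  comp <- runif(n)
  log2fpkm <- -2 + 4 * comp + rnorm(n, 0, 1)
  rec <- tibble::tibble(gene_id = paste0("g", 1:n), fpkm = 2^log2fpkm,
                        completeness = comp)
  rec$fpkm[1:5] <- 0   # unexpressed genes are excluded from the fit
  fit <- completeness_expression_fit(rec)
  td <- tidy(fit)
  slope <- td$estimate[td$term == "completeness"]
  se <- td$std.error[td$term == "completeness"]
  expect_gt(slope + 2.1 * se, 4)
  expect_lt(slope - 2.1 * se, 4)
  gl <- glance(fit)
  expect_equal(gl$nobs, n - 5)
  expect_equal(gl$n_zero_fpkm, 5)
  expect_gt(gl$r.squared, 0.3)
})

test_that("the naive translated search finds planted coding fragments", {
  withr::local_seed(29)
  cds <- c(geneA = paste(sample(setdiff(
    apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
          1, paste, collapse = ""), c("TAA","TAG","TGA")), 200, TRUE),
    collapse = ""))
  scaf <- paste0(fixture_seq(500, seed = 31), substr(cds[["geneA"]], 1, 300),
                 fixture_seq(400, seed = 32))
  hits <- translated_search(cds, c(grcS = scaf))
  expect_gt(nrow(hits), 0)
  best <- hits[which.max(hits$bitscore), ]
  expect_equal(best$query_id, "geneA")
  expect_equal(best$strand, "+")
  expect_lte(abs(best$s_start - 500), 15)
  # reverse-complemented insertion is found on the minus strand
  scaf_rc <- paste0(fixture_seq(300, seed = 33),
                    revcomp_seq(substr(cds[["geneA"]], 1, 300)),
                    fixture_seq(300, seed = 34))
  hits_rc <- translated_search(cds, c(grcR = scaf_rc))
  expect_true(any(hits_rc$strand == "-"))
  raw <- gene_raw_proportions(annotate_exons(hits), nchar(cds))
  expect_equal(raw$raw_prop, 300 / 600, tolerance = 0.06)
})
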