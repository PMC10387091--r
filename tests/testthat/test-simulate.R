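small_cfg <- function(seed = 2, germline_a_depth = 12, soma_depth = 8, ...) {
  sim_config(
    seed = seed,
    germline_a_depth = germline_a_depth, soma_depth = soma_depth,
    a_genome = c(chrA1 = 30000L, chrA2 = 15000L),
    grc_segments = tibble::tibble(
      segment = c("u", "dup"), source_scaffold = c("chrA1", "chrA2"),
      start = c(2000L, 1000L), end = c(12000L, 6000L),
      divergence = c(0.01, 0.005), copy_number = c(1L, 3L),
      copy_divergence = 0),
    repeat_array_len = 2000L,
    gene_models = no_genes(),
    n_samples = 1L, ...)
}

test_that("collapsed duplications are byte-identical copies with truth copy number", {
  g <- simulate_genome(small_cfg())
  segs <- g$truth$segments
  dup <- segs[segs$segment == "dup", ]
  expect_equal(dup$copy_number, 3L)
  copies <- g$truth$copies[g$truth$copies$segment == "dup", ]
  expect_equal(nrow(copies), 3L)
  seqs <- g$copy_seqs[copies$copy_id]
  expect_length(unique(seqs), 1)
  expect_equal(unique(unname(seqs)), unname(g$grc_assembly[[dup$scaffold]]))
})

test_that("divergence 0 copies the A source verbatim; diverged copies differ ~ binomially", {
  cfg <- sim_config(
    seed = 5, a_genome = c(chrA1 = 20000L),
    grc_segments = tibble::tibble(
      segment = c("zero", "one"), source_scaffold = "chrA1",
      start = c(0L, 10000L), end = c(10000L, 20000L),
      divergence = c(0, 0.01), copy_number = 1L, copy_divergence = 0),
    repeat_array_len = 0L, gene_models = no_genes(), n_samples = 1L)
  g <- simulate_genome(cfg)
  src <- g$a_seqs[["chrA1"]]
  expect_equal(g$grc_assembly[["grc_zero"]], substr(src, 1, 10000))
  diffs <- sum(strsplit(g$grc_assembly[["grc_one"]], "")[[1]] !=
                 strsplit(substr(src, 10001, 20000), "")[[1]])
  # Binomial(10000, 0.01): 100 +/- 3 sd
  expect_gt(diffs, 100 - 3 * sqrt(100 * 0.99))
  expect_lt(diffs, 100 + 3 * sqrt(100 * 0.99))
  expect_equal(nrow(g$truth$snps), diffs)
})

test_that("copy-weighted truth length is conserved exactly", {
  g <- simulate_genome(small_cfg())
  segs <- g$truth$segments
  expect_equal(true_grc_size(g), sum(segs$length * segs$copy_number))
  # every true copy is accounted for
  expect_equal(nrow(g$truth$copies), sum(segs$copy_number))
})

test_that("identical configuration reproduces byte-identical outputs", {
  d1 <- simulate_grc_dataset(small_cfg())
  d2 <- simulate_grc_dataset(small_cfg())
  expect_identical(d1$genome$a_seqs, d2$genome$a_seqs)
  expect_identical(d1$genome$grc_assembly, d2$genome$grc_assembly)
  expect_identical(d1$reads$reads, d2$reads$reads)
  d3 <- simulate_grc_dataset(small_cfg(seed = 3))
  expect_false(identical(d1$reads$reads$sequence, d3$reads$reads$sequence))
})

test_that("molecules are confined to one source and barcodes are pure", {
  ds <- simulate_grc_dataset(small_cfg())
  tr <- ds$reads$truth_reads
  per_bc <- tapply(tr$source_id, tr$barcode, function(x) length(unique(x)))
  expect_true(all(per_bc == 1))
  tm <- ds$reads$truth_molecules
  expect_true(all(tm$mol_start >= 0))
  # reads fall inside their molecule's interval
  j <- match(tr$barcode, tm$barcode)
  expect_true(all(tr$pos >= tm$mol_start[j]))
  expect_true(all(tr$pos + ds$genome$config$read_len <= tm$mol_end[j]))
})

test_that("with error rate zero every read is an exact substring of its source", {
  ds <- simulate_grc_dataset(small_cfg(error_rate = 0))
  tr <- ds$reads$truth_reads
  reads <- ds$reads$reads
  all_seqs <- c(ds$genome$a_seqs, ds$genome$copy_seqs)
  idx <- sample.int(nrow(reads), 500)
  rl <- ds$genome$config$read_len
  for (i in idx) {
    src <- substr(all_seqs[[tr$source_id[i]]], tr$pos[i] + 1, tr$pos[i] + rl)
    obs <- reads$sequence[i]
    if (tr$strand[i] == "-") obs <- revcomp_seq(obs)
    expect_identical(obs, src)
  }
})

test_that("kidney samples only the A-genome; testis GRC depth matches the ratio", {
  cfg <- small_cfg(seed = 8, grc_singlecopy_ratio = 0.2, germline_a_depth = 50,
                   soma_depth = 10)
  ds <- simulate_grc_dataset(cfg)
  tr <- ds$reads$truth_reads
  a_names <- names(ds$genome$a_seqs)
  expect_true(all(tr$source_id[tr$tissue == "kidney"] %in% a_names))
  # depth over the unique single-copy segment (10 kbp): expect 0.2 * 50 = 10
  u <- tr[tr$source_id == "grc_u_copy1" & tr$tissue == "testis", ]
  depth <- nrow(u) * cfg$read_len / 10000
  expect_gt(depth, 10 - 3 * sqrt(10 * 100 / 10000) * 3)  # generous Poisson band
  expect_lt(abs(depth - 10), 1)
})

test_that("gene fragments carry the configured retained fraction exactly", {
  ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  cfg <- sim_config(
    seed = 4, a_genome = c(chrA1 = 30000L),
    grc_segments = tibble::tibble(
      segment = "u", source_scaffold = "chrA1", start = 0L, end = 5000L,
      divergence = 0.01, copy_number = 1L, copy_divergence = 0),
    repeat_array_len = 0L,
    gene_models = tibble::tibble(
      gene_id = c("full", "half", "stopper"), scaffold = "chrA1",
      exons = list(ex(10000, 10600), ex(12000, 12300, 13000, 13300),
                   ex(15000, 15900)),
      fraction_retained = c(1, 0.5, 1),
      premature_stop = c(FALSE, FALSE, TRUE)),
    n_samples = 1L)
  g <- plant_gene_fragments(simulate_genome(cfg))
  gt <- g$truth$genes
  expect_equal(gt$retained_len[gt$gene_id == "full"], 600L)
  expect_equal(gt$retained_len[gt$gene_id == "half"], 300L)

  # full gene without planted stop translates openly in its frame
  full <- gt[gt$gene_id == "full", ]
  iv <- full$grc_exons[[1]]
  seq <- substr(g$grc_assembly[[full$scaffold]], iv[1, 1] + 1, iv[1, 2])
  expect_false(premature_stop(seq))

  # planted stop sits in frame before 95% of the exon
  st <- gt[gt$gene_id == "stopper", ]
  iv <- st$grc_exons[[1]]
  seq <- substr(g$grc_assembly[[st$scaffold]], iv[1, 1] + 1, iv[1, 2])
  expect_true(premature_stop(seq))
  expect_lt(st$stop_pos - iv[1, 1], 0.95 * (iv[1, 2] - iv[1, 1]))
})

test_that("invalid configurations are rejected", {
  expect_error(small_cfg(grc_singlecopy_ratio = 1.2), class = "grc_config_error")
  expect_error(small_cfg(molecule_len = 50L), class = "grc_config_error")
  expect_error(sim_config(
    a_genome = c(chrA1 = 1000L),
    grc_segments = tibble::tibble(
      segment = "x", source_scaffold = "chrA1", start = 500L, end = 2000L,
      divergence = 0, copy_number = 1L, copy_divergence = 0),
    gene_models = no_genes()), class = "grc_config_error")
  ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  expect_error(sim_config(
    gene_models = tibble::tibble(
      gene_id = "g", scaffold = "chrA3", exons = list(ex(100, 400, 300, 600)),
      fraction_retained = 1, premature_stop = FALSE)),
    "overlapping", class = "grc_config_error")
})
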