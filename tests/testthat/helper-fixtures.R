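# Small shared fixtures built in code.

# deterministic random sequence outside the package's generator
fixture_seq <- function(n, seed = 99) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

# a minimal alignment tibble row
aln_row <- function(query_id, target, target_start, block_len, matches,
                    strand = "+", query_start = 0L) {
  tibble::tibble(
    query_id = query_id, query_len = block_len, query_start = query_start,
    query_end = query_start + block_len, strand = strand, target = target,
    target_len = NA_integer_, target_start = as.integer(target_start),
    target_end = as.integer(target_start + block_len),
    matches = as.integer(matches), block_len = as.integer(block_len),
    mapq = 60L, unique = TRUE)
}

empty_aln <- function() grcfinder:::empty_alignments()

# an empty gene-model tibble for simulations that do not need genes
no_genes <- function() {
  tibble::tibble(gene_id = character(), scaffold = character(), exons = list(),
                 fraction_retained = numeric(), premature_stop = logical())
}

# independent interval-merge oracle: repeated pairwise merging to a fixed point
merge_oracle <- function(start, end, gap) {
  iv <- cbind(start, end)
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i >= j) next
        if (iv[j, 1] - iv[i, 2] <= gap && iv[i, 1] - iv[j, 2] <= gap) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# independent open-reading-frame oracle: translate every frame with Biostrings
# and measure stop-free stretches in bp (leading/trailing partial codons count
# toward the flanking open stretch)
longest_open_oracle <- function(seq) {
  L <- nchar(seq)
  best <- 0L
  for (f in 0:2) {
    n <- (L - f) %/% 3
    if (n <= 0) { best <- max(best, L); next }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, f + 1, f + 3 * n)),
      if.fuzzy.codon = "X"))
    stops <- which(strsplit(aa, "")[[1]] == "*")
    if (length(stops) == 0) { best <- max(best, L); next }
    starts_bp <- f + 3 * (stops - 1)
    bounds <- c(0, rbind(starts_bp, starts_bp + 3), L)
    opens <- bounds[seq(2, length(bounds), 2)] - bounds[seq(1, length(bounds), 2)]
    best <- max(best, max(opens))
  }
  best
}
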