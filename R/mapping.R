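#' Build an exact-seed index over reference sequences
#'
#' Indexes every k-mer position of every scaffold for the minimal
#' seed-and-extend mapper. Output of a production aligner (as PAF) can be
#' substituted for this mapper at every call site in the pipeline.
#'
#' @param seqs Named character vector of reference sequences.
#' @param k Seed length in bp (1--32; use >= 11 for mapping so random seed
#'   collisions stay negligible).
#' @return A `grc_seed_index` object.
#' @export
seed_index <- function(seqs, k = 21L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (k < 1 || k > 32) abort("seed length k must be in 1..32")
  if (min(nchar(seqs)) < k) abort("k is longer than the shortest scaffold")
  structure(list(
    ptr = cpp_build_index(unname(seqs), names(seqs), as.integer(k)),
    names = names(seqs), lengths = setNames(nchar(seqs), names(seqs)),
    k = as.integer(k)
  ), class = "grc_seed_index")
}

#' Look up one seed in the index
#'
#' @param index A `grc_seed_index`.
#' @param seed Character scalar of length `k` (forward orientation).
#' @return Tibble with `scaffold` and 0-based `pos` of every exact occurrence;
#'   empty for absent seeds.
#' @export
index_lookup <- function(index, seed) {
  d <- cpp_index_lookup(index$ptr, seed)
  tibble(scaffold = index$names[d$seq_idx + 1L], pos = d$pos)
}

#' Number of indexed seed positions
#' @param index A `grc_seed_index`.
#' @return Integer count of (scaffold, position) seed entries.
#' @export
index_n_seeds <- function(index) cpp_index_n_seeds(index$ptr)

#' Map reads with exact seeding and ungapped extension
#'
#' Seeds are chained per (scaffold, diagonal, strand) and every candidate
#' placement is scored by full-read Hamming distance; `matches = read length -
#' mismatches`. Placements are reported in ascending mismatch order, ties
#' broken lexicographically by (scaffold, position); the `unique` flag is true
#' only for a best placement whose mismatch count is strictly lower than every
#' other placement of that read.
#'
#' @param reads Tibble with `read_id` and `sequence` columns (e.g. from
#'   [simulate_reads()] or [read_fastq_barcoded()]).
#' @param index A `grc_seed_index` built on the target sequences.
#' @param max_hits Maximum placements reported per read.
#' @param best_only Keep only placements tied with the best mismatch count.
#' @return Alignment tibble (PAF column set plus `unique`); reads with no
#'   placement contribute no rows.
#' @export
map_reads <- function(reads, index, max_hits = 50L, best_only = FALSE) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (nrow(reads) == 0) return(empty_alignments())
  d <- cpp_map_reads(index$ptr, reads$sequence, as.integer(max_hits), best_only)
  if (nrow(d) == 0) return(empty_alignments())
  len <- nchar(reads$sequence)[d$read]
  out <- tibble(
    query_id = reads$read_id[d$read],
    query_len = len, query_start = 0L, query_end = len,
    strand = ifelse(d$minus == 1L, "-", "+"),
    target = index$names[d$target_idx],
    target_len = unname(index$lengths[d$target_idx]),
    target_start = d$target_start, target_end = d$target_start + len,
    matches = len - d$mismatches, block_len = len,
    mapq = ifelse(d$unique_best == 1L, 60L, 0L),
    unique = d$unique_best == 1L
  )
  out
}

#' Keep only the best-tied placements of each query
#'
#' @param aln Alignment tibble.
#' @return Tibble restricted, per `query_id`, to placements with the minimal
#'   mismatch count (`block_len - matches`).
#' @export
best_alignments <- function(aln) {
  mm <- aln$block_len - aln$matches
  grp <- match(aln$query_id, unique(aln$query_id))
  best <- vapply(split(mm, grp), min, numeric(1))
  aln[mm == best[grp], ]
}

#' Reduce alignments to one primary placement per read
#'
#' Coverage-based copy-number estimation needs each read counted exactly once.
#' Among a read's best-tied placements, the primary is chosen from the
#' `prefer` targets when any is tied (so reads ambiguous between an A
#' chromosome and its GRC paralog are counted on the GRC, whose A-chromosomal
#' contamination the somatic subtraction then removes); remaining ties break
#' lexicographically by (scaffold, position).
#'
#' @param aln Alignment tibble.
#' @param prefer Character vector of target names to prefer among ties
#'   (typically the GRC scaffolds).
#' @return Alignment tibble with one row per `query_id`.
#' @export
primary_alignments <- function(aln, prefer = character()) {
  if (nrow(aln) == 0) return(aln)
  mm <- aln$block_len - aln$matches
  o <- order(aln$query_id, mm, !(aln$target %in% prefer),
             aln$target, aln$target_start)
  s <- aln[o, ]
  s[!duplicated(s$query_id), ]
}

#' Resolve ambiguous placements by linked-read barcode voting
#'
#' For a read tied between several best placements (typically between an A
#' chromosome and its near-identical GRC paralog), the other reads of the same
#' molecule usually span diagnostic differences and map uniquely. Each read's
#' tie is therefore resolved toward the target scaffold that carries the most
#' uniquely mapped reads of its barcode; remaining ties fall back to the
#' `prefer` rule of [primary_alignments()]. This is the linked-read analogue
#' of paired-end rescue and is the recommended placement policy for
#' coverage-based copy-number estimation.
#'
#' @param aln Alignment tibble of best-tied placements (from
#'   `map_reads(..., best_only = TRUE)`).
#' @param reads Read tibble with `read_id` and `barcode`.
#' @param prefer Targets preferred when barcode votes do not decide.
#' @return Alignment tibble with one row per `query_id`.
#' @export
barcode_aware_primary <- function(aln, reads, prefer = character()) {
  if (nrow(aln) == 0) return(aln)
  bc <- reads$barcode[match(aln$query_id, reads$read_id)]
  dup <- aln$query_id %in% aln$query_id[duplicated(aln$query_id)]
  votes <- tibble(barcode = bc[aln$unique & !is.na(bc)],
                  target = aln$target[aln$unique & !is.na(bc)]) %>%
    dplyr::count(.data$barcode, .data$target, name = "votes")
  tied <- aln[dup, ]
  tied$barcode <- bc[dup]
  tied <- left_join(tied, votes, by = c("barcode", "target"))
  tied$votes[is.na(tied$votes)] <- 0L
  o <- order(tied$query_id, -tied$votes, !(tied$target %in% prefer),
             tied$target, tied$target_start)
  tied <- tied[o, ]
  tied <- tied[!duplicated(tied$query_id), ]
  tied$votes <- NULL
  tied$barcode <- NULL
  bind_rows(aln[!dup, ], tied)
}

#' Map long sequences as tiles
#'
#' Chops each query sequence into fixed-length tiles and maps each tile with
#' [map_reads()], keeping only best-tied placements. Used to place assembly
#' scaffolds onto a reference for homology and divergence analyses.
#'
#' @param seqs Named character vector of query sequences.
#' @param index A `grc_seed_index` on the reference.
#' @param tile Tile length in bp; a final tile is anchored at the sequence end
#'   so every base is covered.
#' @param step Distance between tile starts (defaults to `tile`).
#' @return Alignment tibble; `query_id` is the sequence name and
#'   `query_start`/`query_end` give the tile interval on it.
#' @export
map_tiles <- function(seqs, index, tile = 500L, step = tile) {
  out <- list()
  for (nm in names(seqs)) {
    L <- nchar(seqs[[nm]])
    w <- min(tile, L)
    starts <- unique(c(seq(0L, max(0L, L - w), by = step), L - w))
    tiles <- tibble(
      read_id = sprintf("%s:%d", nm, starts),
      sequence = substring(seqs[[nm]], starts + 1L, starts + w))
    aln <- map_reads(tiles, index, best_only = TRUE)
    if (nrow(aln) == 0) next
    qs <- as.integer(sub(".*:", "", aln$query_id))
    aln$query_id <- nm
    aln$query_start <- qs
    aln$query_end <- qs + aln$block_len
    out[[nm]] <- aln
  }
  if (length(out) == 0) empty_alignments() else bind_rows(out)
}

#' Brute-force Hamming placement scan
#'
#' Independent oracle for the seed mapper: evaluates every full-length
#' placement of the read on both strands of every reference sequence and
#' returns all placements achieving the minimal mismatch count.
#'
#' @param refs Named character vector of reference sequences.
#' @param read Read sequence (character scalar).
#' @return Tibble of best placements (`target`, 0-based `target_start`,
#'   `strand`) with the minimal mismatch count in attribute `"mismatches"`.
#' @export
hamming_scan <- function(refs, read) {
  d <- cpp_hamming_scan(unname(refs), names(refs), read)
  out <- tibble(target = names(refs)[d$target_idx],
                target_start = d$target_start,
                strand = ifelse(d$minus == 1L, "-", "+"))
  attr(out, "mismatches") <- attr(d, "mismatches")
  out
}
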