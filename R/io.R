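#' Read a FASTA file
#'
#' Strict FASTA reader: the identifier is the header token before the first
#' whitespace, case of the sequence is preserved, and duplicate identifiers or
#' empty sequences are format errors that name the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (length(lines) == 0 || !hdr[1])
    format_error("FASTA must start with a '>' header", path, 1L)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(ids == "")) {
    bad <- which(hdr)[ids == ""][1]
    format_error("malformed FASTA header", path, bad)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    bad <- which(hdr)[ids == dup][2]
    format_error(paste0("duplicate FASTA identifier '", dup, "'"), path, bad)
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1), collapse = "")
  # headers with no sequence lines at all
  if (length(seqs) < length(ids)) {
    missing <- setdiff(as.character(seq_along(ids)), names(seqs))
    bad <- which(hdr)[as.integer(missing[1])]
    format_error("FASTA record has no sequence", path, bad)
  }
  seqs <- seqs[as.character(seq_along(ids))]
  if (any(nchar(seqs) == 0)) {
    bad <- which(hdr)[which(nchar(seqs) == 0)[1]]
    format_error("FASTA record has empty sequence", path, bad)
  }
  setNames(as.character(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read barcoded FASTQ
#'
#' Reads a FASTQ file in which the molecular barcode, when present, is encoded
#' as a SAM-style `TAG:Z:value` token in the header comment (the de facto
#' linked-read convention, e.g. `@r1 BX:Z:AAACC-1`). Order is preserved; reads
#' without the tag get `NA` barcodes.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @param barcode_tag Tag name to look for (default `"BX"`).
#' @return Tibble with columns `read_id`, `sequence`, `qualities`, `barcode`.
#' @export
read_fastq_barcoded <- function(path, barcode_tag = "BX") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    format_error("truncated FASTQ record", path, length(lines))
  if (length(lines) == 0)
    return(tibble(read_id = character(), sequence = character(),
                  qualities = character(), barcode = character()))
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0)
    format_error("FASTQ header must start with '@'", path, (bad_hdr[1] - 1L) * 4L + 1L)
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0)
    format_error("FASTQ separator must start with '+'", path, (bad_plus[1] - 1L) * 4L + 3L)
  bad_len <- which(nchar(qual) != nchar(seqs))
  if (length(bad_len) > 0)
    format_error("quality/sequence length mismatch", path, (bad_len[1] - 1L) * 4L + 4L)
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  pat <- paste0(".*\\s", barcode_tag, ":Z:(\\S+).*")
  has_bc <- grepl(paste0("\\s", barcode_tag, ":Z:"), hdr)
  bc <- ifelse(has_bc, sub(pat, "\\1", hdr), NA_character_)
  tibble(read_id = ids, sequence = seqs, qualities = qual, barcode = bc)
}

#' Write barcoded FASTQ
#'
#' Inverse of [read_fastq_barcoded()]: barcodes, when present, are written as a
#' `TAG:Z:value` header comment.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, and optionally
#'   `qualities` and `barcode`.
#' @param path Output path.
#' @param barcode_tag Tag name (default `"BX"`).
#' @return `path`, invisibly.
#' @export
write_fastq_barcoded <- function(reads, path, barcode_tag = "BX") {
  qual <- if ("qualities" %in% names(reads) && !all(is.na(reads$qualities)))
    reads$qualities else strrep("I", nchar(reads$sequence))
  bc <- if ("barcode" %in% names(reads)) reads$barcode else rep(NA_character_, nrow(reads))
  hdr <- ifelse(is.na(bc), paste0("@", reads$read_id),
                paste0("@", reads$read_id, " ", barcode_tag, ":Z:", bc))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- hdr
  out[seq(2, length(out), 4)] <- reads$sequence
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

paf_cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
              "target", "target_len", "target_start", "target_end",
              "matches", "block_len", "mapq")

#' Read PAF alignments
#'
#' 12+ column PAF dialect: columns 10 and 11 are residue matches and alignment
#' block length, coordinates are 0-based half-open. A `ub:i:` tag, when present,
#' populates the `unique` column (1 = unique best placement).
#'
#' @param path Path to a PAF file.
#' @return Alignment tibble (one row per placement) with PAF columns plus
#'   `unique`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    format_error("PAF line has fewer than 12 columns", path, which(nf < 12)[1])
  m <- matrix(unlist(lapply(fields, `[`, 1:12)), ncol = 12, byrow = TRUE)
  ints <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  for (j in ints) {
    v <- suppressWarnings(as.integer(m[, j]))
    if (anyNA(v))
      format_error("non-integer PAF coordinate", path, which(is.na(v))[1])
  }
  uniq <- vapply(fields, function(f) {
    tag <- grep("^ub:i:", f[-(1:12)], value = TRUE)
    if (length(tag)) as.integer(sub("^ub:i:", "", tag[1])) == 1L else NA
  }, logical(1))
  tibble(
    query_id = m[, 1], query_len = as.integer(m[, 2]),
    query_start = as.integer(m[, 3]), query_end = as.integer(m[, 4]),
    strand = m[, 5], target = m[, 6], target_len = as.integer(m[, 7]),
    target_start = as.integer(m[, 8]), target_end = as.integer(m[, 9]),
    matches = as.integer(m[, 10]), block_len = as.integer(m[, 11]),
    mapq = as.integer(m[, 12]), unique = uniq
  )
}

#' Write PAF alignments
#'
#' @param aln Alignment tibble as returned by [map_reads()] or [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  stopifnot(all(paf_cols %in% names(aln)))
  base <- do.call(paste, c(lapply(paf_cols, function(cc) aln[[cc]]), sep = "\t"))
  if ("unique" %in% names(aln) && !all(is.na(aln$unique)))
    base <- paste0(base, "\tub:i:", as.integer(aln$unique))
  writeLines(base, path)
  invisible(path)
}

empty_alignments <- function() {
  tibble(query_id = character(), query_len = integer(), query_start = integer(),
         query_end = integer(), strand = character(), target = character(),
         target_len = integer(), target_start = integer(), target_end = integer(),
         matches = integer(), block_len = integer(), mapq = integer(),
         unique = logical())
}

#' Alignment identity
#'
#' Fraction of matching residues in the alignment block, `matches / block_len`.
#'
#' @param aln Alignment tibble.
#' @return Numeric vector in `[0, 1]`.
#' @export
alignment_identity <- function(aln) aln$matches / aln$block_len

#' Read a minimal SAM-like alignment table
#'
#' Plain TSV alternative to PAF carrying the same record type, with columns
#' `query_id`, `target`, `target_start` (0-based), `strand`, `matches`,
#' `block_len` and optional `mapq`.
#'
#' @param path Path to the TSV file (with header).
#' @return Alignment tibble.
#' @export
read_alignment_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "target", "target_start", "strand", "matches", "block_len")
  if (!all(need %in% names(d)))
    format_error(paste0("missing columns: ",
                        paste(setdiff(need, names(d)), collapse = ", ")), path)
  tibble(
    query_id = as.character(d$query_id), query_len = as.integer(d$block_len),
    query_start = 0L, query_end = as.integer(d$block_len),
    strand = as.character(d$strand), target = as.character(d$target),
    target_len = NA_integer_, target_start = as.integer(d$target_start),
    target_end = as.integer(d$target_start + d$block_len),
    matches = as.integer(d$matches), block_len = as.integer(d$block_len),
    mapq = if ("mapq" %in% names(d)) as.integer(d$mapq) else NA_integer_,
    unique = if ("unique" %in% names(d)) as.logical(d$unique) else NA
  )
}

#' Read BED intervals
#'
#' 3- or 6-column BED, 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return Tibble with `scaffold`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0)
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3 & nf < 6))
    format_error("BED line must have 3 or >=6 columns", path, which(nf != 3 & nf < 6)[1])
  tibble(
    scaffold = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    strand = vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", character(1))
  )
}

#' Write BED intervals
#'
#' Writes 3-column BED when no interval carries a strand, 6-column otherwise
#' (name and score filled with `.`). Tab-separated, newline-terminated,
#' 0-based half-open; round-trips through [read_bed()].
#'
#' @param intervals Tibble with `scaffold`, `start`, `end` and optional `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("scaffold", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$start < 0 | intervals$start >= intervals$end))
    abort("invalid interval: need 0 <= start < end")
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", nrow(intervals))
  lines <- if (all(strand == "." | is.na(strand))) {
    sprintf("%s\t%d\t%d", intervals$scaffold, intervals$start, intervals$end)
  } else {
    sprintf("%s\t%d\t%d\t.\t.\t%s", intervals$scaffold, intervals$start,
            intervals$end, strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a translated-search hit table
#'
#' Tab-separated hits in BLAST `outfmt 6` column order (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) plus a
#' 13th `frame` column. BLAST's 1-based closed coordinates are converted to
#' 0-based half-open at this boundary; subject coordinates with `sstart > send`
#' are flipped and recorded as minus strand.
#'
#' @param path Path to the hit table (no header).
#' @return Tibble of hits with 0-based half-open `q_start/q_end`,
#'   `s_start/s_end`, `strand`, `evalue`, `bitscore`, `frame`.
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 13)
    format_error("hit table needs 13 columns (outfmt 6 + frame)", path)
  names(d)[1:13] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                      "bitscore", "frame")
  minus <- d$sstart > d$send
  tibble(
    query_id = as.character(d$qseqid), subject_id = as.character(d$sseqid),
    pident = d$pident, length = as.integer(d$length),
    mismatch = as.integer(d$mismatch), gapopen = as.integer(d$gapopen),
    q_start = as.integer(d$qstart - 1L), q_end = as.integer(d$qend),
    s_start = as.integer(ifelse(minus, d$send - 1L, d$sstart - 1L)),
    s_end = as.integer(ifelse(minus, d$sstart, d$send)),
    strand = ifelse(minus, "-", "+"),
    evalue = d$evalue, bitscore = d$bitscore, frame = as.integer(d$frame)
  )
}

#' Read meiotic-spread measurements
#'
#' TSV with header columns `cell_id`, `individual`, `species`, `grc_um`, and 29
#' measured A-chromosome lengths `len_1` .. `len_29` in micrometres.
#'
#' @param path Path to the measurements table.
#' @return Tibble with one row per cell and a list-column `lengths_um` holding
#'   the 29 A-chromosome lengths sorted in descending order.
#' @export
read_spread_measurements <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  len_cols <- grep("^len_", names(d), value = TRUE)
  if (length(len_cols) != 29)
    format_error(sprintf("expected 29 len_* columns, found %d", length(len_cols)), path)
  tibble(
    cell_id = as.character(d$cell_id),
    individual = as.character(d$individual),
    species = if ("species" %in% names(d)) as.character(d$species) else NA_character_,
    grc_um = as.numeric(d$grc_um),
    lengths_um = lapply(seq_len(nrow(d)), function(i)
      sort(as.numeric(d[i, len_cols]), decreasing = TRUE))
  )
}

#' Write a tibble as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
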