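#' Find germline-specific regions of the germline assembly
#'
#' Maximal intervals that are fully covered by germline (testis) reads — depth
#' at least one at every base — while receiving no somatic (kidney) reads at
#' all, and that are at least `min_len` long. These regions are the
#' high-confidence germline-only sequence that seeds barcode recruitment.
#'
#' @param testis_cov,kidney_cov Named lists of per-base integer depth vectors
#'   (one element per scaffold of the germline assembly), e.g. from
#'   [coverage_from_alignments()].
#' @param min_len Minimum region length in bp.
#' @return Tibble of regions (`scaffold`, 0-based half-open `start`, `end`).
#' @export
germline_specific_regions <- function(testis_cov, kidney_cov,
                                      min_len = grc_defaults$min_region_len) {
  if (!setequal(names(testis_cov), names(kidney_cov)))
    abort("coverage tracks cover different scaffold sets")
  out <- list()
  for (sc in names(testis_cov)) {
    tv <- testis_cov[[sc]]; kv <- kidney_cov[[sc]]
    if (length(tv) != length(kv)) abort("track length mismatch")
    mask <- tv >= 1L & kv == 0L
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_len
    if (any(keep))
      out[[sc]] <- tibble(scaffold = sc, start = starts[keep], end = ends[keep])
  }
  if (length(out) == 0)
    return(tibble(scaffold = character(), start = integer(), end = integer()))
  bind_rows(out)
}

overlap_hits <- function(aln, regions, min_overlap) {
  hit <- logical(nrow(aln))
  for (sc in unique(regions$scaffold)) {
    ri <- regions[regions$scaffold == sc, ]
    w <- which(aln$target == sc)
    if (length(w) == 0) next
    q <- IRanges::IRanges(aln$target_start[w] + 1L, aln$target_end[w])
    s <- IRanges::IRanges(ri$start + 1L, ri$end)
    ov <- IRanges::findOverlaps(q, s, minoverlap = min_overlap)
    hit[w[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

#' Channel (a): barcodes of reads overlapping germline-specific regions
#'
#' Selects the barcodes of germline reads whose alignment overlaps any
#' germline-specific region by at least `min_overlap` bp. Reads without a
#' barcode can satisfy the overlap rule but contribute no barcode; their count
#' is reported in the `n_no_barcode` attribute.
#'
#' @param regions Region tibble from [germline_specific_regions()].
#' @param alignments Alignment tibble of testis reads on the germline assembly.
#' @param reads Read tibble carrying `read_id` and `barcode`.
#' @param min_overlap Minimum overlap in bp.
#' @return Barcode-selection tibble (`barcode`, `channel = "region"`), with
#'   attribute `n_no_barcode`.
#' @export
reads_overlapping <- function(regions, alignments, reads,
                              min_overlap = grc_defaults$min_overlap) {
  if (nrow(regions) == 0 || nrow(alignments) == 0) {
    out <- tibble(barcode = character(), channel = character())
    attr(out, "n_no_barcode") <- 0L
    return(out)
  }
  hit <- overlap_hits(alignments, regions, min_overlap)
  ids <- unique(alignments$query_id[hit])
  bc <- reads$barcode[match(ids, reads$read_id)]
  out <- tibble(barcode = sort(unique(bc[!is.na(bc)])), channel = "region")
  attr(out, "n_no_barcode") <- sum(is.na(bc))
  out
}

#' Naive pileup variant caller
#'
#' Calls single-nucleotide variants from ungapped alignments by direct base
#' counting: a site is emitted when at least one sample carries `min_alt`
#' reads supporting the same non-reference base. Support (alt count and total
#' depth) is reported for every sample at every called site. Sites whose
#' reference base is N are skipped. This deliberately simple caller has no
#' quality model; the downstream all-germline/no-soma filter is the decisive
#' gate.
#'
#' @param alignments Alignment tibble (ungapped, full-read blocks) of reads on
#'   the reference.
#' @param reads Read tibble with `read_id`, `sequence`, `sample`, `tissue`.
#' @param reference Named character vector of reference sequences.
#' @param min_alt Minimum alt-supporting reads in at least one sample.
#' @return Long tibble: `scaffold`, 0-based `pos`, `ref`, `alt`, `sample`,
#'   `tissue`, `alt_count`, `depth` (one row per called site and sample).
#' @export
call_variants_pileup <- function(alignments, reads, reference,
                                 min_alt = grc_defaults$min_alt_reads) {
  idx <- match(alignments$query_id, reads$read_id)
  aln <- alignments %>%
    mutate(sequence = reads$sequence[idx],
           sample = reads$sample[idx], tissue = reads$tissue[idx])
  groups <- distinct(aln, .data$sample, .data$tissue) %>% arrange(.data$sample)
  out <- list()
  for (sc in intersect(unique(aln$target), names(reference))) {
    refseq <- reference[[sc]]
    L <- nchar(refseq)
    sub <- aln[aln$target == sc, ]
    counts <- lapply(seq_len(nrow(groups)), function(g) {
      gg <- sub[sub$sample == groups$sample[g] & sub$tissue == groups$tissue[g], ]
      cpp_base_counts(L, gg$target_start, gg$strand == "-", gg$sequence)
    })
    refv <- match(strsplit(refseq, "", fixed = TRUE)[[1]], BASES)  # NA for N
    # candidate sites: some sample has >= min_alt reads of one non-ref base
    cand <- rep(FALSE, L)
    for (g in seq_along(counts)) {
      cm <- counts[[g]]
      ok <- !is.na(refv)
      nonref_max <- integer(L)
      for (b in 1:4) {
        v <- cm[b, ]
        v[!ok | refv == b] <- 0L
        nonref_max <- pmax(nonref_max, v)
      }
      cand <- cand | nonref_max >= min_alt
    }
    sites <- which(cand)
    if (length(sites) == 0) next
    # alt allele: the non-ref base with the largest total support across samples
    tot <- Reduce(`+`, counts)[, sites, drop = FALSE]
    refb <- refv[sites]
    for (b in 1:4) tot[b, refb == b] <- -1L
    altb <- apply(tot, 2, which.max)
    for (g in seq_len(nrow(groups))) {
      cm <- counts[[g]][, sites, drop = FALSE]
      out[[length(out) + 1]] <- tibble(
        scaffold = sc, pos = sites - 1L,
        ref = BASES[refb], alt = BASES[altb],
        sample = groups$sample[g], tissue = groups$tissue[g],
        alt_count = cm[cbind(altb, seq_along(sites))],
        depth = colSums(cm))
    }
  }
  if (length(out) == 0)
    return(tibble(scaffold = character(), pos = integer(), ref = character(),
                  alt = character(), sample = character(), tissue = character(),
                  alt_count = integer(), depth = integer()))
  bind_rows(out) %>% arrange(.data$scaffold, .data$pos, .data$sample)
}

#' Filter variant calls to germline-specific SNPs
#'
#' Keeps sites whose alternative allele is supported by at least `min_alt`
#' reads in every germline (testis) sample and by zero reads in every somatic
#' (kidney) sample.
#'
#' @param calls Long call tibble from [call_variants_pileup()].
#' @param min_alt Minimum alt support per testis sample.
#' @return Tibble of unique germline-specific sites (`scaffold`, `pos`, `ref`,
#'   `alt`).
#' @export
germline_specific_snps <- function(calls, min_alt = grc_defaults$min_alt_reads) {
  if (nrow(calls) == 0)
    return(tibble(scaffold = character(), pos = integer(),
                  ref = character(), alt = character()))
  calls %>%
    group_by(.data$scaffold, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      ok = all(.data$alt_count[.data$tissue == "testis"] >= min_alt) &&
        sum(.data$tissue == "testis") > 0 &&
        all(.data$alt_count[.data$tissue == "kidney"] == 0),
      .groups = "drop") %>%
    filter(.data$ok) %>%
    select(-"ok")
}

#' Diagnostic k-mers for one germline-specific SNP
#'
#' All k-length windows of the alt-substituted reference that contain the
#' variant position. An interior site yields exactly `k` k-mers; a site within
#' `k - 1` bp of a contig end yields fewer (the signal is kept rather than the
#' site discarded).
#'
#' @param scaffold,pos,alt Variant site (0-based position) and alternative
#'   allele.
#' @param reference Named character vector containing `scaffold`.
#' @param k k-mer length in bp.
#' @return Character vector of k-mers, each containing the alt base.
#' @export
snp_to_kmers <- function(scaffold, pos, alt, reference,
                         k = grc_defaults$kmer_len) {
  refseq <- reference[[scaffold]]
  L <- nchar(refseq)
  if (pos < 0 || pos >= L) abort("variant position outside the contig")
  lo <- max(0L, pos - k + 1L)
  hi <- min(pos, L - k)
  if (hi < lo) return(character())
  # substitute the alt base into the local window once, then slide
  ctx_start <- lo
  ctx <- substr(refseq, ctx_start + 1L, min(L, pos + k))
  substr(ctx, pos - ctx_start + 1L, pos - ctx_start + 1L) <- alt
  starts <- (lo:hi) - ctx_start
  substring(ctx, starts + 1L, starts + k)
}

#' Diagnostic k-mers for a set of germline-specific SNPs
#'
#' @param snps Site tibble from [germline_specific_snps()].
#' @param reference Named character vector of reference sequences.
#' @param k k-mer length in bp.
#' @return Character vector of unique candidate k-mers.
#' @export
variants_to_kmers <- function(snps, reference, k = grc_defaults$kmer_len) {
  if (nrow(snps) == 0) return(character())
  unique(unlist(purrr::pmap(
    list(snps$scaffold, snps$pos, snps$alt),
    function(sc, p, a) snp_to_kmers(sc, p, a, reference, k))))
}

read_sequences <- function(reads) {
  if (is.data.frame(reads)) reads$sequence else reads
}

#' Remove k-mers present in the somatic read set
#'
#' A k-mer survives only if neither it nor its reverse complement occurs as an
#' exact substring of any somatic (kidney) read; DNA reads are unstranded, so
#' both strands must be checked.
#'
#' @param kmers Character vector of candidate k-mers (equal length).
#' @param kidney_reads Read tibble (with a `sequence` column) or character
#'   vector of read sequences.
#' @return Surviving k-mers.
#' @export
filter_kmers_against_soma <- function(kmers, kidney_reads) {
  if (length(kmers) == 0) return(character())
  found <- cpp_kmers_in_reads(kmers, read_sequences(kidney_reads))
  kmers[!found]
}

#' Channel (b): barcodes of germline reads matching diagnostic k-mers
#'
#' Selects barcodes of testis reads that contain any surviving diagnostic
#' k-mer as an exact substring on either strand.
#'
#' @param kmers Surviving k-mers from [filter_kmers_against_soma()].
#' @param testis_reads Read tibble with `sequence` and `barcode`.
#' @return Barcode-selection tibble (`barcode`, `channel = "snp_kmer"`), with
#'   attribute `n_no_barcode`.
#' @export
match_kmers <- function(kmers, testis_reads) {
  out <- tibble(barcode = character(), channel = character())
  attr(out, "n_no_barcode") <- 0L
  if (length(kmers) == 0 || nrow(testis_reads) == 0) return(out)
  hit <- cpp_reads_with_kmers(kmers, testis_reads$sequence)
  bc <- testis_reads$barcode[hit]
  out <- tibble(barcode = sort(unique(bc[!is.na(bc)])), channel = "snp_kmer")
  attr(out, "n_no_barcode") <- sum(is.na(bc))
  out
}

#' Channel (c): barcodes of reads matching a germline-restricted repeat
#'
#' Selects barcodes of reads having an alignment block of at least `min_len`
#' bp with identity strictly greater than `min_identity` against the repeat
#' consensus. Alignments can be supplied (e.g. from an external aligner);
#' otherwise reads are mapped to the consensus with the built-in mapper.
#'
#' @param repeat_consensus Consensus sequence of the candidate repeat
#'   (supplied externally; repeat discovery is out of scope).
#' @param reads Read tibble with `read_id`, `sequence`, `barcode`.
#' @param alignments Optional alignment tibble of `reads` against the
#'   consensus; computed if `NULL`.
#' @param min_len Minimum alignment block length (bp).
#' @param min_identity Identity threshold (exclusive).
#' @return Barcode-selection tibble (`barcode`, `channel = "repeat"`), with
#'   attribute `n_no_barcode`.
#' @export
repeat_reads <- function(repeat_consensus, reads, alignments = NULL,
                         min_len = grc_defaults$repeat_min_len,
                         min_identity = grc_defaults$repeat_min_identity) {
  if (is.null(repeat_consensus) || !nzchar(repeat_consensus))
    abort("empty repeat consensus")
  if (is.null(alignments)) {
    idx <- seed_index(c(repeat_consensus = repeat_consensus),
                      k = min(grc_defaults$seed_k, nchar(repeat_consensus)))
    alignments <- map_reads(reads, idx, best_only = TRUE)
  }
  keep <- alignments$block_len >= min_len &
    alignment_identity(alignments) > min_identity
  ids <- unique(alignments$query_id[keep])
  bc <- reads$barcode[match(ids, reads$read_id)]
  out <- tibble(barcode = sort(unique(bc[!is.na(bc)])), channel = "repeat")
  attr(out, "n_no_barcode") <- sum(is.na(bc))
  out
}

#' Barcode expansion: recruit all reads sharing selected barcodes
#'
#' @param selection Barcode-selection tibble (any combination of channels).
#' @param reads Read tibble with a `barcode` column.
#' @return The rows of `reads` whose barcode is selected; reads without
#'   barcodes are never recruited.
#' @export
expand_barcodes <- function(selection, reads) {
  reads[!is.na(reads$barcode) & reads$barcode %in% selection$barcode, ]
}

#' End-to-end germline read identification
#'
#' Runs the full three-channel classifier and barcode expansion: (a) regions
#' of the germline assembly fully covered by testis reads and untouched by
#' kidney reads recruit overlapping reads' barcodes; (b) SNPs present in all
#' testis samples and absent from all kidney samples are turned into
#' diagnostic k-mers, soma-filtered, and matched against testis reads; (c)
#' reads matching a supplied germline-restricted repeat consensus contribute
#' their barcodes. All reads sharing any selected barcode are recruited.
#'
#' @param testis_reads,kidney_reads Read tibbles (`read_id`, `sequence`,
#'   `barcode`, `sample`, `tissue`).
#' @param germline_assembly Named character vector: the germline (testis)
#'   genome assembly, A-chromosomal plus GRC scaffolds.
#' @param soma_reference Named character vector: the somatic reference genome
#'   (A chromosomes only), used for SNP calling.
#' @param repeat_consensus Optional repeat consensus sequence for channel (c).
#' @param min_region_len,min_overlap,kmer_len,repeat_min_len,repeat_min_identity,min_alt
#'   Stage thresholds; see [grc_defaults].
#' @param seed_k Seed length of the built-in mapper.
#' @return A `grc_identify` list: `selection` (barcodes with channel
#'   provenance), `recruited` (recruited read tibble), `regions`, `snps`,
#'   `kmers_surviving`, alignment tables, and a `counts` log of every filter.
#' @export
identify_grc_reads <- function(testis_reads, kidney_reads, germline_assembly,
                               soma_reference, repeat_consensus = NULL,
                               min_region_len = grc_defaults$min_region_len,
                               min_overlap = grc_defaults$min_overlap,
                               kmer_len = grc_defaults$kmer_len,
                               repeat_min_len = grc_defaults$repeat_min_len,
                               repeat_min_identity = grc_defaults$repeat_min_identity,
                               min_alt = grc_defaults$min_alt_reads,
                               seed_k = grc_defaults$seed_k) {
  idx_germ <- seed_index(germline_assembly, k = seed_k)
  aln_t_germ <- map_reads(testis_reads, idx_germ, best_only = TRUE)
  aln_k_germ <- map_reads(kidney_reads, idx_germ, best_only = TRUE)
  lens <- setNames(nchar(germline_assembly), names(germline_assembly))
  # channel (a) works on uniquely mapping reads: a read whose best placement
  # ties between an A chromosome and an identical GRC stretch carries no
  # tissue-specific information and would otherwise leak A-chromosomal
  # molecules into the selection
  aln_t_uni <- aln_t_germ[aln_t_germ$unique, ]
  aln_k_uni <- aln_k_germ[aln_k_germ$unique, ]
  cov_t <- coverage_from_alignments(aln_t_uni, lens)
  cov_k <- coverage_from_alignments(aln_k_uni, lens)
  regions <- germline_specific_regions(cov_t, cov_k, min_region_len)
  sel_a <- reads_overlapping(regions, aln_t_uni, testis_reads, min_overlap)

  idx_soma <- seed_index(soma_reference, k = seed_k)
  aln_soma <- bind_rows(
    map_reads(testis_reads, idx_soma, best_only = TRUE),
    map_reads(kidney_reads, idx_soma, best_only = TRUE))
  all_reads <- bind_rows(testis_reads, kidney_reads)
  calls <- call_variants_pileup(aln_soma, all_reads, soma_reference, min_alt)
  snps <- germline_specific_snps(calls, min_alt)
  kmers0 <- variants_to_kmers(snps, soma_reference, kmer_len)
  kmers <- filter_kmers_against_soma(kmers0, kidney_reads)
  sel_b <- match_kmers(kmers, testis_reads)

  sel_c <- if (!is.null(repeat_consensus)) {
    repeat_reads(repeat_consensus, testis_reads,
                 min_len = repeat_min_len, min_identity = repeat_min_identity)
  } else tibble(barcode = character(), channel = character())

  selection <- bind_rows(sel_a, sel_b, sel_c) %>% distinct()
  recruited <- expand_barcodes(selection, testis_reads)
  structure(list(
    selection = selection, recruited = recruited, regions = regions,
    snps = snps, kmers_surviving = kmers,
    aln_testis_germ = aln_t_germ, aln_kidney_germ = aln_k_germ,
    counts = tibble(
      stage = c("regions", "snps", "kmers_candidate", "kmers_surviving",
                "barcodes_region", "barcodes_snp_kmer", "barcodes_repeat",
                "barcodes_total", "reads_recruited"),
      n = c(nrow(regions), nrow(snps), length(kmers0), length(kmers),
            sum(selection$channel == "region"),
            sum(selection$channel == "snp_kmer"),
            sum(selection$channel == "repeat"),
            dplyr::n_distinct(selection$barcode), nrow(recruited)))
  ), class = "grc_identify")
}
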