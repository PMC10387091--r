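#' Translate a nucleotide string
#'
#' Standard-code translation of one frame; stop codons become `*`, codons with
#' ambiguous bases become `X`.
#'
#' @param seq Nucleotide string.
#' @param frame 0-based frame offset (0, 1, 2).
#' @return Amino-acid string.
#' @export
translate_dna <- function(seq, frame = 0L) {
  L <- nchar(seq)
  n <- (L - frame) %/% 3
  if (n <= 0) return("")
  starts <- frame + 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Naive translated search of coding sequences against GRC scaffolds
#'
#' A deliberately simple tblastx-style scan for toy data (real analyses should
#' supply an external hit table through [read_blast_hits()]): the first frame
#' of each coding sequence is translated and matched against all six frames of
#' each GRC scaffold by exact protein word seeding and ungapped X-drop
#' extension (match +2, mismatch -3, drop 12). Scores are crude
#' (bitscore = 2 x identities; evalue = m n 2^-bitscore) but monotone in hit
#' quality, which is all the downstream e-value cut-off needs.
#'
#' @param cds_seqs Named character vector of coding sequences (frame 1).
#' @param grc_seqs Named character vector of GRC scaffolds.
#' @param word Protein seed word length (aa).
#' @param min_aa Minimum reported hit length (aa).
#' @return Hit tibble in the same shape as [read_blast_hits()] output: the
#'   query is the gene, the subject the GRC scaffold, all coordinates 0-based
#'   half-open on the nucleotide sequences.
#' @export
translated_search <- function(cds_seqs, grc_seqs, word = 5L, min_aa = 8L) {
  out <- list()
  for (scaf in names(grc_seqs)) {
    S <- grc_seqs[[scaf]]
    L <- nchar(S)
    frames <- list()
    for (f in 0:2) frames[[f + 1]] <- translate_dna(S, f)
    rc <- cpp_revcomp(S)
    for (f in 0:2) frames[[f + 4]] <- translate_dna(rc, f)
    # word -> positions, per frame
    word_maps <- lapply(frames, function(p) {
      np <- nchar(p) - word + 1L
      if (np < 1) return(list())
      ws <- substring(p, seq_len(np), seq_len(np) + word - 1L)
      split(seq_len(np) - 1L, ws)
    })
    for (gene in names(cds_seqs)) {
      q <- translate_dna(cds_seqs[[gene]], 0L)
      nq <- nchar(q) - word + 1L
      if (nq < 1) next
      qwords <- substring(q, seq_len(nq), seq_len(nq) + word - 1L)
      for (fr in 1:6) {
        wm <- word_maps[[fr]]
        p <- frames[[fr]]
        np <- nchar(p)
        seen_diag <- new.env(parent = emptyenv())
        for (qi in seq_len(nq)) {
          hits_at <- wm[[qwords[qi]]]
          if (is.null(hits_at)) next
          for (ti in hits_at) {
            diag_key <- as.character(ti - (qi - 1L))
            if (!is.null(seen_diag[[diag_key]])) next
            ext <- xdrop_extend(q, p, qi - 1L, ti)
            seen_diag[[diag_key]] <- TRUE
            if (ext$len < min_aa) next
            out[[length(out) + 1]] <- hit_row(gene, scaf, ext, fr, L,
                                              nchar(q), np)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  pident = numeric(), length = integer(), mismatch = integer(),
                  gapopen = integer(), q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(), strand = character(),
                  evalue = numeric(), bitscore = numeric(), frame = integer()))
  }
  bind_rows(out) %>% distinct()
}

# greedy ungapped X-drop extension on protein strings; q0/t0 are 0-based seed
# starts; returns the maximal-scoring window around the seed
xdrop_extend <- function(q, t, q0, t0, match = 2, mismatch = -3, xdrop = 12) {
  nq <- nchar(q); nt <- nchar(t)
  scan_dir <- function(step) {
    best <- 0L; score <- 0; best_score <- 0
    i <- 1L
    repeat {
      qi <- q0 + if (step > 0) i else -i
      ti <- t0 + if (step > 0) i else -i
      if (qi < 0 || ti < 0 || qi >= nq || ti >= nt) break
      score <- score + if (substr(q, qi + 1, qi + 1) == substr(t, ti + 1, ti + 1))
        match else mismatch
      if (score > best_score) { best_score <- score; best <- i }
      if (best_score - score > xdrop) break
      i <- i + 1L
    }
    best
  }
  left <- scan_dir(-1L)
  right <- scan_dir(+1L)
  qs <- q0 - left; ts <- t0 - left
  len <- left + right + 1L
  qa <- substring(q, qs + 1L, qs + len)
  ta <- substring(t, ts + 1L, ts + len)
  ident <- sum(strsplit(qa, "")[[1]] == strsplit(ta, "")[[1]])
  list(q_start = qs, t_start = ts, len = len, ident = ident)
}

hit_row <- function(gene, scaf, ext, fr, nt_len, q_aa_len, t_aa_len) {
  q_s <- 3L * ext$q_start
  q_e <- 3L * (ext$q_start + ext$len)
  f <- (fr - 1L) %% 3L
  if (fr <= 3) {
    s_s <- f + 3L * ext$t_start
    s_e <- s_s + 3L * ext$len
    strand <- "+"
    frame <- f + 1L
  } else {
    # coordinates on the reverse complement, mapped back
    r_s <- f + 3L * ext$t_start
    r_e <- r_s + 3L * ext$len
    s_s <- nt_len - r_e
    s_e <- nt_len - r_s
    strand <- "-"
    frame <- -(f + 1L)
  }
  bits <- 2 * ext$ident
  tibble(query_id = gene, subject_id = scaf,
         pident = 100 * ext$ident / ext$len, length = ext$len,
         mismatch = ext$len - ext$ident, gapopen = 0L,
         q_start = q_s, q_end = q_e, s_start = s_s, s_end = s_e,
         strand = strand,
         evalue = 3 * q_aa_len * t_aa_len * 2^(-min(bits, 1000)),
         bitscore = bits, frame = frame)
}

#' Merge translated hits into annotated exons
#'
#' Drops hits above the e-value cut-off, merges overlapping same-strand hit
#' intervals on each GRC scaffold into exons, and assigns each merged exon to
#' the top hit by bitscore among the hits it contains. The matched portions of
#' the winning gene's coding sequence are recorded for completeness scoring.
#'
#' @param hits Hit tibble from [translated_search()] or [read_blast_hits()].
#' @param evalue_max E-value cut-off (hits with `evalue > evalue_max` are
#'   dropped).
#' @return Exon tibble: `scaffold`, `start`, `end`, `strand`, `gene_id`,
#'   `bitscore` of the winning hit, and a list-column `cds_intervals` of the
#'   winning gene's matched CDS intervals (0-based half-open, nt).
#' @export
annotate_exons <- function(hits, evalue_max = grc_defaults$evalue_max) {
  hits <- filter(hits, .data$evalue <= evalue_max)
  if (nrow(hits) == 0)
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  bitscore = numeric(), cds_intervals = list()))
  out <- list()
  for (key in unique(paste(hits$subject_id, hits$strand))) {
    h <- hits[paste(hits$subject_id, hits$strand) == key, ]
    merged <- merge_within_gap(tibble(start = h$s_start, end = h$s_end), gap = -1L)
    for (i in seq_len(nrow(merged))) {
      inside <- h$s_start < merged$end[i] & h$s_end > merged$start[i]
      hh <- h[inside, ]
      win <- hh %>% arrange(desc(.data$bitscore), .data$query_id) %>% slice(1)
      gene_hits <- hh[hh$query_id == win$query_id, ]
      out[[length(out) + 1]] <- tibble(
        scaffold = win$subject_id, start = merged$start[i], end = merged$end[i],
        strand = win$strand, gene_id = win$query_id, bitscore = win$bitscore,
        cds_intervals = list(cbind(gene_hits$q_start, gene_hits$q_end)))
    }
  }
  bind_rows(out) %>% arrange(.data$scaffold, .data$start)
}

interval_union_len <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(ir(m[, 1], m[, 2]))))
}

#' Raw per-gene proportion of coding sequence found
#'
#' Union of the matched CDS intervals of every exon assigned to the gene,
#' divided by the CDS length.
#'
#' @param exons Exon tibble from [annotate_exons()].
#' @param cds_lengths Named integer vector of CDS lengths (nt).
#' @return Tibble: `gene_id`, `raw_prop`.
#' @export
gene_raw_proportions <- function(exons, cds_lengths) {
  genes <- unique(exons$gene_id)
  raw <- vapply(genes, function(g) {
    m <- do.call(rbind, exons$cds_intervals[exons$gene_id == g])
    interval_union_len(m) / cds_lengths[[g]]
  }, numeric(1))
  tibble(gene_id = genes, raw_prop = pmin(1, unname(raw)))
}

#' Conservation-normalized gene completeness
#'
#' Divides the proportion of the gene found on the GRC by the proportion found
#' in the reference genome — a baseline of expected conservation — with the
#' denominator floored at `floor` and the result capped at 1. A gene found at
#' 80% on the GRC and 80% in the genome is treated as 100% present; one found
#' at 5% and 5% as 6.7% present.
#'
#' @param raw_prop_grc Proportion of the coding region found on the GRC.
#' @param prop_genome Proportion of the coding region found in the reference
#'   genome.
#' @param floor Smallest allowed denominator.
#' @return Normalized completeness in `[0, 1]` (vectorized).
#' @export
completeness <- function(raw_prop_grc, prop_genome,
                         floor = grc_defaults$completeness_floor) {
  stopifnot(all(raw_prop_grc >= 0 & raw_prop_grc <= 1, na.rm = TRUE),
            all(prop_genome >= 0 & prop_genome <= 1, na.rm = TRUE))
  pmin(1, raw_prop_grc / pmax(prop_genome, floor))
}

#' Gene inclusion rule
#'
#' A gene is analysed only when at least `min_prop` of its coding region is
#' present in at least one species (boundary inclusive); short spurious
#' protein matches are excluded this way.
#'
#' @param ... Per-species completeness vectors (NA allowed).
#' @param min_prop Inclusion threshold.
#' @return Logical vector.
#' @export
include_gene <- function(..., min_prop = grc_defaults$include_min) {
  m <- do.call(cbind, list(...))
  best <- apply(m, 1, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  best >= min_prop
}

longest_open_stretch <- function(seq, frame) {
  L <- nchar(seq)
  n <- (L - frame) %/% 3
  if (n <= 0) return(L)
  starts <- frame + 3L * (seq_len(n) - 1L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  stops <- starts[codons %in% STOP_CODONS]
  if (length(stops) == 0) return(L)
  bounds <- c(0L, rep(stops, each = 2) + c(0L, 3L), L)
  max(bounds[seq(2, length(bounds), 2)] - bounds[seq(1, length(bounds), 2)])
}

#' Premature-stop test for an annotated exon
#'
#' Because exons are annotated from coding sequences, no untranslated sequence
#' is expected inside them; an exon is deemed pseudogenic when no reading
#' frame on the annotated strand contains an open (stop-free) stretch spanning
#' at least `frac` of the exon length. The boundary is inclusive: an open
#' stretch of exactly `frac * length` does not flag the exon. All three frames
#' on the annotated strand are considered, so an exon is flagged only when no
#' frame rescues it.
#'
#' @param exon_seq Exon nucleotide sequence (as annotated; at least 3 bp).
#' @param strand `"+"` or `"-"`; minus-strand exons are reverse-complemented
#'   before scanning.
#' @param frac Open-fraction threshold.
#' @return `TRUE` when the exon has a premature stop codon.
#' @export
premature_stop <- function(exon_seq, strand = "+",
                           frac = grc_defaults$orf_frac) {
  L <- nchar(exon_seq)
  if (L < 3) abort("exon shorter than one codon")
  s <- if (strand == "-") cpp_revcomp(exon_seq) else exon_seq
  best <- max(vapply(0:2, function(f) longest_open_stretch(s, f), numeric(1)))
  best < frac * L
}

#' Vectorized premature-stop test
#'
#' @param exon_seqs Character vector of exon sequences.
#' @param strands Strand per exon (recycled).
#' @param frac Open-fraction threshold.
#' @return Logical vector.
#' @export
premature_stops <- function(exon_seqs, strands = "+",
                            frac = grc_defaults$orf_frac) {
  strands <- rep_len(strands, length(exon_seqs))
  mapply(premature_stop, exon_seqs, strands, MoreArgs = list(frac = frac),
         USE.NAMES = FALSE)
}

#' Per-gene copy number from scaffold copy numbers
#'
#' Exon-length-weighted mean of the copy numbers of the scaffolds a gene's
#' exons lie on, per sample.
#'
#' @param exons Exon tibble with `gene_id`, `scaffold`, `start`, `end`.
#' @param scaffold_cn Tibble from [scaffold_copy_number()] (`scaffold`,
#'   `sample`, `copy_number`).
#' @return Tibble: `gene_id`, `sample`, `copy_number`.
#' @export
gene_copy_number <- function(exons, scaffold_cn) {
  exons %>%
    mutate(width = .data$end - .data$start) %>%
    left_join(scaffold_cn, by = "scaffold", relationship = "many-to-many") %>%
    group_by(.data$gene_id, .data$sample) %>%
    summarise(copy_number = sum(.data$copy_number * .data$width) / sum(.data$width),
              .groups = "drop")
}

#' Completeness band of a gene
#'
#' The highest of the thresholds 0%, 50%, 75%, 95% that the completeness
#' strictly exceeds.
#'
#' @param x Completeness values in `[0, 1]`.
#' @return Ordered factor with levels `none`, `>0%`, `>50%`, `>75%`, `>95%`.
#' @export
completeness_band <- function(x) {
  cut(x, breaks = c(-Inf, 0, 0.5, 0.75, 0.95, Inf),
      labels = c("none", ">0%", ">50%", ">75%", ">95%"),
      right = TRUE, ordered_result = TRUE)
}

#' Cross-species sharing category of a gene
#'
#' `both_unambiguous` when the gene is annotated in both species;
#' `potentially_shared` when annotated in only one species but lying inside a
#' potentially homologous region of that GRC (its absence elsewhere may be an
#' assembly gap); `species_specific` otherwise.
#'
#' @param present_sp1,present_sp2 Logical: gene annotated in each species.
#' @param locus_label Homology label of the gene's locus in the species where
#'   it is present (ignored when present in both).
#' @return Character vector of categories.
#' @export
sharing_category <- function(present_sp1, present_sp2, locus_label) {
  dplyr::case_when(
    present_sp1 & present_sp2 ~ "both_unambiguous",
    xor(present_sp1, present_sp2) &
      locus_label == "potentially_homologous" ~ "potentially_shared",
    .default = "species_specific"
  )
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `fpkm = unique_fragment_count / (exon_kbp * library_mapped_millions)`;
#' only uniquely mapped fragments should be counted upstream.
#'
#' @param unique_fragment_count Uniquely mapped fragments on the gene's exons.
#' @param exon_kbp Total exon length in kbp.
#' @param library_mapped_millions Mapped library size in millions.
#' @return FPKM (vectorized).
#' @export
fpkm <- function(unique_fragment_count, exon_kbp, library_mapped_millions) {
  if (any(exon_kbp == 0)) abort("exon_kbp must be > 0")
  unique_fragment_count / (exon_kbp * library_mapped_millions)
}

#' Fit expression against gene completeness
#'
#' Ordinary least squares of `log2(FPKM)` on normalized completeness over
#' genes with positive FPKM (a log-linear relation: expression rises
#' exponentially with completeness).
#'
#' @param records Tibble with columns `gene_id`, `fpkm`, `completeness`.
#' @return A `grc_expr_fit` object; see [tidy()] and [glance()] methods.
#' @export
completeness_expression_fit <- function(records) {
  d <- filter(records, .data$fpkm > 0)
  fit <- lm(log2(fpkm) ~ completeness, data = d)
  structure(list(model = fit, data = d, n_zero = sum(records$fpkm == 0),
                 slope = unname(coef(fit)[2]),
                 r_squared = summary(fit)$r.squared),
            class = "grc_expr_fit")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the completeness-expression fit
#' @param x A `grc_expr_fit`.
#' @param ... Unused.
#' @return Tibble of coefficient estimates with standard errors and p-values.
#' @export
tidy.grc_expr_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of the completeness-expression fit
#' @param x A `grc_expr_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `slope`, `nobs`, `n_zero_fpkm`.
#' @export
glance.grc_expr_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope,
         nobs = stats::nobs(x$model), n_zero_fpkm = x$n_zero)
}

#' @export
print.grc_expr_fit <- function(x, ...) {
  cat("Completeness-expression fit: log2(FPKM) ~ completeness\n")
  cat(sprintf("  slope %.3f, R^2 %.3f, n = %d (+%d zero-FPKM genes excluded)\n",
              x$slope, x$r_squared, stats::nobs(x$model), x$n_zero))
  invisible(x)
}
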