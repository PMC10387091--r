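#' Merge intervals lying within a gap of each other
#'
#' Minimal set of disjoint intervals such that any two inputs separated by at
#' most `gap` bp end up in the same output interval (transitive closure).
#' Idempotent and order-invariant.
#'
#' @param intervals Tibble with `start`, `end` and optionally `scaffold`
#'   (merging is per scaffold).
#' @param gap Maximum separation in bp (`gap = 0` merges touching intervals).
#' @return Tibble of merged intervals, sorted.
#' @export
merge_within_gap <- function(intervals, gap = grc_defaults$merge_gap) {
  if (nrow(intervals) == 0) return(intervals)
  has_sc <- "scaffold" %in% names(intervals)
  key <- if (has_sc) intervals$scaffold else rep("*", nrow(intervals))
  out <- lapply(split(seq_len(nrow(intervals)), key), function(ix) {
    st <- intervals$start[ix]; en <- intervals$end[ix]
    o <- order(st, en)
    st <- st[o]; en <- en[o]
    ms <- st[1]; me <- en[1]
    res_s <- integer(); res_e <- integer()
    for (i in seq_along(st)[-1]) {
      if (st[i] - me <= gap) {
        me <- max(me, en[i])
      } else {
        res_s <- c(res_s, ms); res_e <- c(res_e, me)
        ms <- st[i]; me <- en[i]
      }
    }
    res_s <- c(res_s, ms); res_e <- c(res_e, me)
    tibble(scaffold = key[ix[1]], start = res_s, end = res_e)
  })
  out <- bind_rows(out) %>% arrange(.data$scaffold, .data$start)
  if (!has_sc) out$scaffold <- NULL
  out
}

ir <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
ir_to_tbl <- function(x, scaffold) {
  tibble(scaffold = scaffold, start = IRanges::start(x) - 1L, end = IRanges::end(x))
}

# union of (possibly empty) interval tibble as per-scaffold IRanges list
split_ir <- function(d, scaffolds) {
  out <- lapply(scaffolds, function(sc) {
    w <- d$scaffold == sc
    IRanges::reduce(ir(d$start[w], d$end[w]))
  })
  setNames(out, scaffolds)
}

#' Classify GRC sequence by cross-species homology
#'
#' Every base of the focal species' GRC assembly receives exactly one label:
#' `homologous` when covered by a direct alignment to the other species' GRC
#' assembly (block at least `min_len` bp at identity at least `min_identity`);
#' otherwise `potentially_homologous` when the base's placement on the
#' reference genome falls in a shared A-origin footprint — both species'
#' genome alignments merged jointly within `gap` bp, keeping merged regions
#' that received alignments from both species — so its absence from the other
#' assembly may simply be an assembly gap; `species_specific` otherwise.
#'
#' @param grc_lengths Named integer vector of the focal GRC scaffold lengths.
#' @param cross_aln Alignments of the focal GRC (query) onto the other
#'   species' GRC assembly.
#' @param genome_aln_self Alignments of the focal GRC (query) onto the shared
#'   reference genome.
#' @param genome_aln_other Alignments of the other species' GRC onto the same
#'   reference genome.
#' @param gap Merge gap for A-origin footprints (bp).
#' @param min_len,min_identity Thresholds for calling direct GRC-GRC homology.
#' @return Tibble (`scaffold`, `start`, `end`, `label`) partitioning every
#'   base of every focal scaffold.
#' @export
classify_homology <- function(grc_lengths, cross_aln, genome_aln_self,
                              genome_aln_other,
                              gap = grc_defaults$merge_gap,
                              min_len = grc_defaults$homology_min_len,
                              min_identity = grc_defaults$homology_min_identity) {
  scaffolds <- names(grc_lengths)
  cross <- cross_aln %>%
    filter(.data$block_len >= min_len,
           alignment_identity(cross_aln) >= min_identity)
  hom <- split_ir(tibble(scaffold = cross$query_id, start = cross$query_start,
                         end = cross$query_end), scaffolds)

  # A-origin footprints: alignments of both species onto the reference genome
  # are merged jointly within `gap`; a merged region that received alignments
  # from both species marks potentially shared ancestry
  both <- bind_rows(
    tibble(scaffold = genome_aln_self$target,
           start = genome_aln_self$target_start,
           end = genome_aln_self$target_end, species = "self"),
    tibble(scaffold = genome_aln_other$target,
           start = genome_aln_other$target_start,
           end = genome_aln_other$target_end, species = "other"))
  merged <- merge_within_gap(both[, c("scaffold", "start", "end")], gap)
  shared <- logical(nrow(merged))
  for (sc in unique(merged$scaffold)) {
    w <- which(merged$scaffold == sc)
    for (sp in c("self", "other")) {
      v <- which(both$scaffold == sc & both$species == sp)
      ov <- IRanges::countOverlaps(ir(merged$start[w], merged$end[w]),
                                   ir(both$start[v], both$end[v]))
      if (sp == "self") has_self <- ov > 0 else has_other <- ov > 0
    }
    shared[w] <- has_self & has_other
  }
  shared_foot <- merged[shared, , drop = FALSE]
  # GRC intervals whose genome placement lands in a shared footprint
  pot_raw <- tibble(scaffold = character(), start = integer(), end = integer())
  if (nrow(shared_foot) > 0 && nrow(genome_aln_self) > 0) {
    in_shared <- logical(nrow(genome_aln_self))
    for (sc in unique(shared_foot$scaffold)) {
      w <- which(genome_aln_self$target == sc)
      v <- which(shared_foot$scaffold == sc)
      if (length(w) == 0) next
      ov <- IRanges::countOverlaps(
        ir(genome_aln_self$target_start[w], genome_aln_self$target_end[w]),
        ir(shared_foot$start[v], shared_foot$end[v]))
      in_shared[w] <- ov > 0
    }
    pot_raw <- tibble(scaffold = genome_aln_self$query_id[in_shared],
                      start = genome_aln_self$query_start[in_shared],
                      end = genome_aln_self$query_end[in_shared])
  }
  pot <- split_ir(pot_raw, scaffolds)

  out <- lapply(scaffolds, function(sc) {
    full <- ir(0L, grc_lengths[[sc]])
    h <- hom[[sc]]
    p <- IRanges::setdiff(pot[[sc]], h)
    s <- IRanges::setdiff(IRanges::setdiff(full, h), p)
    bind_rows(
      if (length(h)) mutate(ir_to_tbl(h, sc), label = "homologous"),
      if (length(p)) mutate(ir_to_tbl(p, sc), label = "potentially_homologous"),
      if (length(s)) mutate(ir_to_tbl(s, sc), label = "species_specific"))
  })
  bind_rows(out) %>% arrange(.data$scaffold, .data$start)
}

#' Per-class base-pair totals, raw and copy-number weighted
#'
#' @param classes Label tibble from [classify_homology()].
#' @param scaffold_cn Optional tibble (`scaffold`, `copy_number`) used to
#'   weight each base by its scaffold's copy number, correcting for collapsed
#'   duplications.
#' @return Tibble per label: `bp` and (when weights are given) `weighted_bp`.
#' @export
homology_summary <- function(classes, scaffold_cn = NULL) {
  out <- classes %>%
    group_by(.data$label) %>%
    summarise(bp = sum(.data$end - .data$start), .groups = "drop")
  if (!is.null(scaffold_cn)) {
    w <- classes %>%
      left_join(scaffold_cn, by = "scaffold") %>%
      mutate(copy_number = ifelse(is.na(.data$copy_number), 1, .data$copy_number)) %>%
      group_by(.data$label) %>%
      summarise(weighted_bp = sum((.data$end - .data$start) * .data$copy_number),
                .groups = "drop")
    out <- left_join(out, w, by = "label")
  }
  out
}

#' Attribute GRC sequence to A-chromosomal origins
#'
#' Each aligned GRC interval is attributed to the chromosome of its
#' top-scoring hit on the reference genome (most matches; ties broken by the
#' longest block, then lexicographically by chromosome). Observed per-
#' chromosome contributions are copy-number weighted when `scaffold_cn` is
#' given ("corrected for coverage"); the expected contribution of each
#' chromosome is proportional to its length.
#'
#' @param genome_aln Alignments of GRC intervals (query) on the reference
#'   genome.
#' @param chrom_table Tibble mapping reference scaffolds to chromosomes:
#'   columns `scaffold`, `chromosome`, `length` (bp).
#' @param scaffold_cn Optional tibble (`scaffold`, `copy_number`) for the GRC
#'   scaffolds.
#' @return List with `attributions` (per GRC interval: winning `chromosome`,
#'   `weight_bp`) and `proportions` (per chromosome: `expected`, `observed`).
#' @export
origin_attribution <- function(genome_aln, chrom_table, scaffold_cn = NULL) {
  aln <- genome_aln %>%
    left_join(select(chrom_table, "scaffold", "chromosome"),
              by = c(target = "scaffold"))
  top <- aln %>%
    group_by(.data$query_id, .data$query_start, .data$query_end) %>%
    arrange(desc(.data$matches), desc(.data$block_len), .data$chromosome,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  cn <- if (is.null(scaffold_cn)) {
    tibble(scaffold = unique(top$query_id), copy_number = 1)
  } else scaffold_cn
  attributions <- top %>%
    left_join(cn, by = c(query_id = "scaffold")) %>%
    mutate(copy_number = ifelse(is.na(.data$copy_number), 1, .data$copy_number),
           weight_bp = (.data$query_end - .data$query_start) * .data$copy_number) %>%
    select(scaffold = "query_id", start = "query_start", end = "query_end",
           "chromosome", "weight_bp")
  observed <- attributions %>%
    group_by(.data$chromosome) %>%
    summarise(weight_bp = sum(.data$weight_bp), .groups = "drop") %>%
    mutate(observed = .data$weight_bp / sum(.data$weight_bp))
  proportions <- chrom_table %>%
    group_by(.data$chromosome) %>%
    summarise(length = sum(.data$length), .groups = "drop") %>%
    mutate(expected = .data$length / sum(.data$length)) %>%
    left_join(select(observed, "chromosome", "observed"), by = "chromosome") %>%
    mutate(observed = ifelse(is.na(.data$observed), 0, .data$observed)) %>%
    select("chromosome", "expected", "observed")
  list(attributions = attributions, proportions = proportions)
}

#' Divergence polarity of GRC regions between two species' A chromosomes
#'
#' For each GRC region aligned to both species' genomes, computes the signed
#' difference in mismatch proportion, `d = mismatch_prop(species 1) -
#' mismatch_prop(species 2)`: negative values mean the region is closer to
#' species 1's A chromosomes (it was likely acquired from, or diverged less
#' from, that genome). Regions equally divergent from both genomes (`d = 0`)
#' are removed; regions aligning to only one genome are excluded and counted.
#'
#' @param aln_sp1,aln_sp2 Best alignments of the same GRC regions (matching
#'   `query_id`/`query_start`/`query_end` keys) onto species 1's and species
#'   2's genome.
#' @return Tibble (`scaffold`, `start`, `end`, `mm1`, `mm2`, `d`) with
#'   attributes `n_single_side` (regions seen in only one genome) and
#'   `n_equal` (regions removed at `d = 0`).
#' @export
divergence_polarity <- function(aln_sp1, aln_sp2) {
  best_mm <- function(aln, col) {
    aln %>%
      mutate(mm = (.data$block_len - .data$matches) / .data$block_len) %>%
      group_by(.data$query_id, .data$query_start, .data$query_end) %>%
      summarise(!!col := min(.data$mm), .groups = "drop")
  }
  b1 <- best_mm(aln_sp1, "mm1")
  b2 <- best_mm(aln_sp2, "mm2")
  both <- dplyr::inner_join(b1, b2,
                            by = c("query_id", "query_start", "query_end"))
  n_single <- nrow(b1) + nrow(b2) - 2L * nrow(both)
  both <- mutate(both, d = .data$mm1 - .data$mm2)
  n_equal <- sum(both$d == 0)
  out <- both %>%
    filter(.data$d != 0) %>%
    select(scaffold = "query_id", start = "query_start", end = "query_end",
           "mm1", "mm2", "d")
  attr(out, "n_single_side") <- n_single
  attr(out, "n_equal") <- n_equal
  out
}
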