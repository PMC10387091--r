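#' Configuration for the synthetic GRC data generator
#'
#' Builds the configuration object consumed by [simulate_genome()],
#' [plant_gene_fragments()] and [simulate_reads()]. The defaults describe a
#' small but structurally complete study system: an A-genome of three
#' scaffolds; a GRC assembled from A-chromosomal segments carrying 0.1--2%
#' divergence; a recent near-identical within-GRC duplication (which collapses
#' to one assembly scaffold, like duplications merged by a real assembler) and
#' an older diverged duplication (which assembles into separate paralogous
#' scaffolds); a GRC-restricted tandem repeat; and partially retained gene
#' copies, some with planted premature stop codons. Germline libraries place
#' single-copy GRC coverage at 20% of the A-chromosome coverage, the centre of
#' the 14--23% range observed in real germline data, because the GRC is
#' present in only a subset of gonadal cells and as a single copy per male
#' germ cell.
#'
#' @param seed Integer seed; every simulation output is a deterministic
#'   function of the configuration including this seed.
#' @param a_genome Named integer vector of A-scaffold lengths (bp).
#' @param grc_segments Tibble describing the A-segments the GRC is built from:
#'   columns `segment`, `source_scaffold`, `start`, `end` (0-based half-open on
#'   the source), `divergence` (substitution fraction vs the A source),
#'   `copy_number` (true copies on the GRC), `copy_divergence` (substitution
#'   fraction between copies; 0 means byte-identical copies that collapse into
#'   one assembly scaffold).
#' @param repeat_monomer Monomer sequence for the GRC-restricted tandem repeat,
#'   or `NULL` to generate a random monomer of `repeat_monomer_len` bp.
#' @param repeat_monomer_len,repeat_array_len Monomer and total array length in
#'   bp; `repeat_array_len = 0` disables the repeat.
#' @param gene_models Tibble of planted genes: `gene_id`, `scaffold`, `exons`
#'   (list-column of two-column matrices with 0-based half-open exon intervals
#'   on the A scaffold), `fraction_retained` (fraction of the coding length
#'   present on the GRC), `premature_stop` (logical).
#' @param read_len Read length (bp).
#' @param soma_depth Kidney (somatic) sequencing depth over the A-genome (x).
#' @param germline_a_depth Testis sequencing depth over the A-genome (x);
#'   germline libraries are sequenced deeper than somatic ones.
#' @param grc_singlecopy_ratio Single-copy GRC depth divided by A-chromosome
#'   depth in the testis library; must lie in (0, 1).
#' @param molecule_len Linked-read molecule length (bp); one barcode per
#'   molecule, molecules never span two source sequences.
#' @param reads_per_molecule Reads drawn from each molecule.
#' @param error_rate Per-base substitution error rate of the sequencer.
#' @param n_samples Individuals sequenced per tissue.
#' @return A `grc_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       a_genome = c(chrA1 = 120000L, chrA2 = 60000L, chrA3 = 30000L),
                       grc_segments = NULL,
                       repeat_monomer = NULL,
                       repeat_monomer_len = 150L,
                       repeat_array_len = 5000L,
                       gene_models = NULL,
                       read_len = 100L,
                       soma_depth = 20,
                       germline_a_depth = 30,
                       grc_singlecopy_ratio = 0.2,
                       molecule_len = 50000L,
                       reads_per_molecule = 10L,
                       error_rate = 0.001,
                       n_samples = 3L) {
  if (is.null(names(a_genome)))
    names(a_genome) <- paste0("chrA", seq_along(a_genome))
  if (is.null(grc_segments)) {
    grc_segments <- tibble(
      segment = c("seg1", "seg2", "seg3", "seg4"),
      source_scaffold = c("chrA1", "chrA1", "chrA2", "chrA2"),
      start = c(10000L, 50000L, 5000L, 40000L),
      end   = c(30000L, 62000L, 20000L, 48000L),
      divergence = c(0.010, 0.005, 0.020, 0.002),
      copy_number = c(1L, 3L, 2L, 1L),
      copy_divergence = c(0, 0, 0.05, 0)
    )
  }
  if (is.null(gene_models)) {
    ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
    gene_models <- tibble(
      gene_id = paste0("g", 1:6),
      scaffold = "chrA3",
      exons = list(
        ex(1000, 1400, 1800, 2100, 2500, 2800),
        ex(4000, 4600, 5000, 5600),
        ex(7000, 7900),
        ex(10000, 10600, 11000, 11450),
        ex(14000, 15000),
        ex(17000, 17800, 18200, 18600)
      ),
      fraction_retained = c(1.0, 0.5, 0.25, 1.0, 0.10, 0.80),
      premature_stop = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
    )
  }
  cfg <- structure(list(
    seed = as.integer(seed), a_genome = a_genome, grc_segments = grc_segments,
    repeat_monomer = repeat_monomer, repeat_monomer_len = as.integer(repeat_monomer_len),
    repeat_array_len = as.integer(repeat_array_len), gene_models = gene_models,
    read_len = as.integer(read_len), soma_depth = soma_depth,
    germline_a_depth = germline_a_depth, grc_singlecopy_ratio = grc_singlecopy_ratio,
    molecule_len = as.integer(molecule_len),
    reads_per_molecule = as.integer(reads_per_molecule),
    error_rate = error_rate, n_samples = as.integer(n_samples)
  ), class = "grc_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$grc_segments$divergence, cfg$grc_segments$copy_divergence,
          cfg$error_rate, cfg$gene_models$fraction_retained)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]", class = "grc_config_error")
  if (cfg$soma_depth <= 0 || cfg$germline_a_depth <= 0)
    abort("depths must be > 0", class = "grc_config_error")
  if (cfg$grc_singlecopy_ratio <= 0 || cfg$grc_singlecopy_ratio >= 1)
    abort("grc_singlecopy_ratio must lie in (0, 1)", class = "grc_config_error")
  if (cfg$molecule_len < cfg$read_len)
    abort("molecule_len must be >= read_len", class = "grc_config_error")
  segs <- cfg$grc_segments
  lens <- cfg$a_genome[segs$source_scaffold]
  if (anyNA(lens) || any(segs$start < 0) || any(segs$end > lens) || any(segs$start >= segs$end))
    abort("grc_segments must fit inside their source scaffolds", class = "grc_config_error")
  for (i in seq_len(nrow(cfg$gene_models))) {
    e <- cfg$gene_models$exons[[i]]
    sc <- cfg$gene_models$scaffold[i]
    if (!sc %in% names(cfg$a_genome) || any(e[, 2] > cfg$a_genome[[sc]]))
      abort("gene exons must fit inside their scaffold", class = "grc_config_error")
    o <- order(e[, 1])
    if (any(e[o, 1][-1] < e[o, 2][-nrow(e)]))
      abort("overlapping gene exons on one strand", class = "grc_config_error")
  }
  invisible(cfg)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute at positions drawn Binomial(L, rate); returns list(seq, pos, ref, alt)
mutate_seq <- function(seq, rate) {
  L <- nchar(seq)
  n <- stats::rbinom(1, L, rate)
  if (n == 0) return(list(seq = seq, pos = integer(), ref = character(), alt = character()))
  pos <- sort(sample.int(L, n))
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  ref <- v[pos]
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1), USE.NAMES = FALSE)
  v[pos] <- alt
  list(seq = paste(v, collapse = ""), pos = pos - 1L, ref = ref, alt = alt)
}

# stop-free codon string of length n bases (in frame 0 of the string)
open_reading_seq <- function(n) {
  n_codons <- ceiling(n / 3)
  sense <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
                   STOP_CODONS)
  substr(paste(sample(sense, n_codons, replace = TRUE), collapse = ""), 1, n)
}

#' Simulate an A-genome and a GRC with planted structure
#'
#' Generates random A-chromosome scaffolds, rewrites planted gene exons into
#' stop-free open reading frames, and builds the GRC from the configured
#' A-segments. Copies of a segment with `copy_divergence = 0` are
#' byte-identical and are represented by a single assembly scaffold (they
#' collapse, like near-identical duplications merged by a real assembler) with
#' a true copy number greater than one; copies with `copy_divergence > 0`
#' receive private substitutions and assemble into separate scaffolds of copy
#' number one. A GRC-restricted tandem repeat array is appended when
#' configured. All randomness is a deterministic function of the seed.
#'
#' @param config A [sim_config()] object.
#' @return A `grc_sim_genome` list with elements `a_seqs` (named character),
#'   `grc_assembly` (named character; the collapsed assembly), `copy_seqs`
#'   (named character; one sequence per true GRC copy), and `truth` (list of
#'   tibbles: `segments`, `copies`, `snps` with the germline-specific variant
#'   positions on the A source in 0-based coordinates).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  a_seqs <- vapply(config$a_genome, function(L) random_seq(L), character(1))

  # plant open reading frames for the gene models on the A genome
  gm <- config$gene_models
  for (i in seq_len(nrow(gm))) {
    e <- gm$exons[[i]]
    sc <- gm$scaffold[i]
    cds_len <- sum(e[, 2] - e[, 1])
    cds <- open_reading_seq(cds_len)
    off <- 0L
    s <- a_seqs[[sc]]
    for (j in seq_len(nrow(e))) {
      len <- e[j, 2] - e[j, 1]
      substr(s, e[j, 1] + 1L, e[j, 2]) <- substr(cds, off + 1L, off + len)
      off <- off + len
    }
    a_seqs[[sc]] <- s
  }

  segs <- config$grc_segments
  assembly <- character()
  copy_seqs <- character()
  seg_rows <- list()
  copy_rows <- list()
  snp_rows <- list()
  for (i in seq_len(nrow(segs))) {
    src <- substr(a_seqs[[segs$source_scaffold[i]]], segs$start[i] + 1L, segs$end[i])
    mut <- mutate_seq(src, segs$divergence[i])
    if (length(mut$pos) > 0) {
      snp_rows[[length(snp_rows) + 1]] <- tibble(
        segment = segs$segment[i], source_scaffold = segs$source_scaffold[i],
        pos = segs$start[i] + mut$pos, ref = mut$ref, alt = mut$alt)
    }
    cn <- segs$copy_number[i]
    if (segs$copy_divergence[i] == 0) {
      nm <- paste0("grc_", segs$segment[i])
      assembly[nm] <- mut$seq
      seg_rows[[length(seg_rows) + 1]] <- tibble(
        scaffold = nm, segment = segs$segment[i],
        source_scaffold = segs$source_scaffold[i],
        source_start = segs$start[i], source_end = segs$end[i],
        length = nchar(mut$seq), copy_number = cn,
        divergence = segs$divergence[i], kind = "segment")
      for (cc in seq_len(cn)) {
        cid <- paste0(nm, "_copy", cc)
        copy_seqs[cid] <- mut$seq
        copy_rows[[length(copy_rows) + 1]] <- tibble(
          copy_id = cid, scaffold = nm, segment = segs$segment[i])
      }
    } else {
      for (cc in seq_len(cn)) {
        nm <- paste0("grc_", segs$segment[i], "_p", cc)
        s <- if (cc == 1) mut$seq else mutate_seq(mut$seq, segs$copy_divergence[i])$seq
        assembly[nm] <- s
        seg_rows[[length(seg_rows) + 1]] <- tibble(
          scaffold = nm, segment = segs$segment[i],
          source_scaffold = segs$source_scaffold[i],
          source_start = segs$start[i], source_end = segs$end[i],
          length = nchar(s), copy_number = 1L,
          divergence = segs$divergence[i], kind = "segment")
        cid <- paste0(nm, "_copy1")
        copy_seqs[cid] <- s
        copy_rows[[length(copy_rows) + 1]] <- tibble(
          copy_id = cid, scaffold = nm, segment = segs$segment[i])
      }
    }
  }

  if (config$repeat_array_len > 0) {
    monomer <- config$repeat_monomer %||% random_seq(config$repeat_monomer_len)
    array <- substr(strrep(monomer, ceiling(config$repeat_array_len / nchar(monomer))),
                    1, config$repeat_array_len)
    assembly[["grc_repeat"]] <- array
    copy_seqs[["grc_repeat_copy1"]] <- array
    seg_rows[[length(seg_rows) + 1]] <- tibble(
      scaffold = "grc_repeat", segment = "repeat", source_scaffold = NA_character_,
      source_start = NA_integer_, source_end = NA_integer_,
      length = nchar(array), copy_number = 1L, divergence = 0, kind = "repeat")
    copy_rows[[length(copy_rows) + 1]] <- tibble(
      copy_id = "grc_repeat_copy1", scaffold = "grc_repeat", segment = "repeat")
  } else {
    monomer <- config$repeat_monomer
  }

  structure(list(
    a_seqs = a_seqs, grc_assembly = assembly, copy_seqs = copy_seqs,
    repeat_monomer = monomer,
    truth = list(segments = bind_rows(seg_rows), copies = bind_rows(copy_rows),
                 snps = bind_rows(snp_rows), genes = NULL),
    config = config
  ), class = "grc_sim_genome")
}

#' Plant partial gene copies (and premature stops) on the GRC
#'
#' For each configured gene model, copies exactly `fraction_retained` of the
#' gene's coding length from the A-genome onto a new GRC scaffold (exons are
#' retained in order; the last retained exon is truncated to hit the target
#' length exactly). When `premature_stop` is set, one sense codon inside a
#' retained exon is rewritten to TAA in the exon's coding frame, placed before
#' 95% of the exon length so the exon fails the open-reading-frame rule.
#'
#' @param genome A `grc_sim_genome` from [simulate_genome()].
#' @return The genome with gene scaffolds appended to `grc_assembly` and
#'   `copy_seqs`, and a `truth$genes` tibble (per gene: realized retained
#'   length, GRC exon intervals, the matching CDS intervals, planted stop
#'   position or `NA`).
#' @export
plant_gene_fragments <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 101L)
  gm <- cfg$gene_models
  gene_rows <- list()
  for (i in seq_len(nrow(gm))) {
    e <- gm$exons[[i]]
    cds_len <- sum(e[, 2] - e[, 1])
    target <- round(gm$fraction_retained[i] * cds_len)
    if (target == 0) {
      gene_rows[[length(gene_rows) + 1]] <- tibble(
        gene_id = gm$gene_id[i], cds_len = cds_len, retained_len = 0L,
        fraction_retained = 0, scaffold = NA_character_,
        grc_exons = list(matrix(integer(), ncol = 2)),
        cds_exons = list(matrix(integer(), ncol = 2)),
        stop_pos = NA_integer_, premature_stop = FALSE)
      next
    }
    if (target > 0 && nrow(e) == 0)
      abort("fraction retained > 0 but no exon fits", class = "grc_config_error")
    # walk exons in CDS order until the retained length is reached
    kept <- list(); cds_kept <- list(); off <- 0L; got <- 0L
    seqs <- character()
    src <- genome$a_seqs[[gm$scaffold[i]]]
    for (j in seq_len(nrow(e))) {
      len <- e[j, 2] - e[j, 1]
      take <- min(len, target - got)
      if (take > 0) {
        kept[[length(kept) + 1]] <- c(e[j, 1], e[j, 1] + take)
        cds_kept[[length(cds_kept) + 1]] <- c(off, off + take)
        seqs <- c(seqs, substr(src, e[j, 1] + 1L, e[j, 1] + take))
        got <- got + take
      }
      off <- off + len
      if (got >= target) break
    }
    # lay retained exons on a fresh GRC scaffold with 200-bp spacers
    spacer <- 200L
    scaf_name <- paste0("grc_gene_", gm$gene_id[i])
    pieces <- character(); grc_exons <- matrix(integer(), ncol = 2)
    pos <- 0L
    for (j in seq_along(seqs)) {
      sp <- random_seq(spacer)
      pieces <- c(pieces, sp)
      pos <- pos + spacer
      grc_exons <- rbind(grc_exons, c(pos, pos + nchar(seqs[j])))
      pieces <- c(pieces, seqs[j])
      pos <- pos + nchar(seqs[j])
    }
    pieces <- c(pieces, random_seq(spacer))
    scaf <- paste(pieces, collapse = "")
    stop_pos <- NA_integer_
    if (gm$premature_stop[i]) {
      # frame of the first retained exon within the CDS
      frame <- cds_kept[[1]][1] %% 3
      ex_start <- grc_exons[1, 1]; ex_len <- grc_exons[1, 2] - grc_exons[1, 1]
      # first full codon inside the exon, then step to ~40% of the exon
      codon0 <- (3 - frame) %% 3
      n_codons <- (ex_len - codon0) %/% 3
      if (n_codons < 2) abort("retained exon too short to plant a stop",
                              class = "grc_config_error")
      ci <- max(1L, min(n_codons - 1L, floor(0.4 * n_codons)))
      stop_pos <- ex_start + codon0 + 3L * (ci - 1L)
      substr(scaf, stop_pos + 1L, stop_pos + 3L) <- "TAA"
    }
    genome$grc_assembly[scaf_name] <- scaf
    genome$copy_seqs[paste0(scaf_name, "_copy1")] <- scaf
    genome$truth$segments <- bind_rows(genome$truth$segments, tibble(
      scaffold = scaf_name, segment = paste0("gene_", gm$gene_id[i]),
      source_scaffold = gm$scaffold[i], source_start = NA_integer_,
      source_end = NA_integer_, length = nchar(scaf), copy_number = 1L,
      divergence = 0, kind = "gene"))
    genome$truth$copies <- bind_rows(genome$truth$copies, tibble(
      copy_id = paste0(scaf_name, "_copy1"), scaffold = scaf_name,
      segment = paste0("gene_", gm$gene_id[i])))
    gene_rows[[length(gene_rows) + 1]] <- tibble(
      gene_id = gm$gene_id[i], cds_len = cds_len, retained_len = got,
      fraction_retained = got / cds_len, scaffold = scaf_name,
      grc_exons = list(grc_exons),
      cds_exons = list(do.call(rbind, cds_kept)),
      stop_pos = stop_pos, premature_stop = gm$premature_stop[i])
  }
  genome$truth$genes <- bind_rows(gene_rows)
  genome
}

#' Simulate barcoded germline and somatic read sets
#'
#' Draws linked-read molecules and reads from the simulated genome. Kidney
#' (somatic) libraries sample only the A-genome; testis (germline) libraries
#' sample the A-genome at `germline_a_depth` and every true GRC copy at
#' `grc_singlecopy_ratio * germline_a_depth`, reflecting the reduced
#' representation of the single-copy GRC in gonadal tissue. Each molecule gets
#' one unique barcode, is confined to one source sequence, and contributes
#' `reads_per_molecule` uniformly placed reads; per-base substitution errors
#' are applied at `error_rate`. Output is byte-identical across runs with the
#' same configuration.
#'
#' @param genome A `grc_sim_genome`, typically after [plant_gene_fragments()].
#' @return A `grc_sim_reads` list: `reads` (tibble: `read_id`, `sequence`,
#'   `barcode`, `tissue`, `sample`), `truth_reads` (read origins: source copy,
#'   0-based position, strand), `truth_molecules` (per barcode: source copy and
#'   molecule interval).
#' @export
simulate_reads <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 202L)
  rl <- cfg$read_len
  rpm <- cfg$reads_per_molecule
  grc_depth <- cfg$grc_singlecopy_ratio * cfg$germline_a_depth

  sources_for <- function(tissue) {
    if (tissue == "kidney") {
      tibble(source_id = names(genome$a_seqs),
             len = nchar(genome$a_seqs), depth = cfg$soma_depth)
    } else {
      bind_rows(
        tibble(source_id = names(genome$a_seqs),
               len = nchar(genome$a_seqs), depth = cfg$germline_a_depth),
        tibble(source_id = names(genome$copy_seqs),
               len = nchar(genome$copy_seqs), depth = grc_depth))
    }
  }
  all_seqs <- c(genome$a_seqs, genome$copy_seqs)

  mol_list <- list(); read_list <- list()
  for (tissue in c("testis", "kidney")) {
    for (si in seq_len(cfg$n_samples)) {
      sample_id <- sprintf("%s%d", if (tissue == "testis") "T" else "K", si)
      src <- sources_for(tissue)
      src <- src[src$len >= rl, , drop = FALSE]
      # molecule windows may hang off the source; reads falling outside are
      # rejected, which keeps the read-start density exactly uniform (no
      # edge pile-ups); the molecule count compensates for the rejections
      wlen <- pmin(cfg$molecule_len, src$len)
      span <- (src$len - rl + 1) + (wlen - rl)
      n_mol <- pmax(1L, as.integer(round(
        src$depth * src$len / (rpm * rl) * span / (src$len - rl + 1))))
      mol <- tibble(
        source_id = rep(src$source_id, n_mol),
        src_len = rep(src$len, n_mol),
        wlen = rep(wlen, n_mol))
      raw_start <- as.integer(floor(stats::runif(
        nrow(mol), -(mol$wlen - rl), mol$src_len - rl + 1)))
      mol$mol_start <- pmax(0L, raw_start)
      mol$mol_end <- pmin(mol$src_len, raw_start + mol$wlen)
      mol$barcode <- sprintf("bc_%s_%07d", sample_id, seq_len(nrow(mol)))
      mol$tissue <- tissue
      mol$sample <- sample_id
      idx <- rep(seq_len(nrow(mol)), each = rpm)
      starts <- as.integer(floor(stats::runif(
        length(idx), raw_start[idx], raw_start[idx] + mol$wlen[idx] - rl + 1)))
      ok <- starts >= 0L & starts <= mol$src_len[idx] - rl
      reads <- tibble(
        source_id = mol$source_id[idx][ok], pos = starts[ok],
        barcode = mol$barcode[idx][ok], tissue = tissue, sample = sample_id)
      mol$wlen <- NULL
      mol_list[[length(mol_list) + 1]] <- mol
      read_list[[length(read_list) + 1]] <- reads
    }
  }
  molecules <- bind_rows(mol_list)
  reads <- bind_rows(read_list)
  reads$read_id <- sprintf("r%08d", seq_len(nrow(reads)))
  reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)

  # extract sequences source by source
  seq_out <- character(nrow(reads))
  for (sid in unique(reads$source_id)) {
    w <- which(reads$source_id == sid)
    seq_out[w] <- substring(all_seqs[[sid]], reads$pos[w] + 1L, reads$pos[w] + rl)
  }
  minus <- reads$strand == "-"
  if (any(minus)) seq_out[minus] <- cpp_revcomp(seq_out[minus])

  # sequencing errors: Binomial(total bases, error_rate) substitutions
  if (cfg$error_rate > 0) {
    total <- length(seq_out) * rl
    n_err <- stats::rbinom(1, total, cfg$error_rate)
    if (n_err > 0) {
      at <- sample.int(total, n_err)
      ridx <- ((at - 1L) %/% rl) + 1L
      off <- ((at - 1L) %% rl) + 1L
      for (k in seq_len(n_err)) {
        b <- substr(seq_out[ridx[k]], off[k], off[k])
        substr(seq_out[ridx[k]], off[k], off[k]) <- sample(setdiff(BASES, b), 1)
      }
    }
  }

  structure(list(
    reads = tibble(read_id = reads$read_id, sequence = seq_out,
                   barcode = reads$barcode, tissue = reads$tissue,
                   sample = reads$sample),
    truth_reads = tibble(read_id = reads$read_id, source_id = reads$source_id,
                         pos = reads$pos, strand = reads$strand,
                         barcode = reads$barcode, tissue = reads$tissue,
                         sample = reads$sample),
    truth_molecules = molecules[, c("barcode", "source_id", "mol_start",
                                    "mol_end", "tissue", "sample")],
    config = cfg
  ), class = "grc_sim_reads")
}

#' Simulate a complete synthetic GRC dataset
#'
#' Convenience wrapper: [simulate_genome()], then [plant_gene_fragments()],
#' then [simulate_reads()].
#'
#' @param config A [sim_config()] object.
#' @return List with `genome` (`grc_sim_genome`) and `reads` (`grc_sim_reads`).
#' @export
simulate_grc_dataset <- function(config) {
  genome <- plant_gene_fragments(simulate_genome(config))
  list(genome = genome, reads = simulate_reads(genome))
}

#' Copy-weighted true GRC length
#'
#' Sum of segment length times true copy number over the simulated GRC; the
#' quantity a duplication-corrected size estimate should recover.
#'
#' @param genome A `grc_sim_genome`.
#' @return Length in bp.
#' @export
true_grc_size <- function(genome) {
  with(genome$truth$segments, sum(length * copy_number))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
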