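#' Build a full-run configuration
#'
#' One serializable object holding every stage parameter of the pipeline —
#' simulation geometry, mapper settings, and all procedural thresholds (which
#' default to [grc_defaults]). Round-trips through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Integer seed governing all randomness of the run.
#' @param ... Overrides for any field of [grc_defaults] or of the simulation
#'   parameters accepted by [sim_config()] (scalar fields only).
#' @return A `grc_run_config` list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- c(list(seed = as.integer(seed)), grc_defaults,
           list(read_len = 100L, soma_depth = 20, germline_a_depth = 30,
                grc_singlecopy_ratio = 0.2, molecule_len = 50000L,
                reads_per_molecule = 10L, error_rate = 0.001, n_samples = 3L))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "grc_run_config")
}

#' Write a run configuration to YAML
#' @param config A `grc_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file written by [write_run_config()].
#' @return A `grc_run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$seed <- as.integer(x$seed)
  structure(x, class = "grc_run_config")
}

#' Run the full synthetic-data pipeline into a run directory
#'
#' Executes the stages in dependency order — simulate, map, identify,
#' coverage/copy-number, gene annotation — writing each stage's outputs as
#' plain-text files plus a manifest recording the configuration hash and
#' per-file checksums. Re-running an unchanged configuration reproduces
#' byte-identical outputs and manifest.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory (created if absent).
#' @return Invisible list with the in-memory stage results (`sim`, `identify`,
#'   `constants`, `windows`, `sizes`, `genes`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "grc_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_cfg <- sim_config(
    seed = config$seed, read_len = config$read_len,
    soma_depth = config$soma_depth, germline_a_depth = config$germline_a_depth,
    grc_singlecopy_ratio = config$grc_singlecopy_ratio,
    molecule_len = config$molecule_len,
    reads_per_molecule = config$reads_per_molecule,
    error_rate = config$error_rate, n_samples = config$n_samples)
  sim <- simulate_grc_dataset(sim_cfg)
  genome <- sim$genome
  reads <- sim$reads$reads

  write_fasta(genome$a_seqs, file.path(out_dir, "a_genome.fa"))
  write_fasta(genome$grc_assembly, file.path(out_dir, "grc_assembly.fa"))
  write_tsv_table(genome$truth$segments, file.path(out_dir, "truth_segments.tsv"))
  for (sm in unique(reads$sample)) {
    write_fastq_barcoded(reads[reads$sample == sm, ],
                         file.path(out_dir, paste0("reads_", sm, ".fastq")))
  }

  testis <- reads[reads$tissue == "testis", ]
  kidney <- reads[reads$tissue == "kidney", ]
  consensus <- if (!is.null(genome$repeat_monomer))
    strrep(genome$repeat_monomer,
           ceiling(3 * config$read_len / nchar(genome$repeat_monomer)))
  ident <- identify_grc_reads(
    testis, kidney,
    germline_assembly = c(genome$a_seqs, genome$grc_assembly),
    soma_reference = genome$a_seqs,
    repeat_consensus = consensus,
    min_region_len = config$min_region_len, min_overlap = config$min_overlap,
    kmer_len = config$kmer_len, repeat_min_len = config$repeat_min_len,
    repeat_min_identity = config$repeat_min_identity,
    min_alt = config$min_alt_reads, seed_k = config$seed_k)
  write_tsv_table(ident$selection, file.path(out_dir, "barcodes.tsv"))
  write_tsv_table(ident$counts, file.path(out_dir, "identify_counts.tsv"))
  if (nrow(ident$regions) > 0)
    write_bed(ident$regions, file.path(out_dir, "germline_regions.bed"))
  write_fastq_barcoded(ident$recruited, file.path(out_dir, "recruited_reads.fastq"))

  # per-sample coverage on the combined genome + GRC assembly
  grc_names <- names(genome$grc_assembly)
  a_names <- names(genome$a_seqs)
  lens <- setNames(nchar(c(genome$a_seqs, genome$grc_assembly)),
                   c(a_names, grc_names))
  windows <- list(); constants <- list()
  t_samples <- sort(unique(testis$sample))
  k_samples <- sort(unique(kidney$sample))
  for (i in seq_along(t_samples)) {
    at <- ident$aln_testis_germ[
      ident$aln_testis_germ$query_id %in%
        testis$read_id[testis$sample == t_samples[i]], ]
    ak <- ident$aln_kidney_germ[
      ident$aln_kidney_germ$query_id %in%
        kidney$read_id[kidney$sample == k_samples[i]], ]
    cov_t <- coverage_from_alignments(
      barcode_aware_primary(at, testis, prefer = grc_names), lens)
    cov_k <- coverage_from_alignments(
      barcode_aware_primary(ak, kidney, prefer = grc_names), lens)
    const <- estimate_constants(cov_t[grc_names], cov_k[grc_names],
                                cov_t[a_names], cov_k[a_names],
                                sample = t_samples[i])
    constants[[i]] <- const
    windows[[i]] <- copy_number_windows(cov_t[grc_names], cov_k[grc_names],
                                        const, window = config$window)
  }
  constants <- bind_rows(constants)
  windows <- bind_rows(windows)
  sizes <- grc_size_estimate(windows)
  write_tsv_table(constants, file.path(out_dir, "normalization_constants.tsv"))
  write_tsv_table(windows, file.path(out_dir, "copy_number_windows.tsv"))
  write_tsv_table(sizes, file.path(out_dir, "grc_size_estimates.tsv"))

  # gene annotation of the GRC assembly against the planted coding sequences
  cds <- planted_cds(genome)
  genes <- NULL
  if (length(cds) > 0) {
    hits <- translated_search(cds, genome$grc_assembly)
    exons <- annotate_exons(hits, evalue_max = config$evalue_max)
    genes <- gene_report(exons, cds, genome, config)
    write_tsv_table(genes, file.path(out_dir, "genes.tsv"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("grcfinder")),
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(sim = sim, identify = ident, constants = constants,
                 windows = windows, sizes = sizes, genes = genes,
                 manifest = manifest))
}

# coding sequences of the planted gene models, extracted from the A genome
planted_cds <- function(genome) {
  gm <- genome$config$gene_models
  if (nrow(gm) == 0) return(character())
  cds <- vapply(seq_len(nrow(gm)), function(i) {
    e <- gm$exons[[i]]
    paste(substring(genome$a_seqs[[gm$scaffold[i]]], e[, 1] + 1L, e[, 2]),
          collapse = "")
  }, character(1))
  setNames(cds, gm$gene_id)
}

gene_report <- function(exons, cds, genome, config) {
  if (nrow(exons) == 0) return(tibble())
  raw <- gene_raw_proportions(exons, nchar(cds))
  exon_seq <- vapply(seq_len(nrow(exons)), function(i)
    substr(genome$grc_assembly[[exons$scaffold[i]]],
           exons$start[i] + 1L, exons$end[i]), character(1))
  exons$premature_stop <- premature_stops(exon_seq, exons$strand,
                                          frac = config$orf_frac)
  stops <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(premature_stop_exons = sum(.data$premature_stop),
              n_exons = n(), .groups = "drop")
  raw %>%
    left_join(stops, by = "gene_id") %>%
    mutate(norm_completeness = completeness(
      .data$raw_prop, 1, floor = config$completeness_floor),
      included = include_gene(.data$norm_completeness,
                              min_prop = config$include_min),
      band = as.character(completeness_band(.data$norm_completeness)))
}
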