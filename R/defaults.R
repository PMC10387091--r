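#' Pipeline default constants
#'
#' Every procedural constant of the pipeline in one place; stage functions
#' default their arguments from this list (never from literals), and
#' [run_config()] exposes the same fields for a whole run. Values: 500 bp
#' minimum germline-specific region length; 10 bp minimum read/region overlap;
#' 29 bp diagnostic k-mers; 100 bp / 90% identity repeat-match thresholds;
#' >= 2 alt reads per sample for the naive pileup caller; 1 kbp copy-number
#' windows; 10 kbp interval-merge gap; 1e-6 e-value cut-off for translated
#' hits; 0.75 completeness-denominator floor; 25% gene inclusion threshold;
#' 95% open-reading-frame rule; 1.5 univalent divisor for meiotic-spread GRC
#' lengths; and mapper seed/tile sizes.
#'
#' @format Named list.
#' @export
grc_defaults <- list(
  min_region_len = 500L,
  min_overlap = 10L,
  kmer_len = 29L,
  repeat_min_len = 100L,
  repeat_min_identity = 0.90,
  min_alt_reads = 2L,
  window = 1000L,
  merge_gap = 10000L,
  evalue_max = 1e-6,
  completeness_floor = 0.75,
  include_min = 0.25,
  orf_frac = 0.95,
  univalent_divisor = 1.5,
  homology_min_len = 500L,
  homology_min_identity = 0.90,
  seed_k = 21L,
  tile = 500L
)
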