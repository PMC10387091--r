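---
title: "Detecting and characterizing a germline-restricted chromosome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing a germline-restricted chromosome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grcfinder)
```

## The problem

A germline-restricted chromosome (GRC) is present in germ cells but
programmatically eliminated from somatic cells early in development. In
songbirds it occurs as a single copy in male germ cells and only in a subset
of gonadal cells, so in a testis sequencing library single-copy GRC sequence
is covered at only ~15--25% of the A-chromosomal depth, while a kidney
library from the same individual contains no GRC at all. Much GRC sequence
is recently derived from A chromosomes and is nearly identical to its
paralogs, which defeats naive assembly and read classification.

`grcfinder` implements a desk-scale, fully testable version of the analysis
used to assemble and characterize such chromosomes from tissue-paired
(testis/kidney) libraries: identification of germline-derived linked reads,
coverage-based copy-number and size estimation, cross-species homology and
origin classification, gene completeness and pseudogenization scoring, and
an independent cytogenetic size estimate from meiotic spreads.

## Germline read identification

Three marker channels flag high-confidence germline reads; barcode expansion
then recruits everything sharing a molecule with them.

* **Channel (a), germline-specific regions.** Reads of both tissues are
  aligned to the germline (testis) assembly. Maximal intervals at least
  500 bp long that are fully covered by testis reads (depth ≥ 1 at every
  base) while receiving no kidney reads are germline-specific; testis reads
  overlapping them by ≥ 10 bp contribute their barcodes. Both the coverage
  tracks and the overlap rule use *uniquely* mapping reads. This resolves an
  ambiguity in what "fully covered" should mean when a read ties between an
  A chromosome and an identical GRC stretch: a tied read carries no
  tissue-diagnostic information, and counting ties lets A-chromosomal
  molecules leak into the selection wherever the pooled kidney ties happen,
  by sampling chance, to miss an identical stretch. A read with a perfect
  A-chromosomal placement can never be unique on the GRC, so with error-free
  reads the unique-only rule is exactly precise.
* **Channel (b), diagnostic k-mers.** A naive pileup caller counts bases at
  each site of the somatic reference (a site is called when ≥ 2 reads of one
  sample support the same non-reference base; there is no quality model —
  the decisive gate is the next filter). Variants present in *all* testis
  samples and *no* kidney sample are germline-specific. Each variant is
  expanded into all 29-bp windows of the alt-substituted reference containing
  it (29 k-mers for an interior site; sites within 28 bp of a contig end
  yield fewer — the signal is kept rather than the site discarded). Any
  k-mer occurring in the kidney reads, on either strand, is removed; testis
  reads containing a surviving k-mer contribute their barcodes. Matching is
  exact-substring on both strands, the only choice consistent with
  unstranded DNA reads.
* **Channel (c), germline-restricted repeats.** Given an externally supplied
  repeat consensus (repeat discovery is out of scope), reads with an
  alignment block of at least 100 bp at identity above 90% contribute their
  barcodes.

Reads without barcodes may trigger a channel but cannot recruit companions;
expansion is defined on barcodes.

## Coverage normalization and copy number

Reads are aligned to the combined somatic genome + GRC assembly. For
copy-number work each read is counted exactly once: ties between placements
are resolved by *barcode voting* (the target that carries the most uniquely
mapped reads of the same molecule wins — the linked-read analogue of
paired-end rescue), and remaining ties prefer the GRC scaffold so that
ambiguous coverage lands where the somatic subtraction can correct it.

For each individual, GRC bases with zero kidney coverage estimate the
expected single-copy GRC testis depth; its ratio to the modal A-chromosomal
testis depth (expected in the 14--23% band) serves as a proxy for the
expected GRC coverage in the kidney library. Copy number per base is

```
cn(b) = testis(b) / single_copy_grc_depth - kidney(b) / (ratio * modal_a_depth_kidney)
```

averaged over 1-kbp windows and floored at zero. Subtraction happens per
base, before windowed averaging. Trailing short windows are kept with their
true width and weighted accordingly in the size estimate, which is
`sum(cn * window_width)` — sequence collapsed from several near-identical
copies counts once per copy.

Two numerical choices matter at 10--25x single-copy depth. `depth_mode()`
is the plain integer-histogram mode (binwidth 1, ties toward the smaller
depth — deterministic and permutation-invariant). For the normalization
*constants*, however, the integer mode quantizes a depth of ~10 by ±5--10%
and the skew of the depth distribution biases it low, which propagates
multiplicatively into every window. `modal_depth()` therefore refines the
estimate: it averages depth over 1-kb windows (restricted to the zero-soma
mask where applicable) and takes the kernel-density mode of the window
means. The most abundant copy-number class forms a well-separated,
near-symmetric peak, giving sub-integer resolution while remaining robust to
the high-copy tail. This assumes single-copy sequence is the most abundant
class on the GRC, which holds for the simulated designs and for the real
chromosomes this models.

## Homology, origin, and divergence polarity

GRC scaffolds are aligned (as 500-bp tiles by the built-in mapper, or with
any external aligner producing PAF) to the other species' GRC and to one
shared reference genome. Bases covered by a direct cross-GRC alignment of at
least 500 bp and 90% identity are `homologous` (both thresholds are
configurable; no published value exists for this call). For the rest, all
genome alignments of *both* species are merged jointly within 10 kbp;
merged regions that received alignments from both species are shared
A-origin footprints, and GRC bases placing into them are
`potentially_homologous` — their absence from the other assembly may simply
be an assembly gap. Everything else is `species_specific`. The three labels
partition every assembly base exactly once; copy-number weighting is applied
only when reporting proportions.

Origin attribution assigns each aligned GRC interval to the chromosome of
its top hit (most matches, ties to the longest block, then lexicographic),
with contributions copy-number weighted; expected contributions are
proportional to chromosome length. Divergence polarity is the signed
difference in best-alignment mismatch proportion against the two species'
genomes; regions with identical divergence are removed, and regions aligning
to only one genome are excluded and counted.

## Gene content

Translated hits (an external tblastx-style table, or the bundled naive
protein-space scan: exact 5-aa word seeding, ungapped X-drop extension —
intended for toy data only) are filtered at e-value 1e-6; overlapping
same-strand intervals merge into exons assigned to the top-bitscore gene.
Completeness divides the proportion of the coding region found on the GRC
by the proportion found in the reference genome, flooring the denominator at
0.75 and capping at 1 (a proportion cannot exceed totality; this matches the
80%/80% → 100% and 5%/5% → 6.7% worked examples). Genes need ≥ 25% of their
coding region in at least one species to be analysed. An exon has a
premature stop when no reading frame on the annotated strand contains an
open stretch of at least 95% of the exon length (boundary inclusive; all
three frames are considered, so only exons no frame rescues are flagged).
Per-gene copy number is the exon-length-weighted mean of harboring
scaffolds' copy numbers. Expression uses FPKM over uniquely mapped
fragments, and the completeness--expression relation is fit as ordinary
least squares of log2(FPKM) on completeness over genes with positive FPKM,
consistent with a log-scaled expression axis.

## Cytogenetic size estimation

Within each pachytene spread cell, the 29 largest measured chromosome
lengths are rank-paired with the 29 largest chromosomes of a reference
karyotype and log(bp) is regressed on log(µm); the measured GRC length is
first divided by 1.5 because the unpaired univalent's chromatin state
inflates its apparent length. Natural logarithms are used (any fixed base
gives identical predictions), and the estimate is invariant to the µm unit
scale. Rank pairing can mis-rank similar-length chromosomes; with a
noiseless power law the estimate is exact (R² = 1). Per-individual sizes
are means over cells; among-individual variation is tested with a one-way
ANOVA over per-cell estimates (3 individuals × 10 cells gives 29 total
degrees of freedom, matching the reported design) followed by Tukey HSD.

## The synthetic-data generator

`sim_config()` / `simulate_grc_dataset()` build a toy study system with full
truth tables: an A-genome; a GRC assembled from A-segments carrying 0.1--2%
substitution divergence; a recent near-identical within-GRC duplication
(byte-identical copies represented by one assembly scaffold with true copy
number > 1 — the collapsed-duplication signature) and an older diverged
duplication (separate paralogous scaffolds); a GRC-restricted tandem
repeat; and gene fragments retaining an exact fraction of their coding
length, optionally with a TAA planted in frame before 95% of a retained
exon. Germline libraries cover each GRC copy at
`grc_singlecopy_ratio × germline_a_depth` (default ratio 0.2, the centre of
the observed 14--23% band; testis libraries are deeper than kidney ones,
30x vs 20x by default).

Reads come from barcoded molecules (default length 50 kb, matching real
linked-read molecules; 10 reads each), one barcode per molecule, molecules
never spanning two source sequences. Molecule windows may overhang the
source and reads falling outside are rejected, keeping the read-start
density exactly uniform — naive clipping concentrates reads near scaffold
ends and inflates depth variance severalfold. Divergence is
substitution-only (no indels), so mismatch-proportion arithmetic downstream
is exact; errors are uniform substitutions at `error_rate` (default 0.001)
with no quality model or GC bias. Everything is a deterministic function of
the configuration, including the seed.

What the generator does *not* emulate — indels and structural variants,
PCR duplicates, GC bias, quality-dependent errors, the high read counts per
molecule of real linked-read libraries (which make real regional coverage
noisier than the toy's), repeats with internal structure, and genuine
assembly artifacts — bounds what passing tests show: they validate the
statistical machinery and its thresholds, not robustness to every artifact
of real libraries, where a production aligner and variant caller should
feed the same module surfaces (PAF and tabular hit inputs are accepted
everywhere).

## Problem sizes used by the test-suite

The bundled checks run at desk scale, chosen so the full suite completes in
minutes: the default demonstration genome is 210 kb with an ~32 kb
(copy-weighted ~52 kb) GRC; the end-to-end identification check uses a
2-Mbp A-genome with a ~200-kbp copy-weighted GRC, three individuals per
tissue and error-free reads; copy-number recovery plants copy numbers
{1, 2, 3, 5} at 10x effective single-copy depth on a 200-kb genome; the
premature-stop rule is cross-checked against a codon-level translation
oracle on 10,000 random exons; and the cytology noise study uses 1,000
seeded replicates. Headline numbers from real ~100x datasets (assembly
sizes, 192 genes, 3.0x/1.6x mean copy numbers) are not reproducible at this
scale and are not targets of the suite; the procedural constants and worked
examples are.

## Known limitations

* The built-in mapper is ungapped and exact-seeded: adequate for the
  substitution-only simulator, not for real indel-bearing reads.
* The pileup caller has no quality or strand-bias model; its ≥ 2-read rule
  is a stand-in for a production caller whose thresholds were not published.
* Homology classification inherits the 10-kbp merge's coarseness: footprints
  closer than the gap are treated as shared ancestry regardless of exact
  overlap.
* The density-mode normalization assumes single-copy sequence dominates the
  zero-soma GRC base set; a GRC that is mostly high-copy would need the
  constant supplied externally.
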