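---
title: "Methods: quantifying chloroplast translation from ribosome profiling"
author: "chlororibo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chloroplast translation from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A plant cell translates three genomes. Ribosome footprints — the ~20–40 nt
mRNA fragments protected by translating ribosomes — can be sequenced in
bulk, and their normalized abundance per gene is a proxy for the molar
rate of protein synthesis. In a C4 seedling leaf, cells along the blade
form a developmental gradient from non-photosynthetic base to
photosynthetic tip, so leaf segments sample successive stages of the
proplastid-to-chloroplast transition. `chlororibo` implements the
computational side of such a study: from aligned Ribo-seq/RNA-seq reads to
per-gene translational output, mRNA abundance and translational
efficiency, P-site calibration, intron splice fractions, compartment
partitioning, developmental clustering, bundle-sheath/mesophyll ratios,
and C-to-U editing quantification — together with a synthetic-read
generator that provides exact ground truth for every stage.

## Reference categories and ingest

Reads are assigned hierarchically to six reference categories in a fixed
priority order: chloroplast tRNA/rRNA, chloroplast genome, mitochondrial
tRNA/rRNA, mitochondrial genome, nuclear tRNA/rRNA, nuclear genome. Each
read belongs to the first category in which it has a primary alignment;
this reproduces a sequential alignment strategy in which unaligned reads
from each step seed the next. Within a category only the primary
alignment is kept — multimapper placement is delegated to the upstream
aligner, which is the only defensible choice when the aligner's own
tie-breaking is not observable downstream.

Ribo-seq reads are restricted to aligned lengths of 18–40 nt (closed
interval), applied after deduplication and before all counting. RNA-seq
libraries built with UMI-containing adapters are deduplicated by the
(reference, start, strand, length, UMI) key; footprint libraries are not
deduplicated, as their randomized adapter bases are consumed upstream and
footprint pileups are legitimately non-uniform.

Malformed SAM records are rejected by the HTSlib-based reader at
conversion time; the pipeline treats an unreadable file as a hard error
rather than silently skipping records.

## P-site calibration from footprint 3' ends

Organellar (70S-type) ribosome footprints have a variable 5' end but a 3'
end at a fixed distance from the decoded codon, so P-sites are inferred
from 3' ends. For each footprint size, the offset `d` — the distance from
the P-site first nucleotide to the footprint 3' end (exclusive
coordinate) — is the modal 3'-end distance from start-codon first
nucleotides in the start-anchored metagene, searched over `[0, 18]` nt.
Choices made here, all surfaced as parameters and recorded in output
metadata:

* search window `[0, 18]` nt: bounded by ribosome geometry; a footprint
  3' end cannot trail the P site by more than the downstream protected
  arm;
* ties broken toward the smaller `d`;
* size classes with fewer than `min_support = 50` start-anchored reads
  inherit the compartment-wide modal offset (flagged `fallback_used`);
  sizes never observed at start codons inherit the best-supported offset
  at assignment time;
* cytosolic (80S) footprints are approximately centered on the P site;
  "centered" is implemented deterministically as `floor(length/2)` nt
  from the 5' end to the P-site first nucleotide.

P-site assignment walks the aligned bases of each read from the relevant
end, so the geometry holds across gapped (spliced) alignments. Assigned
P-sites falling inside a gene's union CDS yield the reading-frame
distribution per compartment and size; frame 0 fraction is the
periodicity summary.

## Counting, RPKM and translational efficiency

Translational output is Ribo-seq RPKM; mRNA level is RNA-seq RPKM;
translational efficiency (TE) is their ratio. RPKM here is reads per kb
of counting region per million reads mapped to *nuclear* coding
sequences. Normalizing to nuclear CDS reads rather than all mapped reads
keeps organellar values on a common scale across samples in which the
organellar fraction itself changes — exactly the situation along a
developmental gradient.

Counting rules:

* a footprint counts toward a gene when its P-site first nucleotide lies
  in the gene's counting region;
* an RNA-seq read counts when at least 50% of its aligned bases lie in
  the region;
* for intron-containing genes the counting region is the **last exon**
  only (for both assays, keeping TE's numerator and denominator on the
  same region): translation can initiate on unspliced precursors and
  terminate within introns, so upstream exons mix mRNA and pre-mRNA
  signal;
* positions shared by two overlapping genes are counted to both, and the
  fraction of such ambiguous assignments is reported rather than
  silently dropped;
* compartment partitioning (cytosol / plastid / mitochondrion) uses all
  CDS-mapped footprints — the full union CDS, not the last-exon
  restriction — because it asks where ribosomes are, not which mRNA
  isoform they sit on. Replicates of a condition are summed before
  fractions are formed, so the three fractions sum to 1 exactly.

mRNA level and TE are reported as not-determined for: two-intron genes
(the fully spliced fraction cannot be confidently inferred when two
introns are independently retained), intron genes failing the splice
consensus gate (below), and genes whose transcript is shorter than
`min_mrna_len = 150` nt — short mRNAs fall below the size cut-off of
standard RNA-seq library preparation and are not represented
quantitatively.

## Spliced fractions by three methods

Group II intron genes require the spliced (translatable) mRNA fraction.
Three estimators are computed per intron:

1. **junction (genomic)** — spliced reads span the exon–exon junction
   with a gap exactly matching the intron and at least `min_overhang = 5`
   aligned nt on each side; unspliced reads span the exon–intron or
   intron–exon boundary contiguously with the same overhang. An
   unspliced molecule exposes *two* countable boundaries where a spliced
   molecule exposes one junction, so the two unspliced boundary counts
   are averaged; without this the estimator is biased low by a factor
   that grows with the unspliced fraction (e.g. 0.67 observed at a true
   0.8).
2. **junction (reference-window)** — the same counting core restricted to
   reads lying within 100 nt of the intron boundaries, emulating
   alignment against spliced/unspliced junction references carrying
   100-nt flanks.
3. **coverage** — `(exon RPKM − intron RPKM) / exon RPKM`, clamped to
   `[0, 1]`, from mean per-base coverage over the gene's exons versus the
   intron.

The consensus gate reports mRNA (and TE) for an intron gene only when all
three estimates are defined and their largest pairwise difference is at
most `tol = 0.10`. No numeric criterion for "similar results" is implied
by the estimators themselves; 0.10 is this package's declared default,
configurable and logged. The `min_overhang` of 5 nt guards against 1–2 nt
spurious junction matches.

## Developmental dynamics

Per-gene profiles across conditions (replicate means) are standardized to
mean 0, standard deviation 1, using the **sample** (n−1) standard
deviation — stated explicitly because z-scores with the population
denominator differ at n = 4 by a factor of 1.155 and would not reproduce
across implementations. Constant or partially not-determined profiles are
excluded with a reason.

Clustering is hierarchical with distance `1 − Pearson r` between gene
profiles and unweighted average linkage (UPGMA). The tree is cut at a
user-supplied `k` (defaults: 4 for output and mRNA, 5 for TE — the
cluster counts this kind of data typically resolves into); no automatic
cut rule is implied, so none is invented. Rows are sorted
lexicographically by gene id before clustering, making the result
invariant to input order.

## RNA editing

At each annotated C-to-U site, aligned read bases are classified on the
coding strand: T edited / C unedited for plus-strand genes; for
minus-strand genes the forward-strand read base is complemented (A
edited / G unedited). Any other base, and any read whose alignment
carries an indel, counts as `n_other` and is excluded from the percent.
A Ribo-seq read is counted whenever the footprint overlaps the site —
not only when the site is within the decoded codons — which is the
simpler rule and the one consistent with footprints reporting the
translated molecule's identity. Sites are reportable when at least two
samples have ≥ 100 informative reads in *both* assays. Start-codon sites
(where editing creates the AUG) are quantified identically; any
preferential translation of edited RNA is a property of the data, not a
special-cased rule.

## The synthetic-read generator

The generator emits pre-aligned, coordinate-sorted SAM (the upstream
aligner is out of scope) over a deterministic ~18 kb three-compartment
miniature genome: 14 plastid genes — among them a four-gene
ATP-synthase-like operon with 1:14:1:3 subunit stoichiometry, a
minus-strand operon mixing photosystem and ribosomal-protein genes, one-
and two-intron genes, a start-codon editing site (ACG precursor) and two
internal editing sites, and a 90-nt gene exercising the short-mRNA
exclusion — plus mitochondrial and nuclear stub genes and one tRNA/rRNA
decoy reference per compartment.

What it emulates, with defaults chosen once as the study conditions:

* footprint-length mixtures: discretized triangular components around
  modes 30/35 nt (plastid, weights 0.55/0.45), 28/36 nt (mitochondrion,
  0.75/0.25), 23/31 nt (cytosol, 0.25/0.75), spread ±2 nt. Only modal
  sizes are biologically established; the triangular shape is a
  smoothness assumption, not a parametric claim.
* P-site geometry: organellar footprints are 3'-anchored with `d = 7` nt
  (the plastid value; the mitochondrial distance is not established
  quantitatively, so the plastid value is reused), cytosolic footprints
  centered.
* 3-nt periodicity: `frame_purity = 0.9` of P-sites in frame 0, the
  remainder shifted ±1 nt.
* an initiation peak: `init_peak = 0.08` extra probability mass on the
  start codon. Strictly uniform codon usage would make the start-anchored
  metagene mode unidentifiable (distances d, d+3, d+6 … equally
  frequent); real footprint data show pronounced initiation peaks, and a
  modest peak makes offset inference exact, as the recovery tests
  require.
* per-gene output weights following subunit stoichiometry, TE
  multipliers spanning 50-fold (the mRNA weight is output/TE), baseline
  compartment shares 60% cytosol / 38% plastid / 2% mitochondrion (a
  young-chloroplast stage), 5% decoy (residual rRNA) share;
* per-intron spliced fractions (0.5–0.8), per-site editing fractions
  (start-codon site: 0.95 in Ribo-seq vs 0.55 in RNA-seq; internal
  sites ~0.95 in both);
* RNA-seq: 75-nt reads, (gene, isoform) sampled proportionally to mRNA
  weight × isoform probability × isoform length so per-base coverage is
  uniform within isoforms, 8-nt UMIs, 10% PCR duplication, 100-nt
  transcript flanks beyond the CDS;
* condition overrides (leaf segments, BS/M) apply per-gene multipliers
  RPKM-faithfully: a gene's k-fold output change rescales its
  compartment's read share via the weighted-sum change rather than
  diluting its neighbors, so configured fold-changes survive
  normalization to nuclear CDS reads. The `compartment_shares` are
  therefore baseline shares at the config's reference weights.
* replicates perturb per-gene weights by a lognormal factor
  (sdlog 0.05) keyed to (seed, replicate), shared between the two assays
  of a replicate.

What it does **not** emulate: sequencing errors (beyond editing-site base
identity), indels, soft-clipping, multimapping ambiguity, ribosome
pausing and codon-level dwell-time variation, rRNA contamination
structure beyond a flat decoy share, UTR transcription beyond the fixed
flank, and library-preparation biases. Passing recovery tests therefore
demonstrates the correctness of the estimators under the model's
assumptions, not robustness to every artifact of real libraries.

## Numerical and interface choices

* Internal coordinates are 0-based half-open; GFF3 I/O converts at the
  boundary. Compartment and category membership of each reference
  sequence come from configuration, never from name matching.
* The 3'-end coordinate convention is exclusive (one past the terminal
  base in transcript orientation), so `P-site = 3'end − d` holds as
  integer arithmetic on both strands.
* TE is defined up to a dataset-wide constant (it inherits the ratio of
  the two assays' sequencing depths through the shared nuclear-CDS
  denominator); recovery tests compare TE after normalizing both sides
  by their geometric mean.
* Degenerate inputs: zero requested reads yield a header-only SAM and a
  complete truth table; a compartment with no start-anchored reads warns
  and fails offset inference with an explicit error; a zero nuclear-CDS
  total makes RPKM undefined and is an error, not an NaN.
* Pipeline configuration is an R object (`pipeline_config()`); runs are
  orchestrated by `run_pipeline()`, and all outputs are TSVs headed by
  the package version, a configuration hash and the seed, so identical
  configurations produce byte-identical outputs. The package's interface
  is its functions; a shell wrapper would add nothing over
  `Rscript -e`.

## Problem sizes in the test suite

The test suite simulates 1.5×10^4–10^6 reads per stage: offset recovery
at 10^5 reads, TE recovery at 10^6 Ribo + 10^6 RNA reads, splice
estimators at 6×10^5 RNA reads, editing at 5×10^5 footprints, and the
end-to-end pipeline at 1.5×10^4 reads per sample over multiple
conditions and replicates. These sizes give the recovery checks enough
support that their 3-SD binomial bands are a few percentage points wide
while keeping the whole suite to a few minutes on one CPU.

## Known limitations

* Splice-fraction estimation assumes uniform coverage within isoforms;
  strong 3' bias in real libraries would shift the coverage-based
  estimator away from the junction-based ones (the consensus gate would
  then correctly withhold those genes).
* The last-exon rule discards signal for intron genes, inflating
  variance for short last exons.
* Editing quantification trusts aligned bases; alignment of heavily
  edited reads depends on the upstream aligner's mismatch tolerance,
  which is outside this package's control.
* The BS/M mean TE ratio is a geometric mean over genes with defined
  ratios; genes absent in one cell type drop out rather than being
  imputed.
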