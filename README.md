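# chlororibo

Ribosome profiling (Ribo-seq) and RNA-seq analysis for the three genetic
compartments of a plant cell — plastid, mitochondrion and
nucleus/cytosol — oriented toward studies of chloroplast translation
along developmental gradients such as the proplastid-to-chloroplast
transition of a C4 seedling leaf. It is written for researchers who have
aligned footprint and RNA-seq reads in hand and want per-gene measures of
translation, together with a fully specified synthetic-data generator to
validate every step against ground truth.

## What it computes

For each gene *g* and sample:

- **translational output** — Ribo-seq RPKM:
  `output_g = count_g / (L_g/10^3 × N_nuc/10^6)`, where `count_g` is the
  number of footprints whose P-site first nucleotide falls in the gene's
  counting region, `L_g` is that region's length, and `N_nuc` is the
  number of reads mapped to *nuclear* coding sequences. Normalizing to
  nuclear CDS reads keeps organellar values comparable across samples
  whose organellar content changes.
- **mRNA level** — RNA-seq RPKM on the same region (reads counted when
  ≥ 50% of aligned bases fall inside).
- **translational efficiency** — `TE_g = output_g / mRNA_g`.

For intron-containing genes both assays are counted on the **last exon**
only, and mRNA/TE are reported only when three independent estimators of
the intron's spliced fraction (junction reads in genomic alignments,
junction reads in a 100-nt reference window, exon-vs-intron coverage)
agree within a tolerance; two-intron genes are always withheld.

Around this core: hierarchical six-category read assignment
(plastid tRNA/rRNA → plastid genome → mito tRNA/rRNA → mito genome →
nuclear tRNA/rRNA → nuclear genome), UMI deduplication, 18–40 nt
footprint length bounds, metagene analysis at start/stop codons,
footprint-size-dependent P-site offsets inferred from footprint **3'
ends** (organellar ribosomes protect a constant 3' arm; cytosolic
footprints are centered), 3-nt periodicity, compartment partitioning of
translation, stoichiometry-relative output ratios within protein
complexes, bundle-sheath/mesophyll ratios, UPGMA clustering (Pearson
correlation distance) of standardized developmental profiles, and
per-site C-to-U editing quantification with a 100-read/2-sample
reporting filter.

The methods vignette (`vignettes/chlororibo-methods.Rmd`) documents the
model, every tunable parameter, and the generator's assumptions.

## Worked example

Simulate a sample over the built-in miniature three-compartment genome,
calibrate P-sites, and quantify:

```r
library(chlororibo)

ann <- sim_genome()
#> GenomeAnnotation: 6 sequences, 20 genes, 2 transcription units, 3 editing sites
#>   genes per compartment: mitochondrion=2, nucleus=4, plastid=14

cfg <- sim_config(ann, seed = 1, n_ribo_reads = 2e5, n_rna_reads = 2e5)
rb <- simulate_riboseq(ann, cfg)
rn <- simulate_rnaseq(ann, cfg)

offsets <- rbind(
  infer_offsets(metagene_profile(rb$reads, ann, "plastid")),
  infer_offsets(metagene_profile(rb$reads, ann, "mitochondrion")),
  centered_offsets())
head(offsets, 4)
#>    compartment  size     d support fallback_used   rule
#> 1:     plastid    28     7     456         FALSE 3prime
#> 2:     plastid    29     7     923         FALSE 3prime
#> 3:     plastid    30     7    1376         FALSE 3prime
#> 4:     plastid    31     7     847         FALSE 3prime

reads <- assign_psites(rb$reads, offsets, ann)
compartment_partition(count_cds_reads(reads, ann, "ribo"))
#>      compartment n_reads   fraction
#> 1:       cytosol  113810 0.59879200
#> 2:       plastid   72367 0.38074669
#> 3: mitochondrion    3889 0.02046131

gate <- consensus_splice_filter(splice_estimates(rn$reads, ann), ann)
expr <- build_expression(count_cds_reads(reads, ann, "ribo"),
                         count_cds_reads(dedup_umi(rn$reads), ann, "rna"),
                         ann, splice_gate = gate)
expr[gene_id %in% c("atpI", "atpH", "psbA", "atpF", "ycf3")]
#>    gene_id compartment output_rpkm mrna_rpkm   nd_reason        te
#> 1:    atpF     plastid   18793.506  38413.46        none 0.4892427
#> 2:    atpH     plastid  252774.736  60045.48        none 4.2097213
#> 3:    atpI     plastid   20053.230  44963.83        none 0.4459858
#> 4:    psbA     plastid  415077.761 186877.91        none 2.2211173
#> 5:    ycf3     plastid    5330.522        NA two_introns        NA
```

Reading the output: the inferred offset `d = 7` says plastid footprint 3'
ends sit 7 nt downstream of the P-site first nucleotide regardless of
footprint size (the generator's geometry, recovered from the data
alone). The partition shows ~60/38/2% of CDS-mapped footprints in
cytosol/plastid/mitochondrion — the configured compartment shares. In the
expression table, `atpH` — co-transcribed with `atpI` and similar in
mRNA level — has ~13× its translational output, carried by an ~9× higher
translational efficiency, while the two-intron gene `ycf3` has its mRNA
and TE withheld as not-determined.

Multi-sample studies are orchestrated by `simulate_dataset()` (writes
SAMs, a sample sheet and truth tables) and `run_pipeline()`
(`pipeline_config()` holds every threshold), which writes
`offsets.tsv`, `metagene.tsv`, `splice.tsv`, `expression.tsv`,
`partition.tsv`, `clusters.tsv`, `editing.tsv` and Newick dendrograms,
each headed by the package version, a configuration hash and the seed.

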