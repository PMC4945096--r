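# CDS-restricted counting, RPKM against the nuclear-CDS denominator,
# translational efficiency, compartment partitioning, stoichiometry-
# relative output ratios, and bundle-sheath/mesophyll ratios.
#
# Translational output is Ribo-seq RPKM and mRNA level is RNA-seq RPKM,
# both normalized per kb of counting region and per million reads mapped
# to nuclear coding sequences, which keeps organellar values comparable
# across samples whose organellar content changes developmentally. For
# intron-containing genes both assays are counted on the last exon only,
# since translation can initiate on unspliced precursors and terminate
# within introns; mRNA levels of intron genes are reported only when the
# splice-consensus gate passes.

#' Count reads in CDS counting regions
#'
#' Ribo-seq reads are counted to a gene when their P-site first nucleotide
#' lies in the gene's counting region (union CDS; for intron-containing
#' genes the last exon only). RNA-seq reads are counted when at least half
#' of their aligned bases lie within the counting region. A read falling
#' in the counting regions of two overlapping genes is counted to both and
#' flagged; the flagged fraction is reported. The nuclear-CDS total -- the
#' RPKM denominator -- is computed with the same rule over nuclear genes.
#'
#' @param reads Read `data.table`; Ribo-seq reads must carry a `psite`
#'   column ([assign_psites()]), RNA-seq reads should be deduplicated.
#' @param ann A `GenomeAnnotation`.
#' @param assay `"ribo"` or `"rna"`.
#' @return A `CountTable`: list with `counts` (gene_id, compartment,
#'   count, counting_region, region_length), `nuclear_cds_total`,
#'   `compartment_reads` (distinct CDS-mapped reads per compartment),
#'   `flagged_fraction`, `assay`, `sample_id`.
#' @export
count_cds_reads <- function(reads, ann, assay) {
  stopifnot(assay %in% c("ribo", "rna"))
  regions <- counting_regions(ann, region = "auto")
  full_regions <- counting_regions(ann, region = "full_cds")
  geneinfo <- unique(regions[, .(gene_id, compartment, counting_region,
                                 region_length)])
  hit_regions <- function(reg) {
    if (assay == "ribo") {
      stopifnot("psite" %in% names(reads))
      rr <- reads[!is.na(psite)]
      if (nrow(rr) == 0L)
        return(data.table::data.table(i = integer(),
                                      gene_id = character()))
      pts <- data.table::data.table(
        i = seq_len(nrow(rr)), seq_id = rr$seq_id, strand = rr$strand,
        p = rr$psite, p2 = rr$psite)
      reg[pts, on = .(seq_id, strand, start <= p, end > p2),
          nomatch = NULL, .(i, gene_id)]
    } else {
      rr <- reads
      bl <- read_blocks(rr)
      if (nrow(bl) == 0L)
        return(data.table::data.table(i = integer(),
                                      gene_id = character()))
      bl[, strand := rr$strand[ri]]
      bl[, seq_id := rr$seq_id[ri]]
      ov <- reg[bl, on = .(seq_id, strand, start < e, end > s),
                nomatch = NULL,
                .(ri, gene_id, ovlen = pmin(x.end, i.e) -
                    pmax(x.start, i.s))]
      if (nrow(ov) == 0L)
        return(data.table::data.table(i = integer(),
                                      gene_id = character()))
      ov <- ov[, .(ovlen = sum(ovlen)), by = .(ri, gene_id)]
      ov[, frac := ovlen / rr$width[ri]]
      ov[frac >= 0.5, .(i = ri, gene_id)]
    }
  }
  hits <- unique(hit_regions(regions))
  # compartment partitioning uses all CDS-mapped reads, not the
  # last-exon-restricted counting regions
  full_hits <- unique(hit_regions(full_regions))
  counts <- hits[, .(count = .N), by = gene_id]
  tab <- merge(geneinfo, counts, by = "gene_id", all.x = TRUE)
  tab[is.na(count), count := 0L]

  n_multi <- if (nrow(hits)) sum(duplicated(hits$i)) else 0L
  n_counted <- length(unique(hits$i))
  flagged_fraction <- if (n_counted > 0L) n_multi / n_counted else 0

  comp_reads <- if (nrow(full_hits) == 0L)
    stats::setNames(integer(3), c("plastid", "mitochondrion", "nucleus"))
  else {
    hh <- unique(merge(full_hits,
      data.table::as.data.table(geneinfo[, .(gene_id, compartment)]),
      by = "gene_id")[, .(i, compartment)])
    tt <- table(factor(hh$compartment,
                       levels = c("plastid", "mitochondrion", "nucleus")))
    stats::setNames(as.integer(tt), names(tt))
  }
  nuclear_total <- sum(tab$count[tab$compartment == "nucleus"])

  structure(list(
    counts = tab[, .(gene_id, compartment, count, counting_region,
                     region_length)],
    nuclear_cds_total = nuclear_total,
    compartment_reads = comp_reads,
    flagged_fraction = flagged_fraction,
    assay = assay,
    sample_id = if (nrow(reads)) reads$sample_id[1L] else NA_character_),
    class = "CountTable")
}

#' RPKM from a count table
#'
#' rpkm = count / (region length in kb x nuclear-CDS-mapped reads / 1e6).
#'
#' @param ct A `CountTable`.
#' @return data.table gene_id, compartment, count, region_length, rpkm.
#' @export
compute_rpkm <- function(ct) {
  stopifnot(inherits(ct, "CountTable"))
  if (ct$nuclear_cds_total <= 0)
    stop("nuclear CDS total is zero; RPKM denominator undefined")
  out <- data.table::copy(ct$counts)
  out[, rpkm := count / ((region_length / 1e3) *
                           (ct$nuclear_cds_total / 1e6))]
  out[]
}

#' Per-sample expression table: output, mRNA and translational efficiency
#'
#' Combines a Ribo-seq and an RNA-seq `CountTable` of the same biological
#' sample. mRNA level (and hence TE) is set to not-determined for genes
#' failing the splice-consensus gate, for two-intron genes, and for genes
#' whose transcript is shorter than `min_mrna_len` (short mRNAs fall below
#' the size cut-off of typical RNA-seq library preparation and are not
#' represented quantitatively).
#'
#' @param ribo_ct,rna_ct `CountTable`s (assays "ribo" and "rna").
#' @param ann A `GenomeAnnotation`.
#' @param splice_gate Output of [consensus_splice_filter()], or NULL to
#'   exclude every intron-containing gene's mRNA.
#' @param min_mrna_len Minimum transcript length (nt) for a quantitative
#'   mRNA estimate.
#' @return data.table gene_id, compartment, output_rpkm, mrna_rpkm, te,
#'   nd_reason.
#' @export
build_expression <- function(ribo_ct, rna_ct, ann, splice_gate = NULL,
                             min_mrna_len = 150L) {
  stopifnot(ribo_ct$assay == "ribo", rna_ct$assay == "rna")
  out <- compute_rpkm(ribo_ct)[, .(gene_id, compartment,
                                   output_rpkm = rpkm)]
  mr <- compute_rpkm(rna_ct)[, .(gene_id, mrna_rpkm = rpkm)]
  out <- merge(out, mr, by = "gene_id", all.x = TRUE, sort = FALSE)
  gi <- ann$genes
  ucds <- union_cds(ann)
  tx_len <- vapply(out$gene_id, function(g) ucds[[g]]$length, numeric(1))
  ic <- gi$intron_count[match(out$gene_id, gi$gene_id)]
  out[, nd_reason := "none"]
  out[tx_len < min_mrna_len, nd_reason := "short_mrna"]
  if (is.null(splice_gate)) {
    out[ic > 0L, nd_reason := "splice_inconsistent"]
  } else {
    for (j in which(ic > 0L)) {
      row <- splice_gate[splice_gate$gene_id == out$gene_id[j], ]
      if (nrow(row) == 1L && !row$included)
        out$nd_reason[j] <- if (row$reason == "two_introns") "two_introns"
                            else "splice_inconsistent"
    }
  }
  out[ic >= 2L, nd_reason := "two_introns"]
  out[nd_reason != "none", mrna_rpkm := NA_real_]
  translational_efficiency(out)
}

#' Fill translational efficiency into an expression table
#'
#' te = output_rpkm / mrna_rpkm; not-determined (NA) where the mRNA level
#' is not-determined or zero.
#'
#' @param expr data.table with output_rpkm and mrna_rpkm columns.
#' @return The table with a `te` column.
#' @export
translational_efficiency <- function(expr) {
  expr[, te := ifelse(!is.na(mrna_rpkm) & mrna_rpkm > 0,
                      output_rpkm / mrna_rpkm, NA_real_)]
  expr[]
}

#' Partition of translation among the three genetic compartments
#'
#' Fractions of CDS-mapped ribosome footprints attributed to the cytosol
#' (nuclear genes), plastids and mitochondria; replicate count tables of a
#' condition are summed before the fractions are formed, so the fractions
#' sum to 1 exactly.
#'
#' @param cts A `CountTable` or list of `CountTable`s (assay "ribo").
#' @return data.table compartment (cytosol, plastid, mitochondrion),
#'   n_reads, fraction.
#' @export
compartment_partition <- function(cts) {
  if (inherits(cts, "CountTable")) cts <- list(cts)
  stopifnot(all(vapply(cts, function(x) x$assay == "ribo", logical(1))))
  tot <- Reduce(`+`, lapply(cts, `[[`, "compartment_reads"))
  n <- sum(tot)
  if (n == 0) stop("no CDS-mapped footprints to partition")
  lab <- c(nucleus = "cytosol", plastid = "plastid",
           mitochondrion = "mitochondrion")
  out <- data.table::data.table(
    compartment = unname(lab[names(tot)]),
    n_reads = as.integer(tot),
    fraction = as.numeric(tot) / n)
  out[order(match(compartment, c("cytosol", "plastid", "mitochondrion")))]
}

#' Output ratios of a gene set relative to a reference gene
#'
#' For each gene of a complex, the mean translational output (Ribo-seq
#' RPKM) over the chosen conditions is divided by that of the reference
#' gene; annotated subunit stoichiometries are attached for comparison.
#'
#' @param expr Long expression table with columns gene_id, condition,
#'   output_rpkm (replicates are averaged).
#' @param genes Genes of the complex.
#' @param reference Reference gene (ratio 1 by construction).
#' @param conditions Conditions averaged over.
#' @param ann A `GenomeAnnotation` (for stoichiometries).
#' @return data.table gene_id, mean_output, output_ratio, stoichiometry.
#' @export
output_ratio <- function(expr, genes, reference, conditions, ann) {
  stopifnot(length(conditions) > 0, reference %in% genes)
  ee <- expr[gene_id %in% genes & condition %in% conditions]
  if (nrow(ee) == 0L) stop("no expression rows for the requested subset")
  mm <- ee[, .(mean_output = mean(output_rpkm)), by = gene_id]
  ref <- mm$mean_output[mm$gene_id == reference]
  if (length(ref) != 1L || ref <= 0)
    stop("reference gene has no positive mean output")
  mm[, output_ratio := mean_output / ref]
  mm[, stoichiometry :=
       ann$genes$stoichiometry[match(gene_id, ann$genes$gene_id)]]
  mm[match(genes, gene_id)]
}

#' Bundle-sheath / mesophyll expression ratios
#'
#' Per-gene BS/M ratios of mean translational output, mRNA level and TE
#' across replicates, plus the global mean TE ratio (geometric mean over
#' genes with both values defined). Ratios with a zero or not-determined
#' denominator are not-determined.
#'
#' @param expr_bs,expr_m Long expression tables (gene_id, output_rpkm,
#'   mrna_rpkm, te; replicate rows averaged per gene).
#' @return List with `table` (gene_id, output_ratio, mrna_ratio,
#'   te_ratio) and `mean_te_ratio`.
#' @export
celltype_ratio <- function(expr_bs, expr_m) {
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  agg <- function(e) e[, .(output = mean_na(output_rpkm),
                           mrna = mean_na(mrna_rpkm),
                           te = mean_na(te)), by = gene_id]
  bs <- agg(expr_bs); m <- agg(expr_m)
  tab <- merge(bs, m, by = "gene_id", suffixes = c("_bs", "_m"))
  ratio <- function(a, b) ifelse(!is.na(a) & !is.na(b) & b > 0, a / b,
                                 NA_real_)
  tab[, output_ratio := ratio(output_bs, output_m)]
  tab[, mrna_ratio := ratio(mrna_bs, mrna_m)]
  tab[, te_ratio := ratio(te_bs, te_m)]
  ok <- !is.na(tab$te_ratio) & tab$te_ratio > 0
  mean_te <- if (any(ok)) exp(mean(log(tab$te_ratio[ok]))) else NA_real_
  list(table = tab[, .(gene_id, output_ratio, mrna_ratio, te_ratio)],
       mean_te_ratio = mean_te)
}
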