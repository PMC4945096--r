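# Per-intron spliced-fraction estimation by three methods, and the
# cross-method consensus gate.
#
# Unspliced precursors of group II intron genes make up a substantial part
# of the organellar RNA pool, so the abundance of translatable (spliced)
# mRNA is inferred per intron by: (i) counting junction-spanning reads in
# genomic alignments, (ii) the same count restricted to a junction-local
# window (emulating alignment to spliced/unspliced junction references
# with 100-nt flanks), and (iii) comparing exon to intron coverage.
# mRNA-level results are reported only for genes where the methods agree.

# genomic interval of intron k (transcript order) of a gene
intron_interval <- function(ann, gene_id, intron_index) {
  iv <- union_cds(ann)[[gene_id]]$intervals
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (intron_index < 1L || intron_index > nrow(iv) - 1L)
    stop("gene ", gene_id, " has no intron ", intron_index)
  if (g$strand == "+")
    list(start = iv$end[intron_index], end = iv$start[intron_index + 1L])
  else
    list(start = iv$end[intron_index + 1L], end = iv$start[intron_index])
}

# classify reads of one gene's intron into spliced / unspliced junction
# evidence; window (if finite) restricts to reads lying within `window` nt
# of the intron boundaries, emulating junction-reference alignment
junction_counts <- function(reads, ann, gene_id, intron_index,
                            min_overhang = 5L, window = Inf) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  ii <- intron_interval(ann, gene_id, intron_index)
  rr <- reads[seq_id == g$seq_id & strand == g$strand]
  if (nrow(rr) == 0L) return(list(n_spliced = 0L, n_unspliced = 0L))
  bl <- read_blocks(rr)
  ag <- bl[, .(smin = min(s), emax = max(e)), by = ri]
  if (is.finite(window)) {
    ok <- ag[smin >= ii$start - window & emax <= ii$end + window, ri]
    bl <- bl[ri %in% ok]
    if (nrow(bl) == 0L) return(list(n_spliced = 0L, n_unspliced = 0L))
  }
  # spliced: consecutive blocks whose gap is exactly the intron, with
  # >= min_overhang aligned nt on each side
  data.table::setorder(bl, ri, s)
  bl[, nxt_s := data.table::shift(s, type = "lead"), by = ri]
  bl[, w := e - s]
  bl[, nxt_w := data.table::shift(w, type = "lead"), by = ri]
  spl <- bl[e == ii$start & nxt_s == ii$end &
            w >= min_overhang & nxt_w >= min_overhang, unique(ri)]
  # unspliced: one contiguous block covering a boundary with the same
  # overhang on both sides. An unspliced molecule exposes two countable
  # boundaries where a spliced molecule exposes one junction, so the two
  # boundary counts are averaged to keep both classes on the same
  # per-junction footing.
  un1 <- bl[s <= ii$start - min_overhang & e >= ii$start + min_overhang,
            unique(ri)]
  un2 <- bl[s <= ii$end - min_overhang & e >= ii$end + min_overhang,
            unique(ri)]
  un1 <- setdiff(un1, spl); un2 <- setdiff(un2, spl)
  list(n_spliced = length(spl),
       n_unspliced = (length(un1) + length(un2)) / 2)
}

#' Spliced fraction from junction-spanning reads
#'
#' A read is spliced evidence if it spans the exon-exon junction (a gapped
#' alignment whose gap is exactly the intron) with at least `min_overhang`
#' aligned nt on both sides, and unspliced evidence if it spans the
#' exon-intron or intron-exon boundary contiguously with the same
#' overhang; the two unspliced boundary counts are averaged, since an
#' unspliced molecule exposes two countable boundaries where a spliced
#' molecule exposes one junction. The fraction is
#' spliced / (spliced + unspliced), undefined (NA) when the denominator
#' is zero.
#'
#' @param reads RNA-seq read `data.table` (deduplicated).
#' @param ann A `GenomeAnnotation`.
#' @param gene_id,intron_index Intron addressed in transcript order.
#' @param min_overhang Minimum aligned nt on each side of a boundary.
#' @param window If finite, only reads lying within `window` nt of the
#'   intron boundaries are counted (junction-reference emulation).
#' @return List with n_spliced, n_unspliced, fraction.
#' @export
splice_fraction_junction <- function(reads, ann, gene_id, intron_index,
                                     min_overhang = 5L, window = Inf) {
  jc <- junction_counts(reads, ann, gene_id, intron_index, min_overhang,
                        window)
  denom <- jc$n_spliced + jc$n_unspliced
  list(n_spliced = jc$n_spliced, n_unspliced = jc$n_unspliced,
       fraction = if (denom > 0L) jc$n_spliced / denom else NA_real_)
}

#' Spliced fraction from exon versus intron coverage
#'
#' Closed form: (exon RPKM - intron RPKM) / exon RPKM, clamped to
#' `[0, 1]`; undefined when exon RPKM is zero. Any per-base coverage
#' measure proportional to RPKM may be supplied.
#'
#' @param exon_rpkm,intron_rpkm Non-negative coverage summaries.
#' @return Fraction in `[0, 1]` (attribute `"clamped"` records whether
#'   clamping occurred), or NA.
#' @export
splice_fraction_coverage <- function(exon_rpkm, intron_rpkm) {
  stopifnot(exon_rpkm >= 0, intron_rpkm >= 0)
  if (exon_rpkm == 0) return(NA_real_)
  f <- (exon_rpkm - intron_rpkm) / exon_rpkm
  clamped <- f < 0 || f > 1
  f <- min(max(f, 0), 1)
  attr(f, "clamped") <- clamped
  f
}

# mean per-base read coverage of a genomic interval
interval_coverage <- function(bl, start, end) {
  ov <- bl[e > start & s < end]
  if (nrow(ov) == 0L) return(0)
  sum(pmin(ov$e, end) - pmax(ov$s, start)) / (end - start)
}

#' Coverage-based spliced fraction of one intron
#'
#' Mean per-base coverage over the gene's (union CDS) exons versus over
#' the intron, combined with [splice_fraction_coverage()].
#'
#' @inheritParams splice_fraction_junction
#' @return List with exon_cov, intron_cov, fraction.
#' @export
splice_coverage_estimate <- function(reads, ann, gene_id, intron_index) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  ii <- intron_interval(ann, gene_id, intron_index)
  iv <- union_cds(ann)[[gene_id]]$intervals
  rr <- reads[seq_id == g$seq_id & strand == g$strand]
  bl <- read_blocks(rr)
  exon_cov <- sum(vapply(seq_len(nrow(iv)), function(b)
    interval_coverage(bl, iv$start[b], iv$end[b]) *
      (iv$end[b] - iv$start[b]), numeric(1))) / sum(iv$end - iv$start)
  intron_cov <- interval_coverage(bl, ii$start, ii$end)
  list(exon_cov = exon_cov, intron_cov = intron_cov,
       fraction = splice_fraction_coverage(exon_cov, intron_cov))
}

#' Spliced-fraction estimates for every intron, by all three methods
#'
#' @param reads Deduplicated RNA-seq read `data.table`.
#' @param ann A `GenomeAnnotation`.
#' @param min_overhang Junction overhang (nt).
#' @param junction_window Window for the junction-reference method (nt on
#'   each side of each junction).
#' @return `SpliceEstimate` data.table: gene_id, intron_index,
#'   n_spliced, n_unspliced, est_junction_genomic,
#'   est_junction_reference, est_coverage, consistent (NA until a
#'   tolerance is applied by [consensus_splice_filter()]).
#' @export
splice_estimates <- function(reads, ann, min_overhang = 5L,
                             junction_window = 100L) {
  genes <- ann$genes[ann$genes$intron_count > 0L, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    for (k in seq_len(genes$intron_count[i])) {
      m1 <- splice_fraction_junction(reads, ann, gid, k, min_overhang)
      m2 <- splice_fraction_junction(reads, ann, gid, k, min_overhang,
                                     window = junction_window)
      m3 <- splice_coverage_estimate(reads, ann, gid, k)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = gid, intron_index = k,
        n_spliced = m1$n_spliced, n_unspliced = m1$n_unspliced,
        est_junction_genomic = m1$fraction,
        est_junction_reference = m2$fraction,
        est_coverage = as.numeric(m3$fraction),
        consistent = NA)
    }
  }
  if (!length(rows))
    return(data.table::data.table(
      gene_id = character(), intron_index = integer(),
      n_spliced = integer(), n_unspliced = integer(),
      est_junction_genomic = numeric(), est_junction_reference = numeric(),
      est_coverage = numeric(), consistent = logical()))
  data.table::rbindlist(rows)
}

#' Consensus gate for reportable mRNA levels of intron genes
#'
#' A gene's spliced-mRNA abundance is considered reliable -- and hence its
#' mRNA level and translational efficiency reportable -- only when it has
#' at most one intron, all three estimators are defined for each of its
#' introns, and the largest pairwise difference between estimators is at
#' most `tol`. Two-intron genes are always excluded: the fully spliced
#' fraction cannot be confidently inferred when two introns are
#' independently retained.
#'
#' @param estimates Output of [splice_estimates()].
#' @param ann A `GenomeAnnotation`.
#' @param tol Maximum pairwise absolute difference between estimators.
#' @return data.table gene_id, included, reason
#'   (none / two_introns / undefined_estimate / inconsistent); also
#'   updates the `consistent` column of a copy of `estimates`, returned
#'   as attribute `"estimates"`.
#' @export
consensus_splice_filter <- function(estimates, ann, tol = 0.10) {
  genes <- ann$genes[ann$genes$intron_count > 0L, , drop = FALSE]
  est <- data.table::copy(estimates)
  rows <- lapply(genes$gene_id, function(gid) {
    ic <- genes$intron_count[genes$gene_id == gid]
    if (ic >= 2L)
      return(data.table::data.table(gene_id = gid, included = FALSE,
                                    reason = "two_introns"))
    ee <- est[gene_id == gid]
    vals <- c(ee$est_junction_genomic, ee$est_junction_reference,
              ee$est_coverage)
    if (anyNA(vals))
      return(data.table::data.table(gene_id = gid, included = FALSE,
                                    reason = "undefined_estimate"))
    spread <- max(vals) - min(vals)
    est[gene_id == gid, consistent := spread <= tol]
    data.table::data.table(gene_id = gid, included = spread <= tol,
                           reason = if (spread <= tol) "none"
                                    else "inconsistent")
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "estimates", est)
  out
}
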