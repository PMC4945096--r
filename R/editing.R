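# Quantification of C-to-U RNA editing from read base calls, and the
# coverage filter for reportable sites.

#' Quantify edited versus unedited reads at editing sites
#'
#' For each editing site and each read overlapping it, the aligned read
#' base at the site is classified on the coding strand: for a plus-strand
#' gene, read base T is edited and C unedited; for a minus-strand gene the
#' coding-strand base is the complement of the forward-strand read base
#' (A edited, G unedited). Any other base, or a read whose alignment
#' carries an insertion or deletion, contributes to `n_other`. Ribo-seq
#' reads are counted whenever the footprint overlaps the site.
#'
#' @param reads Read `data.table` (one sample, one assay; `sample_id` and
#'   `assay` columns are carried through).
#' @param ann A `GenomeAnnotation` with editing sites.
#' @param sites Optional subset of `ann$editing_sites`.
#' @return `EditingQuant` data.table: site_id, sample_id, assay,
#'   n_edited, n_unedited, n_other, percent_edited.
#' @export
quantify_editing <- function(reads, ann, sites = NULL) {
  if (is.null(sites)) sites <- ann$editing_sites
  if (is.null(sites) || nrow(sites) == 0L)
    return(data.table::data.table(
      site_id = character(), sample_id = character(), assay = character(),
      n_edited = integer(), n_unedited = integer(), n_other = integer(),
      percent_edited = numeric()))
  sample_id <- if (nrow(reads)) reads$sample_id[1L] else NA_character_
  assay <- if (nrow(reads)) reads$assay[1L] else NA_character_
  bl <- if (nrow(reads)) read_blocks(reads) else
    data.table::data.table(ri = integer(), s = integer(), e = integer())
  if (nrow(bl)) {
    data.table::setorder(bl, ri, s)
    bl[, w := e - s]
    bl[, qoff := cumsum(w) - w, by = ri]
    bl[, seq_id := reads$seq_id[ri]]
    bl[, strand := reads$strand[ri]]
    bl[, has_indel := grepl("[ID]", reads$cigar[ri])]
  }
  rows <- lapply(seq_len(nrow(sites)), function(si) {
    p <- sites$pos_0based[si]
    hit <- bl[seq_id == sites$seq_id[si] & strand == sites$strand[si] &
              s <= p & e > p]
    n_ed <- n_un <- n_ot <- 0L
    if (nrow(hit)) {
      at <- hit$qoff + (p - hit$s) + 1L
      base <- substr(reads$seq[hit$ri], at, at)
      base[hit$has_indel] <- "N"   # indel across/near the site: exclude
      if (sites$strand[si] == "+") {
        n_ed <- sum(base == "T"); n_un <- sum(base == "C")
      } else {
        n_ed <- sum(base == "A"); n_un <- sum(base == "G")
      }
      n_ot <- nrow(hit) - n_ed - n_un
    }
    data.table::data.table(
      site_id = sites$site_id[si], sample_id = sample_id, assay = assay,
      n_edited = n_ed, n_unedited = n_un, n_other = n_ot,
      percent_edited = if (n_ed + n_un > 0L) 100 * n_ed / (n_ed + n_un)
                       else NA_real_)
  })
  data.table::rbindlist(rows)
}

#' Coverage filter for reportable editing sites
#'
#' A site is reportable when at least `min_samples` samples have
#' `min_reads` or more informative reads (edited + unedited) in BOTH
#' assays.
#'
#' @param quants Row-bound [quantify_editing()] output across samples and
#'   assays; sample pairing is by the `sample_id` column with the assay
#'   suffix removed, or via `pairing`.
#' @param min_reads Minimum informative reads per assay per sample.
#' @param min_samples Minimum number of qualifying samples.
#' @param pairing Optional data.frame (sample_id, pair_id) mapping each
#'   sample to its biological sample; by default sample_ids are matched
#'   across assays after stripping a leading "ribo_"/"rna_" prefix or
#'   trailing "_ribo"/"_rna" suffix.
#' @return data.table site_id, n_qualifying_samples, included.
#' @export
filter_editing <- function(quants, min_reads = 100L, min_samples = 2L,
                           pairing = NULL) {
  if (nrow(quants) == 0L)
    return(data.table::data.table(site_id = character(),
                                  n_qualifying_samples = integer(),
                                  included = logical()))
  q <- data.table::copy(quants)
  if (is.null(pairing)) {
    q[, pair_id := sub("^(ribo|rna)_", "",
                       sub("_(ribo|rna)$", "", sample_id))]
  } else {
    q[, pair_id := pairing$pair_id[match(sample_id, pairing$sample_id)]]
  }
  q[, informative := n_edited + n_unedited]
  per <- q[, .(ok_ribo = any(assay == "ribo" & informative >= min_reads),
               ok_rna = any(assay == "rna" & informative >= min_reads)),
           by = .(site_id, pair_id)]
  out <- per[, .(n_qualifying_samples = sum(ok_ribo & ok_rna)),
             by = site_id]
  out[, included := n_qualifying_samples >= min_samples]
  out[]
}
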