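# Reading SAM/BAM, hierarchical category assignment, length bounds, and
# UMI deduplication.

#' Read alignments from SAM/BAM into a read table
#'
#' Secondary, supplementary and unmapped records are dropped. Each read's
#' hierarchical category is taken from the reference sequence it aligns to
#' (via the annotation's seq_id -> category map) unless `category` is
#' given, in which case the whole file is treated as alignments against
#' that category's reference set (file-of-origin semantics).
#'
#' @param path A SAM or BAM file.
#' @param ann A `GenomeAnnotation`.
#' @param category Optional category name overriding per-reference lookup.
#' @param sample_id,assay Labels stamped on every read.
#' @return A read `data.table` with columns read_id, seq_id, pos (0-based),
#'   strand, width (query nt), cigar, seq, umi, sample_id, assay, category.
#' @export
read_alignments <- function(path, ann, category = NULL,
                            sample_id = NA_character_,
                            assay = NA_character_) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressWarnings(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "rname", "pos", "strand", "qwidth", "cigar", "seq"),
    tag = "RX")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  umi <- x$tag$RX
  if (is.null(umi)) umi <- rep(NA_character_, n)
  reads <- data.table::data.table(
    read_id = x$qname,
    seq_id = as.character(x$rname),
    pos = x$pos - 1L,
    strand = as.character(x$strand),
    width = x$qwidth,
    cigar = x$cigar,
    seq = as.character(x$seq),
    umi = umi,
    sample_id = sample_id,
    assay = assay)
  if (is.null(category)) {
    reads <- annotate_read_category(reads, ann)
    if (anyNA(reads$category))
      stop("alignments to reference(s) absent from the annotation: ",
           paste(unique(reads$seq_id[is.na(reads$category)]), collapse = ", "))
  } else {
    stopifnot(category %in% reference_categories())
    reads$category <- category
  }
  reads
}

#' Hierarchical first-match category assignment
#'
#' Given per-category alignment sets (reads of the same library aligned
#' independently against each reference category), assigns every read_id
#' to the first category, in the fixed priority order returned by
#' [reference_categories()], in which it has a primary alignment; its
#' alignments in later categories are discarded. This reproduces the
#' sequential alignment strategy in which unaligned reads from each step
#' feed the next round.
#'
#' @param category_sets Named list of read `data.table`s keyed by category.
#' @param all_read_ids Optional vector of every read_id in the library;
#'   ids aligning in no category are counted as unassigned.
#' @return A single read `data.table`; the attribute `"unassigned"` counts
#'   read_ids present in none of the categories, and
#'   `"assignment_summary"` tabulates reads per category.
#' @export
assign_category <- function(category_sets, all_read_ids = NULL) {
  order6 <- reference_categories()
  bad <- setdiff(names(category_sets), order6)
  if (length(bad))
    stop("unknown category name(s): ", paste(bad, collapse = ", "))
  seen <- character(0)
  kept <- list()
  for (cat in order6) {
    dt <- category_sets[[cat]]
    if (is.null(dt) || nrow(dt) == 0L) next
    dt <- dt[!read_id %in% seen]
    # one primary alignment per read_id within the category
    dt <- dt[!duplicated(read_id)]
    dt$category <- cat
    kept[[cat]] <- dt
    seen <- c(seen, dt$read_id)
  }
  out <- if (length(kept)) data.table::rbindlist(kept)
         else empty_read_table()[, category := character(0)][]
  summ <- table(factor(out$category, levels = order6))
  data.table::setattr(out, "assignment_summary", summ)
  unassigned <- if (is.null(all_read_ids)) 0L
                else length(setdiff(all_read_ids, out$read_id))
  data.table::setattr(out, "unassigned", unassigned)
  out
}

#' Footprint length filter
#'
#' Keeps Ribo-seq reads whose aligned query length lies within the closed
#' interval `[min, max]` (default 18-40 nt).
#'
#' @param reads A read `data.table`.
#' @param min,max Closed length bounds in nt.
#' @return Filtered read table.
#' @export
filter_length <- function(reads, min = 18L, max = 40L) {
  if (min > max) stop("length filter: min exceeds max")
  reads[width >= min & width <= max]
}

#' UMI deduplication of RNA-seq reads
#'
#' Collapses PCR duplicates: one representative is kept per
#' (seq_id, start, strand, length, UMI) key. Idempotent.
#'
#' @param reads A read `data.table` whose `umi` column is fully populated.
#' @return Deduplicated read table.
#' @export
dedup_umi <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  if (anyNA(reads$umi))
    stop("reads without UMIs; run without deduplication for UMI-free ",
         "libraries")
  reads[!duplicated(reads[, .(seq_id, pos, strand, width, umi)])]
}

#' Read a sample sheet
#'
#' Tab-separated table with columns sample_id, assay ("ribo"/"rna"),
#' condition, replicate, path (SAM/BAM, combined across categories).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "assay", "condition", "replicate", "path")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(ss$replicate < 1)) stop("replicate indices must be >= 1")
  if (!all(ss$assay %in% c("ribo", "rna")))
    stop("assay must be 'ribo' or 'rna'")
  ss
}

#' Per-sample assignment summary
#'
#' Tabulates reads per hierarchical category for one sample -- the machine
#' twin of a mapping-statistics table.
#'
#' @param reads A categorized read `data.table`.
#' @return data.frame with category and n_reads.
#' @export
assignment_summary <- function(reads) {
  tab <- table(factor(reads$category, levels = reference_categories()))
  data.frame(category = names(tab), n_reads = as.integer(tab),
             stringsAsFactors = FALSE)
}
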