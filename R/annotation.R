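# Multi-compartment genome annotation: data model and I/O.
#
# All internal coordinates are 0-based, half-open [start, end). GFF3 I/O
# converts to/from the 1-based closed convention at the boundary. Exons of a
# gene are stored in transcript order (rank 1 = 5'-most exon of the mRNA),
# which for minus-strand genes means descending genomic coordinates.

#' Canonical hierarchical reference categories
#'
#' The six reference categories, in the fixed order used for hierarchical
#' read assignment: reads are aligned to chloroplast tRNA/rRNA first, then
#' the chloroplast genome, then mitochondrial tRNA/rRNA, the mitochondrial
#' genome, nuclear tRNA/rRNA, and finally the nuclear genome, with each
#' read claimed by the first category in which it aligns.
#'
#' @return Character vector of the six category names, in priority order.
#' @export
reference_categories <- function() {
  c("plastid_trna_rrna", "plastid_genome",
    "mito_trna_rrna", "mito_genome",
    "nuclear_trna_rrna", "nuclear_genome")
}

#' Compartment of each reference category
#' @return Named character vector mapping category to compartment.
#' @keywords internal
category_compartments <- function() {
  c(plastid_trna_rrna = "plastid", plastid_genome = "plastid",
    mito_trna_rrna = "mitochondrion", mito_genome = "mitochondrion",
    nuclear_trna_rrna = "nucleus", nuclear_genome = "nucleus")
}

new_annotation <- function(sequences, genes, exons, tus, editing_sites, refs) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  stopifnot(all(exons$start < exons$end),
            all(nchar(exons$gene_id) > 0))
  ann <- structure(list(
    sequences = sequences,
    genes = genes,
    exons = exons,
    tus = tus,
    editing_sites = editing_sites,
    refs = refs,
    reference_categories = reference_categories()
  ), class = "GenomeAnnotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  g <- ann$genes
  e <- ann$exons
  if (anyDuplicated(g$gene_id))
    stop("duplicated gene_id in annotation")
  bad <- setdiff(e$gene_id, g$gene_id)
  if (length(bad))
    stop("exons reference unknown gene(s): ", paste(bad, collapse = ", "))
  seqlen <- vapply(ann$sequences, nchar, integer(1))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    if (!g$seq_id[i] %in% names(ann$sequences))
      stop("gene ", gid, " references missing seq_id ", g$seq_id[i])
    ee <- e[e$gene_id == gid, , drop = FALSE]
    if (nrow(ee) == 0L) stop("gene ", gid, " has no CDS intervals")
    if (any(ee$end > seqlen[[g$seq_id[i]]]))
      stop("CDS of gene ", gid, " extends beyond sequence ", g$seq_id[i])
    # intron_count = number of gaps between consecutive CDS pieces
    if (g$intron_count[i] != nrow(ee) - 1L)
      stop("gene ", gid, ": intron_count does not match exon count")
    ee <- ee[order(ee$rank), , drop = FALSE]
    gs <- if (g$strand[i] == "+") ee$start else rev(ee$start)
    if (is.unsorted(gs, strictly = TRUE) && nrow(ee) > 1L)
      stop("gene ", gid, ": exons not ordered 5'->3' in transcript orientation")
  }
  st <- g$stoichiometry
  if (any(!is.na(st) & st <= 0)) stop("stoichiometry must be > 0 where set")
  invisible(ann)
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$sequences), "sequences,",
      nrow(x$genes), "genes,",
      if (is.null(x$tus)) 0L else length(unique(x$tus$tu_id)),
      "transcription units,",
      if (is.null(x$editing_sites)) 0L else nrow(x$editing_sites),
      "editing sites\n")
  tab <- table(x$genes$compartment)
  cat("  genes per compartment:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Exons of one gene in transcript order
#' @keywords internal
gene_exons <- function(ann, gene_id) {
  ee <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  ee[order(ee$rank), , drop = FALSE]
}

#' Load a multi-compartment genome annotation
#'
#' Reads a GFF3 file (gene/mRNA/CDS features), the matching FASTA, and an
#' optional editing-site table, and assembles a `GenomeAnnotation`. GFF3
#' 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Compartment membership of each reference sequence
#' comes from the `compartments` argument rather than being inferred from
#' sequence names, and the hierarchical alignment category of each sequence
#' comes from `categories`.
#'
#' @param gff3_path Path to a GFF3 annotation. `gene` features may carry
#'   `tu_id`, `function_category` and `stoichiometry` attributes.
#' @param fasta_path Path to the genome FASTA. All GFF3 seq_ids must be
#'   present.
#' @param editing_tsv_path Optional path to a tab-separated editing-site
#'   table with columns `site_id`, `gene_id`, `seq_id`, `pos_0based`,
#'   `strand`, `creates_start`.
#' @param compartments Named character vector: seq_id ->
#'   {plastid, mitochondrion, nucleus}.
#' @param categories Named character vector: seq_id -> one of
#'   [reference_categories()]. Defaults to the `<compartment>_genome`
#'   category of each sequence.
#' @return A `GenomeAnnotation` object.
#' @export
read_annotation <- function(gff3_path, fasta_path, editing_tsv_path = NULL,
                            compartments, categories = NULL) {
  stopifnot(file.exists(gff3_path), file.exists(fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sequences <- stats::setNames(as.character(seqs), names(seqs))

  gff <- rtracklayer::import(gff3_path, format = "gff3")
  gdf <- as.data.frame(gff, stringsAsFactors = FALSE)
  missing_seq <- setdiff(unique(as.character(gdf$seqnames)), names(sequences))
  if (length(missing_seq))
    stop("GFF3 references seq_id(s) absent from FASTA: ",
         paste(missing_seq, collapse = ", "))
  missing_comp <- setdiff(names(sequences), names(compartments))
  if (length(missing_comp))
    stop("no compartment assignment for seq_id(s): ",
         paste(missing_comp, collapse = ", "))
  if (is.null(categories))
    categories <- stats::setNames(
      paste0(sub("nucleus", "nuclear",
                 sub("mitochondrion", "mito", compartments)), "_genome"),
      names(compartments))

  is_gene <- gdf$type == "gene"
  genes_raw <- gdf[is_gene, , drop = FALSE]
  cds_raw <- gdf[gdf$type == "CDS", , drop = FALSE]
  getattr <- function(df, col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  }
  # CDS features point at their gene via Parent ("<gene>.mRNA") or gene_id
  parent <- vapply(cds_raw$Parent, function(p) {
    if (length(p) == 0) NA_character_ else sub("\\.mRNA.*$", "", p[[1]])
  }, character(1))
  cds_gene <- ifelse(is.na(parent), getattr(cds_raw, "gene_id"), parent)

  genes <- data.frame(
    gene_id = as.character(genes_raw$ID),
    seq_id = as.character(genes_raw$seqnames),
    strand = as.character(genes_raw$strand),
    compartment = unname(compartments[as.character(genes_raw$seqnames)]),
    tu_id = getattr(genes_raw, "tu_id"),
    function_category = getattr(genes_raw, "function_category"),
    stoichiometry = suppressWarnings(as.numeric(getattr(genes_raw, "stoichiometry"))),
    stringsAsFactors = FALSE
  )

  ex_list <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    cc <- cds_raw[cds_gene == gid, , drop = FALSE]
    if (nrow(cc) == 0L) return(NULL)
    start0 <- cc$start - 1L   # GFF3 1-based closed -> 0-based half-open
    end0 <- cc$end
    o <- order(start0)
    if (genes$strand[i] == "-") o <- rev(o)
    data.frame(gene_id = gid, rank = seq_along(o),
               start = start0[o], end = end0[o], stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, ex_list)
  keep <- genes$gene_id %in% exons$gene_id
  genes <- genes[keep, , drop = FALSE]
  genes$intron_count <- vapply(genes$gene_id, function(g)
    sum(exons$gene_id == g) - 1L, integer(1))

  tus <- NULL
  if (any(!is.na(genes$tu_id))) {
    tt <- genes[!is.na(genes$tu_id), c("tu_id", "gene_id", "strand")]
    tt <- tt[order(tt$tu_id), , drop = FALSE]
    tus <- data.frame(tu_id = tt$tu_id, gene_id = tt$gene_id,
                      strand = tt$strand, stringsAsFactors = FALSE)
  }

  editing_sites <- NULL
  if (!is.null(editing_tsv_path)) {
    editing_sites <- utils::read.delim(editing_tsv_path,
                                       stringsAsFactors = FALSE)
    need <- c("site_id", "gene_id", "seq_id", "pos_0based", "strand",
              "creates_start")
    miss <- setdiff(need, names(editing_sites))
    if (length(miss))
      stop("editing table lacks column(s): ", paste(miss, collapse = ", "))
    editing_sites$creates_start <- as.logical(editing_sites$creates_start)
  }

  refs <- data.frame(
    seq_id = names(sequences),
    length = unname(vapply(sequences, nchar, integer(1))),
    category = unname(categories[names(sequences)]),
    compartment = unname(compartments[names(sequences)]),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- rownames(exons) <- NULL
  new_annotation(sequences, genes, exons, tus, editing_sites, refs)
}

#' Write an annotation back to GFF3 + FASTA + editing TSV
#'
#' Inverse of [read_annotation()]; `read_annotation(write_annotation(ann))`
#' reproduces the annotation.
#'
#' @param ann A `GenomeAnnotation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff3 <- file.path(dir, "annotation.gff3")
  fasta <- file.path(dir, "genome.fa")
  etsv <- file.path(dir, "editing_sites.tsv")

  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    ee <- gene_exons(ann, g$gene_id)
    attrs <- paste0("ID=", g$gene_id)
    if (!is.na(g$tu_id)) attrs <- paste0(attrs, ";tu_id=", g$tu_id)
    if (!is.na(g$function_category))
      attrs <- paste0(attrs, ";function_category=", g$function_category)
    if (!is.na(g$stoichiometry))
      attrs <- paste0(attrs, ";stoichiometry=", format(g$stoichiometry))
    lo <- min(ee$start); hi <- max(ee$end)
    lines <- c(lines,
      paste(g$seq_id, "chlororibo", "gene", lo + 1L, hi, ".", g$strand, ".",
            attrs, sep = "\t"),
      paste(g$seq_id, "chlororibo", "mRNA", lo + 1L, hi, ".", g$strand, ".",
            paste0("ID=", g$gene_id, ".mRNA;Parent=", g$gene_id), sep = "\t"),
      paste(g$seq_id, "chlororibo", "CDS", ee$start + 1L, ee$end, ".",
            g$strand, "0", paste0("ID=", g$gene_id, ".cds", ee$rank,
                                  ";Parent=", g$gene_id, ".mRNA"), sep = "\t"))
  }
  writeLines(lines, gff3)

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ann$sequences), fasta)

  es <- ann$editing_sites
  if (is.null(es))
    es <- data.frame(site_id = character(), gene_id = character(),
                     seq_id = character(), pos_0based = integer(),
                     strand = character(), creates_start = logical())
  utils::write.table(es, etsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(gff3 = gff3, fasta = fasta, editing_tsv = etsv))
}

#' Seq_id -> compartment and seq_id -> category maps of an annotation
#' @keywords internal
ref_maps <- function(ann) {
  list(
    compartment = stats::setNames(ann$refs$compartment, ann$refs$seq_id),
    category = stats::setNames(ann$refs$category, ann$refs$seq_id)
  )
}

#' Merge CDS intervals of every gene into a union CDS
#'
#' Overlapping CDS pieces (e.g. from multiple transcript variants) are
#' merged per gene into a minimal set of disjoint intervals, returned in
#' transcript order together with the total union length in nucleotides.
#'
#' @param ann A `GenomeAnnotation`.
#' @return Named list (per gene) with elements `intervals` (data.frame of
#'   0-based half-open `start`, `end` in transcript order) and `length`.
#' @export
union_cds <- function(ann) {
  out <- lapply(ann$genes$gene_id, function(gid) {
    ee <- gene_exons(ann, gid)
    iv <- merge_intervals(ee$start, ee$end)
    strand <- ann$genes$strand[ann$genes$gene_id == gid]
    if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
    rownames(iv) <- NULL
    list(intervals = iv, length = sum(iv$end - iv$start))
  })
  stats::setNames(out, ann$genes$gene_id)
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  rs <- re <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      rs <- c(rs, ms); re <- c(re, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(rs, ms), end = c(re, me))
}

#' 3'-most CDS exon of a gene
#'
#' Returns the last exon in transcript orientation: the rightmost CDS
#' interval for a plus-strand gene, the leftmost for a minus-strand gene.
#' Used as the counting region for intron-containing genes, where reads in
#' upstream exons may derive from partially spliced precursors.
#'
#' @param ann A `GenomeAnnotation`.
#' @param gene_id Gene identifier.
#' @return List with `seq_id`, `strand`, `start`, `end` (0-based half-open)
#'   and `length`.
#' @export
last_exon <- function(ann, gene_id) {
  g <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene_id: ", gene_id)
  ee <- gene_exons(ann, gene_id)
  last <- ee[nrow(ee), ]
  list(seq_id = g$seq_id, strand = g$strand,
       start = last$start, end = last$end,
       length = last$end - last$start)
}

#' Counting-region table for all genes
#'
#' For each gene: the region over which reads are counted -- the union CDS
#' for intronless genes, the last exon only for intron-containing genes --
#' as a table of genomic blocks in transcript order with cumulative
#' transcript offsets. Frame is tracked relative to the *full* spliced CDS
#' so that codon positions remain meaningful in last-exon regions.
#'
#' @param ann A `GenomeAnnotation`.
#' @param region `"auto"` (last exon for intron genes), `"full_cds"`, or
#'   `"last_exon"`.
#' @return `data.table` with columns gene_id, seq_id, strand, compartment,
#'   start, end, toffset (transcript offset of block start within the
#'   spliced CDS), region_length, counting_region.
#' @keywords internal
counting_regions <- function(ann, region = "auto") {
  ucds <- union_cds(ann)
  rows <- lapply(ann$genes$gene_id, function(gid) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    iv <- ucds[[gid]]$intervals
    w <- iv$end - iv$start
    toff <- cumsum(c(0, w[-length(w)]))
    use_last <- switch(region,
      auto = g$intron_count > 0L,
      full_cds = FALSE,
      last_exon = TRUE)
    keep <- if (use_last) nrow(iv) else seq_len(nrow(iv))
    data.table::data.table(
      gene_id = gid, seq_id = g$seq_id, strand = g$strand,
      compartment = g$compartment,
      start = iv$start[keep], end = iv$end[keep], toffset = toff[keep],
      region_length = sum(w[keep]),
      counting_region = if (use_last) "last_exon" else "full_cds")
  })
  data.table::rbindlist(rows)
}

#' Genomic -> transcript coordinate of positions within a gene's spliced CDS
#'
#' @param ann A `GenomeAnnotation`.
#' @param gene_id Gene.
#' @param pos Integer vector of 0-based genomic positions.
#' @return Integer vector of 0-based transcript offsets within the spliced
#'   union CDS (NA for positions outside it).
#' @keywords internal
genomic_to_transcript <- function(ann, gene_id, pos) {
  iv <- union_cds(ann)[[gene_id]]$intervals
  strand <- ann$genes$strand[ann$genes$gene_id == gene_id]
  w <- iv$end - iv$start
  toff <- cumsum(c(0, w[-length(w)]))
  out <- rep(NA_integer_, length(pos))
  for (b in seq_len(nrow(iv))) {
    inb <- !is.na(pos) & pos >= iv$start[b] & pos < iv$end[b]
    out[inb] <- if (strand == "+") toff[b] + (pos[inb] - iv$start[b])
                else                toff[b] + (iv$end[b] - 1L - pos[inb])
  }
  out
}
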