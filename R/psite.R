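# Metagene analysis, footprint-size-dependent P-site offset inference,
# P-site assignment, and 3-nt periodicity.
#
# Organellar ribosome footprints have a variable 5' end but a constant 3'
# end relative to the decoded codon, so P-sites are inferred from footprint
# 3' ends: the P-site first nucleotide lies d nt upstream of the 3' end,
# with d estimated per footprint size from the start-codon metagene.
# Cytosolic footprints are approximately centered on the P site, which is
# implemented as floor(length/2) nt from the 5' end.

# per-read aligned reference blocks (M operations), 0-based half-open
read_blocks <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.table::data.table(ri = integer(), s = integer(),
                                  e = integer()))
  rl <- GenomicAlignments::extractAlignmentRangesOnReference(
    reads$cigar, pos = reads$pos + 1L)
  n_per <- S4Vectors::elementNROWS(rl)
  flat <- unlist(rl, use.names = FALSE)
  data.table::data.table(
    ri = rep(seq_len(nrow(reads)), n_per),
    s = BiocGenerics::start(flat) - 1L,
    e = BiocGenerics::end(flat))
}

# genomic markers of read ends: 3' exclusive-style marker and 5' base
read_end_coords <- function(reads, blocks = NULL) {
  if (is.null(blocks)) blocks <- read_blocks(reads)
  ag <- blocks[, .(smin = min(s), emax = max(e)), by = ri]
  out <- data.table::data.table(ri = seq_len(nrow(reads)))
  out <- merge(out, ag, by = "ri", all.x = TRUE)
  plus <- reads$strand[out$ri] == "+"
  out[, end3 := ifelse(plus, emax, smin)]       # see dist conventions below
  out[, end5 := ifelse(plus, smin, emax - 1L)]
  out
}

#' Metagene profile of read ends around start or stop codons
#'
#' For every read of a compartment whose chosen end (3' or 5') falls
#' within +-`window` nt of a gene's anchor codon (the first nucleotide of
#' the start codon, or of the stop codon), increments a
#' (footprint size, signed distance) count. Distances are measured in
#' transcript orientation: +d means d nt downstream (3'-ward on the mRNA)
#' of the anchor. For the 3' end the distance is exclusive-style, so a
#' footprint whose P-site sits at the anchor and whose 3' end is anchored
#' d nt downstream of the P-site first nt contributes distance exactly d.
#'
#' @param reads Categorized read `data.table`.
#' @param ann A `GenomeAnnotation`.
#' @param compartment One of plastid, mitochondrion, nucleus.
#' @param anchor `"start"` or `"stop"`.
#' @param end_used `"3prime"` or `"5prime"`.
#' @param window Half-width of the metagene window in nt.
#' @return A `MetageneProfile`: list with `counts`
#'   (data.table size, dist, count), plus anchor/compartment/end metadata.
#' @export
metagene_profile <- function(reads, ann, compartment, anchor = "start",
                             end_used = "3prime", window = 50L) {
  stopifnot(anchor %in% c("start", "stop"),
            end_used %in% c("3prime", "5prime"))
  genes <- ann$genes[ann$genes$compartment == compartment, , drop = FALSE]
  comp_reads <- reads[category %in%
    ann$refs$category[ann$refs$compartment == compartment &
                      !grepl("trna_rrna", ann$refs$category)]]
  counts <- data.table::data.table(size = integer(), dist = integer(),
                                   count = integer())
  if (nrow(comp_reads) > 0L && nrow(genes) > 0L) {
    ends <- read_end_coords(comp_reads)
    acc <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      L <- union_cds(ann)[[g$gene_id]]$length
      t_anchor <- if (anchor == "start") 0L else L - 3L
      a <- transcript_to_genomic(ann, g$gene_id, t_anchor)
      sel <- comp_reads$seq_id == g$seq_id & comp_reads$strand == g$strand
      if (!any(sel)) next
      ee <- ends[sel]
      rr <- comp_reads[sel]
      if (end_used == "3prime") {
        dist <- if (g$strand == "+") ee$end3 - a else a - ee$end3 + 1L
      } else {
        dist <- if (g$strand == "+") ee$end5 - a else a - ee$end5
      }
      keep <- abs(dist) <= window
      if (!any(keep)) next
      acc[[length(acc) + 1L]] <- data.table::data.table(
        size = rr$width[keep], dist = dist[keep])
    }
    if (length(acc)) {
      counts <- data.table::rbindlist(acc)[, .(count = .N),
                                           by = .(size, dist)]
      data.table::setorder(counts, size, dist)
    }
  }
  if (nrow(counts) == 0L)
    warning("no reads anchored at ", anchor, " codons for compartment ",
            compartment)
  structure(list(counts = counts, anchor = anchor,
                 compartment = compartment, end_used = end_used,
                 window = window),
            class = "MetageneProfile")
}

#' Infer per-size P-site offsets from a start-codon metagene
#'
#' For each footprint size, the offset d is the modal 3'-end distance from
#' the start-codon first nucleotide over distances in `[0, 18]` nt (ties
#' broken toward the smaller d). Sizes supported by fewer than
#' `min_support` reads in that window inherit the compartment-wide modal
#' offset and are flagged `fallback_used`.
#'
#' @param profile A start-anchored, 3'-end `MetageneProfile`.
#' @param min_support Minimum reads per size class.
#' @param search_window Inclusive distance range searched for the mode.
#' @return An `OffsetTable` data.table: compartment, size, d, support,
#'   fallback_used, rule.
#' @export
infer_offsets <- function(profile, min_support = 50L,
                          search_window = c(0L, 18L)) {
  stopifnot(inherits(profile, "MetageneProfile"),
            profile$anchor == "start", profile$end_used == "3prime")
  cc <- profile$counts[dist >= search_window[1] & dist <= search_window[2]]
  if (nrow(cc) == 0L)
    stop("no start-anchored reads in the offset search window")
  modal <- function(d, n) {
    mx <- max(n)
    min(d[n == mx])
  }
  overall <- cc[, .(count = sum(count)), by = dist]
  comp_mode <- modal(overall$dist, overall$count)
  per_size <- cc[, .(d = modal(dist, count), support = sum(count)),
                 by = size]
  per_size[, fallback_used := support < min_support]
  per_size[fallback_used == TRUE, d := comp_mode]
  if (all(per_size$fallback_used) && nrow(overall) == 0L)
    stop("offset inference failed: no size class reaches min_support")
  out <- data.table::data.table(
    compartment = profile$compartment,
    size = per_size$size, d = as.integer(per_size$d),
    support = per_size$support, fallback_used = per_size$fallback_used,
    rule = "3prime")
  data.table::setorder(out, size)
  out[]
}

#' Offset table for the centered (cytosolic) rule
#'
#' Cytosolic footprints are approximately centered on the P site; the
#' P-site first nucleotide is placed floor(length/2) nt from the 5' end.
#'
#' @param compartment Compartment name (default nucleus).
#' @return An `OffsetTable` row with rule `"centered"`.
#' @export
centered_offsets <- function(compartment = "nucleus") {
  data.table::data.table(compartment = compartment, size = NA_integer_,
                         d = NA_integer_, support = NA_integer_,
                         fallback_used = FALSE, rule = "centered")
}

# offsets argument for assign_psites: rbind of OffsetTable rows across
# compartments; helper to look up rule for a compartment
offsets_for_compartment <- function(offsets, comp) {
  offsets[offsets$compartment == comp, , drop = FALSE]
}

#' Assign P-site positions to reads
#'
#' Organellar reads: the P-site first nucleotide is the d-th aligned base
#' counting back from the 3' end (equivalently, 3'-end coordinate minus d),
#' with d looked up per footprint size in the offset table; gapped
#' alignments are walked along their aligned bases so the geometry holds
#' across splice junctions. Cytosolic reads: the centered rule. Reads of
#' sizes absent from the table, or shorter than their offset, get NA.
#'
#' @param reads Categorized read `data.table`.
#' @param offsets Row-bound `OffsetTable` (e.g. [infer_offsets()] output
#'   plus [centered_offsets()]).
#' @param ann A `GenomeAnnotation`.
#' @return `reads` with a `psite` column (0-based genomic position of the
#'   P-site first nucleotide).
#' @export
assign_psites <- function(reads, offsets, ann) {
  if (nrow(reads) == 0L) {
    reads$psite <- integer(0)
    return(reads)
  }
  maps <- ref_maps(ann)
  comp <- unname(maps$compartment[reads$seq_id])
  bl <- read_blocks(reads)
  bl[, strand := reads$strand[ri]]

  # per-read target index from the relevant end
  d <- rep(NA_integer_, nrow(reads))
  from3 <- rep(NA, nrow(reads))
  for (cc in unique(comp)) {
    sel <- which(comp == cc)
    ot <- offsets_for_compartment(offsets, cc)
    if (nrow(ot) == 0L) next
    if (any(ot$rule == "centered")) {
      d[sel] <- reads$width[sel] %/% 2L + 1L   # index from 5' end
      from3[sel] <- FALSE
    } else {
      dd <- ot$d[match(reads$width[sel], ot$size)]
      # sizes never observed at start codons inherit the compartment's
      # best-supported offset (same spirit as the min_support fallback)
      dd[is.na(dd)] <- ot$d[which.max(ot$support)]
      d[sel] <- dd                              # index from 3' end
      from3[sel] <- TRUE
    }
  }
  bl[, d := d[ri]]
  bl[, from3 := from3[ri]]
  bl <- bl[!is.na(d)]
  # block order along the walk: from the 3' end for anchored reads,
  # from the 5' end for centered reads
  bl[, walk_left_first := (strand == "-") == from3]
  data.table::setorder(bl, ri, s)
  bl[, ord := seq_len(.N), by = ri]
  bl[walk_left_first == FALSE, ord := max(ord) + 1L - ord, by = ri]
  data.table::setorder(bl, ri, ord)
  bl[, w := e - s]
  bl[, cumbefore := cumsum(w) - w, by = ri]
  hit <- bl[cumbefore < d & d <= cumbefore + w]
  hit[, within := d - cumbefore]
  # base position depends on whether the walk moves leftward or rightward
  hit[, psite := ifelse(walk_left_first, s + within - 1L, e - within)]
  psite <- rep(NA_integer_, nrow(reads))
  psite[hit$ri] <- as.integer(hit$psite)
  # d == 0 (3'-anchored): P-site is the position just past the 3' end
  if (any(bl$d == 0L)) {
    z <- bl[d == 0L, .(smin = min(s), emax = max(e),
                       strand = strand[1L]), by = ri]
    psite[z$ri] <- as.integer(ifelse(z$strand == "+", z$emax, z$smin - 1L))
  }
  out <- data.table::copy(reads)
  out$psite <- psite
  out
}

#' Reading-frame distribution of assigned P-sites
#'
#' P-sites falling inside a gene's union CDS are mapped to transcript
#' coordinates; the frame is the CDS offset modulo 3, tabulated per
#' compartment and footprint size.
#'
#' @param reads Read `data.table` with a `psite` column.
#' @param ann A `GenomeAnnotation`.
#' @return A `FrameDistribution` data.table: compartment, size, support,
#'   frame0, frame1, frame2 (fractions summing to 1 where support > 0).
#' @export
frame_periodicity <- function(reads, ann) {
  stopifnot("psite" %in% names(reads))
  regions <- counting_regions(ann, region = "full_cds")
  maps <- ref_maps(ann)
  rr <- reads[!is.na(psite)]
  empty <- data.table::data.table(
    compartment = character(), size = integer(), support = integer(),
    frame0 = numeric(), frame1 = numeric(), frame2 = numeric())
  if (nrow(rr) == 0L) return(empty)
  pts <- data.table::data.table(
    i = seq_len(nrow(rr)), seq_id = rr$seq_id, strand = rr$strand,
    p = rr$psite, p2 = rr$psite, size = rr$width,
    compartment = unname(maps$compartment[rr$seq_id]))
  hits <- regions[pts,
    on = .(seq_id, strand, start <= p, end > p2),
    nomatch = NULL,
    .(i, size, compartment, gstart = x.start, gend = x.end,
      toffset = x.toffset, gstrand = x.strand, p = i.p)]
  if (nrow(hits) == 0L) return(empty)
  hits[, t := ifelse(gstrand == "+", toffset + (p - gstart),
                     toffset + (gend - 1L - p))]
  hits[, frame := t %% 3L]
  # a P-site in two overlapping genes contributes once per gene
  out <- hits[, .(support = .N,
                  frame0 = mean(frame == 0L),
                  frame1 = mean(frame == 1L),
                  frame2 = mean(frame == 2L)),
              by = .(compartment, size)]
  data.table::setorder(out, compartment, size)
  out[]
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("MetageneProfile:", x$compartment, "anchor =", x$anchor,
      "end =", x$end_used, "window =", x$window, "\n")
  cat("  ", sum(x$counts$count), "anchored reads,",
      length(unique(x$counts$size)), "size classes\n")
  invisible(x)
}
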