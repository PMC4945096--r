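# Synthetic Ribo-seq / RNA-seq read generator with ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: compartment-specific footprint-length mixtures (cytosolic peaks
# at 23/31 nt, mitochondrial at 28-29/36 nt, plastid at ~30/35 nt),
# 3'-end-anchored P-site geometry for organellar footprints versus
# P-site-centered cytosolic footprints, 3-nt periodicity with configurable
# frame purity, CDS-restricted coverage with an initiation peak, per-gene
# translational output and efficiency, per-intron spliced fractions,
# per-site C-to-U editing fractions, and UMI-tagged RNA-seq reads with PCR
# duplicates. Reads are emitted pre-aligned (SAM records); the upstream
# aligner is out of scope.

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("chlororibo")),
           error = function(e) "dev")
}

# ---- seeded RNG helpers -----------------------------------------------------

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# distinct sub-streams from one user seed; stays below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + k * 197 + 1)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

random_cds <- function(n_codons, start_codon = "ATG",
                       codon_overrides = list()) {
  stopifnot(n_codons >= 3)
  cod <- c(start_codon,
           sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
           "TAA")
  for (idx in names(codon_overrides)) {
    i <- as.integer(idx) + 1L   # 0-based codon index
    stopifnot(i > 1L, i < n_codons)
    cod[i] <- codon_overrides[[idx]]
  }
  paste(cod, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- built-in miniature genome ---------------------------------------------

#' Build the default miniature three-compartment genome
#'
#' A deterministic ~18 kb annotation used as ground truth for simulations:
#' a plastid chromosome carrying 14 protein-coding genes, including a
#' four-gene ATP-synthase-like operon with unequal subunit stoichiometry
#' (1:14:1:3), a minus-strand mixed-function operon (PSI reaction-center
#' genes co-transcribed with a ribosomal-protein gene), one single-intron
#' gene in the operon, a two-intron gene, a second single-intron gene with
#' an internal editing site, a gene whose start codon is created by C-to-U
#' editing of an ACG precursor, and a very short gene mimicking transcripts
#' under-represented by size-selected RNA-seq libraries; a mitochondrial
#' chromosome with two stub genes; a nuclear chromosome with four stub
#' genes; and one tRNA/rRNA decoy reference per compartment.
#'
#' Calling this function twice yields byte-identical annotations.
#'
#' @return A `GenomeAnnotation`.
#' @export
sim_genome <- function() {
  with_seed(20160714L, build_sim_genome())
}

build_sim_genome <- function() {
  spacer <- 200L

  gene_specs <- list(
    Pt = list(
      list(gene_id = "psbA", strand = "+", exons = 600L,
           fc = "photosynthesis-PSII", stoich = 1),
      list(gene_id = "rbcL", strand = "+", exons = 600L,
           fc = "rubisco", stoich = 8,
           codon_overrides = list(`100` = "CCA")),
      list(gene_id = "atpI", strand = "+", exons = 372L, tu = "TU_atp",
           fc = "ATP-synthase", stoich = 1),
      list(gene_id = "atpH", strand = "+", exons = 246L, tu = "TU_atp",
           fc = "ATP-synthase", stoich = 14),
      list(gene_id = "atpF", strand = "+", exons = c(150L, 360L),
           introns = 300L, tu = "TU_atp", fc = "ATP-synthase", stoich = 1),
      list(gene_id = "atpA", strand = "+", exons = 900L, tu = "TU_atp",
           fc = "ATP-synthase", stoich = 3),
      # psaA-psaB-rps14-like operon, transcribed right-to-left
      list(gene_id = "rps14", strand = "-", exons = 300L, tu = "TU_psa",
           fc = "ribosome", stoich = 1),
      list(gene_id = "psaB", strand = "-", exons = 600L, tu = "TU_psa",
           fc = "photosynthesis-PSI", stoich = 1),
      list(gene_id = "psaA", strand = "-", exons = 600L, tu = "TU_psa",
           fc = "photosynthesis-PSI", stoich = 1),
      list(gene_id = "rpl2", strand = "+", exons = 402L,
           fc = "ribosome", stoich = 1, start_codon = "ACG"),
      list(gene_id = "ycf3", strand = "-", exons = c(150L, 150L, 150L),
           introns = c(250L, 250L), fc = "assembly-factor", stoich = NA),
      list(gene_id = "ndhA", strand = "+", exons = c(180L, 360L),
           introns = 300L, fc = "NDH", stoich = 1,
           codon_overrides = list(`150` = "CCA")),
      list(gene_id = "petN", strand = "+", exons = 90L,
           fc = "cytb6f", stoich = 1),
      list(gene_id = "rpoA", strand = "+", exons = 450L,
           fc = "RNA-polymerase", stoich = 2)
    ),
    Mt = list(
      list(gene_id = "atp6", strand = "+", exons = 600L, fc = "other",
           stoich = NA),
      list(gene_id = "cox1", strand = "-", exons = 450L, fc = "other",
           stoich = NA)
    ),
    Nc = list(
      list(gene_id = "rbcS", strand = "+", exons = 600L, fc = "other",
           stoich = NA),
      list(gene_id = "lhcb1", strand = "-", exons = 600L, fc = "other",
           stoich = NA),
      list(gene_id = "gapdh", strand = "+", exons = 600L, fc = "other",
           stoich = NA),
      list(gene_id = "actin1", strand = "+", exons = 600L, fc = "other",
           stoich = NA)
    )
  )
  comp_of_seq <- c(Pt = "plastid", Mt = "mitochondrion", Nc = "nucleus",
                   Pt_rrna = "plastid", Mt_rrna = "mitochondrion",
                   Nc_rrna = "nucleus")
  cat_of_seq <- c(Pt = "plastid_genome", Mt = "mito_genome",
                  Nc = "nuclear_genome", Pt_rrna = "plastid_trna_rrna",
                  Mt_rrna = "mito_trna_rrna", Nc_rrna = "nuclear_trna_rrna")

  sequences <- character(0)
  genes <- list(); exons <- list()
  for (seqid in names(gene_specs)) {
    parts <- character(0); cursor <- 0L
    for (gs in gene_specs[[seqid]]) {
      parts <- c(parts, random_dna(spacer)); cursor <- cursor + spacer
      n_ex <- length(gs$exons)
      intr <- if (n_ex > 1L) gs$introns else integer(0)
      cds_len <- sum(gs$exons)
      stopifnot(cds_len %% 3L == 0L)
      cds <- random_cds(cds_len / 3L,
                        start_codon = if (is.null(gs$start_codon)) "ATG"
                                      else gs$start_codon,
                        codon_overrides = if (is.null(gs$codon_overrides))
                          list() else gs$codon_overrides)
      # assemble coding-strand body: exon1 intron1 exon2 ...
      body <- character(0); coff <- 0L; offs <- integer(n_ex)
      pos_in_body <- 0L
      for (k in seq_len(n_ex)) {
        offs[k] <- pos_in_body
        body <- c(body, substr(cds, coff + 1L, coff + gs$exons[k]))
        coff <- coff + gs$exons[k]; pos_in_body <- pos_in_body + gs$exons[k]
        if (k < n_ex) {
          body <- c(body, random_dna(intr[k]))
          pos_in_body <- pos_in_body + intr[k]
        }
      }
      body <- paste(body, collapse = "")
      blen <- nchar(body)
      g0 <- cursor
      parts <- c(parts, if (gs$strand == "+") body else revcomp(body))
      cursor <- cursor + blen
      if (gs$strand == "+") {
        ex_start <- g0 + offs
        ex_end <- ex_start + gs$exons
      } else {
        ex_end <- g0 + blen - offs
        ex_start <- ex_end - gs$exons
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gs$gene_id, seq_id = seqid, strand = gs$strand,
        compartment = comp_of_seq[[seqid]],
        tu_id = if (is.null(gs$tu)) NA_character_ else gs$tu,
        function_category = gs$fc,
        stoichiometry = as.numeric(gs$stoich),
        intron_count = n_ex - 1L, stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <- data.frame(
        gene_id = gs$gene_id, rank = seq_len(n_ex),
        start = ex_start, end = ex_end, stringsAsFactors = FALSE)
    }
    parts <- c(parts, random_dna(spacer))
    sequences[[seqid]] <- paste(parts, collapse = "")
  }
  sequences[["Pt_rrna"]] <- random_dna(1500L)
  sequences[["Mt_rrna"]] <- random_dna(800L)
  sequences[["Nc_rrna"]] <- random_dna(800L)

  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  tus <- genes[!is.na(genes$tu_id), c("tu_id", "gene_id", "strand")]
  rownames(tus) <- NULL

  refs <- data.frame(
    seq_id = names(sequences),
    length = unname(vapply(sequences, nchar, integer(1))),
    category = unname(cat_of_seq[names(sequences)]),
    compartment = unname(comp_of_seq[names(sequences)]),
    stringsAsFactors = FALSE)

  ann <- new_annotation(sequences, genes, exons, tus, NULL, refs)

  # editing sites: coding-strand C at a known ORF offset
  site_tbl <- data.frame(
    gene_id = c("rpl2", "ndhA", "rbcL"),
    t_off = c(1L, 450L, 300L),          # 0-based nt within spliced ORF
    creates_start = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  site_tbl$site_id <- paste0(site_tbl$gene_id, "_", site_tbl$t_off + 1L)
  gpos <- mapply(function(g, t) transcript_to_genomic(ann, g, t),
                 site_tbl$gene_id, site_tbl$t_off)
  strands <- ann$genes$strand[match(site_tbl$gene_id, ann$genes$gene_id)]
  seqids <- ann$genes$seq_id[match(site_tbl$gene_id, ann$genes$gene_id)]
  # genome carries the unedited base: C on the coding strand
  for (i in seq_len(nrow(site_tbl))) {
    base <- if (strands[i] == "+") "C" else "G"
    s <- ann$sequences[[seqids[i]]]
    stopifnot(substr(s, gpos[i] + 1L, gpos[i] + 1L) == base)
  }
  ann$editing_sites <- data.frame(
    site_id = site_tbl$site_id, gene_id = site_tbl$gene_id,
    seq_id = seqids, pos_0based = as.integer(gpos), strand = strands,
    creates_start = site_tbl$creates_start, stringsAsFactors = FALSE)
  ann
}

#' Transcript -> genomic coordinate within a gene's spliced CDS
#' @keywords internal
transcript_to_genomic <- function(ann, gene_id, t) {
  iv <- union_cds(ann)[[gene_id]]$intervals
  strand <- ann$genes$strand[ann$genes$gene_id == gene_id]
  w <- iv$end - iv$start
  toff <- cumsum(c(0, w[-length(w)]))
  out <- rep(NA_integer_, length(t))
  for (b in seq_len(nrow(iv))) {
    inb <- !is.na(t) & t >= toff[b] & t < toff[b] + w[b]
    out[inb] <- if (strand == "+") iv$start[b] + (t[inb] - toff[b])
                else                iv$end[b] - 1L - (t[inb] - toff[b])
  }
  out
}

# ---- simulation configuration ----------------------------------------------

#' Simulation configuration
#'
#' Assembles the full parameter set of the read generator. Defaults encode
#' the study conditions the analysis is designed for: footprint-length
#' mixtures peaking at 30/35 nt (plastid), 28/36 nt (mitochondrion) and
#' 23/31 nt (cytosol); a 7-nt distance from the P-site first nucleotide to
#' the footprint 3' end in both organelles versus centered cytosolic
#' footprints; 90% of P-sites in frame 0; compartment shares of 60%
#' cytosol, 38% plastid, 2% mitochondrion (a young-chloroplast stage);
#' per-gene translational output weights following subunit stoichiometry
#' with efficiency multipliers spanning 50-fold; intron spliced fractions
#' of 0.5-0.8; and editing fractions that are high in both assays except at
#' the start-codon site, where most RNA-seq reads are unedited.
#'
#' @param annotation A `GenomeAnnotation` (defaults used by weight tables
#'   are keyed to [sim_genome()] gene names; unknown genes fall back to
#'   their stoichiometry or 1).
#' @param seed Integer seed recorded in SAM headers and used to key every
#'   random draw.
#' @param n_ribo_reads,n_rna_reads Reads per simulated sample.
#' @param size_mixture Per-compartment discrete length mixtures, each a
#'   list of `modes`, `weights`, `spread` (discretized triangular
#'   components).
#' @param offset_rule Per-compartment placement rule: list with
#'   `type = "3prime"` and `d` (scalar, or named by footprint size) giving
#'   the distance from the P-site first nt to the footprint 3' end, or
#'   `type = "centered"`.
#' @param frame_purity Probability that a footprint's P-site is in frame 0.
#' @param init_peak Extra probability mass placed on the start codon,
#'   emulating the initiation peak seen in metagene profiles.
#' @param compartment_shares Named shares of footprints per compartment
#'   (plastid, mitochondrion, nucleus); must sum to 1.
#' @param decoy_share Fraction of reads emitted on the tRNA/rRNA decoy
#'   references (residual rRNA contamination).
#' @param gene_output Named per-gene relative translational output weights
#'   (within compartment).
#' @param gene_te Named per-gene translational efficiency multipliers;
#'   mRNA weight = output / te.
#' @param splice_fraction Named per-intron spliced fractions
#'   (`<gene>.i<k>`).
#' @param editing_fraction Data frame with columns site_id, ribo, rna.
#' @param rna_read_len RNA-seq read length (nt).
#' @param umi_len UMI length (nt) for RNA-seq.
#' @param pcr_dup_rate Fraction of RNA-seq reads that are PCR re-emissions
#'   of an already-sampled molecule.
#' @param utr_flank Transcript extension beyond the CDS on each side (nt).
#' @param replicates Biological replicates per condition.
#' @param replicate_noise_sd sdlog of the lognormal perturbation applied to
#'   per-gene weights in each replicate.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(annotation,
                       seed = 1L,
                       n_ribo_reads = 1e5,
                       n_rna_reads = 1e5,
                       size_mixture = NULL,
                       offset_rule = NULL,
                       frame_purity = 0.9,
                       init_peak = 0.08,
                       compartment_shares = c(plastid = 0.38,
                                              mitochondrion = 0.02,
                                              nucleus = 0.60),
                       decoy_share = 0.05,
                       gene_output = NULL,
                       gene_te = NULL,
                       splice_fraction = NULL,
                       editing_fraction = NULL,
                       rna_read_len = 75L,
                       umi_len = 8L,
                       pcr_dup_rate = 0.1,
                       utr_flank = 100L,
                       replicates = 3L,
                       replicate_noise_sd = 0.05) {
  if (is.null(size_mixture))
    size_mixture <- list(
      plastid = list(modes = c(30, 35), weights = c(0.55, 0.45), spread = 2),
      mitochondrion = list(modes = c(28, 36), weights = c(0.75, 0.25),
                           spread = 2),
      nucleus = list(modes = c(23, 31), weights = c(0.25, 0.75), spread = 2))
  if (is.null(offset_rule))
    offset_rule <- list(
      plastid = list(type = "3prime", d = 7),
      mitochondrion = list(type = "3prime", d = 7),
      nucleus = list(type = "centered"))

  default_output <- c(
    psbA = 20, rbcL = 10, atpI = 1, atpH = 14, atpF = 1, atpA = 3,
    psaA = 4, psaB = 4, rps14 = 1.5, rpl2 = 1, ycf3 = 0.3, ndhA = 0.5,
    petN = 0.8, rpoA = 0.6,
    atp6 = 1, cox1 = 1,
    rbcS = 5, lhcb1 = 5, gapdh = 3, actin1 = 3)
  default_te <- c(
    atpH = 50, psbA = 20, rbcL = 15, atpA = 10, psaA = 8, psaB = 8,
    atpI = 5, atpF = 5, petN = 5, rps14 = 3, rpoA = 2, rpl2 = 2,
    ndhA = 1, ycf3 = 1,
    atp6 = 1, cox1 = 1,
    rbcS = 2, lhcb1 = 2, gapdh = 2, actin1 = 2)

  gids <- annotation$genes$gene_id
  if (is.null(gene_output)) {
    gene_output <- default_output[gids]
    fallback <- annotation$genes$stoichiometry
    gene_output[is.na(gene_output)] <- ifelse(is.na(fallback), 1,
                                              fallback)[is.na(gene_output)]
    names(gene_output) <- gids
  }
  if (is.null(gene_te)) {
    gene_te <- default_te[gids]
    gene_te[is.na(gene_te)] <- 1
    names(gene_te) <- gids
  }
  if (is.null(splice_fraction)) {
    splice_fraction <- c()
    for (gid in gids) {
      ic <- annotation$genes$intron_count[annotation$genes$gene_id == gid]
      if (ic > 0L) {
        defaults <- c(atpF = 0.8, ndhA = 0.7, ycf3 = 0.5)
        f <- if (gid %in% names(defaults)) defaults[[gid]] else 0.7
        sf <- stats::setNames(rep(f, ic), paste0(gid, ".i", seq_len(ic)))
        splice_fraction <- c(splice_fraction, sf)
      }
    }
  }
  if (is.null(editing_fraction)) {
    es <- annotation$editing_sites
    if (is.null(es) || nrow(es) == 0L) {
      editing_fraction <- data.frame(site_id = character(),
                                     ribo = numeric(), rna = numeric())
    } else {
      ribo <- ifelse(es$creates_start, 0.95, 0.95)
      rna <- ifelse(es$creates_start, 0.55, 0.95)
      editing_fraction <- data.frame(site_id = es$site_id,
                                     ribo = ribo, rna = rna,
                                     stringsAsFactors = FALSE)
    }
  }

  cfg <- structure(list(
    seed = as.integer(seed),
    n_ribo_reads = n_ribo_reads, n_rna_reads = n_rna_reads,
    size_mixture = size_mixture, offset_rule = offset_rule,
    frame_purity = frame_purity, init_peak = init_peak,
    compartment_shares = compartment_shares, decoy_share = decoy_share,
    gene_output = gene_output, gene_te = gene_te,
    splice_fraction = splice_fraction, editing_fraction = editing_fraction,
    rna_read_len = as.integer(rna_read_len), umi_len = as.integer(umi_len),
    pcr_dup_rate = pcr_dup_rate, utr_flank = as.integer(utr_flank),
    replicates = as.integer(replicates),
    replicate_noise_sd = replicate_noise_sd
  ), class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  stopifnot(frac_ok(cfg$frame_purity), frac_ok(cfg$init_peak),
            frac_ok(cfg$splice_fraction), frac_ok(cfg$decoy_share),
            frac_ok(cfg$pcr_dup_rate),
            frac_ok(cfg$editing_fraction$ribo),
            frac_ok(cfg$editing_fraction$rna))
  if (abs(sum(cfg$compartment_shares) - 1) > 1e-9)
    stop("compartment_shares must sum to 1")
  if (any(cfg$gene_output < 0) || all(cfg$gene_output == 0))
    stop("gene_output weights must be >= 0 with at least one positive")
  if (any(cfg$gene_te <= 0)) stop("gene_te multipliers must be > 0")
  invisible(cfg)
}

# sample footprint lengths from a discretized triangular mixture
sample_lengths <- function(n, mix) {
  comp <- sample.int(length(mix$modes), n, replace = TRUE,
                     prob = mix$weights)
  spread <- mix$spread
  if (spread == 0) return(as.integer(mix$modes[comp]))
  deltas <- -spread:spread
  p <- spread + 1 - abs(deltas)
  d <- deltas[sample.int(length(deltas), n, replace = TRUE, prob = p)]
  as.integer(mix$modes[comp] + d)
}

# per-size offset lookup (scalar d recycles to every size)
offset_for_sizes <- function(rule, sizes) {
  if (!is.null(names(rule$d))) {
    d <- rule$d[as.character(sizes)]
    if (anyNA(d))
      stop("offset_rule$d lacks an entry for footprint size(s): ",
           paste(unique(sizes[is.na(d)]), collapse = ", "))
    as.integer(d)
  } else rep(as.integer(rule$d), length(sizes))
}

# ---- gene geometry used by both generators ---------------------------------

# extended-transcript block structure: 5' flank + union-CDS exons (+ introns
# kept for the unspliced RNA isoform) + 3' flank; blocks in transcript order
gene_ext_blocks <- function(ann, gene_id, flank, keep_introns = logical(0)) {
  iv <- union_cds(ann)[[gene_id]]$intervals   # transcript order
  strand <- ann$genes$strand[ann$genes$gene_id == gene_id]
  n <- nrow(iv)
  if (length(keep_introns) == 0L) keep_introns <- rep(FALSE, n - 1L)
  stopifnot(length(keep_introns) == max(n - 1L, 0L))
  blocks <- list()
  if (strand == "+") {
    blocks[[1]] <- c(iv$start[1] - flank, iv$start[1])
    for (k in seq_len(n)) {
      blocks[[length(blocks) + 1L]] <- c(iv$start[k], iv$end[k])
      if (k < n && keep_introns[k])
        blocks[[length(blocks) + 1L]] <- c(iv$end[k], iv$start[k + 1])
    }
    blocks[[length(blocks) + 1L]] <- c(iv$end[n], iv$end[n] + flank)
  } else {
    blocks[[1]] <- c(iv$end[1], iv$end[1] + flank)
    for (k in seq_len(n)) {
      blocks[[length(blocks) + 1L]] <- c(iv$start[k], iv$end[k])
      if (k < n && keep_introns[k])
        blocks[[length(blocks) + 1L]] <- c(iv$end[k + 1], iv$start[k])
    }
    blocks[[length(blocks) + 1L]] <- c(iv$start[n] - flank, iv$start[n])
  }
  m <- do.call(rbind, blocks)
  data.frame(start = m[, 1], end = m[, 2], width = m[, 2] - m[, 1])
}

# map transcript intervals [t0, t1) on a block structure to genomic blocks;
# returns data.table(i, gs, ge) with one row per touched block
map_t_intervals <- function(blocks, strand, t0, t1) {
  w <- blocks$width
  cum0 <- cumsum(c(0, w[-length(w)]))
  cum1 <- cum0 + w
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    ov0 <- pmax(t0, cum0[b]); ov1 <- pmin(t1, cum1[b])
    sel <- which(ov0 < ov1)
    if (!length(sel)) next
    if (strand == "+") {
      gs <- blocks$start[b] + (ov0[sel] - cum0[b])
      ge <- blocks$start[b] + (ov1[sel] - cum0[b])
    } else {
      ge <- blocks$end[b] - (ov0[sel] - cum0[b])
      gs <- blocks$end[b] - (ov1[sel] - cum0[b])
    }
    out[[b]] <- data.table::data.table(i = sel, gs = gs, ge = ge)
  }
  data.table::rbindlist(out)
}

# single transcript positions -> genomic (same block structure)
map_t_pos <- function(blocks, strand, t) {
  bl <- map_t_intervals(blocks, strand, t, t + 1L)
  data.table::setorder(bl, i)
  stopifnot(nrow(bl) == length(t))
  if (strand == "+") bl$gs else bl$ge - 1L
}

# assemble cigar + seq + pos for reads given their genomic blocks
reads_from_blocks <- function(bl, seqstr) {
  data.table::setorder(bl, i, gs)
  # merge genomically adjacent blocks (zero-length gaps)
  bl[, gap := gs - data.table::shift(ge), by = i]
  bl[, newblk := cumsum(is.na(gap) | gap > 0L), by = i]
  bl <- bl[, .(gs = min(gs), ge = max(ge)), by = .(i, newblk)]
  bl[, piece := substring(seqstr, gs + 1L, ge)]
  bl[, w := ge - gs]
  res <- bl[, .(
    pos = gs[1L],
    cigar = {
      if (.N == 1L) paste0(w, "M")
      else {
        gaps <- gs[-1L] - ge[-.N]
        paste0(paste0(w[-.N], "M", gaps, "N", collapse = ""), w[.N], "M")
      }
    },
    seq = paste(piece, collapse = ""),
    width = sum(w)
  ), by = i]
  res
}

# flip the base at editing sites in-place on a read table of one gene
apply_editing <- function(reads_dt, bl, sites, fractions, strand) {
  if (is.null(sites) || nrow(sites) == 0L) return(reads_dt)
  for (si in seq_len(nrow(sites))) {
    p <- sites$pos_0based[si]
    frac <- fractions[si]
    if (is.na(frac)) next
    cover <- bl[gs <= p & ge > p]
    if (nrow(cover) == 0L) next
    # query offset of the site: bases of the read aligned before this block
    off_before <- bl[, .(i, gs, ge, w = ge - gs)][order(i, gs)]
    off_before[, qoff := cumsum(w) - w, by = i]
    cover <- merge(cover, off_before, by = c("i", "gs", "ge"))
    cover[, at := qoff + (p - gs) + 1L]
    edited <- stats::runif(nrow(cover)) < frac
    # forward-strand substitution for a C-to-U event on the coding strand
    to <- if (strand == "+") "T" else "A"
    idx <- cover$i[edited]
    at <- cover$at[edited]
    if (length(idx)) {
      s <- reads_dt$seq[idx]
      substr(s, at, at) <- to
      reads_dt$seq[idx] <- s
    }
  }
  reads_dt
}

# replicate-level weight perturbation shared by the two assays
replicate_weights <- function(cfg, ann, replicate) {
  with_seed(derive_seed(cfg$seed, replicate * 7L), {
    n <- length(cfg$gene_output)
    out <- cfg$gene_output *
      stats::rlnorm(n, 0, cfg$replicate_noise_sd)
    mrna <- (cfg$gene_output / cfg$gene_te) *
      stats::rlnorm(n, 0, cfg$replicate_noise_sd)
    list(output = out, mrna = mrna, te = out / mrna)
  })
}

# per-(gene or decoy) expected read shares for one assay
read_shares <- function(cfg, ann, weights, lengths) {
  gids <- ann$genes$gene_id
  comp <- ann$genes$compartment
  w <- weights[gids] * lengths[gids]
  share <- numeric(length(gids))
  for (cc in names(cfg$compartment_shares)) {
    sel <- comp == cc
    if (any(sel) && sum(w[sel]) > 0)
      share[sel] <- (1 - cfg$decoy_share) * cfg$compartment_shares[[cc]] *
        w[sel] / sum(w[sel])
  }
  decoys <- ann$refs[grepl("trna_rrna", ann$refs$category), , drop = FALSE]
  if (nrow(decoys) > 0L && cfg$decoy_share > 0) {
    dshare <- cfg$decoy_share * cfg$compartment_shares[decoys$compartment]
    dshare <- dshare / sum(cfg$compartment_shares[decoys$compartment])
  } else {
    dshare <- rep(0, nrow(decoys))
    share <- share / sum(share)   # no decoys: genes take all the mass
  }
  list(gene = stats::setNames(as.numeric(share), gids),
       decoy = stats::setNames(as.numeric(dshare), decoys$seq_id))
}

# ---- Ribo-seq generator -----------------------------------------------------

#' Simulate ribosome-footprint reads
#'
#' Each footprint: a gene is drawn with probability proportional to its
#' translational output weight times its CDS length; an in-frame P-site
#' codon is drawn uniformly over the sense codons (with extra mass
#' `init_peak` on the start codon, and a +-1 nt shift with probability
#' `1 - frame_purity`); a length is drawn from the compartment's size
#' mixture; and the read is placed so that its 3' end lies `d` nt
#' downstream of the P-site first nucleotide (organellar 3'-anchored rule)
#' or so that the P-site sits at the read midpoint (cytosolic rule). Reads
#' spanning exon junctions receive gapped (N) CIGARs. Editing sites are
#' represented in read sequences at the configured per-site Ribo-seq
#' fractions.
#'
#' @param ann A `GenomeAnnotation`.
#' @param cfg A `SimConfig`.
#' @param replicate Replicate index (keys the RNG stream and the
#'   replicate-level weight perturbation).
#' @param sample_id Sample identifier stamped into read names.
#' @return List with `reads` (a read `data.table`) and `truth` (per-gene
#'   table, per-read P-site truth, expected compartment shares, offsets).
#' @export
simulate_riboseq <- function(ann, cfg, replicate = 1L,
                             sample_id = paste0("ribo_", replicate)) {
  validate_sim_config(cfg)
  if (!is.null(cfg$compartment_shares_ribo))
    cfg$compartment_shares <- cfg$compartment_shares_ribo
  wts <- replicate_weights(cfg, ann, replicate)
  ucds <- union_cds(ann)
  cds_len <- vapply(ucds, function(u) u$length, numeric(1))
  shares <- read_shares(cfg, ann, wts$output, cds_len)

  n <- as.integer(cfg$n_ribo_reads)
  units <- c(names(shares$gene), names(shares$decoy))
  probs <- c(shares$gene, shares$decoy)
  set.seed(derive_seed(cfg$seed, replicate * 13L + 1L))
  pick <- if (n > 0L)
    sample.int(length(units), n, replace = TRUE, prob = probs)
  else integer(0)

  gene_rows <- ann$genes
  reads_all <- list(); truth_reads <- list()
  rid0 <- 0L
  for (u in seq_along(units)) {
    idx <- which(pick == u)
    m <- length(idx)
    if (m == 0L) next
    uname <- units[u]
    if (u > length(shares$gene)) {             # decoy reference
      comp <- ann$refs$compartment[ann$refs$seq_id == uname]
      len <- sample_lengths(m, cfg$size_mixture[[comp]])
      maxstart <- ann$refs$length[ann$refs$seq_id == uname] - len
      pos <- floor(stats::runif(m) * pmax(maxstart, 1L))
      dt <- data.table::data.table(
        read_id = paste0(sample_id, ".r", rid0 + seq_len(m)),
        seq_id = uname, pos = as.integer(pos), strand = "+",
        width = len, cigar = paste0(len, "M"),
        seq = substring(ann$sequences[[uname]], pos + 1L, pos + len),
        umi = NA_character_, sample_id = sample_id, assay = "ribo")
      reads_all[[length(reads_all) + 1L]] <- dt
      truth_reads[[length(truth_reads) + 1L]] <- data.table::data.table(
        read_id = dt$read_id, gene_id = NA_character_,
        psite_pos = NA_integer_, in_frame = NA)
      rid0 <- rid0 + m
      next
    }
    gid <- uname
    g <- gene_rows[gene_rows$gene_id == gid, ]
    comp <- g$compartment
    rule <- cfg$offset_rule[[comp]]
    len <- sample_lengths(m, cfg$size_mixture[[comp]])
    L <- cds_len[[gid]]
    n_cod <- L / 3L
    # P-site codon: uniform over sense codons, plus initiation peak
    qcod <- sample.int(n_cod - 1L, m, replace = TRUE) - 1L
    at_start <- stats::runif(m) < cfg$init_peak
    qcod[at_start] <- 0L
    q <- 3L * qcod
    shift <- stats::runif(m) >= cfg$frame_purity
    dirn <- sample(c(-1L, 1L), m, replace = TRUE)
    q[shift] <- pmax(q[shift] + dirn[shift], 0L)
    in_frame <- q %% 3L == 0L

    flank <- cfg$utr_flank
    p_ext <- flank + q
    if (identical(rule$type, "3prime")) {
      d <- offset_for_sizes(rule, len)
      t1 <- p_ext + d
      t0 <- t1 - len
    } else {
      t0 <- p_ext - len %/% 2L
      t1 <- t0 + len
    }
    blocks <- gene_ext_blocks(ann, gid, flank)
    ext_len <- sum(blocks$width)
    t0 <- pmax(t0, 0L); t1 <- pmin(t1, ext_len)
    bl <- map_t_intervals(blocks, g$strand, t0, t1)
    dt <- reads_from_blocks(bl, ann$sequences[[g$seq_id]])
    data.table::setorder(dt, i)
    stopifnot(nrow(dt) == m)

    # editing representation in footprints
    sites <- NULL
    if (!is.null(ann$editing_sites))
      sites <- ann$editing_sites[ann$editing_sites$gene_id == gid, ,
                                 drop = FALSE]
    if (!is.null(sites) && nrow(sites)) {
      fr <- cfg$editing_fraction$ribo[
        match(sites$site_id, cfg$editing_fraction$site_id)]
      dt <- apply_editing(dt, bl, sites, fr, g$strand)
    }

    psite_g <- map_t_pos(blocks, g$strand, p_ext)
    out <- data.table::data.table(
      read_id = paste0(sample_id, ".r", rid0 + seq_len(m)),
      seq_id = g$seq_id, pos = as.integer(dt$pos), strand = g$strand,
      width = as.integer(dt$width), cigar = dt$cigar, seq = dt$seq,
      umi = NA_character_, sample_id = sample_id, assay = "ribo")
    reads_all[[length(reads_all) + 1L]] <- out
    truth_reads[[length(truth_reads) + 1L]] <- data.table::data.table(
      read_id = out$read_id, gene_id = gid,
      psite_pos = as.integer(psite_g), in_frame = in_frame)
    rid0 <- rid0 + m
  }

  reads <- if (length(reads_all)) data.table::rbindlist(reads_all)
           else empty_read_table()
  reads <- annotate_read_category(reads, ann)

  truth_reads <- if (length(truth_reads)) data.table::rbindlist(truth_reads)
                 else NULL
  realized <- table(factor(
    if (is.null(truth_reads)) character(0)
    else truth_reads$gene_id[!is.na(truth_reads$gene_id)],
    levels = gene_rows$gene_id))
  truth <- list(
    genes = data.table::data.table(
      gene_id = gene_rows$gene_id,
      compartment = gene_rows$compartment,
      replicate = replicate,
      true_output = as.numeric(wts$output[gene_rows$gene_id]),
      true_mrna = as.numeric(wts$mrna[gene_rows$gene_id]),
      true_te = as.numeric(wts$te[gene_rows$gene_id]),
      expected_share = as.numeric(shares$gene[gene_rows$gene_id]),
      n_reads = as.integer(realized)),
    reads = truth_reads,
    compartment_shares = cfg$compartment_shares,
    offsets = cfg$offset_rule,
    seed = cfg$seed)
  list(reads = reads, truth = truth)
}

# ---- RNA-seq generator ------------------------------------------------------

rna_isoforms <- function(ann, cfg, gid) {
  g <- ann$genes[ann$genes$gene_id == gid, ]
  ic <- g$intron_count
  flank <- cfg$utr_flank
  if (ic == 0L) {
    bl <- gene_ext_blocks(ann, gid, flank)
    return(list(list(blocks = bl, prob = 1, kept = logical(0))))
  }
  sf <- cfg$splice_fraction[paste0(gid, ".i", seq_len(ic))]
  sf[is.na(sf)] <- 1
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), ic))  # TRUE = intron kept
  lapply(seq_len(nrow(combos)), function(r) {
    kept <- as.logical(combos[r, ])
    p <- prod(ifelse(kept, 1 - sf, sf))
    list(blocks = gene_ext_blocks(ann, gid, flank, keep_introns = kept),
         prob = p, kept = kept)
  })
}

#' Simulate RNA-seq reads
#'
#' Reads are drawn per (gene, isoform) with probability proportional to
#' mRNA weight x isoform probability x isoform length, with uniform start
#' positions, so that per-base coverage is uniform within each isoform.
#' For intron-containing genes the spliced/unspliced state of each intron
#' is drawn according to the configured spliced fraction; spliced reads
#' spanning exon-exon junctions receive gapped CIGARs. Bases at editing
#' sites are edited at the configured per-site RNA fractions. Each molecule
#' carries a random UMI, and a configurable PCR-duplication rate re-emits
#' exact duplicates of already-sampled molecules.
#'
#' @inheritParams simulate_riboseq
#' @return List with `reads` and `truth` (per-gene table, per-intron
#'   spliced fractions, per-site editing fractions, unique-molecule
#'   counts).
#' @export
simulate_rnaseq <- function(ann, cfg, replicate = 1L,
                            sample_id = paste0("rna_", replicate)) {
  validate_sim_config(cfg)
  if (!is.null(cfg$compartment_shares_rna))
    cfg$compartment_shares <- cfg$compartment_shares_rna
  wts <- replicate_weights(cfg, ann, replicate)
  gene_rows <- ann$genes
  gids <- gene_rows$gene_id

  iso <- lapply(gids, function(g) rna_isoforms(ann, cfg, g))
  names(iso) <- gids
  iso_tab <- data.table::rbindlist(lapply(gids, function(g) {
    data.table::data.table(
      gene_id = g,
      iso_idx = seq_along(iso[[g]]),
      prob = vapply(iso[[g]], `[[`, numeric(1), "prob"),
      len = vapply(iso[[g]], function(x) sum(x$blocks$width), numeric(1)))
  }))
  iso_tab[, comp := gene_rows$compartment[match(gene_id, gids)]]
  iso_tab[, w := wts$mrna[gene_id] * prob * len]
  iso_tab[, share := 0]
  for (cc in names(cfg$compartment_shares)) {
    sel <- iso_tab$comp == cc
    if (any(sel) && sum(iso_tab$w[sel]) > 0)
      iso_tab$share[sel] <- (1 - cfg$decoy_share) *
        cfg$compartment_shares[[cc]] * iso_tab$w[sel] / sum(iso_tab$w[sel])
  }
  decoys <- ann$refs[grepl("trna_rrna", ann$refs$category), , drop = FALSE]
  dshare <- cfg$decoy_share * cfg$compartment_shares[decoys$compartment]
  dshare <- dshare / sum(cfg$compartment_shares[decoys$compartment])

  n <- as.integer(cfg$n_rna_reads)
  n_mol <- as.integer(round(n * (1 - cfg$pcr_dup_rate)))
  set.seed(derive_seed(cfg$seed, replicate * 13L + 2L))
  units <- c(paste0(iso_tab$gene_id, "#", iso_tab$iso_idx), decoys$seq_id)
  probs <- c(iso_tab$share, as.numeric(dshare))
  pick <- if (n_mol > 0L)
    sample.int(length(units), n_mol, replace = TRUE, prob = probs)
  else integer(0)

  rlen <- cfg$rna_read_len
  reads_all <- list(); rid0 <- 0L
  for (u in seq_along(units)) {
    idx <- which(pick == u)
    m <- length(idx)
    if (m == 0L) next
    if (u > nrow(iso_tab)) {                  # decoy
      uname <- units[u]
      reflen <- ann$refs$length[ann$refs$seq_id == uname]
      len <- min(rlen, reflen)
      pos <- floor(stats::runif(m) * max(reflen - len, 1L))
      dt <- data.table::data.table(
        read_id = paste0(sample_id, ".r", rid0 + seq_len(m)),
        seq_id = uname, pos = as.integer(pos), strand = "+",
        width = len, cigar = paste0(len, "M"),
        seq = substring(ann$sequences[[uname]], pos + 1L, pos + len),
        umi = random_umis(m, cfg$umi_len),
        sample_id = sample_id, assay = "rna")
      reads_all[[length(reads_all) + 1L]] <- dt
      rid0 <- rid0 + m
      next
    }
    gid <- iso_tab$gene_id[u]
    g <- gene_rows[gene_rows$gene_id == gid, ]
    blocks <- iso[[gid]][[iso_tab$iso_idx[u]]]$blocks
    ilen <- sum(blocks$width)
    len <- min(rlen, ilen)
    t0 <- floor(stats::runif(m) * (ilen - len + 1L))
    t1 <- t0 + len
    bl <- map_t_intervals(blocks, g$strand, t0, t1)
    dt <- reads_from_blocks(bl, ann$sequences[[g$seq_id]])
    data.table::setorder(dt, i)
    sites <- NULL
    if (!is.null(ann$editing_sites))
      sites <- ann$editing_sites[ann$editing_sites$gene_id == gid, ,
                                 drop = FALSE]
    if (!is.null(sites) && nrow(sites)) {
      fr <- cfg$editing_fraction$rna[
        match(sites$site_id, cfg$editing_fraction$site_id)]
      dt <- apply_editing(dt, bl, sites, fr, g$strand)
    }
    out <- data.table::data.table(
      read_id = paste0(sample_id, ".r", rid0 + seq_len(m)),
      seq_id = g$seq_id, pos = as.integer(dt$pos), strand = g$strand,
      width = as.integer(dt$width), cigar = dt$cigar, seq = dt$seq,
      umi = random_umis(m, cfg$umi_len),
      sample_id = sample_id, assay = "rna")
    reads_all[[length(reads_all) + 1L]] <- out
    rid0 <- rid0 + m
  }
  molecules <- if (length(reads_all)) data.table::rbindlist(reads_all)
               else empty_read_table()

  # PCR duplicates: exact re-emissions of sampled molecules (new read ids)
  n_dup <- n - n_mol
  if (n_dup > 0L && nrow(molecules) > 0L) {
    src <- molecules[sample.int(nrow(molecules), n_dup, replace = TRUE)]
    src[, read_id := paste0(sample_id, ".d", seq_len(n_dup))]
    reads <- data.table::rbindlist(list(molecules, src))
  } else reads <- molecules
  reads <- annotate_read_category(reads, ann)

  key <- molecules[, paste(seq_id, pos, strand, width, umi)]
  cnt <- tabulate(pick, nbins = length(units))
  per_gene <- stats::setNames(numeric(length(gids)), gids)
  for (u in seq_len(nrow(iso_tab)))
    per_gene[iso_tab$gene_id[u]] <- per_gene[iso_tab$gene_id[u]] + cnt[u]

  truth <- list(
    genes = data.table::data.table(
      gene_id = gids, compartment = gene_rows$compartment,
      replicate = replicate,
      true_output = as.numeric(wts$output[gids]),
      true_mrna = as.numeric(wts$mrna[gids]),
      true_te = as.numeric(wts$te[gids]),
      n_molecules = as.integer(per_gene)),
    splice_fraction = cfg$splice_fraction,
    editing_fraction = cfg$editing_fraction,
    n_molecules = n_mol,
    n_unique_keys = length(unique(key)),
    seed = cfg$seed)
  list(reads = reads, truth = truth)
}

random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(c("A", "C", "G", "T")[sample.int(4L, n * len, replace = TRUE)],
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

empty_read_table <- function() {
  data.table::data.table(
    read_id = character(), seq_id = character(), pos = integer(),
    strand = character(), width = integer(), cigar = character(),
    seq = character(), umi = character(), sample_id = character(),
    assay = character(), category = character())
}

annotate_read_category <- function(reads, ann) {
  maps <- ref_maps(ann)
  reads$category <- unname(maps$category[reads$seq_id])
  reads
}

# ---- SAM emission -----------------------------------------------------------

#' Write a read table as a SAM file
#'
#' Emits a coordinate-sorted SAM with one `@SQ` line per reference sequence
#' of the annotation, a `@CO` line recording the seed, and the UMI (when
#' present) in the standard `RX` tag.
#'
#' @param reads A read `data.table` as produced by the simulators.
#' @param ann The `GenomeAnnotation` providing reference lengths.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ann, path, seed = NULL) {
  bad <- setdiff(unique(reads$seq_id), ann$refs$seq_id)
  if (length(bad))
    stop("reads reference unknown seq_id(s): ", paste(bad, collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", ann$refs$seq_id, "\tLN:", ann$refs$length),
           paste0("@PG\tID:chlororibo\tPN:chlororibo\tVN:", pkg_version()))
  if (!is.null(seed)) hdr <- c(hdr, paste0("@CO\tseed:", seed))
  if (nrow(reads) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  r <- data.table::as.data.table(reads)
  r[, refo := match(seq_id, ann$refs$seq_id)]
  data.table::setorder(r, refo, pos)
  flag <- ifelse(r$strand == "-", 16L, 0L)
  tags <- ifelse(is.na(r$umi), "", paste0("\tRX:Z:", r$umi))
  rec <- paste0(r$read_id, "\t", flag, "\t", r$seq_id, "\t", r$pos + 1L,
                "\t42\t", r$cigar, "\t*\t0\t0\t", r$seq, "\t*", tags)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rec), con)
  invisible(path)
}
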