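# Orchestration: dataset simulation across conditions, and the full
# analysis pipeline from SAM alignments to the seven result tables.

#' Default leaf-gradient simulation conditions
#'
#' Four developmental stages from leaf base to tip. Cytosolic translation
#' dominates at the base and falls toward the tip as the plastid share
#' rises; plastid genes encoding the gene-expression machinery peak in
#' output early (segment 4), photosynthesis genes peak in young
#' chloroplasts (segment 9), and a PSII-repair-like gene keeps rising to
#' the tip. Translational efficiency peaks early for expression genes and
#' late for photosynthesis genes.
#'
#' @return Named list of per-condition overrides (compartment_shares,
#'   output_multiplier, te_multiplier).
#' @export
leaf_gradient_conditions <- function() {
  expr_genes <- c("rps14", "rpl2", "rpoA", "ycf3")
  photo_genes <- c("rbcL", "atpI", "atpH", "atpF", "atpA", "psaA", "psaB",
                   "petN", "ndhA")
  late_genes <- c("psbA")
  mk <- function(shares, e, p, l, te_e, te_p) {
    out <- c(stats::setNames(rep(e, length(expr_genes)), expr_genes),
             stats::setNames(rep(p, length(photo_genes)), photo_genes),
             stats::setNames(rep(l, length(late_genes)), late_genes))
    te <- c(stats::setNames(rep(te_e, length(expr_genes)), expr_genes),
            stats::setNames(rep(te_p, length(photo_genes)), photo_genes),
            stats::setNames(rep(te_p, length(late_genes)), late_genes))
    list(compartment_shares = shares, output_multiplier = out,
         te_multiplier = te)
  }
  list(
    segment1 = mk(c(plastid = 0.008, mitochondrion = 0.002,
                    nucleus = 0.99), 1.0, 0.3, 0.2, 1.3, 0.5),
    segment4 = mk(c(plastid = 0.24, mitochondrion = 0.01,
                    nucleus = 0.75), 1.6, 0.9, 0.6, 1.5, 0.9),
    segment9 = mk(c(plastid = 0.38, mitochondrion = 0.02,
                    nucleus = 0.60), 0.8, 1.6, 1.3, 0.9, 1.4),
    segment14 = mk(c(plastid = 0.41, mitochondrion = 0.02,
                     nucleus = 0.57), 0.5, 1.2, 1.8, 0.7, 1.5))
}

#' Default bundle-sheath / mesophyll simulation conditions
#'
#' Rubisco- and NDH-related genes are BS-enriched, PSII genes M-enriched;
#' part of each output difference is mRNA-driven and part TE-driven.
#'
#' @return Named list of per-condition overrides.
#' @export
bs_m_conditions <- function() {
  shares <- c(plastid = 0.40, mitochondrion = 0.02, nucleus = 0.58)
  list(
    BS = list(compartment_shares = shares,
              output_multiplier = c(rbcL = 4, ndhA = 4, psbA = 0.5),
              te_multiplier = c(rbcL = 2, ndhA = 2, psbA = 1)),
    M = list(compartment_shares = shares,
             output_multiplier = c(psbA = 2),
             te_multiplier = c(psbA = 2)))
}

# Apply a condition's overrides to a SimConfig. Per-gene multipliers are
# RPKM-faithful: scaling one gene's output k-fold scales its expected
# footprint count k-fold relative to the nuclear-CDS denominator, so the
# compartment's share of reads is rescaled by the weighted-sum change
# rather than diluting the other genes of the compartment. The shares
# given in `compartment_shares` are therefore baseline shares at the
# config's reference weights.
apply_condition <- function(cfg, cond, ann) {
  base <- cfg
  if (!is.null(cond$compartment_shares)) {
    cfg$compartment_shares <- cond$compartment_shares
    base$compartment_shares <- cond$compartment_shares
  }
  if (!is.null(cond$output_multiplier)) {
    m <- cond$output_multiplier
    hit <- intersect(names(m), names(cfg$gene_output))
    cfg$gene_output[hit] <- cfg$gene_output[hit] * m[hit]
  }
  if (!is.null(cond$te_multiplier)) {
    m <- cond$te_multiplier
    hit <- intersect(names(m), names(cfg$gene_te))
    cfg$gene_te[hit] <- cfg$gene_te[hit] * m[hit]
  }
  cfg$compartment_shares_ribo <-
    rescale_shares(cfg$compartment_shares, ribo_weight_sums(ann, cfg),
                   ribo_weight_sums(ann, base))
  cfg$compartment_shares_rna <-
    rescale_shares(cfg$compartment_shares, rna_weight_sums(ann, cfg),
                   rna_weight_sums(ann, base))
  cfg
}

ribo_weight_sums <- function(ann, cfg) {
  ucds <- union_cds(ann)
  len <- vapply(ucds, function(u) u$length, numeric(1))
  w <- cfg$gene_output[ann$genes$gene_id] * len[ann$genes$gene_id]
  tapply(w, ann$genes$compartment, sum)
}

rna_weight_sums <- function(ann, cfg) {
  m <- cfg$gene_output / cfg$gene_te
  meanlen <- vapply(ann$genes$gene_id, function(g) {
    iso <- rna_isoforms(ann, cfg, g)
    sum(vapply(iso, function(x)
      x$prob * sum(x$blocks$width), numeric(1)))
  }, numeric(1))
  w <- m[ann$genes$gene_id] * meanlen
  tapply(w, ann$genes$compartment, sum)
}

rescale_shares <- function(shares, sums_new, sums_old) {
  k <- rep(1, length(shares))
  names(k) <- names(shares)
  common <- intersect(names(shares), names(sums_new))
  ok <- common[sums_old[common] > 0]
  k[ok] <- as.numeric(sums_new[ok] / sums_old[ok])
  out <- shares * k
  out / sum(out)
}

#' Simulate a full multi-sample dataset to disk
#'
#' For every condition x replicate x assay, simulates reads, writes a
#' coordinate-sorted SAM, and records ground truth. Produces a sample
#' sheet, per-gene truth, intron spliced fractions, editing fractions,
#' and expected compartment shares as TSVs alongside the SAMs.
#'
#' @param ann A `GenomeAnnotation`.
#' @param cfg A `SimConfig`.
#' @param dir Output directory.
#' @param conditions Named list of condition overrides (default
#'   [leaf_gradient_conditions()]).
#' @param assays Assays to simulate.
#' @return Invisibly, a list with the sample sheet and truth tables.
#' @export
simulate_dataset <- function(ann, cfg, dir,
                             conditions = leaf_gradient_conditions(),
                             assays = c("ribo", "rna")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- list(); truth_genes <- list()
  cond_names <- names(conditions)
  for (ci in seq_along(conditions)) {
    cfg_c <- apply_condition(cfg, conditions[[ci]], ann)
    for (r in seq_len(cfg$replicates)) {
      rep_key <- (ci - 1L) * cfg$replicates + r
      for (assay in assays) {
        sid <- paste0(cond_names[ci], "_", assay, "_rep", r)
        sim <- if (assay == "ribo")
          simulate_riboseq(ann, cfg_c, replicate = rep_key, sample_id = sid)
        else
          simulate_rnaseq(ann, cfg_c, replicate = rep_key, sample_id = sid)
        path <- file.path(dir, paste0(sid, ".sam"))
        write_sam(sim$reads, ann, path, seed = cfg$seed)
        sheet[[length(sheet) + 1L]] <- data.frame(
          sample_id = sid, assay = assay, condition = cond_names[ci],
          replicate = r, path = path, stringsAsFactors = FALSE)
        tg <- data.table::copy(sim$truth$genes)
        tg[, sample_id := sid]
        tg[, condition := cond_names[ci]]
        truth_genes[[length(truth_genes) + 1L]] <- tg
      }
    }
  }
  sheet <- do.call(rbind, sheet)
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg <- data.table::rbindlist(truth_genes, fill = TRUE)
  utils::write.table(tg, file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sf <- data.frame(intron = names(cfg$splice_fraction),
                   fraction = as.numeric(cfg$splice_fraction))
  utils::write.table(sf, file.path(dir, "truth_splice.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cfg$editing_fraction,
                     file.path(dir, "truth_editing.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(sample_sheet = sheet, truth_genes = tg,
                 truth_splice = sf,
                 truth_editing = cfg$editing_fraction))
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of [run_pipeline()] with its default.
#'
#' @param annotation A `GenomeAnnotation`, or a list with gff3, fasta,
#'   editing_tsv, compartments, categories passed to [read_annotation()].
#' @param sample_sheet data.frame or TSV path (see [read_sample_sheet()]).
#' @param out_dir Output directory for the result tables.
#' @param min_len,max_len Footprint length bounds (nt).
#' @param metagene_window Metagene half-window (nt).
#' @param min_support Minimum reads per size class for offset inference.
#' @param min_overhang Junction overhang (nt).
#' @param junction_window Junction-reference window (nt).
#' @param splice_tol Consensus tolerance between splice estimators.
#' @param min_mrna_len Minimum transcript length for quantitative mRNA.
#' @param min_reads_editing,min_samples_editing Editing filter thresholds.
#' @param k Named cluster counts for output/mrna/te dynamics.
#' @param dedup Deduplicate RNA-seq reads by UMI.
#' @param seed Seed recorded in output headers.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(annotation, sample_sheet, out_dir,
                            min_len = 18L, max_len = 40L,
                            metagene_window = 50L, min_support = 50L,
                            min_overhang = 5L, junction_window = 100L,
                            splice_tol = 0.10, min_mrna_len = 150L,
                            min_reads_editing = 100L,
                            min_samples_editing = 2L,
                            k = c(output = 4L, mrna = 4L, te = 5L),
                            dedup = TRUE, seed = 1L) {
  if (min_len > max_len)
    stop("invalid length bounds: min_len exceeds max_len")
  structure(list(
    annotation = annotation, sample_sheet = sample_sheet,
    out_dir = out_dir, min_len = min_len, max_len = max_len,
    metagene_window = metagene_window, min_support = min_support,
    min_overhang = min_overhang, junction_window = junction_window,
    splice_tol = splice_tol, min_mrna_len = min_mrna_len,
    min_reads_editing = min_reads_editing,
    min_samples_editing = min_samples_editing,
    k = k, dedup = dedup, seed = seed), class = "PipelineConfig")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  keep <- config[setdiff(names(config),
                         c("annotation", "sample_sheet", "out_dir"))]
  writeLines(deparse(keep), f)
  unname(tools::md5sum(f))
}

write_result_tsv <- function(df, path, config, hash) {
  hdr <- c(paste0("# chlororibo ", pkg_version()),
           paste0("# config_hash: ", hash),
           paste0("# seed: ", config$seed))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest (category-aware SAM reading, footprint length
#' filter, UMI deduplication), P-site calibration (metagene, offsets,
#' P-site assignment, periodicity), splicing (three estimators, consensus
#' gate), quantification (CDS counting, RPKM, TE, compartment partition),
#' dynamics (standardization, UPGMA clustering across conditions), and
#' editing. Writes assignment.tsv, offsets.tsv, metagene.tsv, splice.tsv,
#' expression.tsv, partition.tsv, clusters.tsv, editing.tsv and Newick
#' dendrograms to the
#' output directory, each headed by the package version, a configuration
#' hash, and the seed. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A `PipelineConfig`.
#' @return Result bundle: offsets, frame distribution, splice gate,
#'   expression table, partitions, cluster assignments, editing quants,
#'   and the per-stage log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  ann <- config$annotation
  if (!inherits(ann, "GenomeAnnotation"))
    ann <- read_annotation(ann$gff3, ann$fasta, ann$editing_tsv,
                           compartments = ann$compartments,
                           categories = ann$categories)
  ss <- config$sample_sheet
  if (is.character(ss)) ss <- read_sample_sheet(ss)
  missing <- ss$path[!file.exists(ss$path)]
  if (length(missing))
    stop("ingest: sample file(s) not found: ",
         paste(missing, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }

  # ---- ingest
  samples <- list(); assign_rows <- list()
  for (i in seq_len(nrow(ss))) {
    rd <- tryCatch(
      read_alignments(ss$path[i], ann, sample_id = ss$sample_id[i],
                      assay = ss$assay[i]),
      error = function(e) stop("ingest: ", conditionMessage(e)))
    n0 <- nrow(rd)
    if (ss$assay[i] == "ribo") {
      rd <- filter_length(rd, config$min_len, config$max_len)
      note("ingest: ", ss$sample_id[i], ": ", n0, " alignments, ",
           nrow(rd), " within [", config$min_len, ",", config$max_len,
           "] nt")
    } else {
      if (config$dedup && !anyNA(rd$umi) && nrow(rd) > 0L)
        rd <- dedup_umi(rd)
      note("ingest: ", ss$sample_id[i], ": ", n0, " alignments, ",
           nrow(rd), " after UMI deduplication")
    }
    samples[[ss$sample_id[i]]] <- rd
    asum <- assignment_summary(rd)
    asum$sample_id <- ss$sample_id[i]
    assign_rows[[i]] <- asum
  }
  ribo_ids <- ss$sample_id[ss$assay == "ribo"]
  rna_ids <- ss$sample_id[ss$assay == "rna"]
  ribo_pool <- data.table::rbindlist(samples[ribo_ids])
  rna_pool <- data.table::rbindlist(samples[rna_ids])

  # ---- psite
  offsets <- list(); metagene_rows <- list()
  for (comp in c("plastid", "mitochondrion")) {
    mp <- tryCatch(
      metagene_profile(ribo_pool, ann, comp, anchor = "start",
                       end_used = "3prime",
                       window = config$metagene_window),
      warning = function(w) {
        note("psite: ", conditionMessage(w))
        suppressWarnings(metagene_profile(ribo_pool, ann, comp,
                                          anchor = "start",
                                          end_used = "3prime",
                                          window = config$metagene_window))
      })
    if (nrow(mp$counts) > 0L) {
      offsets[[comp]] <- infer_offsets(mp, min_support = config$min_support)
      cc <- data.table::copy(mp$counts)
      cc[, `:=`(compartment = comp, anchor = "start", end_used = "3prime")]
      metagene_rows[[comp]] <- cc
    }
  }
  offsets$nucleus <- centered_offsets()
  offsets <- data.table::rbindlist(offsets, fill = TRUE)
  note("psite: offsets inferred for ",
       sum(offsets$rule == "3prime"), " size classes")
  for (sid in ribo_ids)
    samples[[sid]] <- assign_psites(samples[[sid]], offsets, ann)
  ribo_pool <- data.table::rbindlist(samples[ribo_ids])
  frames <- frame_periodicity(ribo_pool, ann)

  # ---- splicing
  est <- splice_estimates(rna_pool, ann,
                          min_overhang = config$min_overhang,
                          junction_window = config$junction_window)
  gate <- consensus_splice_filter(est, ann, tol = config$splice_tol)
  note("splicing: ", sum(gate$included), "/", nrow(gate),
       " intron genes pass the consensus gate")

  # ---- quantify
  ribo_cts <- lapply(samples[ribo_ids], count_cds_reads, ann = ann,
                     assay = "ribo")
  rna_cts <- lapply(samples[rna_ids], count_cds_reads, ann = ann,
                    assay = "rna")
  expr_rows <- list()
  for (sid in ribo_ids) {
    row <- ss[ss$sample_id == sid, ]
    mate <- ss$sample_id[ss$assay == "rna" & ss$condition == row$condition &
                         ss$replicate == row$replicate]
    if (length(mate) == 1L) {
      ex <- build_expression(ribo_cts[[sid]], rna_cts[[mate]], ann,
                             splice_gate = gate,
                             min_mrna_len = config$min_mrna_len)
    } else {
      ex <- compute_rpkm(ribo_cts[[sid]])[, .(gene_id, compartment,
                                              output_rpkm = rpkm)]
      ex[, `:=`(mrna_rpkm = NA_real_, te = NA_real_, nd_reason = "no_rna")]
    }
    ex[, `:=`(sample_id = sid, condition = row$condition,
              replicate = row$replicate)]
    expr_rows[[sid]] <- ex
  }
  expr <- data.table::rbindlist(expr_rows, use.names = TRUE)
  note("quantify: expression table for ", length(expr_rows), " samples")

  conds <- unique(ss$condition[ss$assay == "ribo"])
  partitions <- data.table::rbindlist(lapply(conds, function(cd) {
    ids <- ss$sample_id[ss$assay == "ribo" & ss$condition == cd]
    pp <- compartment_partition(ribo_cts[ids])
    pp[, condition := cd]
    pp
  }))

  # ---- dynamics (plastid genes across conditions)
  clusters <- NULL; cluster_rows <- list()
  if (length(conds) >= 2L) {
    pl <- expr[compartment == "plastid"]
    for (metric in c("output", "mrna", "te")) {
      val <- switch(metric, output = pl$output_rpkm, mrna = pl$mrna_rpkm,
                    te = pl$te)
      long <- data.table::data.table(gene_id = pl$gene_id,
                                     condition = pl$condition, value = val)
      long <- long[, .(value = mean(value)), by = .(gene_id, condition)]
      sm <- standardize_profiles(long, source_metric = metric)
      kk <- config$k[[metric]]
      if (nrow(sm$z) >= kk && kk >= 1L) {
        ca <- hierarchical_cluster(sm, k = kk)
        ct <- cluster_table(ca)
        ct$metric <- metric
        cluster_rows[[metric]] <- ct
        write_dendrogram(ca, file.path(config$out_dir,
                                       paste0("dendrogram_", metric,
                                              ".nwk")))
        if (is.null(clusters)) clusters <- list()
        clusters[[metric]] <- ca
      }
    }
    note("dynamics: clustered ", length(cluster_rows), " metrics over ",
         length(conds), " conditions")
  }

  # ---- editing
  edit_rows <- lapply(names(samples), function(sid)
    quantify_editing(samples[[sid]], ann))
  equant <- data.table::rbindlist(edit_rows)
  pairing <- data.frame(sample_id = ss$sample_id,
                        pair_id = paste0(ss$condition, "_rep",
                                         ss$replicate),
                        stringsAsFactors = FALSE)
  egate <- filter_editing(equant, min_reads = config$min_reads_editing,
                          min_samples = config$min_samples_editing,
                          pairing = pairing)
  note("editing: ", if (nrow(egate)) sum(egate$included) else 0L,
       " site(s) pass the coverage filter")

  # ---- outputs
  w <- function(df, name) write_result_tsv(df, file.path(config$out_dir,
                                                         name),
                                           config, hash)
  w(do.call(rbind, assign_rows), "assignment.tsv")
  w(offsets, "offsets.tsv")
  w(if (length(metagene_rows)) data.table::rbindlist(metagene_rows)
    else data.frame(), "metagene.tsv")
  gate_out <- merge(attr(gate, "estimates"), gate, by = "gene_id",
                    all.x = TRUE)
  w(gate_out, "splice.tsv")
  w(expr, "expression.tsv")
  w(partitions, "partition.tsv")
  w(if (length(cluster_rows)) do.call(rbind, cluster_rows)
    else data.frame(), "clusters.tsv")
  ee <- if (nrow(equant)) merge(equant, egate[, .(site_id, included)],
                                by = "site_id", all.x = TRUE) else equant
  w(ee, "editing.tsv")
  writeLines(log, file.path(config$out_dir, "run_log.txt"))

  invisible(list(annotation = ann, offsets = offsets, frames = frames,
                 metagene = metagene_rows, splice = gate_out,
                 splice_gate = gate, expression = expr,
                 partition = partitions, clusters = clusters,
                 editing = equant, editing_filter = egate,
                 counts = list(ribo = ribo_cts, rna = rna_cts),
                 log = log))
}
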