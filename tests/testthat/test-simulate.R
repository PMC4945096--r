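# Synthetic-data generator: determinism, genome structure, read geometry,
# length mixtures, editing and duplication models, SAM validity.

test_that("the built-in genome is deterministic and structurally sound", {
  a1 <- sim_genome()
  a2 <- sim_genome()
  expect_identical(a1, a2)
  expect_gte(sum(a1$genes$compartment == "plastid"), 12L)
  expect_gte(nrow(a1$editing_sites), 2L)
  expect_gte(sum(a1$genes$intron_count), 2L)
  expect_equal(sum(a1$genes$intron_count == 2L), 1L)
  expect_lte(sum(nchar(a1$sequences)), 50000L)
})

test_that("every CDS translates cleanly under the standard code", {
  ann <- fixture_ann()
  u <- union_cds(ann)
  for (gid in ann$genes$gene_id) {
    iv <- u[[gid]]$intervals
    iv <- iv[order(iv$start), , drop = FALSE]
    g <- ann$genes[ann$genes$gene_id == gid, ]
    pieces <- substring(ann$sequences[[g$seq_id]], iv$start + 1L, iv$end)
    cds <- paste(pieces, collapse = "")
    if (g$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    expect_equal(nchar(cds) %% 3L, 0L, info = gid)
    aa <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(cds))))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*", info = gid)
    # no internal stops
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)), info = gid)
  }
})

test_that("plastid footprint lengths peak at 30 and 35 nt", {
  rb <- fixture_ribo()
  pl <- rb$reads[category == "plastid_genome"]
  h <- table(pl$width)
  is_local_mode <- function(x) {
    n <- h[as.character(x)]
    all(n > c(h[as.character(x - 1L)], h[as.character(x + 1L)]))
  }
  expect_true(is_local_mode(30))
  expect_true(is_local_mode(35))
})

test_that("simulation is deterministic given a seed, down to SAM bytes", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 9L, n_ribo_reads = 2000, n_rna_reads = 0)
  r1 <- simulate_riboseq(ann, cfg)
  r2 <- simulate_riboseq(ann, cfg)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.sam"); f2 <- file.path(d, "b.sam")
  write_sam(r1$reads, ann, f1, seed = 9L)
  write_sam(r2$reads, ann, f2, seed = 9L)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the reads
  cfg2 <- sim_config(ann, seed = 10L, n_ribo_reads = 2000, n_rna_reads = 0)
  r3 <- simulate_riboseq(ann, cfg2)
  expect_false(identical(r1$reads$pos, r3$reads$pos))
})

test_that("zero requested reads yield an empty set and a valid truth", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 1L, n_ribo_reads = 0, n_rna_reads = 0)
  rb <- simulate_riboseq(ann, cfg)
  expect_equal(nrow(rb$reads), 0L)
  expect_equal(nrow(rb$truth$genes), nrow(ann$genes))
  expect_true(all(rb$truth$genes$n_reads == 0L))
  d <- withr::local_tempdir()
  f <- file.path(d, "empty.sam")
  write_sam(rb$reads, ann, f)
  expect_true(all(grepl("^@", readLines(f))))
})

test_that("3'-anchored geometry: 3' end minus offset is a codon start", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 4L, n_ribo_reads = 8000, n_rna_reads = 0,
                    frame_purity = 1, decoy_share = 0,
                    compartment_shares = c(plastid = 1, mitochondrion = 0,
                                           nucleus = 0))
  rb <- simulate_riboseq(ann, cfg)
  bl <- chlororibo:::read_blocks(rb$reads)
  ends <- chlororibo:::read_end_coords(rb$reads, bl)
  tr <- rb$truth$reads
  d <- 7L
  for (i in sample.int(nrow(rb$reads), 500L)) {
    gid <- tr$gene_id[i]
    strand <- rb$reads$strand[i]
    p <- if (strand == "+") ends$end3[i] - d else ends$end3[i] + d - 1L
    t <- chlororibo:::genomic_to_transcript(ann, gid, p)
    expect_false(is.na(t))
    expect_equal(t %% 3L, 0L)
  }
})

test_that("per-compartment read counts match expected shares within 3 SD", {
  rb <- fixture_ribo()
  cfg_shares <- c(plastid = 0.38, mitochondrion = 0.02, nucleus = 0.60)
  decoy <- 0.05
  reads <- rb$reads
  n <- nrow(reads)
  comp_of_cat <- chlororibo:::category_compartments()
  genome_cats <- c("plastid_genome", "mito_genome", "nuclear_genome")
  for (cat in genome_cats) {
    comp <- comp_of_cat[[cat]]
    p <- (1 - decoy) * cfg_shares[[comp]]
    obs <- sum(reads$category == cat)
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9,
              label = cat)
  }
})

test_that("RNA editing fractions are reproduced within 3 binomial SD", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 12L, n_ribo_reads = 0, n_rna_reads = 6e4,
                    pcr_dup_rate = 0,
                    editing_fraction = data.frame(
                      site_id = c("rpl2_2", "ndhA_451", "rbcL_301"),
                      ribo = c(0.95, 0.95, 0.98),
                      rna = c(0.5, 0.9, 0.95)))
  rn <- simulate_rnaseq(ann, cfg)
  q <- quantify_editing(rn$reads, ann)
  for (i in seq_len(nrow(q))) {
    f <- cfg$editing_fraction$rna[
      cfg$editing_fraction$site_id == q$site_id[i]]
    nn <- q$n_edited[i] + q$n_unedited[i]
    expect_gt(nn, 100)
    sd3 <- 3 * sqrt(f * (1 - f) / nn)
    expect_lt(abs(q$percent_edited[i] / 100 - f), sd3 + 1e-9,
              label = q$site_id[i])
  }
})

test_that("duplication rate 0 gives all-distinct molecule keys", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 2L, n_ribo_reads = 0, n_rna_reads = 5000,
                    pcr_dup_rate = 0)
  rn <- simulate_rnaseq(ann, cfg)
  keys <- rn$reads[, paste(seq_id, pos, strand, width, umi)]
  expect_equal(rn$truth$n_unique_keys, length(keys))
  expect_equal(rn$truth$n_molecules, nrow(rn$reads))
})

test_that("spliced fraction 1 leaves no RNA-seq read over intron bases", {
  ann <- fixture_ann()
  sf <- rep(1, 4)
  names(sf) <- c("atpF.i1", "ndhA.i1", "ycf3.i1", "ycf3.i2")
  cfg <- sim_config(ann, seed = 3L, n_ribo_reads = 0, n_rna_reads = 2e4,
                    splice_fraction = sf)
  rn <- simulate_rnaseq(ann, cfg)
  for (gid in c("atpF", "ndhA", "ycf3")) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    rr <- rn$reads[seq_id == g$seq_id & strand == g$strand]
    bl <- chlororibo:::read_blocks(rr)
    ic <- g$intron_count
    for (k in seq_len(ic)) {
      ii <- chlororibo:::intron_interval(ann, gid, k)
      expect_equal(nrow(bl[s < ii$end & e > ii$start]), 0L,
                   info = paste(gid, k))
    }
  }
})

test_that("emitted SAM passes an external validator and round-trips", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 8L, n_ribo_reads = 1500, n_rna_reads = 0)
  rb <- simulate_riboseq(ann, cfg)
  d <- withr::local_tempdir()
  f <- file.path(d, "x.sam")
  write_sam(rb$reads, ann, f, seed = 8L)
  skip_if(Sys.which("samtools") == "", "samtools not on PATH")
  expect_equal(system2("samtools", c("quickcheck", f)), 0L)
  cnt <- as.integer(system2("samtools", c("view", "-c", f), stdout = TRUE))
  expect_equal(cnt, nrow(rb$reads))
  back <- read_alignments(f, ann)
  expect_equal(nrow(back), nrow(rb$reads))
})
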