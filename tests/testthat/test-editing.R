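# C-to-U editing quantification and the coverage filter.

edit_site <- function(gene_id, seq_id, pos, strand,
                      site_id = "site1", creates_start = FALSE) {
  data.frame(site_id = site_id, gene_id = gene_id, seq_id = seq_id,
             pos_0based = as.integer(pos), strand = strand,
             creates_start = creates_start, stringsAsFactors = FALSE)
}

reads_with_base <- function(seq_id, site_pos, bases, strand = "+",
                            assay = "ribo") {
  data.table::rbindlist(lapply(bases, function(b) {
    s <- paste(c(rep("T", 10), b, rep("T", 19)), collapse = "")
    make_read(seq_id, site_pos - 10L, 30L, strand = strand, seq = s,
              assay = assay)
  }))
}

test_that("plus-strand sites: T edited, C unedited, others excluded", {
  ann <- toy_annotation()
  sites <- edit_site("gplus", "chr", 350L, "+")
  reads <- reads_with_base("chr", 350L, c(rep("T", 60), rep("C", 40),
                                          "A", "N"))
  q <- quantify_editing(reads, ann, sites)
  expect_equal(q$n_edited, 60L)
  expect_equal(q$n_unedited, 40L)
  expect_equal(q$n_other, 2L)
  expect_equal(q$percent_edited, 60)
  # bookkeeping invariant: all site-overlapping reads are accounted for
  expect_equal(q$n_edited + q$n_unedited + q$n_other, 102L)
})

test_that("minus-strand sites read the coding strand via the complement", {
  ann <- toy_annotation()
  sites <- edit_site("gminus", "chr", 2300L, "-")
  reads <- reads_with_base("chr", 2300L, c(rep("A", 70), rep("G", 30)),
                           strand = "-")
  q <- quantify_editing(reads, ann, sites)
  expect_equal(q$n_edited, 70L)
  expect_equal(q$n_unedited, 30L)
  expect_equal(q$percent_edited, 70)
})

test_that("reads with indels across the site land in n_other", {
  ann <- toy_annotation()
  sites <- edit_site("gplus", "chr", 350L, "+")
  clean <- reads_with_base("chr", 350L, "T")
  indel <- make_read("chr", 340L, 30L, cigar = "10M1D19M",
                     seq = paste(rep("T", 29), collapse = ""))
  q <- quantify_editing(data.table::rbindlist(list(clean, indel)), ann,
                        sites)
  expect_equal(q$n_edited, 1L)
  expect_equal(q$n_other, 1L)
})

test_that("sites outside every read give zero counts, not errors", {
  ann <- toy_annotation()
  sites <- edit_site("gplus", "chr", 350L, "+")
  far <- make_read("chr", 900L, 30L)
  q <- quantify_editing(far, ann, sites)
  expect_equal(q$n_edited + q$n_unedited + q$n_other, 0L)
  expect_true(is.na(q$percent_edited))
})

test_that("simulated editing fractions are recovered in both assays", {
  ann <- fixture_ann()
  ef <- data.frame(site_id = c("rpl2_2", "ndhA_451", "rbcL_301"),
                   ribo = c(0.95, 0.95, 0.95),
                   rna = c(0.55, 0.95, 0.95))
  cfg <- sim_config(ann, seed = 61L, n_ribo_reads = 4e5, n_rna_reads = 1e5,
                    pcr_dup_rate = 0, editing_fraction = ef)
  rb <- simulate_riboseq(ann, cfg)
  rn <- simulate_rnaseq(ann, cfg)
  qq <- rbind(quantify_editing(rb$reads, ann),
              quantify_editing(rn$reads, ann))
  for (i in seq_len(nrow(qq))) {
    truth <- ef[[qq$assay[i]]][ef$site_id == qq$site_id[i]]
    n <- qq$n_edited[i] + qq$n_unedited[i]
    expect_gt(n, 40)
    sd3 <- 3 * sqrt(truth * (1 - truth) / n)
    expect_lt(abs(qq$percent_edited[i] / 100 - truth), sd3 + 1e-9,
              label = paste(qq$site_id[i], qq$assay[i]))
  }
})

test_that("no systematic assay bias when true fractions are equal", {
  ann <- fixture_ann()
  ef <- data.frame(site_id = c("rpl2_2", "ndhA_451", "rbcL_301"),
                   ribo = 0.8, rna = 0.8)
  cfg <- sim_config(ann, seed = 62L, n_ribo_reads = 2e5, n_rna_reads = 1e5,
                    pcr_dup_rate = 0, editing_fraction = ef)
  qr <- quantify_editing(simulate_riboseq(ann, cfg)$reads, ann)
  qn <- quantify_editing(simulate_rnaseq(ann, cfg)$reads, ann)
  m <- merge(qr, qn, by = "site_id", suffixes = c("_ribo", "_rna"))
  diffs <- (m$percent_edited_ribo - m$percent_edited_rna) / 100
  pooled_sd <- sqrt(0.8 * 0.2 / (m$n_edited_ribo + m$n_unedited_ribo) +
                    0.8 * 0.2 / (m$n_edited_rna + m$n_unedited_rna))
  expect_lt(mean(abs(diffs)), 3 * mean(pooled_sd))
})

test_that("the coverage filter needs 100 reads in both assays, twice", {
  mk <- function(site, sample, assay, n) data.table::data.table(
    site_id = site, sample_id = sample, assay = assay,
    n_edited = as.integer(round(n * 0.9)),
    n_unedited = as.integer(n - round(n * 0.9)), n_other = 0L,
    percent_edited = 90)
  pairing <- data.frame(
    sample_id = c("s1_ribo", "s1_rna", "s2_ribo", "s2_rna"),
    pair_id = c("s1", "s1", "s2", "s2"))
  # 99 reads everywhere: excluded
  q99 <- data.table::rbindlist(list(
    mk("x", "s1_ribo", "ribo", 99), mk("x", "s1_rna", "rna", 99),
    mk("x", "s2_ribo", "ribo", 99), mk("x", "s2_rna", "rna", 99)))
  f99 <- filter_editing(q99, pairing = pairing)
  expect_false(f99$included)
  # 100 in both assays in two samples: included
  q100 <- data.table::rbindlist(list(
    mk("x", "s1_ribo", "ribo", 100), mk("x", "s1_rna", "rna", 100),
    mk("x", "s2_ribo", "ribo", 100), mk("x", "s2_rna", "rna", 100)))
  f100 <- filter_editing(q100, pairing = pairing)
  expect_true(f100$included)
  # 100 in only one sample: excluded
  q1s <- data.table::rbindlist(list(
    mk("x", "s1_ribo", "ribo", 100), mk("x", "s1_rna", "rna", 100),
    mk("x", "s2_ribo", "ribo", 100), mk("x", "s2_rna", "rna", 12)))
  expect_false(filter_editing(q1s, pairing = pairing)$included)
  # empty input
  f0 <- filter_editing(q99[0])
  expect_equal(nrow(f0), 0L)
})
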