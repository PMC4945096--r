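# CDS counting rules, RPKM units, TE, partition, output and cell-type
# ratios.

# hand-made CountTable for unit checks
mk_ct <- function(counts, lens, comps, assay = "ribo",
                  nuclear_total = 1e6) {
  structure(list(
    counts = data.table::data.table(
      gene_id = names(counts), compartment = comps,
      count = as.integer(counts), counting_region = "full_cds",
      region_length = lens),
    nuclear_cds_total = nuclear_total,
    compartment_reads = c(plastid = 0L, mitochondrion = 0L,
                          nucleus = 0L),
    flagged_fraction = 0, assay = assay, sample_id = "s1"),
    class = "CountTable")
}

test_that("RPKM closed form: 1000 reads, 1 kb, 1e6 nuclear reads -> 1000", {
  ct <- mk_ct(c(g = 1000L, h = 0L), c(1000L, 500L),
              c("plastid", "plastid"))
  r <- compute_rpkm(ct)
  expect_identical(r$rpkm[r$gene_id == "g"], 1000)
  expect_identical(r$rpkm[r$gene_id == "h"], 0)
  # linear in counts
  ct2 <- mk_ct(c(g = 2000L, h = 0L), c(1000L, 500L),
               c("plastid", "plastid"))
  expect_equal(compute_rpkm(ct2)$rpkm[1], 2 * r$rpkm[1])
  ct3 <- mk_ct(c(g = 10L), 1000L, "plastid", nuclear_total = 0)
  expect_error(compute_rpkm(ct3), "nuclear")
})

test_that("P-sites in introns or upstream exons of intron genes don't count", {
  ann <- fixture_ann()
  # atpF (+): exon1, intron, exon2; counting region is the last exon
  ee <- chlororibo:::gene_exons(ann, "atpF")
  mk_ps <- function(p) {
    r <- make_read("Pt", p, 30L)
    r$psite <- as.integer(p)
    r
  }
  in_exon1 <- mk_ps(ee$start[1] + 10L)
  in_intron <- mk_ps(ee$end[1] + 10L)
  in_exon2 <- mk_ps(ee$start[2] + 10L)
  reads <- data.table::rbindlist(list(in_exon1, in_intron, in_exon2))
  ct <- count_cds_reads(reads, ann, assay = "ribo")
  expect_equal(ct$counts$count[ct$counts$gene_id == "atpF"], 1L)
  expect_equal(ct$counts$counting_region[ct$counts$gene_id == "atpF"],
               "last_exon")
  # intronless genes count over the full union CDS either way
  reg_auto <- chlororibo:::counting_regions(ann, "auto")
  reg_full <- chlororibo:::counting_regions(ann, "full_cds")
  intronless <- ann$genes$gene_id[ann$genes$intron_count == 0L]
  expect_equal(reg_auto[gene_id %in% intronless],
               reg_full[gene_id %in% intronless])
})

test_that("RNA reads need >= 50% of aligned bases inside the region", {
  ann <- toy_annotation()
  # gminus CDS [2000, 2600); 40-nt reads
  mostly_in <- make_read("chr", 1979L, 40L, strand = "-", assay = "rna")
  mostly_out <- make_read("chr", 1981L, 40L, strand = "-", assay = "rna")
  ct <- count_cds_reads(data.table::rbindlist(
    list(mostly_in, mostly_out)), ann, assay = "rna")
  # [1979,2019): 19 of 40 bases inside -> dropped;
  # [1981,2021): 21 of 40 -> counted
  expect_equal(ct$counts$count[ct$counts$gene_id == "gminus"], 1L)
})

test_that("TE is output over mRNA with NA propagation", {
  expr <- data.table::data.table(
    gene_id = c("a", "b", "c"), output_rpkm = c(10, 10, 10),
    mrna_rpkm = c(10, 0, NA_real_))
  out <- translational_efficiency(expr)
  expect_equal(out$te, c(1, NA, NA))
})

test_that("partition fractions are exact shares of CDS-mapped footprints", {
  mk_pct <- function(pl, mt, nu) {
    ct <- mk_ct(c(x = 1L), 100L, "plastid")
    ct$compartment_reads <- c(plastid = pl, mitochondrion = mt,
                              nucleus = nu)
    ct
  }
  p <- compartment_partition(mk_pct(1L, 0L, 99L))
  expect_equal(p$fraction[p$compartment == "cytosol"], 0.99)
  expect_equal(p$fraction[p$compartment == "plastid"], 0.01)
  expect_equal(sum(p$fraction), 1, tolerance = 1e-12)
  p2 <- compartment_partition(mk_pct(10L, 0L, 0L))
  expect_equal(p2$fraction, c(0, 1, 0))
  # replicates are summed before fractions are formed
  p3 <- compartment_partition(list(mk_pct(1L, 0L, 3L), mk_pct(3L, 1L, 0L)))
  expect_equal(p3$fraction[p3$compartment == "cytosol"], 3 / 8)
  expect_equal(sum(p3$fraction), 1, tolerance = 1e-12)
})

test_that("simulated compartment shares are recovered within 3 SD", {
  ann <- fixture_ann()
  rb <- fixture_ribo()
  ot <- rbind(infer_offsets(metagene_profile(rb$reads, ann, "plastid")),
              infer_offsets(metagene_profile(rb$reads, ann,
                                             "mitochondrion")),
              centered_offsets())
  pr <- assign_psites(rb$reads, ot, ann)
  ct <- count_cds_reads(pr, ann, assay = "ribo")
  p <- compartment_partition(ct)
  truth <- c(cytosol = 0.60, plastid = 0.38, mitochondrion = 0.02)
  n <- sum(p$n_reads)
  for (cc in names(truth)) {
    sd3 <- 3 * sqrt(truth[[cc]] * (1 - truth[[cc]]) / n)
    expect_lt(abs(p$fraction[p$compartment == cc] - truth[[cc]]), sd3,
              label = cc)
  }
  expect_equal(sum(p$fraction), 1, tolerance = 1e-12)
})

test_that("output ratios against a reference gene track configured weights", {
  expr <- data.table::data.table(
    gene_id = rep(c("a", "b", "c", "d"), each = 2),
    condition = rep(c("s4", "s9"), 4),
    output_rpkm = c(30, 32, 29, 31, 10, 10, 140, 140))
  ann <- fixture_ann()
  rt <- output_ratio(expr, c("a", "b", "c", "d"), reference = "c",
                     conditions = c("s4", "s9"), ann = ann)
  expect_equal(rt$output_ratio[rt$gene_id == "c"], 1)
  expect_equal(rt$output_ratio[rt$gene_id == "a"], 3.1)
  expect_equal(rt$output_ratio[rt$gene_id == "d"], 14)
  expect_error(output_ratio(expr, c("a", "c"), "c", character(0), ann),
               "length")
  expect_error(output_ratio(expr, c("a", "c"), "c", "nope", ann), "no")
})

test_that("identical BS and M tables give unit ratios", {
  e <- data.table::data.table(
    gene_id = c("a", "b"), output_rpkm = c(5, 10), mrna_rpkm = c(5, 5),
    te = c(1, 2))
  cr <- celltype_ratio(data.table::copy(e), data.table::copy(e))
  expect_true(all(cr$table$output_ratio == 1))
  expect_true(all(cr$table$te_ratio == 1))
  expect_equal(cr$mean_te_ratio, 1)
  # zero denominator -> not determined
  e2 <- data.table::copy(e); e2$output_rpkm <- c(0, 10)
  cr2 <- celltype_ratio(e, e2)
  expect_true(is.na(cr2$table$output_ratio[cr2$table$gene_id == "a"]))
})

test_that("overlapping-gene ambiguity is counted to both and flagged", {
  # two plus-strand genes sharing CDS bases
  seqs <- c(chr = paste(rep("ACGT", 500), collapse = ""))
  genes <- data.frame(
    gene_id = c("g1", "g2"), seq_id = "chr", strand = "+",
    compartment = "plastid", tu_id = NA_character_,
    function_category = "other", stoichiometry = NA_real_,
    intron_count = 0L, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("g1", "g2"), rank = 1L,
                      start = c(100L, 250L), end = c(400L, 550L))
  refs <- data.frame(seq_id = "chr", length = 2000L,
                     category = "plastid_genome", compartment = "plastid")
  ann <- chlororibo:::new_annotation(seqs, genes, exons, NULL, NULL, refs)
  r <- make_read("chr", 300L, 30L); r$psite <- 300L
  ct <- count_cds_reads(r, ann, assay = "ribo")
  expect_equal(ct$counts$count, c(1L, 1L))
  expect_equal(ct$flagged_fraction, 1)
  expect_equal(unname(ct$compartment_reads["plastid"]), 1L)
})
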