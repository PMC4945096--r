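# Metagene bookkeeping, offset inference, P-site assignment, periodicity.

test_that("metagene distances follow the 3'-end convention on both strands", {
  ann <- toy_annotation()
  # gplus exon1 starts at 300 (start codon first nt); a 30-nt read with
  # 3' end 7 nt past the anchor occupies [277, 307)
  rplus <- make_read("chr", 277L, 30L)
  mp <- metagene_profile(rplus, ann, "plastid", anchor = "start",
                         end_used = "3prime")
  expect_equal(mp$counts[size == 30 & dist == 7, count], 1L)
  # mirrored on the minus-strand gene: anchor base is 2599 (0-based),
  # a read whose 3'-terminal base is at 2593 has exclusive distance 7
  rminus <- make_read("chr", 2593L, 30L, strand = "-")
  mp2 <- metagene_profile(rminus, ann, "plastid", anchor = "start",
                          end_used = "3prime")
  expect_equal(mp2$counts[size == 30 & dist == 7, count], 1L)
})

test_that("offset inference recovers the mode, ties toward smaller d", {
  mk_profile <- function(counts_dt) {
    structure(list(counts = counts_dt, anchor = "start",
                   compartment = "plastid", end_used = "3prime",
                   window = 50L), class = "MetageneProfile")
  }
  cc <- data.table::data.table(
    size = c(30L, 30L, 30L, 35L, 35L),
    dist = c(7L, 10L, 4L, 7L, 10L),
    count = c(500L, 100L, 50L, 300L, 300L))
  ot <- infer_offsets(mk_profile(cc), min_support = 50)
  expect_equal(ot$d[ot$size == 30], 7L)
  expect_equal(ot$d[ot$size == 35], 7L)   # tie 7 vs 10 -> smaller
  # low-support size falls back to the compartment-wide mode
  cc2 <- rbind(cc, data.table::data.table(size = 28L, dist = 12L,
                                          count = 10L))
  ot2 <- infer_offsets(mk_profile(cc2), min_support = 50)
  expect_true(ot2$fallback_used[ot2$size == 28])
  expect_equal(ot2$d[ot2$size == 28], 7L)
  expect_false(any(ot2$fallback_used[ot2$size != 28]))
})

test_that("size-dependent offsets {28:6, 30:7, 35:7} are recovered exactly", {
  ann <- fixture_ann()
  cfg <- sim_config(
    ann, seed = 7L, n_ribo_reads = 2e4, n_rna_reads = 0, frame_purity = 1,
    size_mixture = list(
      plastid = list(modes = c(28, 30, 35), weights = rep(1 / 3, 3),
                     spread = 0),
      mitochondrion = list(modes = 28, weights = 1, spread = 0),
      nucleus = list(modes = 31, weights = 1, spread = 0)),
    offset_rule = list(
      plastid = list(type = "3prime", d = c(`28` = 6, `30` = 7, `35` = 7)),
      mitochondrion = list(type = "3prime", d = 7),
      nucleus = list(type = "centered")))
  rb <- simulate_riboseq(ann, cfg)
  ot <- infer_offsets(metagene_profile(rb$reads, ann, "plastid"))
  expect_equal(ot$d[match(c(28L, 30L, 35L), ot$size)], c(6L, 7L, 7L))
  expect_false(any(ot$fallback_used))
})

test_that("P-site arithmetic: + strand read [100,130) with d=7 gives 123", {
  ann <- toy_annotation()
  offs <- data.table::data.table(compartment = "plastid", size = 30L,
                                 d = 7L, support = 100L,
                                 fallback_used = FALSE, rule = "3prime")
  rplus <- make_read("chr", 100L, 30L)
  out <- assign_psites(rplus, offs, ann)
  expect_equal(out$psite, 123L)
  # minus strand mirror: read [100,130), 3'-terminal base at 100
  rminus <- make_read("chr", 100L, 30L, strand = "-")
  out2 <- assign_psites(rminus, offs, ann)
  expect_equal(out2$psite, 106L)
  # centered rule: P-site at floor(len/2) from the 5' end
  offc <- centered_offsets("plastid")
  out3 <- assign_psites(rplus, offc, ann)
  expect_equal(out3$psite, 115L)
  out4 <- assign_psites(rminus, offc, ann)
  expect_equal(out4$psite, 129L - 15L)
})

test_that("P-site assignment walks gapped alignments in transcript space", {
  ann <- toy_annotation()
  offs <- data.table::data.table(compartment = "plastid", size = 30L,
                                 d = 7L, support = 100L,
                                 fallback_used = FALSE, rule = "3prime")
  # gplus: exon1 [300,500), exon2 [700,1000); a read with 26 nt at the
  # end of exon1 and 4 nt into exon2: 3' end in exon2, d=7 crosses the
  # junction back into exon1
  r <- make_read("chr", 474L, 30L, cigar = "26M200N4M")
  out <- assign_psites(r, offs, ann)
  # walk 7 aligned bases back from 3' end (703): 703,702,701,700 (4) then
  # 499,498,497 (3) -> P at 497
  expect_equal(out$psite, 497L)
})

test_that("assigning P-sites then re-deriving the 3' distance returns d", {
  rb <- fixture_ribo()
  ann <- fixture_ann()
  ot <- rbind(infer_offsets(metagene_profile(rb$reads, ann, "plastid")),
              infer_offsets(metagene_profile(rb$reads, ann,
                                             "mitochondrion")))
  pr <- assign_psites(rb$reads, ot, ann)
  sel <- pr$category %in% c("plastid_genome", "mito_genome") &
    !is.na(pr$psite) & !grepl("N", pr$cigar)
  ends <- chlororibo:::read_end_coords(pr[sel])
  dist <- ifelse(pr$strand[sel] == "+", ends$end3 - pr$psite[sel],
                 pr$psite[sel] - ends$end3 + 1L)
  comp <- chlororibo:::category_compartments()[pr$category[sel]]
  dexp <- ot$d[match(paste(comp, pr$width[sel]),
                     paste(ot$compartment, ot$size))]
  ok <- !is.na(dexp)
  expect_true(all(dist[ok] == dexp[ok]))
})

test_that("P-sites match simulated truth and frames are pure at purity 1", {
  ann <- fixture_ann()
  cfg <- sim_config(ann, seed = 31L, n_ribo_reads = 2e4, n_rna_reads = 0,
                    frame_purity = 1)
  rb <- simulate_riboseq(ann, cfg)
  ot <- rbind(infer_offsets(metagene_profile(rb$reads, ann, "plastid")),
              infer_offsets(metagene_profile(rb$reads, ann,
                                             "mitochondrion")),
              centered_offsets())
  pr <- assign_psites(rb$reads, ot, ann)
  m <- merge(pr[, .(read_id, psite)], rb$truth$reads, by = "read_id")
  m <- m[!is.na(gene_id)]
  expect_gte(mean(m$psite == m$psite_pos), 0.99)
  fd <- frame_periodicity(pr, ann)
  expect_true(all(abs(fd$frame0 + fd$frame1 + fd$frame2 - 1) < 1e-12))
  expect_true(all(fd$frame0[fd$support > 200] == 1))
})

test_that("frame-0 fraction tracks the configured purity within 3 SD", {
  rb <- fixture_ribo()   # frame_purity 0.9
  ann <- fixture_ann()
  ot <- rbind(infer_offsets(metagene_profile(rb$reads, ann, "plastid")),
              infer_offsets(metagene_profile(rb$reads, ann,
                                             "mitochondrion")),
              centered_offsets())
  pr <- assign_psites(rb$reads, ot, ann)
  fd <- frame_periodicity(pr, ann)
  agg <- fd[support > 1000,
            .(f0 = sum(frame0 * support) / sum(support),
              n = sum(support)), by = compartment]
  for (i in seq_len(nrow(agg))) {
    sd3 <- 3 * sqrt(0.9 * 0.1 / agg$n[i])
    expect_lt(abs(agg$f0[i] - 0.9), sd3 + 0.005, label = agg$compartment[i])
  }
})

test_that("a compartment without anchored reads warns and yields empty", {
  ann <- fixture_ann()
  expect_warning(
    mp <- metagene_profile(chlororibo:::empty_read_table(), ann,
                           "plastid"),
    "no reads")
  expect_equal(nrow(mp$counts), 0L)
  expect_error(infer_offsets(mp), "no start-anchored")
})
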