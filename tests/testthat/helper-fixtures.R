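# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_ann <- function() {
  if (is.null(.fixtures$ann)) .fixtures$ann <- sim_genome()
  .fixtures$ann
}

# a moderate simulated ribo sample reused across tests
fixture_ribo <- function() {
  if (is.null(.fixtures$ribo)) {
    ann <- fixture_ann()
    cfg <- sim_config(ann, seed = 42L, n_ribo_reads = 5e4, n_rna_reads = 0)
    .fixtures$ribo <- simulate_riboseq(ann, cfg)
  }
  .fixtures$ribo
}

fixture_rna <- function() {
  if (is.null(.fixtures$rna)) {
    ann <- fixture_ann()
    cfg <- sim_config(ann, seed = 43L, n_ribo_reads = 0, n_rna_reads = 5e4)
    .fixtures$rna <- simulate_rnaseq(ann, cfg)
  }
  .fixtures$rna
}

# build a read table row by hand (ungapped unless cigar given)
make_read <- function(seq_id, pos, width, strand = "+", cigar = NULL,
                      seq = NULL, umi = NA_character_, read_id = NULL,
                      sample_id = "s1", assay = "ribo",
                      category = "plastid_genome") {
  if (is.null(cigar)) cigar <- paste0(width, "M")
  if (is.null(seq)) seq <- paste(rep("A", width), collapse = "")
  if (is.null(read_id)) {
    .fixtures$rid <- if (is.null(.fixtures$rid)) 1L else .fixtures$rid + 1L
    read_id <- paste0("r", .fixtures$rid)
  }
  data.table::data.table(
    read_id = read_id, seq_id = seq_id, pos = as.integer(pos),
    strand = strand, width = as.integer(width), cigar = cigar, seq = seq,
    umi = umi, sample_id = sample_id, assay = assay, category = category)
}

# minimal annotation with one plus- and one minus-strand gene for
# hand-constructed geometry tests
toy_annotation <- function() {
  seq_len_tot <- 3000L
  seqs <- c(chr = paste(rep("ACGT", seq_len_tot / 4), collapse = ""))
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    seq_id = "chr", strand = c("+", "-"),
    compartment = "plastid",
    tu_id = NA_character_, function_category = "other",
    stoichiometry = NA_real_,
    intron_count = c(1L, 0L), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gplus", "gplus", "gminus"),
    rank = c(1L, 2L, 1L),
    start = c(300L, 700L, 2000L),
    end = c(500L, 1000L, 2600L), stringsAsFactors = FALSE)
  refs <- data.frame(seq_id = "chr", length = seq_len_tot,
                     category = "plastid_genome", compartment = "plastid",
                     stringsAsFactors = FALSE)
  chlororibo:::new_annotation(seqs, genes, exons, NULL, NULL, refs)
}
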