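# Standardization of developmental expression profiles and hierarchical
# clustering (UPGMA on Pearson correlation distance).

#' Standardize per-gene developmental profiles
#'
#' Each gene's profile across conditions is transformed to z-values,
#' z = (x - mean(x)) / sd(x), using the sample standard deviation (n - 1
#' denominator), so that developmental shifts can be compared among genes
#' despite large differences in signal magnitude. Rows containing
#' not-determined values, or with zero standard deviation, are excluded
#' with a reason.
#'
#' @param mat Numeric matrix, genes x conditions (rownames = gene ids); or
#'   a long data.table with gene_id, condition, value columns.
#' @param source_metric Label: "output", "mrna" or "te".
#' @return A `StandardizedMatrix`: list with `z` (matrix of retained
#'   rows), `excluded` (data.frame gene_id, reason), `source_metric`.
#' @export
standardize_profiles <- function(mat, source_metric = "output") {
  if (data.table::is.data.table(mat) || is.data.frame(mat)) {
    dt <- data.table::as.data.table(mat)
    wide <- data.table::dcast(dt, gene_id ~ condition, value.var = "value")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$gene_id
    mat <- m
  }
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  has_na <- apply(mat, 1L, anyNA)
  sds <- apply(mat, 1L, stats::sd)
  zero_sd <- !has_na & (is.na(sds) | sds == 0)
  keep <- !has_na & !zero_sd
  excluded <- data.frame(
    gene_id = rownames(mat)[!keep],
    reason = ifelse(has_na[!keep], "not_determined", "constant_profile"),
    stringsAsFactors = FALSE)
  z <- t(apply(mat[keep, , drop = FALSE], 1L,
               function(x) (x - mean(x)) / stats::sd(x)))
  colnames(z) <- colnames(mat)
  structure(list(z = z, excluded = excluded,
                 source_metric = source_metric),
            class = "StandardizedMatrix")
}

#' Hierarchical clustering of standardized profiles
#'
#' Pairwise distance is 1 - Pearson correlation between gene profiles;
#' agglomeration is unweighted average linkage (UPGMA); the tree is cut
#' into exactly `k` clusters. Rows are ordered lexicographically by gene
#' id before clustering so the result is deterministic regardless of
#' input order.
#'
#' @param sm A `StandardizedMatrix` (or plain z-matrix with rownames).
#' @param k Number of clusters. The developmental data of this system
#'   resolve into about four output and mRNA clusters and five TE
#'   clusters; `k` is user-supplied since no automatic cut rule is
#'   implied.
#' @return A `ClusterAssignment`: list with `labels` (named integer
#'   vector), `tree` (hclust), `k`.
#' @export
hierarchical_cluster <- function(sm, k) {
  z <- if (inherits(sm, "StandardizedMatrix")) sm$z else sm
  stopifnot(is.matrix(z), nrow(z) >= k, k >= 1L)
  z <- z[order(rownames(z)), , drop = FALSE]
  d <- correlation_distance(z)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = k),
            class = "ClusterAssignment")
}

#' 1 - Pearson correlation distance matrix between rows
#' @param z Numeric matrix.
#' @return Symmetric matrix with zero diagonal, values in `[0, 2]`.
#' @export
correlation_distance <- function(z) {
  d <- 1 - stats::cor(t(z))
  d[d < 0] <- 0          # numerical guard
  diag(d) <- 0
  d
}

#' Export a clustering dendrogram as Newick
#'
#' @param ca A `ClusterAssignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(ca, path) {
  phy <- ape::as.phylo(ca$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cluster table (gene, cluster label) for export
#' @param ca A `ClusterAssignment`.
#' @return data.frame gene_id, cluster.
#' @export
cluster_table <- function(ca) {
  data.frame(gene_id = names(ca$labels), cluster = unname(ca$labels),
             stringsAsFactors = FALSE)
}
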