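#' Spearman correlation distance between sample columns
#'
#' d(i,j) = 1 - Spearman rho of columns i and j (not 1 - |rho| and not
#' (1-rho)/2; the transform is recorded in the result's `method`
#' attribute). Rank-based, so any strictly monotone transform of a column
#' leaves its distances unchanged.
#'
#' @param x numeric matrix, items in columns, at least three rows.
#' @return a `dist` object over columns.
#' @export
spearman_distance <- function(x) {
  if (nrow(x) < 3L)
    abort_validation("triomics_input_error",
                     "need at least three rows per column pair")
  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    abort_validation("triomics_constant_column_error",
      sprintf("constant column(s): %s — Spearman correlation undefined",
              paste(colnames(x)[const] %||% which(const), collapse = ",")))
  d <- stats::as.dist(1 - stats::cor(x, method = "spearman"))
  attr(d, "method") <- "1 - spearman"
  d
}

#' Euclidean distance between sample columns
#' @param x numeric matrix, items in columns.
#' @return a `dist` object over columns.
#' @export
euclidean_distance <- function(x) stats::dist(t(x))

#' Agglomerative hierarchical clustering
#'
#' Complete linkage by default (merge heights are then non-decreasing, so
#' the dendrogram has no inversions). Delegates to [stats::hclust()].
#'
#' @param d a `dist` object.
#' @param linkage linkage method (default `"complete"`).
#' @return an `hclust` tree.
#' @export
hcluster <- function(d, linkage = "complete") {
  stopifnot(inherits(d, "dist"))
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into k groups
#' @param hc an `hclust` tree.
#' @param k number of groups (default 2, the two-main-subcluster reading).
#' @return named integer vector of cluster labels.
#' @export
cut_tree <- function(hc, k = 2L) stats::cutree(hc, k = k)

#' Serialize a dendrogram as Newick with merge-height branch lengths
#' @param hc an `hclust` tree.
#' @return single Newick string.
#' @export
as_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    abort_validation("triomics_input_error", "package 'ape' is required")
  ape::write.tree(ape::as.phylo(hc))
}

#' Cluster samples by their dependency odds-ratio profiles
#'
#' The heat-map companion analysis: samples described by their vector of
#' log odds ratios over the 12 two-way combinations, clustered with
#' Euclidean distance and complete linkage (log scale is a display/
#' distance decision, recorded in the result).
#'
#' @param dep a [dependency_analysis()] result.
#' @return list: `hclust` tree, `matrix` (combination x sample log odds
#'   ratios), `scale = "log"`.
#' @export
cluster_by_dependency <- function(dep) {
  m <- stats::xtabs(log(odds_ratio) ~ combo + sample, data = dep)
  hc <- hcluster(euclidean_distance(as.matrix(m)))
  list(hclust = hc, matrix = as.matrix(m), scale = "log")
}
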