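#' @title Binding-mode clustering of fingerprint rows
#' @name clustering
#' @description Euclidean distances between fingerprint rows, agglomerative
#'   hierarchical clustering of the poses, and a cut into binding-mode
#'   classes — the analysis that splits a panel of GluN2B-selective
#'   antagonists into an ifenprodil-like and an EVT-101-like group.
NULL

#' Euclidean distances between fingerprint rows
#'
#' @param m a `fingerprint_matrix` or a plain numeric matrix (ligands as
#'   rows).
#' @return symmetric distance matrix with zero diagonal.
#' @export
row_distances <- function(m) {
  v <- if (inherits(m, "fingerprint_matrix")) m$values else as.matrix(m)
  if (anyNA(v)) {
    numeric_error(paste0(
      "missing values in fingerprint matrix; set a cap (sentinel policy) or ",
      "use drop_missing_columns() before clustering"
    ))
  }
  as.matrix(stats::dist(v, method = "euclidean"))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative merging (via [stats::hclust()]) under the chosen
#' linkage. Complete linkage is the default — the default of the clustered-
#' heatmap tooling this analysis mirrors; single and average are available
#' and the choice is carried on the result.
#'
#' @param d symmetric distance matrix with zero diagonal (n >= 2), e.g. from
#'   [row_distances()].
#' @param linkage "complete" (default), "single" or "average".
#' @return A `pose_dendrogram`: list with `merges` (data.frame `left`,
#'   `right`, `height`; negative entries are leaves, positive entries earlier
#'   merges, as in [stats::hclust()]), `leaf_order`, `labels`, `linkage` and
#'   the underlying `hclust` object.
#' @export
agglomerate <- function(d, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (nrow(d) < 2L) usage_error("need at least 2 items to cluster")
  if (anyNA(d) || any(!is.finite(d))) numeric_error("NaN/Inf in distance matrix")
  if (max(abs(d - t(d))) > 1e-8) usage_error("distance matrix is not symmetric")
  if (max(abs(diag(d))) > 1e-8) usage_error("distance matrix diagonal is not zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("item_", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(
    list(
      merges = data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                          height = hc$height),
      leaf_order = hc$labels[hc$order],
      labels = hc$labels,
      linkage = linkage,
      hclust = hc
    ),
    class = "pose_dendrogram"
  )
}

#' @export
print.pose_dendrogram <- function(x, ...) {
  cat(sprintf("<pose_dendrogram> %d leaves, %s linkage, max height %.3f\n",
              length(x$labels), x$linkage, max(x$merges$height)))
  invisible(x)
}

#' Cut a dendrogram into clusters
#'
#' Two criteria: `fixed_k` cuts into exactly `param` clusters;
#' `relative_height` (the default, `param = 0.5`) removes merges above
#' `param` times the maximum merge height — the "primary clusters" of the
#' tree. A top-level two-group split shows up as exactly 2 clusters at
#' relative height 0.5 whenever the final merge is more than twice as high
#' as every within-group merge.
#'
#' @param dend a `pose_dendrogram`.
#' @param mode "relative_height" or "fixed_k".
#' @param param relative height fraction in (0, 1], or integer k.
#' @return A `cluster_assignment`: `labels` (named integer vector,
#'   ligand_id -> cluster), `k` and a `criterion` description.
#' @export
cut_dendrogram <- function(dend, mode = c("relative_height", "fixed_k"),
                           param = 0.5) {
  mode <- match.arg(mode)
  n <- length(dend$labels)
  if (mode == "fixed_k") {
    k <- as.integer(param)
    if (k < 1L || k > n) usage_error(sprintf("k = %d outside 1..%d", k, n))
    labels <- stats::cutree(dend$hclust, k = k)
    criterion <- sprintf("fixed k = %d", k)
  } else {
    if (param <= 0) usage_error("relative height must be > 0")
    h <- param * max(dend$merges$height)
    labels <- stats::cutree(dend$hclust, h = h)
    criterion <- sprintf("relative height %.3g (cut at %.4g)", param, h)
  }
  structure(
    list(labels = labels, k = length(unique(labels)), criterion = criterion),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d (%s)\n", x$k, x$criterion))
  print(x$labels)
  invisible(x)
}

#' Reorder a fingerprint matrix to dendrogram leaf order
#'
#' Rows follow the pose dendrogram; columns optionally follow a dendrogram
#' of the panel entries (presentation only — column clustering never feeds
#' classification).
#'
#' @param m a `fingerprint_matrix` or matrix.
#' @param row_dend a `pose_dendrogram` over the rows.
#' @param col_dend optional `pose_dendrogram` over the columns.
#' @return the permuted numeric matrix.
#' @export
ordered_matrix <- function(m, row_dend, col_dend = NULL) {
  v <- if (inherits(m, "fingerprint_matrix")) m$values else as.matrix(m)
  v <- v[row_dend$leaf_order, , drop = FALSE]
  if (!is.null(col_dend)) v <- v[, col_dend$leaf_order, drop = FALSE]
  v
}

#' Write a dendrogram as a JSON merge list
#'
#' @param dend a `pose_dendrogram`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_dendrogram_json <- function(dend, file) {
  write_json_report(
    list(
      linkage = dend$linkage,
      labels = dend$labels,
      merges = dend$merges,
      leaf_order = dend$leaf_order
    ),
    file
  )
}

#' Write a cluster assignment as CSV
#'
#' Two columns: `ligand_id`, `cluster`.
#'
#' @param assignment a `cluster_assignment`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_assignment_csv <- function(assignment, file) {
  utils::write.csv(
    data.frame(ligand_id = names(assignment$labels),
               cluster = unname(assignment$labels),
               stringsAsFactors = FALSE),
    file, row.names = FALSE
  )
  invisible(file)
}
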