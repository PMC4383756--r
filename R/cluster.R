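# Lineage assignment by unsupervised structure: correlation distances,
# complete-linkage hierarchical clustering, PCA, and a majority rule over
# the query's nearest subtree.

#' Gene-wise z-scoring
#'
#' Centers and scales each gene across samples (the heat-map convention
#' applied before clustering and PCA). Genes with zero variance are set to
#' zero rather than dropped.
#'
#' @param matrix numeric matrix, genes in rows.
#' @return z-scored matrix.
#' @export
zscore_genes <- function(matrix) {
  v <- unclass(matrix)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  z <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` over the genes of the matrix; 0 on the diagonal,
#' symmetric, in `[0, 2]`.
#'
#' @param matrix numeric matrix, genes in rows, samples in columns.
#' @param samples sample ids to include (default: all columns).
#' @return symmetric distance matrix.
#' @export
pearson_distance_matrix <- function(matrix, samples = colnames(matrix)) {
  v <- unclass(matrix)[, samples, drop = FALSE]
  if (ncol(v) < 2L) stop_data("need at least 2 samples")
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop_data("zero-variance sample(s): %s",
              paste(colnames(v)[sds == 0], collapse = ", "))
  d <- 1 - cor(v)
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering that repeatedly merges the pair of clusters at
#' the smallest inter-cluster distance, with the complete-linkage update
#' `D(A+B, C) = max(D(A, C), D(B, C))`; merge heights are therefore
#' non-decreasing.
#'
#' @param distances symmetric distance matrix with zero diagonal (e.g. from
#'   [pearson_distance_matrix()]).
#' @return an object of class `hclust`.
#' @export
hclust_complete <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 2L) stop_data("need at least 2 samples to cluster")
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop_data("distance matrix must be symmetric")
  hclust(as.dist(distances), method = "complete")
}

#' Principal component analysis of samples
#'
#' Samples are centered gene-wise; components are the leading eigenvectors
#' of the sample covariance, scores their projections, with explained
#' variance fractions in descending order.
#'
#' @param matrix numeric matrix, genes in rows, samples in columns.
#' @param n_components number of components, at most
#'   `min(n_samples - 1, n_genes)`.
#' @return list with `loadings` (genes x components, orthonormal), `scores`
#'   (samples x components), `explained_variance` (fractions, descending).
#' @export
pca_samples <- function(matrix, n_components = 2L) {
  v <- unclass(matrix)
  kmax <- min(ncol(v) - 1L, nrow(v))
  if (n_components > kmax)
    stop_data("n_components (%d) exceeds min(samples - 1, genes) = %d",
              n_components, kmax)
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = expl[seq_len(n_components)])
}

hclust_leaves <- function(hc, node) {
  # node: negative = leaf index, positive = merge row; returns leaf indices
  if (node < 0) return(-node)
  stack <- node
  leaves <- integer()
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    pair <- hc$merge[nd, ]
    for (el in pair) {
      if (el < 0) leaves <- c(leaves, -el) else stack <- c(stack, el)
    }
  }
  leaves
}

#' Assign a query sample to a lineage branch from a dendrogram
#'
#' Looks at the leaves of the subtree the query first merges with and takes
#' the majority branch among their reference labels; if that subtree has no
#' labelled leaves (e.g. the query merged with another query first), walks
#' up the tree to the next merge. Ties are broken by the smallest mean
#' distance from the query to the tied branches' members (requires
#' `distances`), otherwise by label order with a warning.
#'
#' @param dendrogram an `hclust` object from [hclust_complete()].
#' @param query_sample sample label of the query leaf.
#' @param reference_labels named character vector mapping reference sample
#'   ids to branch labels; samples absent from it carry no vote.
#' @param distances optional distance matrix used for tie-breaking.
#' @return list with `branch`, `sibling_samples` (the leaves that voted),
#'   `votes` (table), `merge_height`.
#' @export
assign_lineage <- function(dendrogram, query_sample, reference_labels,
                           distances = NULL) {
  hc <- dendrogram
  qi <- match(query_sample, hc$labels)
  if (is.na(qi)) stop_data("query sample '%s' not in the dendrogram", query_sample)
  # walk up from the query leaf until the sibling subtree has labelled leaves
  node <- -qi
  repeat {
    row <- which(hc$merge[, 1] == node | hc$merge[, 2] == node)
    if (length(row) == 0L)
      stop_data("no labelled reference samples in the tree")
    sibling <- setdiff(hc$merge[row, ], node)
    sib_leaves <- hclust_leaves(hc, sibling)
    sib_samples <- hc$labels[sib_leaves]
    labs <- reference_labels[sib_samples]
    labs <- labs[!is.na(labs)]
    if (length(labs)) break
    node <- row
  }
  votes <- sort(table(labs), decreasing = TRUE)
  top <- names(votes)[votes == max(votes)]
  branch <- top[1]
  if (length(top) > 1L) {
    if (!is.null(distances)) {
      mean_d <- vapply(top, function(b) {
        members <- names(reference_labels)[reference_labels == b]
        members <- intersect(members, sib_samples)
        mean(distances[query_sample, members])
      }, numeric(1))
      branch <- top[which.min(mean_d)]
    } else {
      warning("tied branch vote broken by label order; supply distances for a distance-based tie-break")
    }
  }
  list(branch = branch, sibling_samples = sib_samples, votes = votes,
       merge_height = hc$height[row])
}
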