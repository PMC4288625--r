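# Exploratory structure checks: PCA on samples and agglomerative hierarchical
# clustering with Pearson-correlation distance.

#' Principal component analysis of samples
#'
#' Samples are projected after per-feature centering (no variance scaling),
#' the convention for expression data already equalized by a CoV filter.
#'
#' @param x expression matrix, features x samples.
#' @param n_components number of components to return.
#' @return list with `sample_scores` (samples x n_components),
#'   `variance_fractions`, `feature_loadings` (features x n_components),
#'   `feature_means`, and `component_count`.
#' @export
run_pca <- function(x, n_components = 2) {
  check_expression_matrix(x)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds the matrix rank (", rank, ")")
  }
  total_var <- sum(pc$sdev^2)
  fractions <- pc$sdev^2 / total_var
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  list(sample_scores = scores,
       variance_fractions = fractions[seq_len(n_components)],
       feature_loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       feature_means = pc$center,
       component_count = n_components)
}

#' Agglomerative hierarchical clustering with correlation distance
#'
#' Distance between items is 1 - Pearson r (sample, n-1 denominator), merged
#' by average linkage (UPGMA).
#'
#' @param x expression matrix, features x samples.
#' @param axis cluster `"samples"` (columns) or `"features"` (rows).
#' @return an [stats::hclust] object (merge table, heights, leaf labels).
#' @export
hcluster <- function(x, axis = c("samples", "features")) {
  check_expression_matrix(x)
  axis <- match.arg(axis)
  m <- if (axis == "samples") x else t(x)  # items in columns
  if (ncol(m) < 2) stop("need at least 2 items to cluster")
  v <- apply(m, 2, stats::sd)
  if (any(v == 0)) {
    stop("zero-variance item(s), correlation undefined: ",
         paste(colnames(m)[v == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(m))
  stats::hclust(d, method = "average")
}
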