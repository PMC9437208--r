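#' Principal component embedding of samples
#'
#' PCA of the normalized expression matrix with samples as observations and
#' genes as variables (gene-wise mean-centred, unscaled, via SVD).  Sign
#' convention: within each component the loading of largest magnitude is
#' made positive, so embeddings are reproducible across platforms.
#'
#' @param nm a `normalized_matrix` (see [log_cpm()]) with >= 3 samples, or
#'   a plain genes-by-samples numeric matrix.
#' @param n_components number of components to return (default 2).
#' @return Object of class `sample_embedding`: list with `coords`
#'   (samples x components), `explained` (variance fractions,
#'   non-increasing), `loadings` (genes x components), `condition` (if
#'   known).
#' @export
pca_samples <- function(nm, n_components = 2L) {
  x <- if (inherits(nm, "normalized_matrix")) nm$logcpm else as.matrix(nm)
  condition <- if (inherits(nm, "normalized_matrix")) nm$condition else NULL
  if (ncol(x) < 3L) stop("PCA needs at least 3 samples")
  if (stats::sd(as.vector(x)) == 0)
    stop("expression matrix is constant; PCA is degenerate")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {             # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = coords, explained = explained[seq_len(k)],
                 loadings = load, condition = condition),
            class = "sample_embedding")
}

#' @export
print.sample_embedding <- function(x, ...) {
  cat("<sample_embedding> ", nrow(x$coords), " samples, ",
      ncol(x$coords), " components (",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
      " variance)\n", sep = "")
  invisible(x)
}

#' @export
plot.sample_embedding <- function(x, ...) {
  col <- if (!is.null(x$condition))
    ifelse(x$condition == "case", "firebrick", "steelblue") else "black"
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  invisible(x)
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerative clustering with unweighted average linkage on Euclidean or
#' correlation (1 - Pearson r) distance, producing an ultrametric
#' dendrogram whose merge heights are non-decreasing.  Used to order genes
#' and samples for heatmap display.
#'
#' @param x numeric matrix; items to cluster are rows (`axis = "rows"`) or
#'   columns (`axis = "cols"`).
#' @param axis which margin holds the items.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param zscore row-standardise the matrix first (common for expression
#'   heatmaps); rows with zero variance are left centred at 0.
#' @return Object of class `upgma_dendrogram`: list with `merge`, `height`,
#'   `order` (leaf order), `labels`, and the underlying `hclust` object.
#' @export
upgma_linkage <- function(x, axis = c("rows", "cols"),
                          distance = c("euclidean", "correlation"),
                          zscore = FALSE) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  x <- as.matrix(x)
  if (zscore) {
    sds <- apply(x, 1, stats::sd)
    x <- (x - rowMeans(x)) / ifelse(sds > 0, sds, 1)
  }
  if (axis == "cols") x <- t(x)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  d <- if (distance == "euclidean") stats::dist(x)
       else stats::as.dist(1 - suppressWarnings(stats::cor(t(x))))
  if (any(!is.finite(d)))
    stop("non-finite distances; check for zero-variance items under ",
         "correlation distance")
  hc <- stats::hclust(d, method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("<upgma_dendrogram> ", length(x$order), " leaves, heights [",
      sprintf("%.3g", min(x$height)), ", ", sprintf("%.3g", max(x$height)),
      "]\n", sep = "")
  invisible(x)
}

#' Top genes by absolute PC1 loading
#'
#' Heatmap gene selection: the `k` genes with the largest absolute loading
#' on the first principal component.
#'
#' @param embedding a `sample_embedding` from [pca_samples()].
#' @param k number of genes (default 100).
#' @return Character vector of gene ids, strongest first.
#' @export
top_loading_genes <- function(embedding, k = 100L) {
  stopifnot(inherits(embedding, "sample_embedding"))
  l1 <- abs(embedding$loadings[, 1])
  names(sort(l1, decreasing = TRUE))[seq_len(min(k, length(l1)))]
}
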