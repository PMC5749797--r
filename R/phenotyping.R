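#' Spearman distance between sample signatures
#'
#' `D[i, j] = 1 - rho(rank_i, rank_j)` with midrank handling, so identical
#' signatures are at distance 0 and perfectly anti-correlated signatures at
#' distance 2.
#'
#' @param sm a rank-transformed [signature_matrix()] (or a samples x motifs
#'   numeric matrix, which is rank-transformed row-wise first).
#' @return symmetric matrix of class `c("spearman_distance", "matrix")`.
#' @export
spearman_distance <- function(sm) {
  r <- .signature_ranks(sm)
  if (ncol(r) < 3L) stop("need at least 3 motifs")
  csd <- apply(r, 1, sd)
  if (any(csd == 0))
    stop("constant rank row(s) (all ties): ",
         paste(rownames(r)[csd == 0], collapse = ", "))
  # rows are already ranks, so Pearson on rows == Spearman
  D <- 1 - cor(t(r))
  diag(D) <- 0
  class(D) <- c("spearman_distance", class(D))
  D
}

.signature_ranks <- function(sm) {
  if (inherits(sm, "signature_matrix")) {
    if (is.null(sm$ranks)) sm <- rank_transform(sm)
    return(sm$ranks)
  }
  m <- as.matrix(sm)
  t(apply(m, 1, rank, ties.method = "average"))
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerates samples on the Spearman distance with complete linkage
#' (merge height = maximum pairwise distance), which emphasises
#' dissimilarities between phenotype groups.
#'
#' @param D a [spearman_distance()] matrix (or any symmetric distance matrix).
#' @return an [stats::hclust] object.
#' @export
hcluster_signature <- function(D) {
  hclust(as.dist(D), method = "complete")
}

#' Export a dendrogram as Newick with branch heights
#'
#' @param hc an [stats::hclust] object.
#' @param path output path, or `NULL` to return the Newick string.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' K-means classification of sample signatures
#'
#' Best-of-`n_init` Lloyd-type k-means on the rank rows (Euclidean),
#' deterministic for a given seed.
#'
#' @param sm rank-transformed signature matrix (or numeric matrix).
#' @param k number of groups (default 3).
#' @param n_init random restarts (default 25).
#' @param seed RNG seed (default 1234).
#' @return object of class `phenotype_grouping`: list with `assignments`
#'   (named integer vector of group labels in `1..k`), `k`, and the
#'   underlying `kmeans` fit.
#' @export
kmeans_classify <- function(sm, k = 3L, n_init = 25L, seed = 1234L) {
  r <- .signature_ranks(sm)
  if (k > nrow(r)) stop("k (", k, ") exceeds the number of samples (", nrow(r), ")")
  if (k == nrow(r)) {
    # trivial partition: every sample its own group
    return(structure(list(assignments = setNames(seq_len(nrow(r)), rownames(r)),
                          k = as.integer(k), fit = NULL),
                     class = "phenotype_grouping"))
  }
  set.seed(seed)
  fit <- kmeans(r, centers = k, nstart = n_init, iter.max = 100L)
  structure(list(assignments = setNames(fit$cluster, rownames(r)),
                 k = as.integer(k), fit = fit),
            class = "phenotype_grouping")
}

#' @export
print.phenotype_grouping <- function(x, ...) {
  cat(sprintf("<phenotype_grouping> %d samples in %d groups (sizes: %s)\n",
              length(x$assignments), x$k,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' Principal component analysis of sample signatures
#'
#' SVD of the column-centered rank matrix.  Scaling to unit variance is off
#' by default (columns are already on a common rank scale); a flag exposes
#' the unit-variance alternative.
#'
#' @param sm rank-transformed signature matrix (or numeric matrix).
#' @param n_components number of components to keep (default
#'   `min(S, M) - 1` capped at 10).
#' @param scale. unit-variance scale columns first? Default `FALSE`.
#' @return object of class `signature_pca`: list with `scores` (S x C),
#'   `loads` (M x C motif weights), `variance_explained` (fractions,
#'   non-increasing).
#' @export
signature_pca <- function(sm, n_components = NULL, scale. = FALSE) {
  r <- .signature_ranks(sm)
  if (nrow(r) < 3L) stop("need at least 3 samples for PCA")
  pr <- prcomp(r, center = TRUE, scale. = scale.)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  cmax <- sum(pr$sdev > 1e-12)
  if (is.null(n_components)) n_components <- min(cmax, 10L)
  n_components <- min(n_components, cmax)
  idx <- seq_len(n_components)
  structure(list(scores = pr$x[, idx, drop = FALSE],
                 loads = pr$rotation[, idx, drop = FALSE],
                 variance_explained = ve[idx]),
            class = "signature_pca")
}

#' @export
print.signature_pca <- function(x, ...) {
  cat(sprintf("<signature_pca> %d components; variance explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' Motifs with high PCA loads
#'
#' Selects motifs whose absolute load exceeds `threshold` in at least one of
#' the first two components.
#'
#' @param pr a [signature_pca()] result with at least 2 components.
#' @param threshold absolute load cutoff (default 0.05).
#' @return character vector of motif ids.
#' @export
high_load_motifs <- function(pr, threshold = 0.05) {
  stopifnot(inherits(pr, "signature_pca"))
  if (ncol(pr$loads) < 2L) stop("need at least 2 components")
  sel <- abs(pr$loads[, 1]) > threshold | abs(pr$loads[, 2]) > threshold
  rownames(pr$loads)[sel]
}

#' Plot methods
#'
#' `plot.signature_pca` draws the first two component scores, optionally
#' colored by group; `plot.spearman_distance` draws the sample distance map.
#'
#' @param x object to plot.
#' @param groups optional [kmeans_classify()] result or integer vector.
#' @param ... passed to the underlying base graphics call.
#' @method plot signature_pca
#' @export
plot.signature_pca <- function(x, groups = NULL, ...) {
  col <- 1
  if (!is.null(groups)) {
    if (inherits(groups, "phenotype_grouping")) groups <- groups$assignments
    col <- as.integer(groups)[match(rownames(x$scores), names(groups))]
  }
  plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_explained[2]), ...)
  graphics::text(x$scores[, 1], x$scores[, 2], rownames(x$scores),
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' @rdname plot.signature_pca
#' @method plot spearman_distance
#' @export
plot.spearman_distance <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), unclass(x)[, n:1],
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlGnBu"), ...)
  graphics::axis(1, seq_len(n), rownames(x), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(x)), las = 2, cex.axis = 0.7)
  invisible(x)
}
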