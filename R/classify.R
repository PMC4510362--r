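# Functional classification of genomes from their MCR patterns: drop
# modules with identical MCR in every genome, cluster genomes on pairwise
# Euclidean distance with complete linkage, and run a covariance PCA with
# module-loading diagnostics.

#' Drop modules with identical MCR across all genomes
#'
#' Modules whose MCR value (at stored full precision, exact equality) is the
#' same in every genome carry no information for classification and are
#' removed, whatever that shared value is (0 through 100).
#'
#' @param matrix genomes-by-modules numeric MCR matrix with dimnames.
#' @return list with `matrix` (the retained columns, genome order unchanged)
#'   and `removed` (character vector of dropped module IDs).
#' @export
filter_constant_modules <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1, ncol(matrix) >= 1)
  if (nrow(matrix) == 1L)
    warning("single-genome matrix: every module is constant", call. = FALSE)
  varies <- apply(matrix, 2L, function(v) any(v != v[1L]))
  list(matrix = matrix[, varies, drop = FALSE],
       removed = colnames(matrix)[!varies])
}

#' Pairwise Euclidean distances between genome MCR patterns
#'
#' @param matrix genomes-by-modules numeric MCR matrix (>= 2 genomes,
#'   >= 1 module).
#' @return symmetric numeric matrix of distances with zero diagonal and
#'   genome IDs as dimnames.
#' @export
euclidean_distances <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L)
    stop("need at least two genomes for pairwise distances", call. = FALSE)
  if (ncol(matrix) == 0L)
    stop("empty module set: nothing to compute distances over",
         call. = FALSE)
  d <- as.matrix(stats::dist(matrix, method = "euclidean"))
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' Complete-linkage hierarchical clustering of genomes
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the maximum pairwise distance between their members; merge heights are
#' therefore monotone non-decreasing.
#'
#' @param dist a symmetric distance matrix (as from
#'   [euclidean_distances()]) or a `dist` object.
#' @return a [stats::hclust] tree (fields `merge`, `height`, `labels`).
#' @export
complete_linkage_cluster <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (nrow(dist) < 2L)
    stop("need at least two genomes to cluster", call. = FALSE)
  if (any(!is.finite(dist)))
    stop("non-finite distances", call. = FALSE)
  if (max(abs(dist - t(dist))) > 1e-8 || any(abs(diag(dist)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  stats::hclust(stats::as.dist(dist), method = "complete")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; label identity is arbitrary but stable
#' for a fixed input.
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters, between 1 and the number of genomes.
#' @return named integer vector of cluster labels, one per genome.
#' @export
cut_dendrogram <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must be between 1 and the number of genomes (", n, ")",
         call. = FALSE)
  stats::cutree(tree, k = as.integer(k))
}

#' Export a dendrogram to Newick text
#'
#' Leaf labels are the genome IDs and branch lengths are derived from the
#' merge heights (ultrametric tree).
#'
#' @param tree an `hclust` tree.
#' @param path optional file to write; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' PCA of the MCR pattern matrix
#'
#' Column-mean centering with, by default, no variance scaling: all MCRs
#' already share the 0-100 scale, and standardizing would inflate
#' near-constant modules.  Scores, loadings and per-component variance
#' percentages come from the eigendecomposition of the covariance matrix
#' (via [stats::prcomp()]).  Sign convention: each loading column is flipped,
#' together with its scores, so that its largest-magnitude entry is positive.
#'
#' @param matrix genomes-by-modules MCR matrix (>= 3 genomes, >= 2
#'   modules); filter constant modules first.
#' @param scaling `"center_only"` (default) or `"standardize"`.
#' @return an object of class `mcr_pca`: list with `scores` (genomes x
#'   components), `loadings` (modules x components), `variance_explained`
#'   (percentages summing to 100 over all components), `center`, `scaling`.
#' @export
run_pca <- function(matrix, scaling = c("center_only", "standardize")) {
  scaling <- match.arg(scaling)
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 3L || ncol(matrix) < 2L)
    stop("PCA needs at least 3 genomes and 2 modules", call. = FALSE)
  sds <- apply(matrix, 2L, stats::sd)
  if (all(sds == 0))
    stop("constant matrix: filter constant modules first", call. = FALSE)
  if (scaling == "standardize" && any(sds == 0))
    stop("cannot standardize constant modules: filter first", call. = FALSE)
  p <- stats::prcomp(matrix, center = TRUE,
                     scale. = (scaling == "standardize"))
  scores <- p$x
  loadings <- p$rotation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  names(var_pct) <- colnames(loadings)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = var_pct,
                 center = p$center, scaling = scaling),
            class = "mcr_pca")
}

#' @export
print.mcr_pca <- function(x, ...) {
  cat(sprintf("<MCR PCA> %d genomes x %d modules, scaling = %s\n",
              nrow(x$scores), nrow(x$loadings), x$scaling))
  v <- utils::head(x$variance_explained, 5)
  cat("  variance explained:",
      paste(sprintf("%s %.1f%%", names(v), v), collapse = ", "), "\n")
  invisible(x)
}

#' Modules contributing most to a principal axis
#'
#' Ranks modules by absolute loading on the requested component, descending;
#' ties broken by module ID in lexicographic order.
#'
#' @param pca an `mcr_pca` object.
#' @param axis component index (1 = PC1).
#' @param n number of modules to return; values beyond the module count
#'   return the full ranking.
#' @return data.frame with columns `module_id`, `loading`, `rank`.
#' @export
top_loading_modules <- function(pca, axis = 1, n = 10) {
  stopifnot(inherits(pca, "mcr_pca"))
  if (!is.numeric(axis) || length(axis) != 1L || axis < 1 ||
      axis > ncol(pca$loadings))
    stop("axis out of range: computed components are 1..",
         ncol(pca$loadings), call. = FALSE)
  l <- pca$loadings[, axis]
  ord <- order(-abs(l), names(l))
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(module_id = names(l)[ord], loading = unname(l[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
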