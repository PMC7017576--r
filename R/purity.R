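#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing HVG selection: per gene, mean and variance of the
#' raw counts are computed across cells; the expected variance given the
#' mean is fitted by local regression (loess, default span 0.3) on the
#' log10/log10 scale over genes with positive variance; each observation
#' is standardized by the fitted sd and clipped at sqrt(n_cells); genes
#' are ranked by the variance of the clipped standardized values.
#'
#' @param counts raw count matrix, genes x cells (>= 3 cells).
#' @param n number of genes to return (default 2000).
#' @param span loess span for the mean-variance trend (default 0.3).
#' @return character vector of gene names, ordered by decreasing
#'   standardized variance.
#' @export
selectHVGs <- function(counts, n = 2000L, span = 0.3) {
  if (ncol(counts) < 3L) stop("HVG selection needs at least 3 cells")
  if (n > nrow(counts)) {
    warning("n exceeds gene count; returning all genes")
    n <- nrow(counts)
  }
  mu <- rowMeans(counts)
  v <- apply(counts, 1L, stats::var)
  fit_on <- v > 0 & mu > 0
  stdvar <- stats::setNames(numeric(nrow(counts)), rownames(counts))
  if (sum(fit_on) < 10L) stop("too few variable genes to fit a trend")
  fit <- stats::loess(log10(v[fit_on]) ~ log10(mu[fit_on]), span = span,
                      degree = 2)
  exp_sd <- sqrt(10^stats::predict(fit, log10(mu[fit_on])))
  clip <- sqrt(ncol(counts))
  z <- (counts[fit_on, , drop = FALSE] - mu[fit_on]) / exp_sd
  z <- pmin(pmax(z, -clip), clip)
  stdvar[fit_on] <- rowSums(z^2) / (ncol(counts) - 1L)
  names(sort(stdvar, decreasing = TRUE))[seq_len(n)]
}

#' Positive and negative HVG control matrices
#'
#' The positive control keeps the top \code{nFeatures} HVGs; the negative
#' control keeps a seeded uniform sample of \code{nFeatures} genes from
#' the full HVG list (by default its first 2000 entries). Both are
#' expression matrices with as many rows as an activity matrix would
#' have, making them comparable purity baselines.
#'
#' @param expr expression matrix, genes x cells.
#' @param hvgs ordered HVG list from \code{\link{selectHVGs}}.
#' @param nFeatures number of rows for the controls (e.g. 14 for pathway,
#'   113 for TF comparisons).
#' @param seed integer seed for the negative-control sample.
#' @param pool number of leading HVGs the negative control samples from
#'   (default 2000, capped at \code{length(hvgs)}).
#' @return list with matrices \code{positive} and \code{negative}.
#' @export
makeControls <- function(expr, hvgs, nFeatures, seed = 1L, pool = 2000L) {
  pool <- min(pool, length(hvgs))
  if (nFeatures > pool)
    stop("nFeatures exceeds the HVG pool (", pool, ")")
  positive <- expr[hvgs[seq_len(nFeatures)], , drop = FALSE]
  set.seed(seed)
  negative <- expr[sample(hvgs[seq_len(pool)], nFeatures), , drop = FALSE]
  list(positive = positive, negative = negative)
}

#' Default cell-type hierarchy for a PBMC + cell-line mixture
#'
#' Five granularity levels from every annotated type forming its own
#' cluster (level 0) to the two-way split PBMC vs cell line (level 4).
#' Intermediate levels merge the T/NK compartment and the monocytic/
#' dendritic compartment, then the full lymphoid compartment.
#'
#' @param level integer 0..4.
#' @return named character vector mapping cell type to cluster label.
#' @export
defaultHierarchyMap <- function(level) {
  types <- c("CD4 T cells", "CD8 T cells", "NK cells", "B cells",
             "CD14+ monocytes", "FCGR3A+ monocytes", "dendritic cells",
             "HEK cells")
  maps <- list(
    `0` = stats::setNames(types, types),
    `1` = stats::setNames(c("T cells", "T cells", "NK cells", "B cells",
                            "CD14+ monocytes", "FCGR3A+ monocytes",
                            "dendritic cells", "HEK cells"), types),
    `2` = stats::setNames(c("T/NK cells", "T/NK cells", "T/NK cells",
                            "B cells", "myeloid", "myeloid", "myeloid",
                            "HEK cells"), types),
    `3` = stats::setNames(c("lymphoid", "lymphoid", "lymphoid", "lymphoid",
                            "myeloid", "myeloid", "myeloid", "HEK cells"),
                          types),
    `4` = stats::setNames(c(rep("PBMC", 7), "HEK cells"), types))
  m <- maps[[as.character(level)]]
  if (is.null(m)) stop("hierarchy level must be 0..4")
  m
}

#' Load a hierarchy map from JSON
#'
#' Layout: \code{{"2": {"CD4 T cells": "T/NK cells", ...}, ...}} — one
#' object per level mapping cell types to cluster labels.
#'
#' @param path path to the JSON file.
#' @param level which level to extract.
#' @return named character vector (cell type -> cluster label).
#' @export
loadHierarchyMap <- function(path, level) {
  maps <- jsonlite::read_json(path)
  m <- maps[[as.character(level)]]
  if (is.null(m)) stop("level ", level, " absent from ", path)
  unlist(m)
}

#' Relabel annotated cells at a hierarchy level
#'
#' @param annotation data.frame with columns \code{cell_id},
#'   \code{cell_type}.
#' @param map named character vector (cell type -> cluster label), e.g.
#'   from \code{\link{defaultHierarchyMap}}.
#' @return named character vector of cluster labels (names = cell ids).
#' @export
relabelHierarchy <- function(annotation, map) {
  unmapped <- setdiff(unique(annotation$cell_type), names(map))
  if (length(unmapped))
    stop("cell type(s) missing from hierarchy map: ",
         paste(unmapped, collapse = ", "))
  stats::setNames(unname(map[annotation$cell_type]), annotation$cell_id)
}

#' Two-dimensional embedding of a feature matrix
#'
#' Projects cells into 2-D with uniform manifold approximation (UMAP);
#' deterministic under a fixed seed (single-threaded optimization).
#'
#' @param features numeric matrix, features x cells (>= 2 features,
#'   >= 10 cells).
#' @param seed integer seed.
#' @param nNeighbors neighbourhood size (default 15, capped at
#'   n_cells - 1).
#' @return matrix, cells x 2, rownames = cell ids.
#' @export
embed2D <- function(features, seed = 1L, nNeighbors = 15L) {
  if (nrow(features) < 2L || ncol(features) < 10L)
    stop("embedding needs >= 2 features and >= 10 cells")
  if (!all(is.finite(features))) stop("non-finite values in feature matrix")
  set.seed(seed)
  coords <- uwot::umap(t(features),
                       n_neighbors = min(nNeighbors, ncol(features) - 1L),
                       n_threads = 1L, n_sgd_threads = 0L)
  rownames(coords) <- colnames(features)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

#' Silhouette-width cluster purity
#'
#' For each cell, \code{a} is its mean Euclidean distance to the other
#' cells of its cluster and \code{b} the smallest mean distance to the
#' cells of any foreign cluster; the silhouette width is
#' \eqn{s = (b - a) / \max(a, b) \in [-1, 1]}. Cells in singleton
#' clusters get \code{s = 0}. Cluster purity is aggregated in two ways:
#' the unweighted mean over clusters of their mean widths (primary) and
#' the cell-weighted mean.
#'
#' @param coords numeric matrix, cells x d (typically the 2-D embedding).
#' @param labels cluster label per cell (>= 2 clusters).
#' @return a \linkS4class{SilhouetteReport}.
#' @export
silhouettePurity <- function(coords, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stop("one label per coordinate row required")
  clusters <- unique(labels)
  if (length(clusters) < 2L)
    stop("silhouette purity needs at least 2 clusters")
  d <- as.matrix(stats::dist(coords))
  idx <- split(seq_along(labels), labels)
  n <- length(labels)
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(idx[[labels[i]]], i)
    if (!length(own)) { s[i] <- 0; a[i] <- 0; b[i] <- 0; next }
    a[i] <- mean(d[i, own])
    b[i] <- min(vapply(clusters[clusters != labels[i]],
                       function(cl) mean(d[i, idx[[cl]]]), numeric(1)))
    s[i] <- if (max(a[i], b[i]) == 0) 0 else (b[i] - a[i]) / max(a[i], b[i])
  }
  cw <- data.frame(
    cell = if (is.null(rownames(coords))) as.character(seq_len(n))
           else rownames(coords),
    cluster = labels, a = a, b = b, s = s, stringsAsFactors = FALSE)
  cm <- vapply(idx, function(i) mean(s[i]), numeric(1))
  new("SilhouetteReport", cellWidths = cw, clusterMeans = cm,
      globalPurity = mean(cm), weightedPurity = mean(s))
}

#' Cross-protocol consistency of aggregated activities
#'
#' Pearson correlation, per protocol pair, of the activity values over
#' the feature-by-cell-type combinations both protocols share. Pairs
#' sharing fewer than 3 features are skipped with a warning.
#'
#' @param perProtocol named list of matrices (features x cell types) of
#'   per-cell-type mean activities, one per protocol.
#' @return list: \code{pairs} (data.frame protocol_1, protocol_2,
#'   n_shared_features, cor) and \code{median} of the correlations.
#' @export
crossProtocolConsistency <- function(perProtocol) {
  if (length(perProtocol) < 2L) stop("need at least 2 protocols")
  prots <- names(perProtocol)
  rows <- list()
  for (i in seq_len(length(prots) - 1L)) for (j in seq(i + 1L, length(prots))) {
    A <- perProtocol[[i]]; B <- perProtocol[[j]]
    feat <- intersect(rownames(A), rownames(B))
    ct <- intersect(colnames(A), colnames(B))
    if (length(feat) < 3L || !length(ct)) {
      warning("pair ", prots[i], "/", prots[j],
              " skipped: fewer than 3 shared features")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protocol_1 = prots[i], protocol_2 = prots[j],
      n_shared_features = length(feat),
      cor = stats::cor(as.vector(A[feat, ct]), as.vector(B[feat, ct])),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no protocol pair shares enough features")
  tab <- do.call(rbind, rows)
  list(pairs = tab, median = stats::median(tab$cor))
}
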