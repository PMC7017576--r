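#' Scale an expression matrix gene-wise
#'
#' Transforms every gene row to mean 0 and standard deviation 1 across
#' columns (sample standard deviation). Constant rows cannot be scaled and
#' are set to all-zero with a warning.
#'
#' @param mat numeric matrix, genes x samples, at least 2 columns.
#' @return the scaled matrix.
#' @export
scaleGeneWise <- function(mat) {
  if (ncol(mat) < 2L) stop("gene-wise scaling needs at least 2 columns")
  mu <- rowMeans(mat)
  sd <- apply(mat, 1L, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene row(s) set to zero")
    sd[flat] <- 1
  }
  out <- (mat - mu) / sd
  out[flat, ] <- 0
  out
}

#' Pathway activity by weighted footprint sums
#'
#' For every pathway p and signature s the raw activity is
#' \deqn{score(p, s) = \sum_{g \in footprint(p) \cap genes(s)} w_{p,g} \, x_{s,g},}
#' the weighted sum of the signature values of the pathway's footprint
#' genes. With \code{scale = TRUE} each pathway row is subsequently
#' standardised to mean 0, sd 1 across columns; rows with zero spread are
#' dropped with a warning. Pathways sharing no gene with the signatures
#' are dropped with a warning.
#'
#' @param signatures numeric matrix, genes x samples/cells/contrasts
#'   (normalized expression or logFC).
#' @param model a \linkS4class{FootprintModel}.
#' @param scale standardise pathway rows across columns (default TRUE).
#' @return an \linkS4class{ActivityMatrix} with statistic
#'   \code{"footprint_sum"}.
#' @export
footprintScores <- function(signatures, model, scale = TRUE) {
  e <- entries(model)
  pws <- pathways(model)
  genes <- rownames(signatures)
  e <- e[e$gene %in% genes, , drop = FALSE]
  measured <- unique(e$pathway)
  dropped <- setdiff(pws, measured)
  if (length(dropped))
    warning("pathway(s) with no measured footprint gene dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(measured)) stop("no pathway shares a gene with the signatures")
  W <- matrix(0, nrow = length(genes), ncol = length(measured),
              dimnames = list(genes, measured))
  W[cbind(match(e$gene, genes), match(e$pathway, measured))] <- e$weight
  sc <- t(W) %*% signatures
  if (scale && ncol(sc) >= 2L) {
    sd <- apply(sc, 1L, stats::sd)
    flat <- sd == 0
    if (any(flat)) {
      warning("pathway row(s) with zero spread dropped: ",
              paste(rownames(sc)[flat], collapse = ", "))
      sc <- sc[!flat, , drop = FALSE]
    }
    sc <- (sc - rowMeans(sc)) / apply(sc, 1L, stats::sd)
  }
  ActivityMatrix(as.matrix(sc), "footprint_sum")
}

#' Analytic rank-based regulon enrichment score
#'
#' Scores one gene signature against every regulon of a network. The
#' signature's genes are ranked (average ranks on ties) and mapped to
#' standard-normal quantiles \eqn{q_g = \Phi^{-1}(rank_g / (n + 1))}; the
#' normalized enrichment score of a TF is the likelihood-weighted,
#' mode-signed mean of its targets' quantiles,
#' \deqn{NES = \sum_t mode_t \, lik_t \, q_t \; / \; \sqrt{\sum_t lik_t^2},}
#' which is asymptotically standard normal when the signature carries no
#' signal (exchangeable null). TFs with fewer than \code{minTargets}
#' targets present in the signature receive no score.
#'
#' @param signature named numeric vector (gene -> statistic).
#' @param net a \linkS4class{RegulonNetwork}.
#' @param minTargets minimum number of targets present (default 4).
#' @return named numeric vector of NES values, one per scored TF.
#' @export
regulonNES <- function(signature, net, minTargets = 4L) {
  genes <- names(signature)
  if (is.null(genes)) stop("signature must be a named vector")
  n <- length(signature)
  q <- stats::qnorm(rank(signature, ties.method = "average") / (n + 1))
  names(q) <- genes
  e <- edges(net)
  e <- e[e$target %in% genes, , drop = FALSE]
  if (nrow(e) == 0L) return(stats::setNames(numeric(0), character(0)))
  per_tf <- split(e, e$tf)
  per_tf <- per_tf[vapply(per_tf, nrow, integer(1)) >= minTargets]
  vapply(per_tf, function(tf_edges) {
    w <- tf_edges$mode * tf_edges$likelihood
    sum(w * q[tf_edges$target]) / sqrt(sum(tf_edges$likelihood^2))
  }, numeric(1))
}

#' Regulon enrichment scores for a whole matrix
#'
#' Applies \code{\link{regulonNES}} column-wise. Only TFs scored in every
#' column (those passing the minimum-target rule against the shared gene
#' universe) are retained, yielding a dense activity matrix.
#'
#' @param signatures numeric matrix, genes x columns.
#' @param net a \linkS4class{RegulonNetwork}.
#' @param minTargets minimum measured targets per TF (default 4).
#' @return an \linkS4class{ActivityMatrix} with statistic \code{"nes"}.
#' @export
regulonNESMatrix <- function(signatures, net, minTargets = 4L) {
  pruned <- pruneMinTargets(net, rownames(signatures), minTargets)
  if (is.null(pruned)) stop("no TF has enough measured targets")
  cols <- lapply(seq_len(ncol(signatures)), function(j)
    regulonNES(signatures[, j], pruned, minTargets))
  feat <- sort(unique(unlist(lapply(cols, names))))
  sc <- vapply(cols, function(v) v[feat], numeric(length(feat)))
  sc <- matrix(sc, nrow = length(feat),
               dimnames = list(feat, colnames(signatures)))
  if (anyNA(sc)) sc <- sc[stats::complete.cases(sc), , drop = FALSE]
  ActivityMatrix(sc, "nes")
}

#' Consensus enrichment score across multiple regulatory networks
#'
#' Integrates per-network TF scores into one consensus score per TF with a
#' squared-score self-weighted average,
#' \deqn{consensus = \sum_k NES_k^2 \, NES_k / \sum_k NES_k^2,}
#' taken over the networks that report the TF. Networks not reporting a TF
#' are ignored for it; a TF whose scores are all zero gets consensus 0.
#' This weighting favours networks making a confident (large-magnitude)
#' call, the behaviour wanted when most networks are uninformative for a
#' given TF.
#'
#' @param perNetwork named list of named numeric vectors (network ->
#'   (tf -> NES)), e.g. one \code{\link{regulonNES}} result per network.
#' @return named numeric vector of consensus scores.
#' @export
consensusNES <- function(perNetwork) {
  if (length(perNetwork) == 0L) stop("need at least one scored network")
  all_tfs <- unique(unlist(lapply(perNetwork, names)))
  vapply(stats::setNames(all_tfs, all_tfs), function(tf) {
    v <- unlist(lapply(perNetwork, function(x) unname(x[tf])))
    v <- v[!is.na(v)]
    w <- sum(v^2)
    if (w == 0) 0 else sum(v^3) / w
  }, numeric(1))
}

#' Consensus scores over several networks for a signature matrix
#'
#' Runs \code{\link{regulonNESMatrix}} per network, then integrates with
#' \code{\link{consensusNES}} column by column.
#'
#' @param signatures numeric matrix, genes x columns.
#' @param networks list of \linkS4class{RegulonNetwork} objects.
#' @param minTargets minimum measured targets per TF (default 4).
#' @return an \linkS4class{ActivityMatrix} with statistic
#'   \code{"consensus_nes"}.
#' @export
consensusNESMatrix <- function(signatures, networks, minTargets = 4L) {
  per_net <- lapply(networks, function(net)
    scores(regulonNESMatrix(signatures, net, minTargets)))
  cols <- lapply(seq_len(ncol(signatures)), function(j) {
    consensusNES(lapply(per_net, function(m) m[, j]))
  })
  feat <- sort(unique(unlist(lapply(cols, names))))
  sc <- vapply(cols, function(v) {
    out <- v[feat]
    out[is.na(out)] <- 0
    out
  }, numeric(length(feat)))
  sc <- matrix(sc, nrow = length(feat),
               dimnames = list(feat, colnames(signatures)))
  ActivityMatrix(sc, "consensus_nes")
}

#' Recovery-curve AUC scores (top-quantile gene-set enrichment)
#'
#' For every cell, genes are ranked by decreasing raw count (ties broken
#' by input order, a fixed seed-independent rule) and the recovery curve
#' of a gene set counts its members among the top \eqn{i} ranks for
#' \eqn{i = 1 \ldots k}, with \eqn{k = \lceil quantile \cdot n \rceil}. The
#' score is the area under this step curve divided by the maximum area
#' achievable at threshold k, so a set occupying the very top ranks scores
#' 1. Weights, modes and likelihoods of the resource are deliberately
#' ignored; footprint models are first intersected with the measured
#' genes. Sets with no measured member are dropped with a warning.
#'
#' @param counts non-negative matrix of raw counts, genes x cells.
#' @param geneSets a \linkS4class{RegulonNetwork} or
#'   \linkS4class{FootprintModel} (memberships only are used), or a named
#'   list of gene vectors.
#' @param quantile top fraction of the ranking to integrate over
#'   (default 0.05).
#' @return an \linkS4class{ActivityMatrix} with statistic \code{"auc"}.
#' @export
aucellScores <- function(counts, geneSets, quantile = 0.05) {
  if (any(counts < 0)) stop("counts must be non-negative")
  sets <- asGeneSetList(geneSets)
  genes <- rownames(counts)
  sets <- lapply(sets, function(s) intersect(s, genes))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("gene set(s) with no measured member dropped: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no gene set has a measured member")
  n <- nrow(counts)
  k <- ceiling(quantile * n)
  maxArea <- vapply(sets, function(s) sum(pmin(seq_len(k), length(s))),
                    numeric(1))
  sc <- vapply(seq_len(ncol(counts)), function(j) {
    # rank 1 = highest count; stable on ties (input order)
    ord <- order(-counts[, j])
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    names(pos) <- genes
    vapply(seq_along(sets), function(i) {
      h <- pos[sets[[i]]]
      h <- h[h <= k]
      sum(k - h + 1L) / maxArea[[i]]
    }, numeric(1))
  }, numeric(length(sets)))
  sc <- matrix(sc, nrow = length(sets),
               dimnames = list(names(sets), colnames(counts)))
  ActivityMatrix(sc, "auc")
}

asGeneSetList <- function(geneSets) {
  if (is(geneSets, "RegulonNetwork")) {
    e <- edges(geneSets)
    lapply(split(e$target, e$tf), unique)
  } else if (is(geneSets, "FootprintModel")) {
    e <- entries(geneSets)
    lapply(split(e$gene, e$pathway), unique)
  } else if (is.list(geneSets)) {
    geneSets
  } else stop("unsupported gene-set container")
}

#' Permutation GSEA on a contrast signature
#'
#' Standard weighted Kolmogorov-Smirnov gene-set enrichment (weight
#' exponent 1, gene-level statistic = logFC) with a gene-label permutation
#' null: the enrichment score ES is the maximum deviation from zero of the
#' running sum; NES divides ES by the mean absolute same-sign permutation
#' ES; p is the permutation tail fraction. Computation is delegated to
#' fgsea's simple permutation routine. Sets with no gene in the contrast
#' are skipped with a warning.
#'
#' @param contrast named numeric vector of logFC values.
#' @param geneSets named list of gene identifier vectors (unsigned sets).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @return data.frame with columns \code{set}, \code{ES}, \code{NES},
#'   \code{p}, \code{size}.
#' @export
gseaScores <- function(contrast, geneSets, nPerm = 1000L, seed = 1L) {
  if (is.null(names(contrast))) stop("contrast must be a named vector")
  measured <- names(contrast)
  empty <- vapply(geneSets, function(s) !any(s %in% measured), logical(1))
  if (any(empty)) {
    warning("gene set(s) with empty intersection skipped: ",
            paste(names(geneSets)[empty], collapse = ", "))
    geneSets <- geneSets[!empty]
  }
  if (!length(geneSets)) stop("no gene set intersects the contrast")
  set.seed(seed)
  res <- suppressWarnings(fgsea::fgseaSimple(
    pathways = geneSets, stats = contrast, nperm = nPerm,
    minSize = 1L, maxSize = length(contrast), gseaParam = 1, nproc = 0L))
  out <- data.frame(set = res$pathway, ES = res$ES, NES = res$NES,
                    p = res$pval, size = res$size,
                    stringsAsFactors = FALSE)
  out[match(names(geneSets), out$set), , drop = FALSE]
}
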