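#' @import methods
NULL

CONFIDENCE_LEVELS <- c("A", "B", "C", "D", "E")

#' RegulonNetwork: signed, likelihood-weighted TF-target interactions
#'
#' Container for a regulon resource: a table of signed transcription factor
#' (TF) to target-gene interactions, each carrying a mode of regulation
#' (+1 activation, -1 repression), an interaction likelihood in (0, 1], and a
#' curated confidence level from A (most reliable) to E. An optional per-TF
#' summary confidence table can be attached; when absent, a TF's summary
#' confidence is the best (closest to A) confidence among its interactions.
#'
#' @slot edges data.frame with columns \code{tf}, \code{target},
#'   \code{mode}, \code{likelihood}, \code{confidence}.
#' @slot tfConfidence named character vector of per-TF summary confidence
#'   levels, or an empty vector when not supplied.
#' @slot name single label for the network (e.g. a tissue, for
#'   multi-network consensus scoring).
#'
#' @exportClass RegulonNetwork
setClass("RegulonNetwork",
  representation(edges = "data.frame", tfConfidence = "character",
                 name = "character"))

setValidity("RegulonNetwork", function(object) {
  e <- object@edges
  required <- c("tf", "target", "mode", "likelihood", "confidence")
  if (!all(required %in% names(e)))
    return(paste("edges must have columns:", paste(required, collapse = ", ")))
  if (nrow(e) == 0L) return("network has no edges")
  if (!all(e$mode %in% c(-1, 1))) return("mode must be -1 or +1")
  if (!all(e$likelihood > 0 & e$likelihood <= 1))
    return("likelihood must lie in (0, 1]")
  if (!all(e$confidence %in% CONFIDENCE_LEVELS))
    return("confidence must be one of A-E")
  key <- paste(e$tf, e$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- e[duplicated(key), , drop = FALSE]
    return(paste("duplicate (tf, target) pairs:",
                 paste(unique(paste(d$tf, d$target, sep = "->")),
                       collapse = ", ")))
  }
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})

RegulonNetwork <- function(edges, name = "network", tfConfidence = character()) {
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  edges$mode <- as.numeric(edges$mode)
  edges$likelihood <- as.numeric(edges$likelihood)
  if (is.null(edges$confidence)) edges$confidence <- "E"
  edges$confidence <- as.character(edges$confidence)
  rownames(edges) <- NULL
  new("RegulonNetwork", edges = edges, name = name,
      tfConfidence = tfConfidence)
}

#' FootprintModel: pathway footprint gene sets with weights
#'
#' A footprint model assigns to each pathway a set of downstream
#' (footprint) genes whose expression responds to pathway activity. Each
#' entry carries a signed weight (strength and direction of regulation) and
#' a responsiveness rank ordering the genes by the strength of their
#' response upon pathway perturbation (1 = most responsive), which supports
#' top-N footprint subsetting.
#'
#' @slot entries data.frame with columns \code{pathway}, \code{gene},
#'   \code{weight}, \code{responsiveness_rank}.
#'
#' @exportClass FootprintModel
setClass("FootprintModel", representation(entries = "data.frame"))

setValidity("FootprintModel", function(object) {
  e <- object@entries
  required <- c("pathway", "gene", "weight", "responsiveness_rank")
  if (!all(required %in% names(e)))
    return(paste("entries must have columns:", paste(required, collapse = ", ")))
  if (nrow(e) == 0L) return("model has no entries")
  if (!all(is.finite(e$weight))) return("weights must be finite")
  if (!all(e$responsiveness_rank >= 1)) return("responsiveness_rank must be >= 1")
  dup <- vapply(split(e$responsiveness_rank, e$pathway),
                function(r) anyDuplicated(r) > 0L, logical(1))
  if (any(dup))
    return(paste("duplicated responsiveness_rank within pathway:",
                 paste(names(dup)[dup], collapse = ", ")))
  TRUE
})

FootprintModel <- function(entries) {
  entries$pathway <- as.character(entries$pathway)
  entries$gene <- as.character(entries$gene)
  entries$weight <- as.numeric(entries$weight)
  entries$responsiveness_rank <- as.integer(entries$responsiveness_rank)
  rownames(entries) <- NULL
  new("FootprintModel", entries = entries)
}

#' ActivityMatrix: feature-by-sample activity scores
#'
#' Rows are features (TFs or pathways), columns are samples, cells or
#' contrasts; entries are activity scores produced by one of the five
#' scoring statistics. The statistic tag records which.
#'
#' @slot scores numeric matrix (features x columns).
#' @slot statistic one of \code{"footprint_sum"}, \code{"nes"},
#'   \code{"consensus_nes"}, \code{"auc"}, \code{"gsea_nes"}.
#'
#' @exportClass ActivityMatrix
setClass("ActivityMatrix",
  representation(scores = "matrix", statistic = "character"))

ACTIVITY_STATISTICS <- c("footprint_sum", "nes", "consensus_nes", "auc",
                         "gsea_nes")

setValidity("ActivityMatrix", function(object) {
  if (!is.numeric(object@scores)) return("scores must be numeric")
  if (is.null(rownames(object@scores))) return("scores must have feature rownames")
  if (!all(is.finite(object@scores))) return("scores must be finite")
  if (length(object@statistic) != 1L ||
      !object@statistic %in% ACTIVITY_STATISTICS)
    return(paste("statistic must be one of:",
                 paste(ACTIVITY_STATISTICS, collapse = ", ")))
  TRUE
})

ActivityMatrix <- function(scores, statistic) {
  new("ActivityMatrix", scores = scores, statistic = statistic)
}

#' ContrastMatrix: genes-by-contrasts log fold changes
#'
#' Summarises perturbation experiments as per-gene log fold changes
#' (perturbed minus control). A logFC of exactly zero encodes a gene that
#' is not covered (not measured) in that contrast; the per-contrast count
#' of nonzero entries is the contrast's gene coverage.
#'
#' @slot logFC numeric matrix, genes x contrasts.
#'
#' @exportClass ContrastMatrix
setClass("ContrastMatrix", representation(logFC = "matrix"))

setValidity("ContrastMatrix", function(object) {
  if (!is.numeric(object@logFC)) return("logFC must be numeric")
  if (is.null(rownames(object@logFC)) || is.null(colnames(object@logFC)))
    return("logFC must have gene rownames and contrast colnames")
  if (!all(is.finite(object@logFC))) return("logFC must be finite")
  TRUE
})

ContrastMatrix <- function(logFC) new("ContrastMatrix", logFC = logFC)

#' BenchmarkResult: perturbation-recovery scores, labels and curves
#'
#' Holds the score/label pairs of one benchmark run (positives: the
#' perturbed feature's score in its own contrast; negatives: every other
#' feature-contrast score), the ROC and precision-recall curves swept over
#' all thresholds, their areas, and the metadata the run was computed
#' under (tool, coverage, TF coverage, ...).
#'
#' @slot scores numeric vector of oriented activity scores.
#' @slot labels integer vector (1 positive, 0 negative), same length.
#' @slot roc data.frame with columns \code{fpr}, \code{tpr}.
#' @slot pr data.frame with columns \code{recall}, \code{precision}.
#' @slot auroc area under the ROC curve.
#' @slot auprc area under the precision-recall curve.
#' @slot meta named list of run metadata; always includes
#'   \code{tf_coverage}, the number of distinct perturbed features that
#'   were actually scored, and \code{excluded_targets}, the perturbed
#'   features absent from the gene-set resource.
#'
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
  representation(scores = "numeric", labels = "integer", roc = "data.frame",
                 pr = "data.frame", auroc = "numeric", auprc = "numeric",
                 meta = "list"))

setValidity("BenchmarkResult", function(object) {
  if (length(object@scores) != length(object@labels))
    return("scores and labels must have equal length")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (!any(object@labels == 1L) || !any(object@labels == 0L))
    return("labels must contain both classes")
  if (object@auroc < 0 || object@auroc > 1) return("auroc must lie in [0,1]")
  if (object@auprc < 0 || object@auprc > 1) return("auprc must lie in [0,1]")
  TRUE
})

#' SilhouetteReport: per-cell silhouette widths and global cluster purity
#'
#' For every cell, \code{a} is the mean distance to cells of its own
#' cluster, \code{b} the smallest mean distance to a foreign cluster, and
#' \code{s = (b - a) / max(a, b)} the silhouette width in [-1, 1]. Global
#' purity is the unweighted mean over clusters of their mean widths; the
#' cell-weighted mean is reported alongside.
#'
#' @slot cellWidths data.frame with columns \code{cell}, \code{cluster},
#'   \code{a}, \code{b}, \code{s}.
#' @slot clusterMeans named numeric vector of per-cluster mean widths.
#' @slot globalPurity unweighted mean of the cluster means.
#' @slot weightedPurity cell-weighted mean silhouette width.
#'
#' @exportClass SilhouetteReport
setClass("SilhouetteReport",
  representation(cellWidths = "data.frame", clusterMeans = "numeric",
                 globalPurity = "numeric", weightedPurity = "numeric"))

setValidity("SilhouetteReport", function(object) {
  s <- object@cellWidths$s
  if (any(s < -1 - 1e-12 | s > 1 + 1e-12))
    return("silhouette widths must lie in [-1, 1]")
  TRUE
})
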