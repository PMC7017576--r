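#' Accessors for scActivityBench classes
#'
#' Small accessor layer over the S4 containers: edge and entry tables,
#' feature/TF/pathway identifiers, score and logFC matrices, coverage
#' counts, curve areas and purity summaries.
#'
#' @param object one of the package's S4 objects.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("tfs", function(object) standardGeneric("tfs"))
#' @rdname accessors
#' @export
setGeneric("networkName", function(object) standardGeneric("networkName"))
#' @rdname accessors
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("pathways", function(object) standardGeneric("pathways"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("logFC", function(object) standardGeneric("logFC"))
#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))
#' @rdname accessors
#' @export
setGeneric("auroc", function(object) standardGeneric("auroc"))
#' @rdname accessors
#' @export
setGeneric("auprc", function(object) standardGeneric("auprc"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("prPoints", function(object) standardGeneric("prPoints"))
#' @rdname accessors
#' @export
setGeneric("benchmarkMeta", function(object) standardGeneric("benchmarkMeta"))
#' @rdname accessors
#' @export
setGeneric("cellWidths", function(object) standardGeneric("cellWidths"))
#' @rdname accessors
#' @export
setGeneric("clusterMeans", function(object) standardGeneric("clusterMeans"))
#' @rdname accessors
#' @export
setGeneric("globalPurity", function(object) standardGeneric("globalPurity"))

#' @rdname accessors
setMethod("edges", "RegulonNetwork", function(object) object@edges)
#' @rdname accessors
setMethod("tfs", "RegulonNetwork", function(object) unique(object@edges$tf))
#' @rdname accessors
setMethod("networkName", "RegulonNetwork", function(object) object@name)
#' @rdname accessors
setMethod("entries", "FootprintModel", function(object) object@entries)
#' @rdname accessors
setMethod("pathways", "FootprintModel",
          function(object) unique(object@entries$pathway))
#' @rdname accessors
setMethod("scores", "ActivityMatrix", function(object) object@scores)
#' @rdname accessors
setMethod("statistic", "ActivityMatrix", function(object) object@statistic)
#' @rdname accessors
setMethod("features", "ActivityMatrix",
          function(object) rownames(object@scores))
#' @rdname accessors
setMethod("logFC", "ContrastMatrix", function(object) object@logFC)
#' @rdname accessors
setMethod("coverage", "ContrastMatrix",
          function(object) colSums(object@logFC != 0))
#' @rdname accessors
setMethod("auroc", "BenchmarkResult", function(object) object@auroc)
#' @rdname accessors
setMethod("auprc", "BenchmarkResult", function(object) object@auprc)
#' @rdname accessors
setMethod("rocPoints", "BenchmarkResult", function(object) object@roc)
#' @rdname accessors
setMethod("prPoints", "BenchmarkResult", function(object) object@pr)
#' @rdname accessors
setMethod("benchmarkMeta", "BenchmarkResult", function(object) object@meta)
#' @rdname accessors
setMethod("cellWidths", "SilhouetteReport", function(object) object@cellWidths)
#' @rdname accessors
setMethod("clusterMeans", "SilhouetteReport",
          function(object) object@clusterMeans)
#' @rdname accessors
setMethod("globalPurity", "SilhouetteReport",
          function(object) object@globalPurity)

setMethod("show", "RegulonNetwork", function(object) {
  cat("RegulonNetwork '", object@name, "': ", nrow(object@edges),
      " edges, ", length(tfs(object)), " TFs\n", sep = "")
  lv <- table(factor(object@edges$confidence, levels = CONFIDENCE_LEVELS))
  cat("  edge confidence:",
      paste(names(lv), lv, sep = "=", collapse = " "), "\n")
})

setMethod("show", "FootprintModel", function(object) {
  cat("FootprintModel: ", length(pathways(object)), " pathways, ",
      nrow(object@entries), " footprint entries\n", sep = "")
})

setMethod("show", "ActivityMatrix", function(object) {
  cat("ActivityMatrix [", object@statistic, "]: ",
      nrow(object@scores), " features x ", ncol(object@scores),
      " columns\n", sep = "")
})

setMethod("show", "ContrastMatrix", function(object) {
  cv <- coverage(object)
  cat("ContrastMatrix: ", nrow(object@logFC), " genes x ",
      ncol(object@logFC), " contrasts; coverage ",
      min(cv), "-", max(cv), "\n", sep = "")
})

setMethod("show", "BenchmarkResult", function(object) {
  cat("BenchmarkResult: ", sum(object@labels == 1L), " positives, ",
      sum(object@labels == 0L), " negatives\n",
      "  AUROC ", round(object@auroc, 4), ", AUPRC ",
      round(object@auprc, 4), ", TF coverage ",
      object@meta$tf_coverage, "\n", sep = "")
})

setMethod("show", "SilhouetteReport", function(object) {
  cat("SilhouetteReport: ", nrow(object@cellWidths), " cells, ",
      length(object@clusterMeans), " clusters\n",
      "  global purity (unweighted) ", round(object@globalPurity, 4),
      ", cell-weighted ", round(object@weightedPurity, 4), "\n", sep = "")
})
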