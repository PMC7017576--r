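#' Load a regulon network from a TSV table
#'
#' Reads a tab-separated interaction table with header columns \code{tf},
#' \code{target}, \code{mode}, \code{likelihood} and optionally
#' \code{confidence} (default E when absent). A missing (NA) likelihood is
#' set to 1, the convention for resources that do not quantify interaction
#' confidence. Rows with a mode outside \{-1, +1\} or a likelihood outside
#' (0, 1] are rejected with an error.
#'
#' @param path path to the TSV file.
#' @param name label for the network.
#' @return a \linkS4class{RegulonNetwork}.
#' @export
loadRegulonNetwork <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("tf", "target", "mode", "likelihood")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("network table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$likelihood[is.na(tab$likelihood)] <- 1
  if (!all(tab$mode %in% c(-1, 1)))
    stop("invalid mode value(s); mode must be -1 or +1")
  if (!all(tab$likelihood > 0 & tab$likelihood <= 1))
    stop("invalid likelihood value(s); likelihood must lie in (0, 1]")
  if (is.null(tab$confidence)) tab$confidence <- "E"
  RegulonNetwork(tab[c("tf", "target", "mode", "likelihood", "confidence")],
                 name = name)
}

#' Load a footprint model from a TSV table
#'
#' Expects header columns \code{pathway}, \code{gene}, \code{weight},
#' \code{responsiveness_rank}.
#'
#' @param path path to the TSV file.
#' @return a \linkS4class{FootprintModel}.
#' @export
loadFootprintModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("pathway", "gene", "weight", "responsiveness_rank")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("footprint table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  FootprintModel(tab[required])
}

#' Load unsigned gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, fields set name, description,
#' then members, tab-separated. Members become mode +1, likelihood 1 edges
#' so unsigned collections (e.g. GO terms) plug into the regulon scorers.
#'
#' @param path path to the GMT file.
#' @param name network label.
#' @return a \linkS4class{RegulonNetwork} with all modes +1.
#' @export
loadGMT <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parsed <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    data.frame(tf = f[1], target = unique(f[-(1:2)]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, parsed)
  tab$mode <- 1
  tab$likelihood <- 1
  tab$confidence <- "E"
  RegulonNetwork(tab, name = name)
}

tfSummaryConfidence <- function(net) {
  e <- edges(net)
  if (length(net@tfConfidence)) {
    conf <- net@tfConfidence[tfs(net)]
    if (anyNA(conf)) stop("tfConfidence missing for some TFs")
    return(conf)
  }
  # best (closest to A) edge confidence per TF
  vapply(split(e$confidence, e$tf),
         function(x) CONFIDENCE_LEVELS[min(match(x, CONFIDENCE_LEVELS))],
         character(1))[tfs(net)]
}

#' Filter a regulon network by TF confidence levels
#'
#' Keeps the TFs whose summary confidence level falls in \code{levels}
#' (e.g. \code{c("A","B")} for the high-confidence "AB" combination). The
#' summary level is the supplied per-TF level when the network carries one,
#' otherwise the best (closest to A) confidence among the TF's
#' interactions.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @param levels non-empty subset of \code{c("A","B","C","D","E")}.
#' @return the filtered \linkS4class{RegulonNetwork}.
#' @export
filterByConfidence <- function(net, levels) {
  if (length(levels) == 0L || !all(levels %in% CONFIDENCE_LEVELS))
    stop("levels must be a non-empty subset of A-E")
  conf <- tfSummaryConfidence(net)
  keep <- names(conf)[conf %in% levels]
  e <- edges(net)
  e <- e[e$tf %in% keep, , drop = FALSE]
  if (nrow(e) == 0L)
    stop("no TFs left after confidence filtering; benchmark cannot proceed")
  out <- RegulonNetwork(e, name = networkName(net))
  if (length(net@tfConfidence))
    out@tfConfidence <- net@tfConfidence[intersect(names(net@tfConfidence),
                                                   keep)]
  out
}

#' Drop TFs with too few measured targets
#'
#' Retains only TFs having at least \code{minTargets} targets inside the
#' measured gene universe (default 4, the conventional cutoff below which
#' a regulon enrichment score is unstable). Edges to unmeasured genes are
#' kept for retained TFs: pruning decides TF inclusion only, and scoring
#' intersects with each signature again.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @param measuredGenes character vector of measured gene identifiers.
#' @param minTargets minimum measured-target count (default 4).
#' @return the pruned network, or NULL if no TF survives.
#' @export
pruneMinTargets <- function(net, measuredGenes, minTargets = 4L) {
  if (length(measuredGenes) == 0L) stop("measuredGenes must be non-empty")
  e <- edges(net)
  nMeasured <- vapply(split(e$target, e$tf),
                      function(tg) sum(tg %in% measuredGenes), integer(1))
  keep <- names(nMeasured)[nMeasured >= minTargets]
  e <- e[e$tf %in% keep, , drop = FALSE]
  if (nrow(e) == 0L) return(NULL)
  out <- RegulonNetwork(e, name = networkName(net))
  if (length(net@tfConfidence))
    out@tfConfidence <- net@tfConfidence[intersect(names(net@tfConfidence),
                                                   keep)]
  out
}

#' Subset a footprint model to the top-N most responsive genes per pathway
#'
#' Keeps, per pathway, the entries whose responsiveness rank is at most
#' \code{topN}; pathways with fewer entries keep what they have. The
#' sentinel \code{"all"} returns the model unchanged.
#'
#' @param model a \linkS4class{FootprintModel}.
#' @param topN positive integer or \code{"all"}.
#' @return the subsetted \linkS4class{FootprintModel}.
#' @export
subsetFootprint <- function(model, topN) {
  if (identical(topN, "all")) return(model)
  if (!is.numeric(topN) || length(topN) != 1L || topN < 1)
    stop("topN must be a positive integer or \"all\"")
  e <- entries(model)
  FootprintModel(e[e$responsiveness_rank <= topN, , drop = FALSE])
}
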