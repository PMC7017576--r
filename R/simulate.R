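#' Simulation settings for bulk-to-single-cell sampling
#'
#' Bundles the parameters of the single-cell sampling model: the desired
#' mean library size \code{mu} (per-cell totals are drawn from
#' Normal(mu, sd = mu/2)), the number of cells per bulk sample, the number
#' of repetitions, the seed, and the minimum library size below which a
#' simulated cell is discarded (default 100 counts).
#'
#' @param mu mean library size in counts (> 0).
#' @param nCells cells to sample per bulk profile.
#' @param nReps simulation repetitions.
#' @param seed integer seed.
#' @param minLibrary discard cells with fewer total counts (strict <).
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(mu = 5000, nCells = 10L, nReps = 25L,
                             seed = 1L, minLibrary = 100L) {
  stopifnot(mu > 0, nCells >= 1, nReps >= 1)
  structure(list(mu = mu, nCells = as.integer(nCells),
                 nReps = as.integer(nReps), seed = as.integer(seed),
                 minLibrary = as.integer(minLibrary)),
            class = "simulationConfig")
}

#' Convert a bulk count profile to gene sampling probabilities
#'
#' Counts are first normalized for gene length and library size into TPM
#' values \eqn{B_g = (C_g / len_g) / \sum_h (C_h / len_h) \cdot 10^6}, then
#' scaled to probabilities \eqn{P_g = B_g / \sum B}. When no lengths are
#' given all genes are treated as equal length and TPM reduces to CPM.
#'
#' @param counts named non-negative integer vector of bulk counts.
#' @param lengths optional named positive vector of gene lengths (bases).
#' @return list with components \code{tpm} and \code{p} (named vectors;
#'   \code{sum(p) == 1}).
#' @export
bulkToProbabilities <- function(counts, lengths = NULL) {
  if (is.null(names(counts))) stop("counts must be named by gene")
  if (sum(counts) <= 0) stop("bulk profile has no counts")
  if (is.null(lengths)) {
    lengths <- rep(1, length(counts))
    names(lengths) <- names(counts)
  }
  lengths <- lengths[names(counts)]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("every counted gene needs a positive length")
  rate <- counts / lengths
  tpm <- rate / sum(rate) * 1e6
  p <- tpm / sum(tpm)
  list(tpm = tpm, p = p)
}

#' Draw per-cell library sizes
#'
#' Library sizes are drawn from Normal(mu, sd = mu/2), rounded to the
#' nearest integer and truncated below at zero. Tiny or negative draws are
#' expected at small mu; downstream filtering removes cells whose totals
#' fall under the minimum library size.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param n number of draws.
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return integer vector of length n.
#' @export
drawLibrarySizes <- function(cfg, n, seed = cfg$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  L <- round(stats::rnorm(n, mean = cfg$mu, sd = cfg$mu / 2))
  as.integer(pmax(L, 0))
}

#' Sample synthetic single cells from a bulk profile
#'
#' Each cell is a multinomial draw of its library size L over the bulk
#' gene probabilities (the exact distribution of L with-replacement draws
#' by inverse transform sampling from the cumulative gene frequencies).
#' Cells whose total count falls below \code{cfg$minLibrary} are
#' discarded. Column sums of kept cells equal their drawn L.
#'
#' @param counts named bulk count vector.
#' @param cfg a \code{\link{simulationConfig}}.
#' @param lengths optional gene lengths for TPM normalization.
#' @param seed optional seed overriding \code{cfg$seed}.
#' @return list: \code{counts} (genes x kept cells integer matrix),
#'   \code{librarySizes} (all drawn L), \code{kept} (logical mask).
#' @export
simulateCells <- function(counts, cfg, lengths = NULL, seed = cfg$seed) {
  prob <- bulkToProbabilities(counts, lengths)
  L <- drawLibrarySizes(cfg, cfg$nCells, seed = seed)
  cells <- vapply(L, function(l) {
    if (l == 0L) integer(length(prob$p))
    else as.integer(stats::rmultinom(1L, size = l, prob = prob$p))
  }, integer(length(prob$p)))
  cells <- matrix(cells, nrow = length(prob$p),
                  dimnames = list(names(counts),
                                  paste0("cell", seq_len(cfg$nCells))))
  kept <- colSums(cells) >= cfg$minLibrary
  if (!any(kept))
    stop("all simulated cells fell below the minimum library size (",
         cfg$minLibrary, ")")
  list(counts = cells[, kept, drop = FALSE], librarySizes = L, kept = kept)
}

#' Size-factor log-normalization of cell counts
#'
#' Per-cell size factor = library size / geometric mean of library sizes;
#' normalized value = log2(count / sizeFactor + 1). Cells with a zero
#' library must have been filtered beforehand and raise an error.
#'
#' @param counts genes x cells count matrix.
#' @return matrix of normalized log2 expression, same shape.
#' @export
normalizeCells <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero-library cell present; filter cells first")
  sf <- lib / exp(mean(log(lib)))
  log2(sweep(counts, 2L, sf, "/") + 1)
}
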