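#' Write / read an activity matrix as TSV
#'
#' Two-line header: line 1 carries the statistic tag
#' (\code{#statistic<TAB><tag>}), line 2 the column identifiers; one row
#' per feature thereafter. The round trip is lossless.
#'
#' @param am an \linkS4class{ActivityMatrix}.
#' @param path output path.
#' @return \code{writeActivityMatrix}: \code{path}, invisibly.
#' @export
writeActivityMatrix <- function(am, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#statistic\t", statistic(am)), con)
  sc <- scores(am)
  writeLines(paste(c("feature", colnames(sc)), collapse = "\t"), con)
  utils::write.table(
    data.frame(feature = rownames(sc), sc, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeActivityMatrix
#' @return \code{readActivityMatrix}: the \linkS4class{ActivityMatrix}.
#' @export
readActivityMatrix <- function(path) {
  header <- readLines(path, n = 2L)
  tag <- strsplit(header[1], "\t", fixed = TRUE)[[1]][2]
  cols <- strsplit(header[2], "\t", fixed = TRUE)[[1]][-1]
  tab <- utils::read.delim(path, skip = 2L, header = FALSE,
                           stringsAsFactors = FALSE)
  sc <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(sc) <- list(tab[[1]], cols)
  ActivityMatrix(sc, tag)
}

#' Write a regulon network / footprint model as TSV
#'
#' The tables use the same headers the loaders expect, so written
#' resources read back identically.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegulonNetwork <- function(net, path) {
  utils::write.table(edges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegulonNetwork
#' @param model a \linkS4class{FootprintModel}.
#' @export
writeFootprintModel <- function(model, path) {
  utils::write.table(entries(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a count matrix in MatrixMarket triplet layout
#'
#' Writes \code{matrix.mtx}, \code{genes.tsv} and \code{barcodes.tsv}
#' into \code{dir}, plus a \code{config.json} sidecar when a
#' configuration list is supplied (so any simulated dataset records the
#' settings and seed it was produced under).
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if absent).
#' @param config optional named list written as JSON sidecar.
#' @return \code{dir}, invisibly.
#' @export
writeCountsMTX <- function(counts, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(config))
    jsonlite::write_json(config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCountsMTX
#' @return \code{readCountsMTX}: the dense genes x cells matrix.
#' @export
readCountsMTX <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write per-experiment ground truth as JSON
#'
#' @param truth ground-truth list from the synthetic generators.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
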