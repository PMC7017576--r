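#' Perturbation records
#'
#' One record per perturbation contrast: the perturbed feature (TF or
#' pathway), the direction of the perturbation (+1 activation, -1
#' inhibition/knockdown), and the sample groups the contrast compares.
#'
#' @param contrast_id character vector of contrast identifiers.
#' @param target perturbed TF/pathway identifier per contrast.
#' @param direction +1 or -1 per contrast.
#' @param kind \code{"tf"} or \code{"pathway"} per contrast.
#' @param perturbed list of perturbed-sample id vectors.
#' @param control list of control-sample id vectors.
#' @return data.frame with list columns \code{perturbed}, \code{control}.
#' @export
perturbationRecords <- function(contrast_id, target, direction, kind,
                                perturbed, control) {
  stopifnot(all(direction %in% c(-1, 1)),
            length(perturbed) == length(contrast_id),
            length(control) == length(contrast_id))
  for (i in seq_along(contrast_id)) {
    if (!length(perturbed[[i]]) || !length(control[[i]]))
      stop("empty sample group in contrast ", contrast_id[i])
    if (length(intersect(perturbed[[i]], control[[i]])))
      stop("overlapping sample groups in contrast ", contrast_id[i])
  }
  data.frame(contrast_id = as.character(contrast_id),
             target = as.character(target),
             direction = as.numeric(direction),
             kind = as.character(kind),
             perturbed = I(perturbed), control = I(control),
             stringsAsFactors = FALSE)
}

#' Read perturbation metadata from a long-format CSV
#'
#' Expects one row per sample with columns \code{experiment_id},
#' \code{target}, \code{direction} (+1/-1), \code{sample_id},
#' \code{group} (\code{"perturbed"} or \code{"control"}) and optionally
#' \code{kind} — the layout of curated perturbation-compendium metadata
#' tables (perturbation target, direction, and which samples belong to
#' the control or perturbation group).
#'
#' @param path path to the CSV file.
#' @return perturbation records (see \code{\link{perturbationRecords}}).
#' @export
readPerturbationMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment_id", "target", "direction", "sample_id", "group")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(tab$kind)) tab$kind <- "tf"
  per <- split(tab, tab$experiment_id)
  perturbationRecords(
    contrast_id = names(per),
    target = vapply(per, function(x) x$target[1], character(1)),
    direction = vapply(per, function(x) x$direction[1], numeric(1)),
    kind = vapply(per, function(x) x$kind[1], character(1)),
    perturbed = lapply(per, function(x) x$sample_id[x$group == "perturbed"]),
    control = lapply(per, function(x) x$sample_id[x$group == "control"]))
}

groupMeansDiff <- function(mat, records, what) {
  sapply(seq_len(nrow(records)), function(i) {
    p <- records$perturbed[[i]]
    c_ <- records$control[[i]]
    miss <- setdiff(c(p, c_), colnames(mat))
    if (length(miss))
      stop("contrast ", records$contrast_id[i], ": missing ", what,
           " id(s): ", paste(miss, collapse = ", "))
    rowMeans(mat[, p, drop = FALSE]) - rowMeans(mat[, c_, drop = FALSE])
  })
}

#' Summarise perturbation experiments as a logFC contrast matrix
#'
#' For each record, logFC(gene) = mean normalized log expression over the
#' perturbed samples minus the mean over the control samples. Exact zeros
#' encode genes not covered by the contrast.
#'
#' @param expr normalized log-expression matrix, genes x samples.
#' @param records perturbation records.
#' @return a \linkS4class{ContrastMatrix}, one column per record.
#' @export
buildExpressionContrasts <- function(expr, records) {
  lfc <- groupMeansDiff(expr, records, "sample")
  lfc <- matrix(lfc, nrow = nrow(expr),
                dimnames = list(rownames(expr), records$contrast_id))
  ContrastMatrix(lfc)
}

#' Summarise per-sample activities as activity contrasts
#'
#' Feature-wise analogue of \code{\link{buildExpressionContrasts}}: the
#' change in activity per contrast is the mean over perturbed samples
#' minus the mean over control samples.
#'
#' @param activities \linkS4class{ActivityMatrix} over single
#'   samples/cells.
#' @param records perturbation records.
#' @return an \linkS4class{ActivityMatrix} over contrasts (statistic
#'   preserved).
#' @export
buildActivityContrasts <- function(activities, records) {
  sc <- scores(activities)
  d <- groupMeansDiff(sc, records, "sample")
  d <- matrix(d, nrow = nrow(sc),
              dimnames = list(rownames(sc), records$contrast_id))
  ActivityMatrix(d, statistic(activities))
}

#' Mask gene coverage by inserting random zeros
#'
#' Reduces every contrast to exactly \code{target} covered genes (nonzero
#' logFC) by zeroing uniformly chosen nonzero positions, independently per
#' contrast and per replicate. Surviving logFC values are never altered,
#' only positions are zeroed.
#'
#' @param contrasts a \linkS4class{ContrastMatrix}.
#' @param target covered-gene count to keep per contrast.
#' @param nReps replicates (default 25).
#' @param seed integer seed.
#' @return list of \code{nReps} \linkS4class{ContrastMatrix} objects.
#' @export
maskCoverage <- function(contrasts, target, nReps = 25L, seed = 1L) {
  m <- logFC(contrasts)
  nz <- colSums(m != 0)
  short <- nz < target
  if (any(short))
    stop("coverage target ", target, " exceeds available nonzeros in: ",
         paste(colnames(m)[short], collapse = ", "))
  set.seed(seed)
  lapply(seq_len(nReps), function(r) {
    out <- m
    for (j in seq_len(ncol(m))) {
      idx <- which(m[, j] != 0)
      drop_n <- length(idx) - target
      if (drop_n > 0L)
        out[sample(idx, drop_n), j] <- 0
    }
    ContrastMatrix(out)
  })
}

#' Orient activity scores by perturbation direction
#'
#' Multiplies the activity scores of inhibition/knockdown contrasts
#' (direction -1) by -1, so that in the ideal case the perturbed feature
#' has the highest score in every contrast and the benchmark becomes a
#' binary ranking problem.
#'
#' @param activityContrasts \linkS4class{ActivityMatrix} over contrasts.
#' @param records perturbation records covering every contrast column.
#' @return the oriented \linkS4class{ActivityMatrix}.
#' @export
orientScores <- function(activityContrasts, records) {
  sc <- scores(activityContrasts)
  idx <- match(colnames(sc), records$contrast_id)
  if (anyNA(idx))
    stop("contrast(s) without a perturbation record: ",
         paste(colnames(sc)[is.na(idx)], collapse = ", "))
  sc <- sweep(sc, 2L, records$direction[idx], "*")
  ActivityMatrix(sc, statistic(activityContrasts))
}

#' Quality-filter knockdown perturbations by their own target's logFC
#'
#' A knockdown/inhibition experiment in which the targeted gene's own
#' logFC is positive contradicts the annotated perturbation; such records
#' are discarded (strict > 0). The rule applies to direction -1 records
#' only; records whose target gene is not measured are kept with a
#' warning.
#'
#' @param contrasts a \linkS4class{ContrastMatrix}.
#' @param records perturbation records.
#' @return the surviving subset of \code{records}.
#' @export
qcFilterPerturbations <- function(contrasts, records) {
  m <- logFC(contrasts)
  keep <- rep(TRUE, nrow(records))
  unmeasured <- character(0)
  for (i in seq_len(nrow(records))) {
    if (records$direction[i] != -1) next
    g <- records$target[i]
    cid <- records$contrast_id[i]
    if (!g %in% rownames(m) || !cid %in% colnames(m)) {
      unmeasured <- c(unmeasured, cid)
      next
    }
    if (m[g, cid] > 0) keep[i] <- FALSE
  }
  if (length(unmeasured))
    warning("target gene unmeasured; record(s) kept: ",
            paste(unmeasured, collapse = ", "))
  records[keep, , drop = FALSE]
}

rocPrCurves <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- label[ord]
  P <- sum(y == 1L); N <- sum(y == 0L)
  # group tied scores so curves step once per distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  prec <- tp / (tp + fp)
  pr <- data.frame(recall = tp / P, precision = prec)
  auprc <- sum(diff(c(0, tp)) / P * prec)
  list(roc = roc, pr = pr, auprc = auprc)
}

#' Evaluate perturbation recovery with ROC and PR curves
#'
#' In every contrast the oriented score of the perturbed feature is the
#' single positive; the scores of all other features in all contrasts are
#' negatives. Contrasts whose target is not among the scored features are
#' excluded from scoring but recorded in the result's metadata
#' (\code{excluded_targets}); \code{tf_coverage} counts the distinct
#' perturbed features that were scored. AUROC is computed by pairwise
#' concordance with half credit on ties (equal to trapezoidal integration
#' of the tie-grouped ROC curve); AUPRC by step integration.
#'
#' @param oriented oriented \linkS4class{ActivityMatrix} over contrasts.
#' @param records perturbation records.
#' @param meta optional named list of extra metadata to carry along.
#' @return a \linkS4class{BenchmarkResult}.
#' @export
evaluateRecovery <- function(oriented, records, meta = list()) {
  sc <- scores(oriented)
  idx <- match(colnames(sc), records$contrast_id)
  if (anyNA(idx))
    stop("contrast(s) without a perturbation record: ",
         paste(colnames(sc)[is.na(idx)], collapse = ", "))
  target <- records$target[idx]
  scored <- target %in% rownames(sc)
  excluded <- unique(target[!scored])
  use <- which(scored)
  if (!length(use)) stop("no contrast has a scored target: no positives")
  lab <- matrix(0L, nrow(sc), ncol(sc))
  lab[cbind(match(target[use], rownames(sc)), use)] <- 1L
  score <- as.vector(sc[, use, drop = FALSE])
  label <- as.vector(lab[, use, drop = FALSE])
  if (!any(label == 0L)) stop("no negative scores; benchmark undefined")
  P <- sum(label == 1L); N <- sum(label == 0L)
  r <- rank(score, ties.method = "average")
  auroc_val <- (sum(r[label == 1L]) - P * (P + 1) / 2) / (P * N)
  curves <- rocPrCurves(score, label)
  meta$tf_coverage <- length(unique(target[use]))
  meta$excluded_targets <- excluded
  new("BenchmarkResult", scores = score, labels = as.integer(label),
      roc = curves$roc, pr = curves$pr, auroc = auroc_val,
      auprc = curves$auprc, meta = meta)
}

#' Summarise benchmark results over a parameter grid
#'
#' Aggregates replicate-level results into one row per grid cell: the
#' mean and sd of AUROC and AUPRC across replicates. When a per-cell bulk
#' baseline is supplied (named by the grid-cell key), the mean difference
#' single-cell minus bulk is added; cells without a baseline get NA.
#'
#' @param results list of \linkS4class{BenchmarkResult} objects.
#' @param by character vector of metadata fields defining the grid
#'   (default: every field except \code{replicate}, \code{tf_coverage},
#'   \code{excluded_targets}).
#' @param baseline optional named numeric vector of bulk AUROCs keyed by
#'   the grid-cell key (fields joined with \code{"|"}).
#' @return data.frame, one row per grid cell, ordered by mean AUROC
#'   (best first).
#' @export
summarizeGrid <- function(results, by = NULL, baseline = NULL) {
  metas <- lapply(results, benchmarkMeta)
  if (is.null(by))
    by <- setdiff(unique(unlist(lapply(metas, names))),
                  c("replicate", "tf_coverage", "excluded_targets"))
  key <- vapply(metas, function(m)
    paste(vapply(by, function(f)
      if (is.null(m[[f]])) NA_character_ else as.character(m[[f]]),
      character(1)), collapse = "|"), character(1))
  au <- vapply(results, auroc, numeric(1))
  ap <- vapply(results, auprc, numeric(1))
  cells <- split(seq_along(results), key)
  out <- do.call(rbind, lapply(names(cells), function(k) {
    i <- cells[[k]]
    fields <- strsplit(k, "|", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(stats::setNames(fields, by)),
                         stringsAsFactors = FALSE)
    row$n_reps <- length(i)
    row$mean_auroc <- mean(au[i])
    row$sd_auroc <- stats::sd(au[i])
    row$mean_auprc <- mean(ap[i])
    row$sd_auprc <- stats::sd(ap[i])
    row$mean_auroc_diff <-
      if (is.null(baseline) || is.na(baseline[k])) NA_real_
      else mean(au[i]) - unname(baseline[k])
    row
  }))
  out[order(-out$mean_auroc), , drop = FALSE]
}
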