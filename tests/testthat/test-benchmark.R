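makeRecords <- function(n, targets, directions,
                        kind = rep("tf", n)) {
  perturbationRecords(
    contrast_id = sprintf("E%02d", seq_len(n)),
    target = targets, direction = directions, kind = kind,
    perturbed = lapply(seq_len(n), function(i) sprintf("p%d", i)),
    control = lapply(seq_len(n), function(i) sprintf("c%d", i)))
}

test_that("expression contrasts are group mean differences", {
  expr <- rbind(g1 = c(p1 = 4, p2 = 4, c1 = 2, c2 = 2),
                g2 = c(p1 = 1, p2 = 1, c1 = 1, c2 = 1))
  rec <- perturbationRecords("E1", "T1", 1, "tf",
                             list(c("p1", "p2")), list(c("c1", "c2")))
  cm <- buildExpressionContrasts(expr, rec)
  expect_equal(logFC(cm)["g1", "E1"], 2)
  expect_equal(logFC(cm)["g2", "E1"], 0)          # identical means
  expect_equal(unname(coverage(cm)), 1L)

  # 15 records -> 15 contrast columns
  expr15 <- matrix(rnorm(10 * 30), nrow = 10,
                   dimnames = list(paste0("g", 1:10),
                                   c(sprintf("p%d", 1:15),
                                     sprintf("c%d", 1:15))))
  rec15 <- makeRecords(15, sprintf("T%d", 1:15), rep(1, 15),
                       kind = rep("pathway", 15))
  expect_equal(ncol(logFC(buildExpressionContrasts(expr15, rec15))), 15L)

  bad <- perturbationRecords("E1", "T1", 1, "tf", list("nope"), list("c1"))
  expect_error(buildExpressionContrasts(expr, bad), "E1.*nope")
})

test_that("activity contrasts are feature-wise mean differences, invariant to group duplication", {
  sc <- matrix(c(1, 3, 5, 2), nrow = 2,
               dimnames = list(c("T1", "T2"), c("p1", "c1")))
  am <- new("ActivityMatrix", scores = sc, statistic = "nes")
  rec <- perturbationRecords("E1", "T1", 1, "tf", list("p1"), list("c1"))
  d <- buildActivityContrasts(am, rec)
  expect_equal(scores(d)[, "E1"], c(T1 = 1 - 5, T2 = 3 - 2))
  expect_equal(statistic(d), "nes")

  # doubling both groups' cells leaves the contrast unchanged
  sc2 <- sc[, c(1, 1, 2, 2)]
  colnames(sc2) <- c("p1", "p2", "c1", "c2")
  am2 <- new("ActivityMatrix", scores = sc2, statistic = "nes")
  rec2 <- perturbationRecords("E1", "T1", 1, "tf",
                              list(c("p1", "p2")), list(c("c1", "c2")))
  expect_equal(scores(buildActivityContrasts(am2, rec2)), scores(d))
})

test_that("coverage masking zeroes positions without altering surviving values", {
  set.seed(14)
  m <- matrix(rnorm(200), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("E", 1:4)))
  m[sample(200, 20)] <- 0
  cm <- new("ContrastMatrix", logFC = m)
  nz <- min(coverage(cm))

  masked <- maskCoverage(cm, target = 20L, nReps = 3L, seed = 1L)
  expect_length(masked, 3L)
  for (rep in masked) {
    expect_true(all(coverage(rep) == 20L))
    # surviving values form a sub-multiset of the originals, per contrast
    for (j in 1:4) {
      surv <- logFC(rep)[, j]; surv <- surv[surv != 0]
      expect_true(all(surv %in% m[, j]))
    }
  }
  # identity at the current nonzero count
  ident <- maskCoverage(cm, target = nz, nReps = 1L, seed = 1L)[[1]]
  keep_col <- which.min(coverage(cm))
  expect_equal(logFC(ident)[, keep_col], m[, keep_col])

  # distinct seeds differ in zeroed positions, never in counts
  a <- maskCoverage(cm, 20L, 1L, seed = 1L)[[1]]
  b <- maskCoverage(cm, 20L, 1L, seed = 2L)[[1]]
  expect_false(identical(logFC(a), logFC(b)))
  expect_equal(coverage(a), coverage(b))

  expect_error(maskCoverage(cm, target = 49L, nReps = 1L, seed = 1L),
               "E")
})

test_that("orientation negates inhibition columns and is an involution", {
  sc <- matrix(c(1.2, -0.4, 0.5, 0.7), nrow = 2,
               dimnames = list(c("T1", "T2"), c("E01", "E02")))
  am <- new("ActivityMatrix", scores = sc, statistic = "nes")
  rec <- makeRecords(2, c("T1", "T2"), c(-1, 1))
  out <- orientScores(am, rec)
  expect_equal(scores(out)[, "E01"], c(T1 = -1.2, T2 = 0.4))  # flipped
  expect_equal(scores(out)[, "E02"], sc[, "E02"])             # unchanged
  expect_equal(scores(orientScores(out, rec)), sc)            # involution
  rec_bad <- makeRecords(1, "T1", 1)
  expect_error(orientScores(am, rec_bad), "E02")
})

test_that("knockdown QC drops records whose target gene moved the wrong way", {
  set.seed(15)
  n <- 10L
  targets <- paste0("T", 1:n)
  rec <- makeRecords(n, targets, rep(-1, n))
  m <- matrix(rnorm(n * n, -1), nrow = n,
              dimnames = list(targets, rec$contrast_id))
  # make exactly 3 targets move up in their own contrast, one sit at 0
  diag(m) <- -abs(diag(m))
  m[cbind(1:3, 1:3)] <- c(0.3, 1.1, 0.02)
  m[4, 4] <- 0
  kept <- qcFilterPerturbations(new("ContrastMatrix", logFC = m), rec)
  expect_equal(nrow(kept), 7L)
  expect_true("E04" %in% kept$contrast_id)   # exactly 0: strict inequality
  expect_false(any(c("E01", "E02", "E03") %in% kept$contrast_id))

  # unmeasured target: kept with a warning; activation records untouched
  rec_mix <- makeRecords(2, c("ZZ", "T1"), c(-1, 1))
  expect_warning(kept2 <- qcFilterPerturbations(
    new("ContrastMatrix", logFC = m[, 1:2]), rec_mix), "unmeasured")
  expect_equal(nrow(kept2), 2L)
})

test_that("recovery evaluation reproduces known AUROCs and the concordance oracle", {
  # perfect scorer: target always the maximum
  sc <- matrix(0, 3, 3, dimnames = list(paste0("T", 1:3),
                                        sprintf("E%02d", 1:3)))
  diag(sc) <- 5
  rec <- makeRecords(3, paste0("T", 1:3), rep(1, 3))
  am <- new("ActivityMatrix", scores = sc, statistic = "nes")
  res <- evaluateRecovery(am, rec)
  expect_equal(auroc(res), 1)
  expect_equal(auprc(res), 1)
  expect_equal(benchmarkMeta(res)$tf_coverage, 3L)

  # hand case: scores (.9,.8,.3,.2), labels (1,0,1,0) -> concordance 3/4
  sc2 <- matrix(c(0.9, 0.8, 0.3, 0.2), nrow = 2,
                dimnames = list(c("T1", "T2"), c("E01", "E02")))
  rec2 <- makeRecords(2, c("T1", "T1"), c(1, 1))
  res2 <- evaluateRecovery(new("ActivityMatrix", scores = sc2,
                               statistic = "nes"), rec2)
  expect_equal(auroc(res2), 0.75)

  # brute-force concordance oracle on a random instance (with ties)
  set.seed(16)
  n_feat <- 10L; n_con <- 20L
  sc3 <- matrix(round(rnorm(n_feat * n_con), 1), nrow = n_feat,
                dimnames = list(paste0("T", 1:n_feat),
                                sprintf("E%02d", 1:n_con)))
  rec3 <- makeRecords(n_con, sample(paste0("T", 1:n_feat), n_con, TRUE),
                      sample(c(-1, 1), n_con, TRUE))
  res3 <- evaluateRecovery(new("ActivityMatrix", scores = sc3,
                               statistic = "nes"), rec3)
  lab <- matrix(0L, n_feat, n_con)
  lab[cbind(match(rec3$target, paste0("T", 1:n_feat)), 1:n_con)] <- 1L
  expect_equal(auroc(res3), bruteForceAUROC(as.vector(sc3), as.vector(lab)))

  # AUROC of a scorer and of its negation sum to 1 (no ties here)
  sc4 <- matrix(rnorm(n_feat * n_con), nrow = n_feat,
                dimnames = dimnames(sc3))
  r_pos <- evaluateRecovery(new("ActivityMatrix", scores = sc4,
                                statistic = "nes"), rec3)
  r_neg <- evaluateRecovery(new("ActivityMatrix", scores = -sc4,
                                statistic = "nes"), rec3)
  expect_equal(auroc(r_pos) + auroc(r_neg), 1)
})

test_that("recovery AUROC and curves agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- matrix(rnorm(8 * 25), nrow = 8,
               dimnames = list(paste0("T", 1:8), sprintf("E%02d", 1:25)))
  rec <- makeRecords(25, sample(paste0("T", 1:8), 25, TRUE), rep(1, 25))
  res <- evaluateRecovery(new("ActivityMatrix", scores = sc,
                              statistic = "nes"), rec)
  ref <- pROC::auc(pROC::roc(response = res@labels, predictor = res@scores,
                             quiet = TRUE, direction = "<"))
  expect_equal(auroc(res), as.numeric(ref))
})

test_that("contrasts with unscored targets are excluded but counted", {
  sc <- matrix(rnorm(4), nrow = 2,
               dimnames = list(c("T1", "T2"), c("E01", "E02")))
  rec <- makeRecords(2, c("T1", "ZZ"), c(1, 1))
  res <- evaluateRecovery(new("ActivityMatrix", scores = sc,
                              statistic = "nes"), rec)
  expect_equal(sum(res@labels == 1L), 1L)        # only E01's target scored
  expect_equal(length(res@scores), 2L)           # E02 column excluded
  expect_equal(benchmarkMeta(res)$excluded_targets, "ZZ")
  expect_equal(benchmarkMeta(res)$tf_coverage, 1L)
})

test_that("grid summaries aggregate replicates and baselines", {
  mk <- function(au, meta) {
    n_pos <- 2L; n_neg <- 8L
    new("BenchmarkResult",
        scores = c(rep(1, n_pos), rep(0, n_neg)),
        labels = c(rep(1L, n_pos), rep(0L, n_neg)),
        roc = data.frame(fpr = 0, tpr = 0),
        pr = data.frame(recall = 1, precision = 1),
        auroc = au, auprc = 0.5, meta = meta)
  }
  results <- list(mk(0.6, list(mu = 1000, replicate = 1)),
                  mk(0.8, list(mu = 1000, replicate = 2)),
                  mk(0.7, list(mu = 2000, replicate = 1)))
  tab <- summarizeGrid(results, by = "mu")
  r1 <- tab[tab$mu == "1000", ]
  expect_equal(r1$mean_auroc, 0.7)
  expect_equal(r1$sd_auroc, sqrt(0.02), tolerance = 1e-6)   # 0.1414
  expect_equal(r1$n_reps, 2L)

  # identical single-cell and bulk performance: difference 0
  tab2 <- summarizeGrid(results, by = "mu",
                        baseline = c(`1000` = 0.7, `2000` = 0.7))
  expect_equal(tab2$mean_auroc_diff[tab2$mu == "1000"], 0)
})

test_that("perturbation metadata CSV round-trips into records", {
  tab <- data.frame(
    experiment_id = rep(c("E1", "E2"), each = 4),
    target = rep(c("STAT1", "EGFR"), each = 4),
    direction = rep(c(-1, 1), each = 4),
    sample_id = paste0("s", 1:8),
    group = rep(c("control", "control", "perturbed", "perturbed"), 2),
    kind = rep(c("tf", "pathway"), each = 4))
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  rec <- readPerturbationMetadata(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$target, c("STAT1", "EGFR"))
  expect_equal(rec$direction, c(-1, 1))
  expect_equal(rec$perturbed[[1]], c("s3", "s4"))
  expect_equal(rec$control[[2]], c("s5", "s6"))
  expect_error(readPerturbationMetadata(
    { p <- tempfile(); write.csv(tab[, -2], p, row.names = FALSE); p }),
    "target")
})
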