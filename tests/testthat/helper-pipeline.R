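# End-to-end helper: synthetic compendium -> simulated single cells ->
# normalized contrasts -> regulon scoring -> recovery AUROC.
simulatedCellRecoveryAUROC <- function(effect, seed, nExperiments = 30L,
                                       mu = 5000, nCellsPerSample = 10L,
                                       nGenes = 2000L, nTFs = 20L,
                                       targetsPerTF = 50L) {
  cfg <- synthConfig(nGenes = nGenes, nTFs = nTFs,
                     targetsPerTF = targetsPerTF, effect = effect,
                     nExperiments = nExperiments, seed = seed)
  reg <- generateRegulons(cfg)
  comp <- generatePerturbationCompendium(reg$network, cfg)
  cells <- list(); groups <- list()
  for (j in seq_len(ncol(comp$counts))) {
    sc <- simulationConfig(mu = mu, nCells = nCellsPerSample,
                           seed = seed * 1000L + j)
    sim <- simulateCells(comp$counts[, j], sc)
    ids <- sprintf("%s_c%d", colnames(comp$counts)[j],
                   seq_len(ncol(sim$counts)))
    colnames(sim$counts) <- ids
    cells[[j]] <- sim$counts
    groups[[colnames(comp$counts)[j]]] <- ids
  }
  counts <- do.call(cbind, cells)
  expr <- normalizeCells(counts)
  # records at the cell level: each bulk sample contributes its cells
  rec <- comp$records
  rec$perturbed <- I(lapply(rec$perturbed,
                            function(s) unlist(groups[s], use.names = FALSE)))
  rec$control <- I(lapply(rec$control,
                          function(s) unlist(groups[s], use.names = FALSE)))
  contrasts <- buildExpressionContrasts(expr, rec)
  am <- regulonNESMatrix(logFC(contrasts), reg$network)
  oriented <- orientScores(am, rec)
  auroc(evaluateRecovery(oriented, rec, meta = list(effect = effect,
                                                    replicate = seed)))
}

# bulk-only compendium -> logCPM contrasts (for coverage masking studies)
syntheticBulkContrasts <- function(cfg) {
  reg <- generateRegulons(cfg)
  comp <- generatePerturbationCompendium(reg$network, cfg)
  cpm <- log2(sweep(comp$counts, 2L, colSums(comp$counts), "/") * 1e6 + 1)
  list(network = reg$network, footprint = reg$footprint,
       records = comp$records,
       contrasts = buildExpressionContrasts(cpm, comp$records))
}

maskedRecoveryAUROC <- function(bulk, target, nReps, seed,
                                scorer = function(m)
                                  regulonNESMatrix(m, bulk$network)) {
  masked <- maskCoverage(bulk$contrasts, target, nReps = nReps, seed = seed)
  vapply(masked, function(cm) {
    am <- scorer(logFC(cm))
    auroc(evaluateRecovery(orientScores(am, bulk$records), bulk$records))
  }, numeric(1))
}
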