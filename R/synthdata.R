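#' Configuration for the synthetic ground-truth generators
#'
#' Parameters of the synthetic regulon networks, bulk perturbation
#' compendia and cell-type mixtures used to exercise the benchmark with a
#' known ground truth. Bulk counts are negative-binomial (overdispersed,
#' the standard count model for RNA-seq); a perturbation multiplies the
#' mean of each direct target g of the perturbed TF by
#' \eqn{2^{effect \cdot mode_g \cdot direction}}. Effects touch direct
#' targets only, which keeps the ground truth unambiguous.
#'
#' @param nGenes size of the gene universe.
#' @param nTFs number of TFs (= pathways in the paired footprint model).
#' @param targetsPerTF regulon size.
#' @param activatingFraction probability a target's mode is +1.
#' @param effect log2 shift magnitude applied to direct targets (>= 0).
#' @param baselineMean negative-binomial mean of unperturbed genes.
#' @param dispersion negative-binomial dispersion (> 0).
#' @param nExperiments number of perturbation experiments.
#' @param directionMix fraction of inhibitory (-1) perturbations.
#' @param samplesPerGroup bulk samples per control/perturbed group.
#' @param seed integer seed.
#' @return a list of class \code{synthConfig}.
#' @export
synthConfig <- function(nGenes = 2000L, nTFs = 20L, targetsPerTF = 50L,
                        activatingFraction = 0.75, effect = 2,
                        baselineMean = 50, dispersion = 0.2,
                        nExperiments = 30L, directionMix = 0.5,
                        samplesPerGroup = 1L, seed = 1L) {
  stopifnot(activatingFraction >= 0, activatingFraction <= 1,
            effect >= 0, dispersion > 0, targetsPerTF >= 1)
  structure(list(nGenes = as.integer(nGenes), nTFs = as.integer(nTFs),
                 targetsPerTF = as.integer(targetsPerTF),
                 activatingFraction = activatingFraction, effect = effect,
                 baselineMean = baselineMean, dispersion = dispersion,
                 nExperiments = as.integer(nExperiments),
                 directionMix = directionMix,
                 samplesPerGroup = as.integer(samplesPerGroup),
                 seed = as.integer(seed)),
            class = "synthConfig")
}

#' Generate a random regulon network and its paired footprint model
#'
#' Every TF receives \code{targetsPerTF} distinct targets sampled from
#' the gene universe (targets may be shared across TFs); modes are +1
#' with probability \code{activatingFraction}, likelihoods 1, edge
#' confidence uniform over A-E. The footprint model reuses the same
#' memberships with weight = mode and responsiveness rank equal to draw
#' order, so footprint subsetting has a well-defined ordering.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list with elements \code{network}
#'   (\linkS4class{RegulonNetwork}) and \code{footprint}
#'   (\linkS4class{FootprintModel}).
#' @export
generateRegulons <- function(cfg) {
  if (cfg$targetsPerTF < 1L) stop("targetsPerTF must be >= 1")
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$nGenes))
  tf_ids <- sprintf("TF%02d", seq_len(cfg$nTFs))
  edges <- do.call(rbind, lapply(tf_ids, function(tf) {
    tg <- sample(genes, cfg$targetsPerTF)
    data.frame(tf = tf, target = tg,
               mode = ifelse(stats::runif(cfg$targetsPerTF) <
                               cfg$activatingFraction, 1, -1),
               likelihood = 1,
               confidence = sample(CONFIDENCE_LEVELS, cfg$targetsPerTF,
                                   replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  fp <- data.frame(pathway = edges$tf, gene = edges$target,
                   weight = edges$mode,
                   responsiveness_rank = unlist(lapply(
                     tf_ids, function(x) seq_len(cfg$targetsPerTF))),
                   stringsAsFactors = FALSE)
  list(network = RegulonNetwork(edges, name = "synthetic"),
       footprint = FootprintModel(fp))
}

#' Generate a bulk perturbation compendium with ground truth
#'
#' For every experiment a target TF is drawn (cycling through the
#' network's TFs) together with a direction (-1 with probability
#' \code{directionMix}). Control and perturbed bulk profiles are
#' negative-binomial draws around the baseline mean; in the perturbed
#' profile every direct target's mean is multiplied by
#' \eqn{2^{effect \cdot mode \cdot direction}}.
#'
#' @param net a \linkS4class{RegulonNetwork} (typically from
#'   \code{\link{generateRegulons}}).
#' @param cfg a \code{\link{synthConfig}}.
#' @return list: \code{counts} (genes x samples integer matrix),
#'   \code{records} (perturbation records), \code{truth} (per-experiment
#'   target, direction and truly shifted genes).
#' @export
generatePerturbationCompendium <- function(net, cfg) {
  if (cfg$nExperiments < 1L) stop("need at least one experiment")
  set.seed(cfg$seed + 1L)
  genes <- sprintf("G%04d", seq_len(cfg$nGenes))
  e <- edges(net)
  tf_pool <- tfs(net)
  size <- 1 / cfg$dispersion
  targets <- tf_pool[(seq_len(cfg$nExperiments) - 1L) %% length(tf_pool) + 1L]
  dirs <- ifelse(stats::runif(cfg$nExperiments) < cfg$directionMix, -1, 1)
  cols <- list(); records <- list(); truth <- list()
  for (i in seq_len(cfg$nExperiments)) {
    eid <- sprintf("E%03d", i)
    reg <- e[e$tf == targets[i], , drop = FALSE]
    mu_ctrl <- stats::setNames(rep(cfg$baselineMean, cfg$nGenes), genes)
    mu_pert <- mu_ctrl
    mu_pert[reg$target] <- mu_pert[reg$target] *
      2^(cfg$effect * reg$mode * dirs[i])
    ctrl_ids <- sprintf("%s_ctrl_%d", eid, seq_len(cfg$samplesPerGroup))
    pert_ids <- sprintf("%s_pert_%d", eid, seq_len(cfg$samplesPerGroup))
    for (s in ctrl_ids)
      cols[[s]] <- stats::rnbinom(cfg$nGenes, mu = mu_ctrl, size = size)
    for (s in pert_ids)
      cols[[s]] <- stats::rnbinom(cfg$nGenes, mu = mu_pert, size = size)
    records[[i]] <- list(contrast_id = eid, target = targets[i],
                         direction = dirs[i], perturbed = pert_ids,
                         control = ctrl_ids)
    truth[[eid]] <- list(target = targets[i], direction = dirs[i],
                         shifted_genes = unique(reg$target))
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes
  rec <- perturbationRecords(
    contrast_id = vapply(records, `[[`, character(1), "contrast_id"),
    target = vapply(records, `[[`, character(1), "target"),
    direction = vapply(records, `[[`, numeric(1), "direction"),
    kind = rep("tf", cfg$nExperiments),
    perturbed = lapply(records, `[[`, "perturbed"),
    control = lapply(records, `[[`, "control"))
  list(counts = counts, records = rec, truth = truth)
}

#' Generate an annotated mixed-cell-type population
#'
#' Each cell type gets a type-specific mean vector: the baseline with the
#' targets of the type's active TFs shifted by
#' \eqn{2^{effect \cdot mode}}. Cells are then sampled from those means
#' with the bulk-to-single-cell multinomial model (library sizes drawn
#' around the configured mu, small cells discarded).
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @param cellTypes named list: cell type -> character vector of active
#'   TFs (must exist in \code{net}).
#' @param cellsPerType cells to draw per type (before filtering).
#' @param cfg a \code{\link{synthConfig}} (effect, baseline, seed).
#' @param simCfg a \code{\link{simulationConfig}} (mu, minLibrary).
#' @return list: \code{counts} (genes x cells), \code{annotation}
#'   (data.frame cell_id, cell_type), \code{truth} (active TFs per type).
#' @export
generateMixturePopulation <- function(net, cellTypes, cellsPerType, cfg,
                                      simCfg = simulationConfig(
                                        mu = 5000, nCells = cellsPerType,
                                        seed = cfg$seed)) {
  e <- edges(net)
  unknown <- setdiff(unique(unlist(cellTypes)), tfs(net))
  if (length(unknown))
    stop("active TF(s) not in network: ", paste(unknown, collapse = ", "))
  genes <- sprintf("G%04d", seq_len(cfg$nGenes))
  blocks <- list(); ann <- list()
  for (ti in seq_along(cellTypes)) {
    type <- names(cellTypes)[ti]
    mu <- stats::setNames(rep(cfg$baselineMean, cfg$nGenes), genes)
    for (tf in cellTypes[[ti]]) {
      reg <- e[e$tf == tf, , drop = FALSE]
      mu[reg$target] <- mu[reg$target] * 2^(cfg$effect * reg$mode)
    }
    sc <- simulationConfig(mu = simCfg$mu, nCells = cellsPerType,
                           seed = cfg$seed + 97L * ti,
                           minLibrary = simCfg$minLibrary)
    sim <- simulateCells(round(mu * 100), sc)
    ids <- sprintf("%s_c%03d", gsub("[^A-Za-z0-9]", "", type),
                   seq_len(ncol(sim$counts)))
    colnames(sim$counts) <- ids
    blocks[[ti]] <- sim$counts
    ann[[ti]] <- data.frame(cell_id = ids, cell_type = type,
                            stringsAsFactors = FALSE)
  }
  list(counts = do.call(cbind, blocks), annotation = do.call(rbind, ann),
       truth = cellTypes)
}
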