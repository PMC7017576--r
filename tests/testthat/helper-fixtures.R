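# Small fixtures built in code; everything takes an explicit seed.

# network with one TF per confidence level, one edge each
oneTFPerLevelNetwork <- function() {
  RegulonNetwork(data.frame(
    tf = paste0("TF_", c("A", "B", "C", "D", "E")),
    target = paste0("G", 1:5),
    mode = 1, likelihood = 1,
    confidence = c("A", "B", "C", "D", "E"),
    stringsAsFactors = FALSE))
}

randomNetwork <- function(nTFs = 20L, nGenes = 50L, targetsPerTF = 6L,
                          seed = 1L) {
  set.seed(seed)
  genes <- paste0("G", seq_len(nGenes))
  edges <- do.call(rbind, lapply(seq_len(nTFs), function(i) {
    data.frame(tf = sprintf("TF%02d", i),
               target = sample(genes, targetsPerTF),
               mode = sample(c(-1, 1), targetsPerTF, replace = TRUE),
               likelihood = round(runif(targetsPerTF, 0.2, 1), 3),
               confidence = sample(c("A", "B", "C", "D", "E"),
                                   targetsPerTF, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  RegulonNetwork(edges)
}

toyFootprint <- function(nPathways = 3L, genesPerPathway = 150L) {
  FootprintModel(do.call(rbind, lapply(seq_len(nPathways), function(i) {
    data.frame(pathway = paste0("P", i),
               gene = sprintf("P%d_G%03d", i, seq_len(genesPerPathway)),
               weight = rep_len(c(1, -1, 0.5), genesPerPathway),
               responsiveness_rank = seq_len(genesPerPathway),
               stringsAsFactors = FALSE)
  })))
}

writeNetworkTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent oracle: AUROC as concordant positive-negative pairs, ties 1/2
bruteForceAUROC <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# independent oracle: silhouette widths from explicit all-pairs distances
bruteForceSilhouette <- function(coords, labels) {
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    d_i <- sqrt(colSums((t(coords) - coords[i, ])^2))
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d_i[own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d_i[labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# independent oracle: recovery-curve area by explicit step summation
bruteForceAUCell <- function(counts_cell, members, quantile = 0.05) {
  n <- length(counts_cell)
  k <- ceiling(quantile * n)
  ord <- order(-counts_cell)  # stable: ties keep input order
  ranked <- names(counts_cell)[ord]
  m <- sum(members %in% names(counts_cell))
  area <- 0; maxarea <- 0
  for (i in seq_len(k)) {
    area <- area + sum(ranked[seq_len(i)] %in% members)
    maxarea <- maxarea + min(i, m)
  }
  area / maxarea
}

# independent oracle: weighted-KS enrichment score by explicit running sum
# (hit: |stat| / sum hit |stat|; miss: 1 / n_miss), max deviation from zero
bruteForceGseaES <- function(stat, members) {
  ord <- order(stat, decreasing = TRUE)
  s <- stat[ord]
  hit <- names(s) %in% members
  nr <- sum(abs(s[hit]))
  nmiss <- sum(!hit)
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) abs(s[i]) / nr else -1 / nmiss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# independent oracle: permutation null for the regulon enrichment score
permutationNESZ <- function(signature, tf_edges, nShuffle = 10000L,
                            seed = 7L) {
  w <- tf_edges$mode * tf_edges$likelihood
  stat <- function(values) {
    n <- length(values)
    q <- qnorm(rank(values, ties.method = "average") / (n + 1))
    names(q) <- names(values)
    sum(w * q[tf_edges$target])
  }
  obs <- stat(signature)
  set.seed(seed)
  null <- replicate(nShuffle, {
    shuffled <- setNames(sample(signature), names(signature))
    stat(shuffled)
  })
  (obs - mean(null)) / sd(null)
}
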