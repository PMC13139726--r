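# Programmatic fixtures shared across test files.

# tiny deterministic dataset: 4 TFs, 9 targets, 40 cells (the negative pool
# comfortably exceeds the positive count, so 1:1 sampling never caps)
tinyData <- function(seed = 11L) {
  simulateDataset(nTFs = 4L, nTargets = 9L, nCells = 40L, edgesPerNode = 2L,
                  seed = seed)
}

# hand-written expression CSV in the BEELINE dialect
writeExprCSV <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# a GraphInput built directly from a feature matrix and undirected edges,
# bypassing GRNData (for encoder/TDA unit tests)
rawGraphInput <- function(features, und) {
  M <- nrow(features)
  und <- matrix(as.integer(und), ncol = 2)
  edges <- rbind(und, und[, 2:1, drop = FALSE], cbind(seq_len(M), seq_len(M)))
  colnames(edges) <- c("src", "dst")
  colnames(und) <- c("u", "v")
  deg <- numeric(M)
  if (nrow(und)) {
    deg <- tabulate(und[, 1], M) + tabulate(und[, 2], M)
    if (max(deg) > 0) deg <- deg / max(deg)
  }
  new("GraphInput", features = features, edges = edges, trainEdges = und,
      degree = deg, geneIds = sprintf("N%d", seq_len(M)))
}

# independent dim-0 persistence oracle: re-count connected components after
# each edge insertion (igraph); a drop at edge k emits death w_k
dim0Oracle <- function(und, w, nNodes) {
  ord <- order(w, und[, 1], und[, 2], method = "radix")
  und <- und[ord, , drop = FALSE]; w <- w[ord]
  g <- igraph::make_empty_graph(n = nNodes, directed = FALSE)
  comp <- nNodes
  deaths <- numeric(0)
  for (k in seq_along(w)) {
    g <- igraph::add_edges(g, c(und[k, 1], und[k, 2]))
    newComp <- igraph::count_components(g)
    if (newComp < comp) deaths <- c(deaths, w[k])
    comp <- newComp
  }
  deaths
}

# exhaustive pairwise AUROC oracle (ties 1/2), independent of rank-based code
aurocOracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# per-positive precision-at-rank AUPRC oracle (stable tie order by index)
auprcOracle <- function(labels, scores) {
  n <- length(scores)
  key <- order(-scores, seq_len(n), method = "radix")
  pos <- which(labels[key] == 1)
  mean(vapply(pos, function(r) sum(labels[key][seq_len(r)] == 1) / r, 0))
}
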