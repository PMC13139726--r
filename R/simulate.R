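## Synthetic BEELINE-style fixtures: a planted scale-free TF->target
## network and a linear structural-equation expression matrix with
## additive noise and optional zero-inflation (dropout). An emulation of
## single-cell regulatory data sufficient for link-prediction testing,
## not a kinetic/biological simulator.

#' Simulate a planted regulatory network
#'
#' Transcription factors form a hub layer; each target gene attaches to
#' \code{edgesPerNode} distinct TFs with probability proportional to the
#' TF's current out-degree plus one (preferential attachment), producing
#' the right-skewed, scale-free out-degree profile typical of regulatory
#' networks.
#'
#' @param nTFs number of TFs (>= 2).
#' @param nTargets number of target genes.
#' @param edgesPerNode TF parents per target (<= nTFs).
#' @param seed integer seed.
#' @return list with \code{network} (data.frame \code{tf}, \code{target}),
#'   \code{tfs} and \code{genes} (TF ids then target ids).
#' @export
simulateGRN <- function(nTFs = 10L, nTargets = 100L, edgesPerNode = 2L,
                        seed = 1L) {
  stopifnot(nTFs >= 2L, nTargets >= 1L, edgesPerNode >= 1L,
            edgesPerNode <= nTFs)
  tfs <- sprintf("TF%d", seq_len(nTFs))
  targets <- sprintf("G%d", seq_len(nTargets))
  withSeed(seed, {
    outDeg <- rep(0L, nTFs)
    tfCol <- character(0L); tgCol <- character(0L)
    for (t in seq_len(nTargets)) {
      parents <- sample.int(nTFs, edgesPerNode, prob = outDeg + 1)
      outDeg[parents] <- outDeg[parents] + 1L
      tfCol <- c(tfCol, tfs[parents])
      tgCol <- c(tgCol, rep(targets[t], edgesPerNode))
    }
    list(network = data.frame(tf = tfCol, target = tgCol,
                              stringsAsFactors = FALSE),
         tfs = tfs, genes = c(tfs, targets))
  })
}

#' Simulate expression from a planted network
#'
#' Linear structural-equation model: each TF's per-cell expression is the
#' absolute value of a mixture of a shared latent program and private
#' noise (so TFs are mildly correlated, as co-regulated hubs are); each
#' target is the weighted sum of its TF parents (weights of magnitude
#' \code{effectSd} and random sign) plus Gaussian noise. The matrix is
#' shifted to non-negative to mimic count-like data, then entries are
#' zeroed independently with probability \code{dropoutRate} to emulate
#' scRNA-seq dropout.
#'
#' @param grn output of [simulateGRN()].
#' @param nCells number of cells (>= 10).
#' @param effectSd magnitude of regulatory weights.
#' @param noiseSd additive noise standard deviation on targets.
#' @param dropoutRate zero-inflation probability in [0, 1).
#' @param nPrograms latent programs the TFs load on (default
#'   \code{max(2, ceiling(nTFs / 3))}).
#' @param seed integer seed.
#' @return numeric matrix genes x cells with gene/cell ids as dimnames;
#'   attribute \code{dropoutMask} marks forced zeros.
#' @export
simulateExpression <- function(grn, nCells = 300L, effectSd = 1,
                               noiseSd = 0.3, dropoutRate = 0.3,
                               nPrograms = NULL, seed = 1L) {
  stopifnot(nCells >= 10L, effectSd > 0, noiseSd >= 0,
            dropoutRate >= 0, dropoutRate < 1)
  tfs <- grn$tfs
  genes <- grn$genes
  targets <- setdiff(genes, tfs)
  if (is.null(nPrograms)) nPrograms <- max(2L, ceiling(length(tfs) / 3))
  withSeed(seed, {
    Z <- matrix(rnorm(nPrograms * nCells), nPrograms, nCells)
    rho <- 0.5
    X <- matrix(0, length(genes), nCells,
                dimnames = list(genes, sprintf("C%d", seq_len(nCells))))
    prog <- sample.int(nPrograms, length(tfs), replace = TRUE)
    for (i in seq_along(tfs)) {
      X[tfs[i], ] <- abs(rho * Z[prog[i], ] + sqrt(1 - rho^2) * rnorm(nCells))
    }
    wSign <- setNames(sample(c(-1, 1), nrow(grn$network), replace = TRUE),
                      NULL)
    for (j in seq_along(targets)) {
      tg <- targets[j]
      rows <- which(grn$network$target == tg)
      val <- rnorm(nCells, sd = noiseSd)
      for (r in rows) {
        val <- val + wSign[r] * effectSd * X[grn$network$tf[r], ]
      }
      X[tg, ] <- val
    }
    ## per-gene shift to a zero baseline: keeps each gene's dynamic range
    ## comparable to its signal so uniform dropout attenuates rather than
    ## obliterates planted correlations (a global shift would inflate every
    ## baseline to |matrix minimum| and make zeroing dominate the variance)
    X <- X - apply(X, 1L, min)
    mask <- matrix(runif(length(X)) < dropoutRate, nrow(X), ncol(X))
    X[mask] <- 0
    attr(X, "dropoutMask") <- mask
    X
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulateGRN()] and
#' [simulateExpression()] into a ready-to-use [GRNData-class] with source
#' label \code{"synthetic"}.
#'
#' @inheritParams simulateGRN
#' @inheritParams simulateExpression
#' @return a [GRNData-class].
#' @export
simulateDataset <- function(nTFs = 10L, nTargets = 100L, nCells = 300L,
                            edgesPerNode = 2L, effectSd = 1, noiseSd = 0.3,
                            dropoutRate = 0.3, seed = 1L) {
  grn <- simulateGRN(nTFs, nTargets, edgesPerNode, seed = seed)
  X <- simulateExpression(grn, nCells, effectSd, noiseSd, dropoutRate,
                          seed = seed + 1L)
  attr(X, "dropoutMask") <- NULL
  grnData(X, grn$network, grn$tfs, sourceLabel = "synthetic")
}

#' Write a dataset as a BEELINE-style fixture
#'
#' Emits \code{ExpressionData.csv} (gene rows, cell columns),
#' \code{network.csv} (\code{Gene1,Gene2}) and \code{TF.csv} in the
#' dialects the readers consume; the files round-trip through
#' [readExpression()], [readNetwork()] and [readTFList()].
#'
#' @param data a [GRNData-class].
#' @param outDir output directory (created if missing).
#' @return named character vector of the three file paths.
#' @export
writeFixture <- function(data, outDir) {
  stopifnot(is(data, "GRNData"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  X <- exprMatrix(data)
  exprPath <- file.path(outDir, "ExpressionData.csv")
  con <- file(exprPath, "wt")
  writeLines(paste(c("gene", colnames(X)), collapse = ","), con)
  writeLines(paste(rownames(X),
                   apply(X, 1L, function(r) {
                     paste(formatC(r, format = "g", digits = 17), collapse = ",")
                   }), sep = ","), con)
  close(con)
  nwPath <- file.path(outDir, "network.csv")
  nw <- networkEdges(data)
  writeLines(c("Gene1,Gene2", paste(nw$tf, nw$target, sep = ",")), nwPath)
  tfPath <- file.path(outDir, "TF.csv")
  writeLines(c("TF", tfList(data)), tfPath)
  c(expression = exprPath, network = nwPath, tfs = tfPath)
}
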