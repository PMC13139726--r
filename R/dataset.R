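## Supervised problem construction: edge splits, negative sampling, and the
## encoder-facing GraphInput. The training adjacency and the persistence
## filtration see training positives only (inductive, leakage-free).

## Evaluate expr under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

pairKey <- function(tf, target) paste(tf, target, sep = "\r")

#' Split positive edges into train/validation/test
#'
#' Shuffles the gold-standard edges under the given seed and allocates
#' \code{floor(trainFrac * n)} to training, \code{floor(valFrac * n)} to
#' validation, and the remainder to test (the 8/10-1/10 holdout protocol
#' at the defaults).
#'
#' @param pairs two-column matrix or data.frame of (tf, target) indices.
#' @param trainFrac,valFrac fractions in (0,1); test takes the remainder.
#' @param seed integer seed.
#' @return list of three data.frames \code{train}, \code{val}, \code{test}
#'   with columns \code{tf}, \code{target}.
#' @examples
#' sp <- splitPositives(cbind(rep(1, 10), 2:11), seed = 1)
#' vapply(sp, nrow, 1L)  # 8, 1, 1
#' @export
splitPositives <- function(pairs, trainFrac = 0.8, valFrac = 0.1, seed = 1L) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 positive edges to split, got ", n)
  if (trainFrac <= 0 || trainFrac >= 1 || valFrac <= 0 || valFrac >= 1 ||
      trainFrac + valFrac >= 1) {
    stop("fractions must lie in (0,1) and leave room for a test split")
  }
  ord <- withSeed(seed, sample.int(n))
  nTrain <- floor(trainFrac * n)
  nVal <- floor(valFrac * n)
  idx <- list(train = ord[seq_len(nTrain)],
              val = ord[nTrain + seq_len(nVal)],
              test = ord[setdiff(seq_len(n), seq_len(nTrain + nVal))])
  if (n >= 10L && any(vapply(idx, length, 1L) == 0L)) {
    warning("a split is empty despite a positive fraction")
  }
  lapply(idx, function(i) {
    data.frame(tf = as.integer(pairs[i, 1L]), target = as.integer(pairs[i, 2L]))
  })
}

## Enumerate the (tf, gene) candidate pool excluding self-pairs and the
## full gold standard. tfIdx restricted to `tfs`; returns a 2-col matrix.
negativePool <- function(tfs, nGenes, goldKeys) {
  tf <- rep(tfs, each = nGenes)
  tg <- rep.int(seq_len(nGenes), length(tfs))
  keep <- tf != tg & !(pairKey(tf, tg) %in% goldKeys)
  cbind(tf = tf[keep], target = tg[keep])
}

#' Balanced negative sampling
#'
#' Draws \code{ratio * nrow(positives)} TF-gene pairs uniformly without
#' replacement from all pairs absent from the full gold standard
#' (self-pairs excluded). Excluding the whole gold standard — not just the
#' current split's positives — avoids labeling a true edge negative.
#'
#' @param positives data.frame/matrix of positive (tf, target) indices the
#'   count is keyed to.
#' @param tfs integer indices of TFs eligible as sources.
#' @param nGenes number of genes (the index space).
#' @param gold data.frame/matrix of all gold-standard (tf, target) indices.
#' @param ratio negatives per positive (default 1).
#' @param seed integer seed.
#' @return data.frame with columns \code{tf}, \code{target}.
#' @export
sampleNegativesBalanced <- function(positives, tfs, nGenes, gold,
                                    ratio = 1, seed = 1L) {
  gold <- as.matrix(gold)
  pool <- negativePool(tfs, nGenes, pairKey(gold[, 1L], gold[, 2L]))
  if (!nrow(pool)) stop("negative candidate pool is empty")
  want <- as.integer(round(ratio * nrow(as.matrix(positives))))
  if (want > nrow(pool)) {
    warning(sprintf("negative pool (%d) smaller than requested (%d); taking all",
                    nrow(pool), want))
    want <- nrow(pool)
  }
  take <- withSeed(seed, sample.int(nrow(pool), want))
  data.frame(tf = pool[take, 1L], target = pool[take, 2L])
}

#' Hard negative sampling
#'
#' For each TF appearing among the positives, candidate negatives are all
#' (tf, gene) pairs absent from the gold standard; the union over TFs is
#' truncated to \code{ratio * nrow(positives)} pairs by seeded uniform
#' subsampling. TFs whose candidate set is empty are skipped with a
#' message. This is the imbalanced, per-TF regime used with cell-type-
#' specific prior networks.
#'
#' @inheritParams sampleNegativesBalanced
#' @return data.frame with columns \code{tf}, \code{target}.
#' @export
sampleNegativesHard <- function(positives, tfs, nGenes, gold,
                                ratio = 1, seed = 1L) {
  positives <- as.matrix(positives)
  gold <- as.matrix(gold)
  goldKeys <- pairKey(gold[, 1L], gold[, 2L])
  posTFs <- intersect(unique(positives[, 1L]), tfs)
  pools <- lapply(posTFs, function(tf) {
    p <- negativePool(tf, nGenes, goldKeys)
    if (!nrow(p)) message("TF index ", tf, " has no negative candidates; skipped")
    p
  })
  pool <- do.call(rbind, pools)
  if (is.null(pool) || !nrow(pool)) stop("negative candidate pool is empty")
  want <- as.integer(round(ratio * nrow(positives)))
  if (want >= nrow(pool)) {
    if (want > nrow(pool)) {
      warning(sprintf("negative pool (%d) smaller than requested (%d); taking all",
                      nrow(pool), want))
    }
    take <- seq_len(nrow(pool))
  } else {
    take <- withSeed(seed, sample.int(nrow(pool), want))
  }
  data.frame(tf = pool[take, 1L], target = pool[take, 2L])
}

#' Build labeled train/validation/test splits
#'
#' End-to-end split construction: positives are allocated by
#' [splitPositives()], negatives are drawn by the balanced or hard scheme
#' and divided with the same fractions, and everything is returned as an
#' [EdgeSplits-class] of integer indices into \code{geneIds(data)}.
#'
#' Hard negatives default to on exactly when the network source label is
#' \code{"cell-type-specific"}, mirroring how the sampling regime is tied
#' to the provenance of the prior network, and can be overridden.
#'
#' @param data a [GRNData-class].
#' @param trainFrac,valFrac split fractions (test takes the remainder).
#' @param negRatio negatives per positive.
#' @param hardNegatives logical; \code{NULL} (default) derives it from the
#'   source label.
#' @param seed integer seed controlling shuffle and sampling.
#' @return an [EdgeSplits-class].
#' @export
buildSplits <- function(data, trainFrac = 0.8, valFrac = 0.1, negRatio = 1,
                        hardNegatives = NULL, seed = 1L) {
  stopifnot(is(data, "GRNData"))
  if (is.null(hardNegatives)) hardNegatives <- data@sourceLabel == "cell-type-specific"
  ids <- geneIds(data)
  idx <- setNames(seq_along(ids), ids)
  gold <- cbind(idx[networkEdges(data)$tf], idx[networkEdges(data)$target])
  tfs <- unname(idx[tfList(data)])
  posSplits <- splitPositives(gold, trainFrac, valFrac, seed)
  sampler <- if (hardNegatives) sampleNegativesHard else sampleNegativesBalanced
  negAll <- sampler(gold, tfs, length(ids), gold, ratio = negRatio,
                    seed = seed + 1L)
  nN <- nrow(negAll)
  negSplits <- if (nN >= 3L) {
    splitPositives(as.matrix(negAll), trainFrac, valFrac, seed + 2L)
  } else {
    list(train = negAll, val = negAll[0, ], test = negAll[0, ])
  }
  lab <- function(df, l) {
    if (!nrow(df)) return(data.frame(tf = integer(), target = integer(), label = integer()))
    data.frame(tf = df$tf, target = df$target, label = rep(l, nrow(df)))
  }
  mk <- function(nm) rbind(lab(posSplits[[nm]], 1L), lab(negSplits[[nm]], 0L))
  new("EdgeSplits",
      train = mk("train"), val = mk("val"), test = mk("test"),
      geneIds = ids, tfIds = tfList(data), seed = as.integer(seed),
      config = list(trainFrac = trainFrac, valFrac = valFrac,
                    negRatio = negRatio, hardNegatives = hardNegatives))
}

#' Assemble the encoder input graph
#'
#' Node features are the per-gene expression vectors, by default log1p-
#' transformed and per-gene z-scored (stabilizes both the cosine
#' filtration and attention logits on count-scale data), with an optional
#' normalized-degree column appended. The message-passing edge set is the
#' symmetrized training positives plus a self-loop on every node, so each
#' node's neighborhood always contains itself; validation/test edges never
#' enter.
#'
#' @param data a [GRNData-class].
#' @param trainPairs data.frame of training-split pairs (only rows with
#'   \code{label == 1} are used if a label column is present), or a
#'   two-column matrix of positive (tf, target) indices.
#' @param degreeFeature append the normalized node degree column
#'   (default TRUE).
#' @param normalizeExpression log1p + per-gene z-score (default TRUE).
#' @return a [GraphInput-class].
#' @export
buildGraphInput <- function(data, trainPairs, degreeFeature = TRUE,
                            normalizeExpression = TRUE) {
  stopifnot(is(data, "GRNData"))
  tp <- as.data.frame(trainPairs)
  if (!all(c("tf", "target") %in% names(tp))) {
    stopifnot(ncol(tp) >= 2L)
    names(tp)[1:2] <- c("tf", "target")
  }
  if ("label" %in% names(tp)) tp <- tp[tp$label == 1L, , drop = FALSE]
  M <- nrow(exprMatrix(data))
  stopifnot(!nrow(tp) || (max(tp$tf, tp$target) <= M && min(tp$tf, tp$target) >= 1))

  X <- exprMatrix(data)
  if (normalizeExpression) {
    X <- log1p(X)
    mu <- rowMeans(X)
    s <- apply(X, 1L, sd)
    s[s == 0] <- 1
    X <- (X - mu) / s
  }

  ## undirected canonical training edges (u < v), duplicates collapsed
  u <- pmin(tp$tf, tp$target); v <- pmax(tp$tf, tp$target)
  keep <- u != v & !duplicated(pairKey(u, v))
  und <- cbind(u[keep], v[keep])

  deg <- numeric(M)
  if (nrow(und)) {
    t1 <- tabulate(und[, 1L], M); t2 <- tabulate(und[, 2L], M)
    deg <- t1 + t2
  }
  degNorm <- if (max(deg) > 0) deg / max(deg) else deg

  feats <- unname(X)
  if (degreeFeature) feats <- cbind(feats, degNorm)

  edges <- rbind(und, und[, 2:1, drop = FALSE],
                 cbind(seq_len(M), seq_len(M)))
  colnames(edges) <- c("src", "dst")
  colnames(und) <- c("u", "v")
  new("GraphInput", features = feats, edges = edges, trainEdges = und,
      degree = degNorm, geneIds = geneIds(data))
}
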