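test_that("positive splits follow the floor-allocation holdout protocol", {
  mk <- function(n) cbind(rep(1L, n), seq_len(n) + 1L)
  s100 <- splitPositives(mk(100), seed = 7)
  expect_identical(vapply(s100, nrow, 1L), c(train = 80L, val = 10L, test = 10L))
  s10 <- splitPositives(mk(10), seed = 7)
  expect_identical(vapply(s10, nrow, 1L), c(train = 8L, val = 1L, test = 1L))
  s5 <- splitPositives(mk(5), seed = 7)
  expect_identical(vapply(s5, nrow, 1L), c(train = 4L, val = 0L, test = 1L))
  expect_error(splitPositives(mk(2), seed = 1), "at least 3")

  # determinism and partition property
  s100b <- splitPositives(mk(100), seed = 7)
  expect_identical(s100, s100b)
  all1 <- do.call(rbind, s100)
  expect_setequal(paste(all1$tf, all1$target),
                  paste(mk(100)[, 1], mk(100)[, 2]))
  expect_identical(anyDuplicated(paste(all1$tf, all1$target)), 0L)
})

test_that("balanced negative sampling respects ratio, pool and determinism", {
  gold <- cbind(tf = rep(1:2, each = 6), target = 3:14)
  neg <- sampleNegativesBalanced(gold, tfs = 1:2, nGenes = 30, gold = gold,
                                 ratio = 1, seed = 5)
  expect_identical(nrow(neg), 12L)
  expect_false(any(paste(neg$tf, neg$target) %in% paste(gold[, 1], gold[, 2])))
  expect_false(any(neg$tf == neg$target))
  neg2 <- sampleNegativesBalanced(gold, tfs = 1:2, nGenes = 30, gold = gold,
                                  ratio = 1, seed = 5)
  expect_identical(neg, neg2)

  # pool smaller than request: capped with a warning
  goldSmall <- cbind(tf = rep(1:2, each = 6), target = rep(3:8, 2))
  expect_warning(
    negCap <- sampleNegativesBalanced(goldSmall, tfs = 1:2, nGenes = 8,
                                      gold = goldSmall, ratio = 1, seed = 1),
    "smaller")
  # pool: 2 TFs x (8 genes - self) = 14 minus 12 gold = 2
  expect_identical(nrow(negCap), 2L)
})

test_that("hard negative sampling enumerates per-TF candidate pools", {
  # 2 TFs (nodes 1-2) over 6 target genes (nodes 3-8);
  # positives: (1,3),(1,4),(2,5),(2,6); per-TF pools have 5 candidates each
  gold <- cbind(tf = c(1L, 1L, 2L, 2L), target = 3:6)
  neg <- sampleNegativesHard(gold, tfs = 1:2, nGenes = 8, gold = gold,
                             ratio = 2, seed = 3)
  expect_identical(nrow(neg), 8L)
  expect_false(any(paste(neg$tf, neg$target) %in% paste(gold[, 1], gold[, 2])))
  # exhaustively enumerated pool smaller than the request: returned whole
  gold2 <- cbind(tf = c(1L, 1L, 2L, 2L), target = c(3L, 4L, 4L, 5L))
  expect_warning(
    negAll <- sampleNegativesHard(gold2, tfs = 1:2, nGenes = 5, gold = gold2,
                                  ratio = 2, seed = 3),
    "smaller")
  poolKeys <- c(paste(1, c(2, 5)), paste(2, c(1, 3)))
  expect_setequal(paste(negAll$tf, negAll$target), poolKeys)

  # a TF whose candidates are exhausted contributes nothing
  goldFull <- cbind(tf = c(rep(1L, 2), 2L), target = c(2:3, 1L))
  expect_message(
    negSkip <- sampleNegativesHard(goldFull, tfs = 1:2, nGenes = 3,
                                   gold = goldFull, ratio = 0.34, seed = 1),
    "no negative candidates")
  expect_true(all(negSkip$tf == 2L))
})

test_that("buildSplits yields disjoint labeled splits excluding the gold standard", {
  d <- tinyData()
  sp <- buildSplits(d, seed = 4)
  tr <- splitPairs(sp, "train"); va <- splitPairs(sp, "val")
  te <- splitPairs(sp, "test")
  keys <- c(paste(tr$tf, tr$target), paste(va$tf, va$target),
            paste(te$tf, te$target))
  expect_identical(anyDuplicated(keys), 0L)

  ids <- geneIds(d)
  goldKeys <- paste(match(networkEdges(d)$tf, ids),
                    match(networkEdges(d)$target, ids))
  allNeg <- rbind(tr, va, te)
  allNeg <- allNeg[allNeg$label == 0L, ]
  expect_false(any(paste(allNeg$tf, allNeg$target) %in% goldKeys))
  allPos <- rbind(tr, va, te)
  allPos <- allPos[allPos$label == 1L, ]
  expect_setequal(paste(allPos$tf, allPos$target), goldKeys)

  # hard-negative mode bound to the cell-type-specific source label
  dH <- d
  dH@sourceLabel <- "cell-type-specific"
  spH <- buildSplits(dH, seed = 4)
  expect_true(spH@config$hardNegatives)
  expect_false(sp@config$hardNegatives)
})

test_that("graph input symmetrizes training edges, adds self-loops, normalizes degree", {
  X <- matrix(rnorm(12), 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  nw <- data.frame(tf = c("A", "B"), target = c("B", "C"))
  d <- grnData(X - min(X), nw, "A")
  # 3-node path A-B-C as training positives
  g <- buildGraphInput(d, cbind(c(1L, 2L), c(2L, 3L)), degreeFeature = TRUE)
  expect_equal(degreeVector(g), c(0.5, 1, 0.5))
  e <- graphEdges(g)
  expect_true(all(paste(c(1, 2, 2, 3, 1, 2, 3), c(2, 1, 3, 2, 1, 2, 3)) %in%
                  paste(e[, 1], e[, 2])))
  A <- adjacencyMatrix(g)
  expect_true(Matrix::isSymmetric(A))
  expect_true(all(Matrix::diag(A) == 1))
  expect_identical(ncol(nodeFeatures(g)), ncol(X) + 1L)
  g0 <- buildGraphInput(d, cbind(c(1L, 2L), c(2L, 3L)), degreeFeature = FALSE)
  expect_identical(ncol(nodeFeatures(g0)), ncol(X))
})

test_that("graph input depends only on the training split (no leakage)", {
  d <- tinyData()
  sp <- buildSplits(d, seed = 4)
  g1 <- buildGraphInput(d, splitPairs(sp, "train"))
  # shuffle val/test contents; adjacency must be bit-identical
  sp2 <- sp
  sp2@val <- sp@test
  sp2@test <- sp@val
  g2 <- buildGraphInput(d, splitPairs(sp2, "train"))
  expect_identical(graphEdges(g1), graphEdges(g2))
  expect_identical(nodeFeatures(g1), nodeFeatures(g2))
  # and no val/test positive appears in the message-passing edges
  off <- graphEdges(g1)
  off <- off[off[, 1] != off[, 2], , drop = FALSE]
  heldOut <- rbind(splitPairs(sp, "val"), splitPairs(sp, "test"))
  heldOut <- heldOut[heldOut$label == 1L, ]
  # held-out (u,v) absent unless the reverse orientation is a train edge
  trainKeys <- paste(off[, 1], off[, 2])
  tr <- splitPairs(sp, "train")
  trPos <- tr[tr$label == 1L, ]
  trKeys <- c(paste(trPos$tf, trPos$target), paste(trPos$target, trPos$tf))
  expect_true(all(trainKeys %in% trKeys))
})
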