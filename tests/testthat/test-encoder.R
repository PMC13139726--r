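# internal autodiff + attention machinery (accessed via :::)

adT <- function() topoGRN:::adTape()

test_that("attention logits follow the LeakyReLU(a . [Wx_i || Wx_j]) form", {
  tape <- adT()
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  W <- diag(2)
  xW <- topoGRN:::adMatmul(tape, topoGRN:::adConst(tape, X),
                           topoGRN:::adConst(tape, W))
  # zero attention vector -> all logits zero
  a0 <- topoGRN:::adMatmul(tape, xW, topoGRN:::adConst(tape, matrix(0, 2, 1)))
  e0 <- topoGRN:::adLeakyReLU(tape, a0, 0.4)
  expect_equal(as.vector(topoGRN:::adValue(tape, e0)), c(0, 0))
  # identity region and negative slope
  z <- topoGRN:::adConst(tape, matrix(c(2.5, -1), 2, 1))
  e <- topoGRN:::adLeakyReLU(tape, z, 0.4)
  expect_equal(as.vector(topoGRN:::adValue(tape, e)), c(2.5, -0.4))
})

test_that("neighborhood softmax normalizes per receiving node", {
  tape <- adT()
  # groups: node 1 has one neighbor; node 2 has two with equal logits;
  # node 3 has logits (ln 3, 0)
  logits <- matrix(c(7, 1.5, 1.5, log(3), 0), ncol = 1)
  grp <- c(1L, 2L, 2L, 3L, 3L)
  s <- topoGRN:::adSegmentSoftmax(tape, topoGRN:::adConst(tape, logits), grp)
  a <- as.vector(topoGRN:::adValue(tape, s))
  expect_equal(a[1], 1)
  expect_equal(a[2:3], c(0.5, 0.5))
  expect_equal(a[4:5], c(0.75, 0.25))
  expect_equal(as.vector(tapply(a, grp, sum)), c(1, 1, 1))
})

test_that("a single attention layer reproduces hand-computable aggregations", {
  cfg <- grnConfig(nLayers = 1L, headsFirst = 1L, headsRest = 1L,
                   hiddenDim = 3L, dropout = 0, variant = "no_residual")
  # star: center 1 with leaves 2..4, plus self-loops
  X <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  g <- rawGraphInput(X, rbind(c(1, 2), c(1, 3), c(1, 4)))
  set.seed(5)
  m <- initGRNModel(3L, cfg)
  # force uniform attention and identity transform
  m$params[["enc.l1.h1.W"]] <- diag(3)
  m$params[["enc.l1.h1.a1"]][] <- 0
  m$params[["enc.l1.h1.a2"]][] <- 0
  fw <- topoGRN:::forwardGRN(m$params, g, rep(0, 4), cbind(1L, 2L), cfg,
                             training = FALSE)
  H <- topoGRN:::adValue(fw$tape, fw$h)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  # center aggregates mean of all four nodes (neighbors + self)
  expect_equal(H[1, ], elu(colMeans(X)), tolerance = 1e-12)
  # each leaf aggregates mean of itself and the center
  expect_equal(H[2, ], elu(colMeans(X[c(1, 2), ])), tolerance = 1e-12)

  # isolated-node setup: self-loop only returns own transformed features
  gIso <- rawGraphInput(X, matrix(integer(), 0, 2))
  fwIso <- topoGRN:::forwardGRN(m$params, gIso, rep(0, 4), cbind(1L, 2L), cfg,
                                training = FALSE)
  expect_equal(topoGRN:::adValue(fwIso$tape, fwIso$h), elu(X),
               tolerance = 1e-12)
})

test_that("multi-head concatenation and residual projections set output widths", {
  X <- matrix(rnorm(5 * 7), 5, 7)
  g <- rawGraphInput(X, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  cfg <- grnConfig(nLayers = 2L, headsFirst = 2L, headsRest = 2L,
                   hiddenDim = 3L, dropout = 0)
  set.seed(6)
  m <- initGRNModel(7L, cfg)
  fw <- topoGRN:::forwardGRN(m$params, g, rep(0, 4), cbind(1L, 2L), cfg,
                             training = FALSE)
  expect_identical(dim(topoGRN:::adValue(fw$tape, fw$h)), c(5L, 6L))
  # layer 1 needs a learned projection (7 -> 6), layer 2 identity residual
  expect_true("enc.l1.P" %in% names(m$params))
  expect_false("enc.l2.P" %in% names(m$params))
})

test_that("embeddings are invariant to edge-list ordering and eval-deterministic", {
  set.seed(9)
  X <- matrix(rnorm(6 * 5), 6, 5)
  und <- rbind(c(1, 2), c(2, 3), c(1, 4), c(4, 5), c(5, 6))
  cfg <- grnConfig(nLayers = 2L, headsFirst = 2L, headsRest = 2L,
                   hiddenDim = 4L, dropout = 0)
  m <- initGRNModel(5L, cfg)
  g1 <- rawGraphInput(X, und)
  g2 <- rawGraphInput(X, und[c(4, 1, 5, 2, 3), ])
  f1 <- topoGRN:::forwardGRN(m$params, g1, rep(0, 4), cbind(1L, 2L), cfg, FALSE)
  f2 <- topoGRN:::forwardGRN(m$params, g2, rep(0, 4), cbind(1L, 2L), cfg, FALSE)
  expect_equal(topoGRN:::adValue(f1$tape, f1$h),
               topoGRN:::adValue(f2$tape, f2$h), tolerance = 1e-12)
  f3 <- topoGRN:::forwardGRN(m$params, g1, rep(0, 4), cbind(1L, 2L), cfg, FALSE)
  expect_identical(topoGRN:::adValue(f1$tape, f1$probs),
                   topoGRN:::adValue(f3$tape, f3$probs))
})

test_that("zero input features with zero biases give zero embeddings", {
  X <- matrix(0, 4, 3)
  g <- rawGraphInput(X, rbind(c(1, 2), c(3, 4)))
  cfg <- grnConfig(nLayers = 2L, headsFirst = 1L, headsRest = 1L,
                   hiddenDim = 3L, dropout = 0)
  set.seed(2)
  m <- initGRNModel(3L, cfg)
  fw <- topoGRN:::forwardGRN(m$params, g, rep(0, 4), cbind(1L, 2L), cfg, FALSE)
  expect_equal(max(abs(topoGRN:::adValue(fw$tape, fw$h))), 0)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  X <- matrix(rnorm(5 * 4), 5, 4)
  g <- rawGraphInput(X, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)))
  cfg <- grnConfig(nLayers = 2L, headsFirst = 2L, headsRest = 2L,
                   hiddenDim = 3L, outDim = 3L, dropout = 0)
  m <- initGRNModel(4L, cfg)
  tdaStd <- c(0.3, 0.7, 0.5, 0.9)
  pairs <- cbind(c(1L, 2L, 3L), c(4L, 5L, 1L))
  lab <- c(1, 0, 1)
  lossOf <- function(params) {
    fw <- topoGRN:::forwardGRN(params, g, tdaStd, pairs, cfg, training = FALSE)
    topoGRN:::adValue(fw$tape,
                      topoGRN:::adBCE(fw$tape, fw$probs, lab))[1, 1]
  }
  fw <- topoGRN:::forwardGRN(m$params, g, tdaStd, pairs, cfg, training = FALSE)
  lid <- topoGRN:::adBCE(fw$tape, fw$probs, lab)
  gr <- topoGRN:::adBackward(fw$tape, lid)
  eps <- 1e-5
  for (nm in names(m$params)) {
    G <- gr[[fw$pid[[nm]]]]
    if (is.null(G)) G <- m$params[[nm]] * 0
    for (i in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
      p2 <- m$params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- lossOf(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l2 <- lossOf(p2)
      num <- (l1 - l2) / (2 * eps)
      expect_lt(abs(num - G[i]) / max(1e-6, abs(num) + abs(G[i])), 1e-4)
    }
  }
})
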