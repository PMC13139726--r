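# gated fusion, TF/target branches and the pairwise decoder

smallSetup <- function(variant = "full", seed = 3L) {
  cfg <- grnConfig(nLayers = 1L, headsFirst = 2L, headsRest = 2L,
                   hiddenDim = 3L, outDim = 4L, dropout = 0, variant = variant)
  X <- matrix(rnorm(5 * 4), 5, 4)
  g <- rawGraphInput(X, rbind(c(1, 2), c(2, 3), c(4, 5)))
  set.seed(seed)
  m <- initGRNModel(4L, cfg)
  list(cfg = cfg, g = g, m = m)
}

test_that("topology vector broadcasts to identical standardized rows", {
  t0 <- summarizePersistence(list(dim0 = numeric(), dim1 = numeric()))
  cfg <- grnConfig()
  expect_equal(topoGRN:::standardizeTDA(t0, cfg), c(0, 0, 0, 0))
  tri <- summarizePersistence(list(dim0 = c(0.1, 0.2), dim1 = 0.3))
  v <- topoGRN:::standardizeTDA(tri, cfg)
  expect_equal(v, c(0.15, log1p(1), 0.2, 0.15 / (0.2 + 1e-8)),
               tolerance = 1e-9)
  # raw mode: the exact feature vector from the worked triangle example
  cfgRaw <- grnConfig(tdaLog1pCycles = FALSE)
  expect_equal(topoGRN:::standardizeTDA(tri, cfgRaw),
               unname(tdaVector(tri)), tolerance = 1e-9)
})

test_that("sigmoid gate algebra: closed, saturated and zero-topology cases", {
  s <- smallSetup()
  hf <- 2L * 3L + 4L  # encoder width + 4 topology channels
  lrelu <- function(x, a = s$cfg$attnSlope) ifelse(x >= 0, x, a * x)
  tdaStd <- c(0.3, 0.6, 0.5, 0.8)

  runFusion <- function(params, tdaStd) {
    fw <- topoGRN:::forwardGRN(params, s$g, tdaStd, cbind(1L, 2L), s$cfg, FALSE)
    list(h = topoGRN:::adValue(fw$tape, fw$h),
         f = topoGRN:::adValue(fw$tape, fw$f))
  }

  # W_g = 0, b_g = 0 -> gate is exactly 1/2, fused input 0.5 * c
  p <- s$m$params
  p[["fus.Wg"]][] <- 0; p[["fus.bg"]][] <- 0
  out <- runFusion(p, tdaStd)
  cMat <- cbind(out$h, matrix(tdaStd, nrow(out$h), 4, byrow = TRUE))
  expected <- lrelu(sweep((0.5 * cMat) %*% p[["fus.Wp"]], 2,
                          as.vector(p[["fus.bp"]]), "+"))
  expect_equal(out$f, expected, tolerance = 1e-12)

  # b_g = +20 saturates the gate open: fused input ~ c within 1e-8
  p2 <- s$m$params
  p2[["fus.Wg"]][] <- 0; p2[["fus.bg"]][] <- 20
  out2 <- runFusion(p2, tdaStd)
  expected2 <- lrelu(sweep(cMat %*% p2[["fus.Wp"]], 2,
                           as.vector(p2[["fus.bp"]]), "+"))
  expect_equal(out2$f, expected2, tolerance = 1e-8)

  # zero topology vector: the 4 topology channels of g (.) c are exactly 0,
  # so perturbing the projection rows that read them cannot change the output
  outZ1 <- runFusion(s$m$params, c(0, 0, 0, 0))
  p3 <- s$m$params
  p3[["fus.Wp"]][(hf - 3L):hf, ] <- 99
  outZ2 <- runFusion(p3, c(0, 0, 0, 0))
  expect_identical(outZ1$f, outZ2$f)
})

test_that("ablation variants rewire the architecture as specified", {
  # no_tda: no fusion parameters, branches consume the encoder width
  sNT <- smallSetup("no_tda")
  expect_false(any(grepl("^fus\\.", names(sNT$m$params))))
  expect_identical(nrow(sNT$m$params[["tf.b1.W"]]), 6L)
  fw <- topoGRN:::forwardGRN(sNT$m$params, sNT$g, c(9, 9, 9, 9),
                             cbind(1L, 2L), sNT$cfg, FALSE)
  fw2 <- topoGRN:::forwardGRN(sNT$m$params, sNT$g, c(0, 0, 0, 0),
                              cbind(1L, 2L), sNT$cfg, FALSE)
  expect_identical(topoGRN:::adValue(fw$tape, fw$probs),
                   topoGRN:::adValue(fw2$tape, fw2$probs))

  # no_fusion: plain concatenation, branch input width encoder + 4
  sNF <- smallSetup("no_fusion")
  expect_false(any(grepl("^fus\\.", names(sNF$m$params))))
  expect_identical(nrow(sNF$m$params[["tf.b1.W"]]), 10L)

  # no_branch: a single shared branch feeds both decoder roles
  sNB <- smallSetup("no_branch")
  expect_true("sh.b1.W" %in% names(sNB$m$params))
  expect_false("tf.b1.W" %in% names(sNB$m$params))
  fwB <- topoGRN:::forwardGRN(sNB$m$params, sNB$g, c(0.1, 0.2, 0.3, 0.4),
                              cbind(1L, 2L), sNB$cfg, FALSE)
  expect_identical(topoGRN:::adValue(fwB$tape, fwB$eTf),
                   topoGRN:::adValue(fwB$tape, fwB$eTg))

  # no_residual: no projection parameters in the encoder
  sNR <- smallSetup("no_residual")
  expect_false(any(grepl("^enc\\.l[0-9]+\\.P$", names(sNR$m$params))))
})

test_that("branches are independent, correctly shaped, and decoder is asymmetric", {
  s <- smallSetup()
  tdaStd <- c(0.2, 0.4, 0.3, 0.7)
  fw <- topoGRN:::forwardGRN(s$m$params, s$g, tdaStd,
                             rbind(c(1L, 2L), c(2L, 1L)), s$cfg, FALSE)
  eTf <- topoGRN:::adValue(fw$tape, fw$eTf)
  eTg <- topoGRN:::adValue(fw$tape, fw$eTg)
  expect_identical(dim(eTf), c(5L, 4L))           # M x O
  expect_identical(dim(eTg), c(5L, 4L))
  expect_gt(max(abs(eTf - eTg)), 1e-6)            # independent parameters
  probs <- as.vector(topoGRN:::adValue(fw$tape, fw$probs))
  expect_true(all(probs > 0 & probs < 1))
  expect_gt(abs(probs[1] - probs[2]), 1e-12)      # score(i,j) != score(j,i)
})

test_that("an all-zero decoder outputs probability one half for every pair", {
  s <- smallSetup()
  p <- s$m$params
  for (nm in grep("^dec\\.", names(p), value = TRUE)) {
    p[[nm]][] <- if (grepl("\\.g[0-9]$", nm)) 1 else 0
  }
  p[["dec.W1"]][] <- 0; p[["dec.W2"]][] <- 0; p[["dec.W3"]][] <- 0
  fw <- topoGRN:::forwardGRN(p, s$g, c(0.5, 0.5, 0.5, 0.5),
                             rbind(c(1L, 2L), c(3L, 4L), c(5L, 1L)),
                             s$cfg, FALSE)
  expect_equal(as.vector(topoGRN:::adValue(fw$tape, fw$probs)),
               rep(0.5, 3))
})
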