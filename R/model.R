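## Model assembly: multi-head graph-attention encoder with residual
## projections, sigmoid-gated fusion of the broadcast topology vector,
## role-specific TF/target branch MLPs, and the pairwise MLP decoder.
## Forward passes are built on the autodiff tape so training gets exact
## gradients; evaluation runs the same code with dropout disabled.

glorotMat <- function(fanIn, fanOut) {
  l <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -l, l), fanIn, fanOut)
}

encoderWidths <- function(inDim, cfg) {
  heads <- c(cfg$headsFirst, rep(cfg$headsRest, cfg$nLayers - 1L))
  outs <- heads * cfg$hiddenDim
  ins <- c(inDim, outs[-cfg$nLayers])
  list(heads = heads, ins = ins, outs = outs, hOut = outs[cfg$nLayers])
}

branchInDim <- function(cfg, hOut) {
  if (cfg$variant == "no_fusion") hOut + 4L else hOut
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization for all transform/attention/projection
#' matrices, zeros for biases, ones/zeros for layer-norm affine terms.
#' Draws from the current RNG stream; [trainGRN()] seeds it.
#'
#' @param inDim input feature width (cells, plus one if the degree
#'   feature is on).
#' @param cfg configuration from [grnConfig()].
#' @return list with \code{params} (named list of matrices), \code{config}
#'   and \code{inDim}.
#' @export
initGRNModel <- function(inDim, cfg = grnConfig()) {
  W <- encoderWidths(inDim, cfg)
  H <- cfg$hiddenDim
  p <- list()
  for (l in seq_len(cfg$nLayers)) {
    for (k in seq_len(W$heads[l])) {
      nm <- sprintf("enc.l%d.h%d", l, k)
      p[[paste0(nm, ".W")]] <- glorotMat(W$ins[l], H)
      p[[paste0(nm, ".a1")]] <- glorotMat(H, 1L)
      p[[paste0(nm, ".a2")]] <- glorotMat(H, 1L)
    }
    if (cfg$variant != "no_residual" && W$ins[l] != W$outs[l]) {
      p[[sprintf("enc.l%d.P", l)]] <- glorotMat(W$ins[l], W$outs[l])
    }
  }
  hOut <- W$hOut
  if (cfg$variant %in% c("full", "no_residual", "no_branch")) {
    hf <- hOut + 4L
    p[["fus.Wg"]] <- glorotMat(hf, hf)
    p[["fus.bg"]] <- matrix(0, 1L, hf)
    p[["fus.Wp"]] <- glorotMat(hf, hOut)
    p[["fus.bp"]] <- matrix(0, 1L, hOut)
  }
  B <- hOut
  bin <- branchInDim(cfg, hOut)
  prefixes <- if (cfg$variant == "no_branch") "sh" else c("tf", "tg")
  for (pre in prefixes) {
    dims <- c(bin, B, B, B)
    for (b in 1:3) {
      nm <- sprintf("%s.b%d", pre, b)
      p[[paste0(nm, ".W")]] <- glorotMat(dims[b], dims[b + 1L])
      p[[paste0(nm, ".b")]] <- matrix(0, 1L, dims[b + 1L])
      p[[paste0(nm, ".g")]] <- matrix(1, 1L, dims[b + 1L])
      p[[paste0(nm, ".be")]] <- matrix(0, 1L, dims[b + 1L])
    }
    p[[paste0(pre, ".proj.W")]] <- glorotMat(B, cfg$outDim)
    p[[paste0(pre, ".proj.b")]] <- matrix(0, 1L, cfg$outDim)
  }
  O <- cfg$outDim
  p[["dec.W1"]] <- glorotMat(2L * O, O); p[["dec.b1"]] <- matrix(0, 1L, O)
  p[["dec.g1"]] <- matrix(1, 1L, O);    p[["dec.be1"]] <- matrix(0, 1L, O)
  p[["dec.W2"]] <- glorotMat(O, O);     p[["dec.b2"]] <- matrix(0, 1L, O)
  p[["dec.g2"]] <- matrix(1, 1L, O);    p[["dec.be2"]] <- matrix(0, 1L, O)
  p[["dec.W3"]] <- glorotMat(O, 1L);    p[["dec.b3"]] <- matrix(0, 1L, 1L)
  list(params = p, config = cfg, inDim = inDim)
}

dropMask <- function(nr, nc, rate) {
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

adDropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  v <- adValue(tape, x)
  adMul(tape, x, adConst(tape, dropMask(nrow(v), ncol(v), rate)))
}

## One multi-head attention layer: per head, logits
## e_ij = LeakyReLU(a1 . W x_i + a2 . W x_j) for receiver i and neighbor j,
## softmax over each receiver's neighborhood, attention-weighted sum of
## transformed neighbors; heads concatenated.
gatLayer <- function(tape, pid, hIn, src, dst, layer, heads, cfg, training) {
  outs <- vector("list", heads)
  nNodes <- nrow(adValue(tape, hIn))
  for (k in seq_len(heads)) {
    nm <- sprintf("enc.l%d.h%d", layer, k)
    Wx <- adMatmul(tape, hIn, pid[[paste0(nm, ".W")]])
    q1 <- adMatmul(tape, Wx, pid[[paste0(nm, ".a1")]])
    q2 <- adMatmul(tape, Wx, pid[[paste0(nm, ".a2")]])
    e <- adAdd(tape, adRows(tape, q1, dst), adRows(tape, q2, src))
    e <- adLeakyReLU(tape, e, cfg$attnSlope)
    alpha <- adSegmentSoftmax(tape, e, dst)
    alpha <- adDropout(tape, alpha, cfg$dropout, training)
    msg <- adRowScale(tape, adRows(tape, Wx, src), alpha)
    outs[[k]] <- adScatterSum(tape, msg, dst, nNodes)
  }
  h <- outs[[1L]]
  for (k in seq_len(heads)[-1L]) h <- adCbind(tape, h, outs[[k]])
  h
}

encoderForward <- function(tape, pid, xId, src, dst, cfg, training, inDim) {
  W <- encoderWidths(inDim, cfg)
  h <- xId
  for (l in seq_len(cfg$nLayers)) {
    hDrop <- adDropout(tape, h, cfg$dropout, training)
    agg <- gatLayer(tape, pid, hDrop, src, dst, l, W$heads[l], cfg, training)
    if (cfg$variant != "no_residual") {
      res <- if (W$ins[l] == W$outs[l]) h else {
        adMatmul(tape, h, pid[[sprintf("enc.l%d.P", l)]])
      }
      agg <- adAdd(tape, agg, res)
    }
    h <- adELU(tape, agg)
    if (any(!is.finite(adValue(tape, h)))) {
      stop("non-finite embeddings at encoder layer ", l)
    }
  }
  h
}

## Standardized topology channels: log1p on the cycle count (unbounded
## integer) then fixed per-channel scaling, so no channel dominates gates.
standardizeTDA <- function(tda, cfg) {
  v <- unname(tdaVector(tda))
  if (isTRUE(cfg$tdaLog1pCycles)) v[2L] <- log1p(v[2L])
  v * cfg$tdaChannelScale
}

fusionForward <- function(tape, pid, h, tdaStd, cfg, training) {
  M <- nrow(adValue(tape, h))
  if (cfg$variant == "no_tda") return(h)
  tBroad <- adConst(tape, matrix(tdaStd, M, 4L, byrow = TRUE))
  cId <- adCbind(tape, h, tBroad)
  if (cfg$variant == "no_fusion") return(cId)
  g <- adSigmoid(tape, adAddBias(tape, adMatmul(tape, cId, pid[["fus.Wg"]]),
                                 pid[["fus.bg"]]))
  f <- adMul(tape, g, cId)
  adLeakyReLU(tape, adAddBias(tape, adMatmul(tape, f, pid[["fus.Wp"]]),
                              pid[["fus.bp"]]),
              cfg$attnSlope)
}

## One branch: 3 x (linear -> layer norm -> LeakyReLU -> dropout), then a
## LeakyReLU projection to the output width.
branchForward <- function(tape, pid, pre, f, cfg, training) {
  x <- f
  for (b in 1:3) {
    nm <- sprintf("%s.b%d", pre, b)
    x <- adAddBias(tape, adMatmul(tape, x, pid[[paste0(nm, ".W")]]),
                   pid[[paste0(nm, ".b")]])
    x <- adLayerNorm(tape, x, pid[[paste0(nm, ".g")]], pid[[paste0(nm, ".be")]])
    x <- adLeakyReLU(tape, x, cfg$attnSlope)
    x <- adDropout(tape, x, cfg$dropout, training)
  }
  adLeakyReLU(tape,
              adAddBias(tape, adMatmul(tape, x, pid[[paste0(pre, ".proj.W")]]),
                        pid[[paste0(pre, ".proj.b")]]),
              cfg$attnSlope)
}

## Pairwise decoder: c = [e_tf(i) || e_target(j)], two
## (linear -> LeakyReLU -> layer norm) blocks, a final linear to a scalar,
## and a sigmoid to yield a probability for the cross-entropy loss.
decoderForward <- function(tape, pid, eTf, eTg, pairs, cfg) {
  cId <- adCbind(tape, adRows(tape, eTf, pairs[, 1L]),
                 adRows(tape, eTg, pairs[, 2L]))
  x <- adAddBias(tape, adMatmul(tape, cId, pid[["dec.W1"]]), pid[["dec.b1"]])
  x <- adLayerNorm(tape, adLeakyReLU(tape, x, cfg$attnSlope),
                   pid[["dec.g1"]], pid[["dec.be1"]])
  x <- adAddBias(tape, adMatmul(tape, x, pid[["dec.W2"]]), pid[["dec.b2"]])
  x <- adLayerNorm(tape, adLeakyReLU(tape, x, cfg$attnSlope),
                   pid[["dec.g2"]], pid[["dec.be2"]])
  iId <- adAddBias(tape, adMatmul(tape, x, pid[["dec.W3"]]), pid[["dec.b3"]])
  adSigmoid(tape, iId)
}

## Full forward pass on a fresh tape. Returns tape, param-id map, and node
## ids for embeddings/branch outputs/pair probabilities.
forwardGRN <- function(params, graph, tdaStd, pairs, cfg, training = FALSE) {
  tape <- adTape()
  pid <- lapply(params, function(m) adParam(tape, m))
  X <- nodeFeatures(graph)
  xId <- adConst(tape, X)
  edges <- graphEdges(graph)
  h <- encoderForward(tape, pid, xId, edges[, 1L], edges[, 2L], cfg,
                      training, ncol(X))
  f <- fusionForward(tape, pid, h, tdaStd, cfg, training)
  if (cfg$variant == "no_branch") {
    eTf <- branchForward(tape, pid, "sh", f, cfg, training)
    eTg <- eTf
  } else {
    eTf <- branchForward(tape, pid, "tf", f, cfg, training)
    eTg <- branchForward(tape, pid, "tg", f, cfg, training)
  }
  probs <- decoderForward(tape, pid, eTf, eTg, as.matrix(pairs), cfg)
  list(tape = tape, pid = pid, h = h, f = f, eTf = eTf, eTg = eTg,
       probs = probs)
}

#' Node embeddings from a fitted model
#'
#' Runs the encoder (and fusion, when enabled) in evaluation mode with the
#' stored best checkpoint and returns the per-gene embedding matrix.
#'
#' @param fit a [GRNFit-class].
#' @param stage \code{"encoder"} for raw attention embeddings or
#'   \code{"fused"} for the gated, topology-aware representation.
#' @return numeric matrix with gene ids as rownames.
#' @export
geneEmbeddings <- function(fit, stage = c("fused", "encoder")) {
  stage <- match.arg(stage)
  cfg <- fit@config
  fw <- forwardGRN(fit@params, fit@graph, standardizeTDA(fit@tda, cfg),
                   cbind(1L, 1L), cfg, training = FALSE)
  out <- adValue(fw$tape, if (stage == "encoder") fw$h else fw$f)
  rownames(out) <- geneIds(fit@graph)
  out
}
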