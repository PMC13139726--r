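## Training: Adam + binary cross-entropy over labeled TF-target pairs.
## Per optimizer step the whole graph is encoded and fused (full-batch
## message passing) while labeled pairs are decoded in shuffled
## mini-batches — the standard reconciliation of full-batch graph encoding
## with an edge batch size.

#' Mean binary cross-entropy
#'
#' \code{-(1/K) sum(y log p + (1-y) log(1-p))} with probabilities clamped
#' to \code{[eps, 1-eps]}.
#'
#' @param labels 0/1 vector.
#' @param probs predicted probabilities in (0,1).
#' @param eps clamp bound (default 1e-7).
#' @return scalar loss.
#' @examples
#' bceLoss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bceLoss <- function(labels, probs, eps = 1e-7) {
  K <- length(labels)
  if (K == 0L) stop("empty label vector")
  stopifnot(length(probs) == K, all(labels %in% c(0, 1)))
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

## Score labeled pairs in evaluation mode (no dropout, no RNG use).
scorePairs <- function(params, graph, tdaStd, pairs, cfg) {
  if (!nrow(pairs)) return(numeric())
  fw <- forwardGRN(params, graph, tdaStd, as.matrix(pairs[, c("tf", "target")]),
                   cfg, training = FALSE)
  as.vector(adValue(fw$tape, fw$probs))
}

#' Train the link-prediction model
#'
#' Builds the training-only graph input and its persistence features (once,
#' before epoch 0), then runs Adam over shuffled edge mini-batches for
#' \code{config$epochs} epochs. Validation AUROC/AUPRC are computed every
#' epoch and the best-validation-AUPRC parameters are kept as the
#' checkpoint used for prediction. Fully reproducible for a fixed
#' \code{config$seed}.
#'
#' @param data a [GRNData-class].
#' @param splits an [EdgeSplits-class] from [buildSplits()].
#' @param config list from [grnConfig()].
#' @param graph optional pre-built [GraphInput-class]; by default built
#'   from the training positives of \code{splits}.
#' @param verbose print per-epoch progress.
#' @return a [GRNFit-class].
#' @export
trainGRN <- function(data, splits, config = grnConfig(), graph = NULL,
                     verbose = FALSE) {
  stopifnot(is(data, "GRNData"), is(splits, "EdgeSplits"))
  cfg <- config
  if (is.null(graph)) {
    graph <- buildGraphInput(data, splitPairs(splits, "train"),
                             degreeFeature = cfg$degreeFeature,
                             normalizeExpression = cfg$normalizeExpression)
  }
  tda <- computeTDAFeatures(graph, scale = cfg$tdaScale, sigma = cfg$tdaSigma)
  tdaStd <- standardizeTDA(tda, cfg)

  tr <- splitPairs(splits, "train")
  va <- splitPairs(splits, "val")
  if (!nrow(tr)) stop("empty training split")
  K <- nrow(tr)
  trPairs <- as.matrix(tr[, c("tf", "target")])
  trLab <- tr$label

  hist <- data.frame(epoch = integer(), loss = numeric(),
                     valAUROC = numeric(), valAUPRC = numeric())
  best <- list(params = NULL, epoch = NA_integer_, valAUPRC = -Inf)

  withSeed(cfg$seed, {
    model <- initGRNModel(ncol(nodeFeatures(graph)), cfg)
    params <- model$params
    opt <- adamInit(params)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(K)
      starts <- seq(1L, K, by = cfg$batchSize)
      lossSum <- 0
      for (s in starts) {
        take <- perm[s:min(s + cfg$batchSize - 1L, K)]
        fw <- forwardGRN(params, graph, tdaStd,
                         trPairs[take, , drop = FALSE], cfg, training = TRUE)
        lossId <- adBCE(fw$tape, fw$probs, trLab[take])
        lossVal <- adValue(fw$tape, lossId)[1L, 1L]
        if (!is.finite(lossVal)) {
          stop(sprintf("non-finite loss at epoch %d, batch starting %d",
                       epoch, s))
        }
        grads <- adBackward(fw$tape, lossId)
        gmap <- lapply(fw$pid, function(id) grads[[id]])
        upd <- adamStep(params, gmap, opt, cfg$lr, cfg$weightDecay)
        params <- upd$params
        opt <- upd$state
        lossSum <- lossSum + lossVal * length(take)
      }
      epochLoss <- lossSum / K
      vAUROC <- NA_real_; vAUPRC <- NA_real_
      if (nrow(va) && length(unique(va$label)) == 2L) {
        vp <- scorePairs(params, graph, tdaStd, va, cfg)
        vAUROC <- aurocScore(va$label, vp)
        vAUPRC <- auprcScore(va$label, vp)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = epochLoss,
                                     valAUROC = vAUROC, valAUPRC = vAUPRC))
      sel <- if (is.na(vAUPRC)) epoch == cfg$epochs else vAUPRC > best$valAUPRC
      if (sel) best <- list(params = params, epoch = epoch,
                            valAUPRC = if (is.na(vAUPRC)) NA_real_ else vAUPRC)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUROC %.4f  AUPRC %.4f",
                        epoch, epochLoss, vAUROC, vAUPRC))
      }
    }
    finalParams <- params
    new("GRNFit", params = best$params, finalParams = finalParams,
        history = hist, bestEpoch = as.integer(best$epoch), config = cfg,
        tda = tda, graph = graph, splits = splits)
  })
}

objectHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Hash of an EdgeSplits object
#'
#' Stable digest of the labeled pairs of all three splits; used to verify
#' that ablation variants (or re-runs) trained on identical supervision.
#'
#' @param splits an [EdgeSplits-class].
#' @return character md5 string.
#' @export
splitsHash <- function(splits) {
  objectHash(list(splits@train, splits@val, splits@test, splits@geneIds))
}

#' Run the ablation battery
#'
#' Trains the requested model variants with identical splits and seeds
#' (one [buildSplits()] per seed, shared across variants) and reports mean
#' and standard deviation of held-out test AUROC/AUPRC per variant.
#'
#' @param data a [GRNData-class].
#' @param variants subset of \code{full}, \code{no_tda}, \code{no_fusion},
#'   \code{no_residual}, \code{no_branch}.
#' @param seeds integer vector, one training repeat per seed.
#' @param config base configuration; \code{variant} and \code{seed} are
#'   overridden per run.
#' @param trainFrac,valFrac,negRatio,hardNegatives forwarded to
#'   [buildSplits()].
#' @return data.frame with one row per variant (mean/sd of both metrics);
#'   attributes \code{perRun} (per-seed metrics) and \code{splitHashes}.
#' @export
runAblation <- function(data, variants = c("full", "no_tda", "no_fusion",
                                           "no_residual", "no_branch"),
                        seeds = 1L, config = grnConfig(),
                        trainFrac = 0.8, valFrac = 0.1, negRatio = 1,
                        hardNegatives = NULL) {
  known <- c("full", "no_tda", "no_fusion", "no_residual", "no_branch")
  bad <- setdiff(variants, known)
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  per <- list()
  hashes <- character()
  for (seed in seeds) {
    splits <- buildSplits(data, trainFrac, valFrac, negRatio, hardNegatives,
                          seed = seed)
    hashes[as.character(seed)] <- splitsHash(splits)
    for (v in variants) {
      cfg <- config
      cfg$variant <- v
      cfg$seed <- as.integer(seed)
      fit <- trainGRN(data, splits, cfg)
      ev <- evaluateSplit(fit, "test")
      per[[length(per) + 1L]] <- data.frame(
        variant = v, seed = seed, splitHash = hashes[[as.character(seed)]],
        testAUROC = ev$auroc, testAUPRC = ev$auprc)
    }
  }
  perRun <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(perRun, perRun$variant), function(d) {
    data.frame(variant = d$variant[1L],
               meanAUROC = mean(d$testAUROC), sdAUROC = sd(d$testAUROC),
               meanAUPRC = mean(d$testAUPRC), sdAUPRC = sd(d$testAUPRC),
               n = nrow(d))
  }))
  agg <- agg[match(variants, agg$variant), ]
  rownames(agg) <- NULL
  attr(agg, "perRun") <- perRun
  attr(agg, "splitHashes") <- hashes
  agg
}

#' Save / load a fitted model
#'
#' Checkpoints are ordinary RDS files holding the full [GRNFit-class];
#' restoring one reproduces its recorded metrics exactly.
#'
#' @param fit a [GRNFit-class].
#' @param path file path.
#' @return \code{writeCheckpoint} the path invisibly;
#'   \code{readCheckpoint} the restored fit.
#' @export
writeCheckpoint <- function(fit, path) {
  stopifnot(is(fit, "GRNFit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(is(fit, "GRNFit"))
  fit
}
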