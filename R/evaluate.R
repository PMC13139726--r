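## Ranking metrics and network-level diagnostics on held-out pairs.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, ties counted 1/2
#' (midranks), so the value is deterministic and invariant to any strictly
#' monotone transform of the scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) {
    stop("AUROC undefined: only one class present (", nPos, " positives, ",
         nNeg, " negatives)")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the mean, over positives, of the precision
#' at each positive's rank in descending-score order (ties broken by
#' stable original index). This is the stricter convention for ranking
#' comparisons; no trapezoidal PR interpolation is applied.
#'
#' @inheritParams aurocScore
#' @return AUPRC in (0, 1].
#' @export
auprcScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1)
  if (nPos == 0L || nPos == length(labels)) {
    stop("AUPRC undefined: only one class present")
  }
  ord <- order(-scores, seq_along(scores), method = "radix")
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1]) / nPos
}

#' Evaluate a fitted model on one split
#'
#' Scores the labeled pairs of the requested split with the best
#' checkpoint and reports both ranking metrics.
#'
#' @param fit a [GRNFit-class].
#' @param split \code{"train"}, \code{"val"} or \code{"test"}.
#' @param checkpoint \code{"best"} (default; the best-validation-AUPRC
#'   parameters) or \code{"final"} (last epoch, e.g. for capacity checks).
#' @return list with \code{auroc}, \code{auprc}, \code{nPos}, \code{nNeg},
#'   \code{split}.
#' @export
evaluateSplit <- function(fit, split = "test", checkpoint = c("best", "final")) {
  stopifnot(is(fit, "GRNFit"))
  checkpoint <- match.arg(checkpoint)
  pairs <- splitPairs(fit@splits, split)
  if (!nrow(pairs)) stop("split '", split, "' is empty")
  params <- if (checkpoint == "best") fit@params else fit@finalParams
  p <- scorePairs(params, fit@graph, standardizeTDA(fit@tda, fit@config),
                  pairs, fit@config)
  list(auroc = aurocScore(pairs$label, p),
       auprc = auprcScore(pairs$label, p),
       nPos = sum(pairs$label == 1L), nNeg = sum(pairs$label == 0L),
       split = split)
}

#' Score all candidate TF-target pairs
#'
#' Scores every (TF, gene) pair with TF != gene using the best checkpoint,
#' optionally excluding training positives, and returns a ranked edge
#' table ready for [writeRankedEdges()].
#'
#' @param fit a [GRNFit-class].
#' @param excludeTrain drop pairs that were training positives
#'   (default TRUE).
#' @return data.frame with \code{tf}, \code{target}, \code{score}, sorted
#'   by descending score with lexicographic tie-breaks.
#' @export
predictEdges <- function(fit, excludeTrain = TRUE) {
  stopifnot(is(fit, "GRNFit"))
  ids <- geneIds(fit@splits)
  tfIdx <- match(tfList(fit@splits), ids)
  M <- length(ids)
  tf <- rep(tfIdx, each = M)
  tg <- rep.int(seq_len(M), length(tfIdx))
  keep <- tf != tg
  if (excludeTrain) {
    tr <- splitPairs(fit@splits, "train")
    tr <- tr[tr$label == 1L, , drop = FALSE]
    keep <- keep & !(pairKey(tf, tg) %in% pairKey(tr$tf, tr$target))
  }
  pairs <- data.frame(tf = tf[keep], target = tg[keep], label = NA_integer_)
  p <- scorePairs(fit@params, fit@graph, standardizeTDA(fit@tda, fit@config),
                  pairs, fit@config)
  out <- data.frame(tf = ids[pairs$tf], target = ids[pairs$target], score = p,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$tf, out$target, method = "radix"), , drop = FALSE]
}

#' Degree distribution and power-law slope of a predicted network
#'
#' Thresholds a scored edge list (top-k per TF and/or a score cutoff),
#' tabulates node degrees over the resulting network, and fits
#' log10(frequency) against log10(degree) by least squares over the
#' nonzero bins. Scale-free networks show a negative slope. With fewer
#' than 3 nonzero degree bins the slope is reported as \code{NA}.
#'
#' @param edges data.frame with \code{tf}, \code{target} and optionally
#'   \code{score}.
#' @param topKPerTF keep only the k highest-scoring targets per TF.
#' @param threshold keep only edges with score >= threshold.
#' @return list with \code{degrees} (named per-gene degree vector),
#'   \code{histogram} (data.frame degree/frequency) and \code{slope}.
#' @export
degreeDistribution <- function(edges, topKPerTF = NULL, threshold = NULL) {
  df <- as.data.frame(edges)
  if (!is.null(threshold)) {
    stopifnot("score" %in% names(df))
    df <- df[df$score >= threshold, , drop = FALSE]
  }
  if (!is.null(topKPerTF)) {
    stopifnot("score" %in% names(df))
    df <- do.call(rbind, lapply(split(df, df$tf), function(d) {
      head(d[order(-d$score), , drop = FALSE], topKPerTF)
    }))
  }
  if (!nrow(df)) stop("thresholded network is empty")
  deg <- table(c(as.character(df$tf), as.character(df$target)))
  histo <- as.data.frame(table(degree = as.integer(deg)),
                         stringsAsFactors = FALSE)
  histo$degree <- as.integer(as.character(histo$degree))
  names(histo)[2L] <- "frequency"
  slope <- NA_real_
  if (nrow(histo) >= 3L) {
    fitLm <- stats::lm(log10(frequency) ~ log10(degree), data = histo)
    slope <- unname(stats::coef(fitLm)[2L])
  } else {
    message("fewer than 3 nonzero degree bins; slope undefined")
  }
  list(degrees = setNames(as.integer(deg), names(deg)),
       histogram = histo, slope = slope)
}
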