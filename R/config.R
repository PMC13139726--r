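#' Model and training configuration
#'
#' Returns the default configuration with any named overrides applied;
#' unknown keys are rejected. Defaults follow the tuned settings of the
#' method: 4 attention layers of hidden width 32 with 4 heads each
#' (concatenated, so the encoder emits width \code{headsRest * hiddenDim}),
#' LeakyReLU slope 0.4, dropout 0.1, Adam with learning rate 5e-4 and
#' weight decay 5e-4, 100 epochs, edge batches of 256, filter scale 1.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list.
#' @section Keys:
#' \describe{
#'   \item{nLayers, headsFirst, headsRest, hiddenDim}{encoder depth/widths.}
#'   \item{attnSlope}{LeakyReLU negative slope used throughout.}
#'   \item{dropout}{dropout rate on attention weights, layer inputs and
#'     branch blocks (training only).}
#'   \item{variant}{\code{"full"}, \code{"no_tda"}, \code{"no_fusion"},
#'     \code{"no_residual"} or \code{"no_branch"} (ablations).}
#'   \item{outDim}{branch output width O.}
#'   \item{tdaScale, tdaSigma}{filter-scale multiplier and normalization
#'     stabilizer of the persistence features.}
#'   \item{tdaLog1pCycles, tdaChannelScale}{standardization of the
#'     broadcast topology channels (log1p on the cycle count, then fixed
#'     per-channel scaling) so the unbounded integer channel cannot
#'     dominate the gate; set \code{tdaLog1pCycles = FALSE} and unit
#'     scales for raw mode.}
#'   \item{lr, weightDecay, epochs, batchSize}{Adam optimizer settings.}
#'   \item{degreeFeature, normalizeExpression}{graph-input assembly flags.}
#'   \item{seed}{integer master seed for init, dropout and batching.}
#' }
#' @export
grnConfig <- function(...) {
  cfg <- list(
    nLayers = 4L, headsFirst = 4L, headsRest = 4L, hiddenDim = 32L,
    attnSlope = 0.4, dropout = 0.1,
    variant = "full", outDim = 16L,
    tdaScale = 1, tdaSigma = 1e-8,
    tdaLog1pCycles = TRUE, tdaChannelScale = c(1, 1, 1, 1),
    lr = 5e-4, weightDecay = 5e-4, epochs = 100L, batchSize = 256L,
    degreeFeature = TRUE, normalizeExpression = TRUE,
    seed = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad) || is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(ov)] <- ov
  }
  stopifnot(cfg$nLayers >= 1L, cfg$headsFirst >= 1L, cfg$headsRest >= 1L,
            cfg$hiddenDim >= 1L, cfg$lr > 0, cfg$epochs >= 1L,
            cfg$batchSize >= 1L, cfg$dropout >= 0, cfg$dropout < 1,
            cfg$tdaScale >= 0, cfg$tdaSigma > 0)
  cfg$variant <- match.arg(cfg$variant,
    c("full", "no_tda", "no_fusion", "no_residual", "no_branch"))
  if (cfg$nLayers > 5L) {
    warning("more than 5 attention layers tends to over-smooth sparse ",
            "regulatory graphs; proceeding anyway")
  }
  cfg
}
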