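#' @import methods
#' @importFrom stats cor quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.table
NULL

#' GRNData: expression matrix plus prior regulatory network
#'
#' Container pairing a genes-by-cells expression matrix with a directed
#' TF-to-target prior network and the transcription-factor list. Gene
#' identifiers are matched case-insensitively across the three inputs;
#' the case used in the expression matrix wins. Network edges whose
#' endpoints carry no expression row are dropped at construction (node
#' features are mandatory downstream).
#'
#' @slot expression numeric matrix, genes in rows (rownames = gene ids),
#'   cells in columns.
#' @slot network data.frame with character columns \code{tf} and
#'   \code{target}; deduplicated, self-edge free.
#' @slot tfs character vector of transcription-factor ids (subset of
#'   rownames of \code{expression}).
#' @slot sourceLabel free-text provenance label, e.g. \code{"STRING"},
#'   \code{"cell-type-specific"} or \code{"synthetic"}.
#' @exportClass GRNData
setClass("GRNData",
  slots = c(
    expression = "matrix",
    network    = "data.frame",
    tfs        = "character",
    sourceLabel = "character"
  )
)

setValidity("GRNData", function(object) {
  msg <- character()
  ex <- object@expression
  if (is.null(rownames(ex))) msg <- c(msg, "expression must have gene ids as rownames")
  if (!is.null(rownames(ex))) {
    dup <- duplicated(tolower(rownames(ex)))
    if (any(dup)) {
      msg <- c(msg, paste0("duplicate gene ids: ",
                           paste(unique(rownames(ex)[dup]), collapse = ", ")))
    }
  }
  if (length(ex) && !all(is.finite(ex))) msg <- c(msg, "expression values must be finite")
  nw <- object@network
  if (!all(c("tf", "target") %in% names(nw))) {
    msg <- c(msg, "network needs columns 'tf' and 'target'")
  } else {
    if (any(tolower(nw$tf) == tolower(nw$target))) msg <- c(msg, "network contains self-edges")
    if (anyDuplicated(paste(tolower(nw$tf), tolower(nw$target)))) {
      msg <- c(msg, "network contains duplicate edges")
    }
    known <- tolower(rownames(ex))
    bad <- setdiff(tolower(c(nw$tf, nw$target)), known)
    if (length(bad)) msg <- c(msg, "network references genes absent from expression")
  }
  if (!length(object@tfs)) msg <- c(msg, "tf list is empty")
  if (length(msg)) msg else TRUE
})

#' EdgeSplits: labeled TF-target pairs per split
#'
#' Holds the supervised link-prediction surface: positive gold-standard
#' edges allocated to train/validation/test by the 8/10-1/10-1/10 holdout
#' protocol (floor allocation, remainder to test) and sampled negatives,
#' all as integer gene indices into \code{geneIds}.
#'
#' @slot train,val,test data.frames with integer columns \code{tf},
#'   \code{target} and binary \code{label}.
#' @slot geneIds character vector defining the index space.
#' @slot tfIds character vector of TF ids.
#' @slot seed integer seed the splits were drawn with.
#' @slot config list of split parameters (fractions, negative ratio, mode).
#' @exportClass EdgeSplits
setClass("EdgeSplits",
  slots = c(
    train = "data.frame", val = "data.frame", test = "data.frame",
    geneIds = "character", tfIds = "character",
    seed = "integer", config = "list"
  )
)

setValidity("EdgeSplits", function(object) {
  msg <- character()
  for (nm in c("train", "val", "test")) {
    df <- slot(object, nm)
    if (!all(c("tf", "target", "label") %in% names(df))) {
      msg <- c(msg, sprintf("%s split needs tf/target/label columns", nm))
      next
    }
    if (nrow(df)) {
      if (!all(df$label %in% c(0L, 1L))) msg <- c(msg, sprintf("%s labels must be 0/1", nm))
      M <- length(object@geneIds)
      if (any(df$tf < 1L | df$tf > M | df$target < 1L | df$target > M)) {
        msg <- c(msg, sprintf("%s indices out of range", nm))
      }
    }
  }
  key <- function(df) paste(df$tf, df$target)
  ks <- lapply(list(object@train, object@val, object@test), key)
  if (anyDuplicated(unlist(ks))) msg <- c(msg, "a pair appears in more than one split")
  if (length(msg)) msg else TRUE
})

#' GraphInput: node features and message-passing structure
#'
#' The encoder-facing view of a dataset: the node feature matrix
#' (per-gene expression across cells, optionally log1p + z-scored, with an
#' optional normalized-degree column), and the symmetrized training-edge
#' adjacency with self-loops on every node. Built from training positives
#' only so that validation/test edges never leak into message passing or
#' into the persistence filtration.
#'
#' @slot features numeric matrix M x d.
#' @slot edges two-column integer matrix of directed (src, dst) pairs,
#'   symmetrized and including all self-loops.
#' @slot trainEdges two-column integer matrix of the undirected training
#'   positives (u < v), the filtration support.
#' @slot degree numeric vector of degrees normalized to [0, 1]
#'   (self-loops excluded from the count).
#' @slot geneIds character rownames of the index space.
#' @exportClass GraphInput
setClass("GraphInput",
  slots = c(
    features = "matrix",
    edges = "matrix",
    trainEdges = "matrix",
    degree = "numeric",
    geneIds = "character"
  )
)

setValidity("GraphInput", function(object) {
  msg <- character()
  M <- nrow(object@features)
  if (length(object@geneIds) != M) msg <- c(msg, "geneIds length != feature rows")
  if (!all(is.finite(object@features))) msg <- c(msg, "features must be finite")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e)) {
    if (min(e) < 1L || max(e) > M) msg <- c(msg, "edge endpoints out of range")
    key <- paste(e[, 1L], e[, 2L])
    if (!all(paste(seq_len(M), seq_len(M)) %in% key)) msg <- c(msg, "missing self-loops")
    off <- e[e[, 1L] != e[, 2L], , drop = FALSE]
    if (nrow(off) && !all(paste(off[, 2L], off[, 1L]) %in% key)) {
      msg <- c(msg, "edges not symmetric")
    }
  }
  if (length(object@degree) && (length(object@degree) != M ||
      any(object@degree < 0) || any(object@degree > 1))) {
    msg <- c(msg, "degree must be length M in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' TDAFeatures: persistent-homology summary of a weighted graph
#'
#' The four-number topological descriptor of the training subgraph under
#' the cosine-dissimilarity edge filtration: mean and maximum dimension-0
#' persistence (component lifespans), their stabilized ratio, and the
#' number of dimension-1 classes (independent cycles). The degenerate
#' (edgeless) input yields \code{(0, 0L, 0, 0)}.
#'
#' @slot avgPers0 mean dimension-0 persistence.
#' @slot numCycles integer count of dimension-1 pairs.
#' @slot maxPers0 maximum dimension-0 persistence.
#' @slot normPers0 \code{avgPers0 / (maxPers0 + sigma)}.
#' @slot diagram data.frame of persistence pairs
#'   (\code{dim}, \code{birth}, \code{death}; death \code{Inf} for dim 1).
#' @exportClass TDAFeatures
setClass("TDAFeatures",
  slots = c(
    avgPers0 = "numeric", numCycles = "integer",
    maxPers0 = "numeric", normPers0 = "numeric",
    diagram = "data.frame"
  )
)

setValidity("TDAFeatures", function(object) {
  msg <- character()
  if (object@avgPers0 < 0 || object@maxPers0 < 0) msg <- c(msg, "persistences must be >= 0")
  if (object@avgPers0 > object@maxPers0 + 1e-12) msg <- c(msg, "avgPers0 must be <= maxPers0")
  if (object@normPers0 < 0 || object@normPers0 > 1) msg <- c(msg, "normPers0 must be in [0,1]")
  if (object@numCycles < 0L) msg <- c(msg, "numCycles must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GRNFit: a trained link-prediction model
#'
#' Returned by [trainGRN()]. Carries the best-validation-AUPRC checkpoint
#' (the parameters used for prediction), the final-epoch parameters, the
#' per-epoch history, the topological features the model was conditioned
#' on, and the graph/splits needed to score new pairs reproducibly.
#'
#' @slot params named list of parameter matrices (best checkpoint).
#' @slot finalParams parameters at the last epoch.
#' @slot history data.frame with epoch, loss, valAUROC, valAUPRC.
#' @slot bestEpoch integer epoch of the stored checkpoint.
#' @slot config list of model/training configuration.
#' @slot tda [TDAFeatures-class] computed from the training subgraph.
#' @slot graph [GraphInput-class] used for encoding.
#' @slot splits [EdgeSplits-class] the fit was trained on.
#' @exportClass GRNFit
setClass("GRNFit",
  slots = c(
    params = "list", finalParams = "list",
    history = "data.frame", bestEpoch = "integer",
    config = "list",
    tda = "TDAFeatures", graph = "GraphInput", splits = "EdgeSplits"
  )
)

setMethod("show", "GRNData", function(object) {
  cat(sprintf("GRNData: %d genes x %d cells, %d prior edges, %d TFs [%s]\n",
              nrow(object@expression), ncol(object@expression),
              nrow(object@network), length(object@tfs), object@sourceLabel))
})

setMethod("show", "EdgeSplits", function(object) {
  s <- function(df) sprintf("%d+/%d-", sum(df$label == 1L), sum(df$label == 0L))
  cat(sprintf("EdgeSplits over %d genes (%d TFs): train %s, val %s, test %s (seed %d)\n",
              length(object@geneIds), length(object@tfIds),
              s(object@train), s(object@val), s(object@test), object@seed))
})

setMethod("show", "GraphInput", function(object) {
  cat(sprintf("GraphInput: %d nodes, %d feature dims, %d directed edges (incl. self-loops)\n",
              nrow(object@features), ncol(object@features), nrow(object@edges)))
})

setMethod("show", "TDAFeatures", function(object) {
  cat(sprintf("TDAFeatures: avgPers0 = %.4g, numCycles = %d, maxPers0 = %.4g, normPers0 = %.4g\n",
              object@avgPers0, object@numCycles, object@maxPers0, object@normPers0))
})

setMethod("show", "GRNFit", function(object) {
  h <- object@history
  cat(sprintf("GRNFit (%s variant): %d epochs, best val AUPRC %.4f at epoch %d\n",
              object@config$variant, nrow(h),
              if (nrow(h)) max(h$valAUPRC) else NA_real_, object@bestEpoch))
})
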