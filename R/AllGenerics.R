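#' Accessors for topoGRN classes
#'
#' Small accessor family so downstream code never touches slots directly.
#'
#' @param x a topoGRN object.
#' @param split one of \code{"train"}, \code{"val"}, \code{"test"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setMethod("exprMatrix", "GRNData", function(x) x@expression)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "GRNData", function(x) x@network)

#' @rdname accessors
#' @export
setGeneric("tfList", function(x) standardGeneric("tfList"))
#' @rdname accessors
#' @export
setMethod("tfList", "GRNData", function(x) x@tfs)
#' @rdname accessors
#' @export
setMethod("tfList", "EdgeSplits", function(x) x@tfIds)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "GRNData", function(x) rownames(x@expression))
#' @rdname accessors
#' @export
setMethod("geneIds", "EdgeSplits", function(x) x@geneIds)
#' @rdname accessors
#' @export
setMethod("geneIds", "GraphInput", function(x) x@geneIds)

#' @rdname accessors
#' @export
setGeneric("splitPairs", function(x, split = c("train", "val", "test")) {
  standardGeneric("splitPairs")
})
#' @rdname accessors
#' @export
setMethod("splitPairs", "EdgeSplits", function(x, split = c("train", "val", "test")) {
  slot(x, match.arg(split))
})

#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "GraphInput", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "GraphInput", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("degreeVector", function(x) standardGeneric("degreeVector"))
#' @rdname accessors
#' @export
setMethod("degreeVector", "GraphInput", function(x) x@degree)

#' Sparse adjacency of a GraphInput
#'
#' Returns the symmetric binary adjacency (self-loops included) as a
#' \code{Matrix::sparseMatrix}.
#'
#' @param x a [GraphInput-class].
#' @return a sparse \code{dgCMatrix}.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "GraphInput", function(x) {
  M <- nrow(x@features)
  Matrix::sparseMatrix(i = x@edges[, 1L], j = x@edges[, 2L], x = 1,
                       dims = c(M, M), dimnames = list(x@geneIds, x@geneIds))
})

#' @rdname accessors
#' @export
setGeneric("tdaVector", function(x) standardGeneric("tdaVector"))
#' @rdname accessors
#' @export
setMethod("tdaVector", "TDAFeatures", function(x) {
  c(avgPers0 = x@avgPers0, numCycles = as.numeric(x@numCycles),
    maxPers0 = x@maxPers0, normPers0 = x@normPers0)
})

#' @rdname accessors
#' @export
setGeneric("persistenceDiagram", function(x) standardGeneric("persistenceDiagram"))
#' @rdname accessors
#' @export
setMethod("persistenceDiagram", "TDAFeatures", function(x) x@diagram)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "GRNFit", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setMethod("modelConfig", "GRNFit", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("tdaVector", "GRNFit", function(x) tdaVector(x@tda))
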