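## Persistent homology of the training subgraph, dimensions 0 and 1, over
## a cosine-dissimilarity edge filtration. Edges enter in ascending weight
## order; an edge that merges two Union-Find components kills a dimension-0
## class (pair (0, w)); an edge inside a component opens a dimension-1
## class (pair (w, Inf)). Only the graph 1-skeleton is considered, so every
## dim-1 class persists forever.

#' Cosine-dissimilarity edge filtration
#'
#' Assigns each undirected edge (i, j) the weight
#' \code{scale * (1 - cos(x_i, x_j))} from the node feature rows and
#' returns edges in ascending weight order (ties broken by (u, v) so the
#' order is deterministic). Zero-norm feature vectors get cosine 0 — an
#' all-zero profile carries no similarity evidence, so the edge receives
#' the neutral dissimilarity \code{scale * 1}.
#'
#' @param features numeric matrix, one row per node.
#' @param edges two-column matrix of node indices; direction is ignored,
#'   duplicates and self-pairs are collapsed/dropped.
#' @param scale positive multiplier on the weights (filter-scale factor).
#' @return data.frame with columns \code{u}, \code{v} (u < v), \code{w},
#'   sorted ascending by \code{w}; attribute \code{nNodes}.
#' @export
edgeFiltration <- function(features, edges, scale = 1) {
  stopifnot(scale >= 0, all(is.finite(features)))
  edges <- as.matrix(edges)
  M <- nrow(features)
  if (nrow(edges)) {
    stopifnot(min(edges) >= 1L, max(edges) <= M)
    u <- pmin(edges[, 1L], edges[, 2L])
    v <- pmax(edges[, 1L], edges[, 2L])
    keep <- u != v & !duplicated(pairKey(u, v))
    u <- u[keep]; v <- v[keep]
  } else {
    u <- integer(); v <- integer()
  }
  if (length(u)) {
    nrm <- sqrt(rowSums(features^2))
    dots <- rowSums(features[u, , drop = FALSE] * features[v, , drop = FALSE])
    den <- nrm[u] * nrm[v]
    cs <- ifelse(den > 0, dots / den, 0)
    cs <- pmin(1, pmax(-1, cs))
    w <- scale * (1 - cs)
    ord <- order(w, u, v, method = "radix")
    out <- data.frame(u = u[ord], v = v[ord], w = w[ord])
  } else {
    out <- data.frame(u = integer(), v = integer(), w = numeric())
  }
  attr(out, "nNodes") <- M
  out
}

## Disjoint-set forest, union by size + path halving.
ufNew <- function(n) {
  e <- new.env(parent = emptyenv())
  e$parent <- seq_len(n)
  e$size <- rep(1L, n)
  e
}

ufFind <- function(uf, x) {
  p <- uf$parent
  while (p[x] != x) {
    p[x] <- p[p[x]]
    x <- p[x]
  }
  uf$parent <- p
  x
}

ufUnion <- function(uf, a, b) {
  if (uf$size[a] < uf$size[b]) { t <- a; a <- b; b <- t }
  uf$parent[b] <- a
  uf$size[a] <- uf$size[a] + uf$size[b]
  invisible(a)
}

#' Dimension-0/1 persistence of a filtered graph
#'
#' Single pass over the weight-sorted edges with a Union-Find structure:
#' a merging edge emits the dimension-0 pair (0, w), a cycle-closing edge
#' the dimension-1 pair (w, Inf).
#'
#' @param filtration output of [edgeFiltration()] (or any data.frame with
#'   \code{u}, \code{v}, \code{w} sorted ascending by \code{w} and an
#'   \code{nNodes} attribute / argument).
#' @param nNodes number of nodes; defaults to the filtration attribute.
#' @return list with numeric \code{dim0} (death times, births all 0) and
#'   \code{dim1} (birth times, deaths all Inf).
#' @export
graphPersistence <- function(filtration, nNodes = attr(filtration, "nNodes")) {
  stopifnot(!is.null(nNodes))
  m <- nrow(filtration)
  dim0 <- numeric(m); n0 <- 0L
  dim1 <- numeric(m); n1 <- 0L
  if (m) {
    stopifnot(!is.unsorted(filtration$w))
    uf <- ufNew(nNodes)
    us <- filtration$u; vs <- filtration$v; ws <- filtration$w
    for (k in seq_len(m)) {
      pu <- ufFind(uf, us[k]); pv <- ufFind(uf, vs[k])
      if (pu != pv) {
        ufUnion(uf, pu, pv)
        n0 <- n0 + 1L; dim0[n0] <- ws[k]
      } else {
        n1 <- n1 + 1L; dim1[n1] <- ws[k]
      }
    }
  }
  list(dim0 = dim0[seq_len(n0)], dim1 = dim1[seq_len(n1)])
}

#' Summarize persistence pairs into the 4-feature descriptor
#'
#' \code{avgPers0}/\code{maxPers0} are the mean/max dimension-0 lifespans
#' (death minus birth; births are 0), \code{normPers0} their
#' sigma-stabilized ratio, and \code{numCycles} the number of dimension-1
#' classes. An input with no dimension-0 pairs (an edgeless graph) yields
#' the degenerate vector (0.0, 0, 0.0, 0.0).
#'
#' @param pers list from [graphPersistence()].
#' @param sigma small stabilizer in the normalization denominator
#'   (default 1e-8).
#' @return a [TDAFeatures-class].
#' @export
summarizePersistence <- function(pers, sigma = 1e-8) {
  stopifnot(sigma > 0)
  diag0 <- data.frame(dim = rep(0L, length(pers$dim0)),
                      birth = rep(0, length(pers$dim0)), death = pers$dim0)
  diag1 <- data.frame(dim = rep(1L, length(pers$dim1)),
                      birth = pers$dim1, death = rep(Inf, length(pers$dim1)))
  diagram <- rbind(diag0, diag1)
  if (!length(pers$dim0)) {
    return(new("TDAFeatures", avgPers0 = 0, numCycles = 0L, maxPers0 = 0,
               normPers0 = 0, diagram = diagram))
  }
  p0 <- pers$dim0  # death - birth with birth = 0
  avg <- mean(p0); mx <- max(p0)
  new("TDAFeatures",
      avgPers0 = avg, numCycles = length(pers$dim1),
      maxPers0 = mx, normPers0 = avg / (mx + sigma),
      diagram = diagram)
}

#' Topological features of a training graph
#'
#' Chains [edgeFiltration()], [graphPersistence()] and
#' [summarizePersistence()] on the undirected training-positive edges of a
#' [GraphInput-class] (the same node feature matrix the encoder consumes).
#' Computed once per training run, before any learning, so the descriptor
#' is static and strictly inductive.
#'
#' @param graph a [GraphInput-class].
#' @param scale filter-scale multiplier (default 1, the optimum of the
#'   scale sweep; 0 collapses all weights and is allowed for ablation).
#' @param sigma normalization stabilizer.
#' @return a [TDAFeatures-class].
#' @export
computeTDAFeatures <- function(graph, scale = 1, sigma = 1e-8) {
  stopifnot(is(graph, "GraphInput"))
  filt <- edgeFiltration(nodeFeatures(graph), graph@trainEdges, scale = scale)
  summarizePersistence(graphPersistence(filt), sigma = sigma)
}
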