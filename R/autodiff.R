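## Minimal reverse-mode automatic differentiation on a tape of matrix ops.
## Internal: no deep-learning framework exists in this R stack, and the
## attention/fusion/branch/decoder architecture needs exact gradients, so a
## small vector-Jacobian-product engine is authored here and verified
## against finite differences in the test suite.
##
## Every value is a numeric matrix (column vectors are n x 1). A node is
## list(value, parents, vjp, needs); vjp(g) returns one gradient per
## parent. Backward walks the tape in reverse creation order, so any
## forward composition of these ops differentiates correctly.

adTape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

adPush <- function(tape, value, parents = integer(), vjp = NULL, needs = NULL) {
  if (is.null(needs)) {
    needs <- length(parents) > 0L &&
      any(vapply(parents, function(p) tape$nodes[[p]]$needs, TRUE))
  }
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = parents, vjp = vjp, needs = needs)
  tape$n <- n
  n
}

adConst <- function(tape, value) adPush(tape, as.matrix(value), needs = FALSE)
adParam <- function(tape, value) adPush(tape, as.matrix(value), needs = TRUE)

## force id before touching tape$nodes: ops nested in arguments (e.g. an
## adConst built inline) push onto the tape while this call's promises are
## still unevaluated, and the node list must be read after that push
adValue <- function(tape, id) {
  force(id)
  tape$nodes[[id]]$value
}

## Accumulate d(root)/d(node) for every node; returns list indexed by id.
adBackward <- function(tape, root) {
  grads <- vector("list", tape$n)
  rv <- tape$nodes[[root]]$value
  grads[[root]] <- matrix(1, nrow(rv), ncol(rv))
  for (id in seq.int(root, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    if (!length(nd$parents) || !nd$needs) next
    pg <- nd$vjp(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (!tape$nodes[[p]]$needs) next
      gk <- pg[[k]]
      if (is.null(gk)) next
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

adMatmul <- function(tape, a, b) {
  A <- adValue(tape, a); B <- adValue(tape, b)
  adPush(tape, A %*% B, c(a, b),
         function(g) list(g %*% t(B), crossprod(A, g)))
}

adAdd <- function(tape, a, b) {
  adPush(tape, adValue(tape, a) + adValue(tape, b), c(a, b),
         function(g) list(g, g))
}

## x (n x k) plus a 1 x k bias row broadcast over rows
adAddBias <- function(tape, x, b) {
  X <- adValue(tape, x); B <- adValue(tape, b)
  adPush(tape, sweep(X, 2L, as.vector(B), "+"), c(x, b),
         function(g) list(g, matrix(colSums(g), 1L)))
}

adMul <- function(tape, a, b) {
  A <- adValue(tape, a); B <- adValue(tape, b)
  adPush(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

## scale rows of x (n x k) by the n x 1 column s
adRowScale <- function(tape, x, s) {
  X <- adValue(tape, x); sv <- as.vector(adValue(tape, s))
  adPush(tape, X * sv, c(x, s),
         function(g) list(g * sv, matrix(rowSums(g * X), ncol = 1L)))
}

adSigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-adValue(tape, x)))
  adPush(tape, y, x, function(g) list(g * y * (1 - y)))
}

adELU <- function(tape, x) {
  X <- adValue(tape, x)
  y <- ifelse(X > 0, X, exp(X) - 1)
  adPush(tape, y, x, function(g) list(g * ifelse(X > 0, 1, y + 1)))
}

adLeakyReLU <- function(tape, x, slope) {
  X <- adValue(tape, x)
  adPush(tape, ifelse(X >= 0, X, slope * X), x,
         function(g) list(g * ifelse(X >= 0, 1, slope)))
}

adCbind <- function(tape, a, b) {
  A <- adValue(tape, a); B <- adValue(tape, b)
  ka <- ncol(A)
  adPush(tape, cbind(A, B), c(a, b),
         function(g) list(g[, seq_len(ka), drop = FALSE],
                          g[, -seq_len(ka), drop = FALSE]))
}

## gather rows; gradient scatter-adds back (duplicates accumulate)
adRows <- function(tape, x, idx) {
  X <- adValue(tape, x)
  idx <- as.integer(idx)
  adPush(tape, X[idx, , drop = FALSE], x, function(g) {
    Z <- matrix(0, nrow(X), ncol(X))
    agg <- rowsum(g, group = idx)
    Z[as.integer(rownames(agg)), ] <- agg
    list(Z)
  })
}

## sum rows of x into n buckets by group id; gradient gathers
adScatterSum <- function(tape, x, group, n) {
  X <- adValue(tape, x)
  group <- as.integer(group)
  Z <- matrix(0, n, ncol(X))
  agg <- rowsum(X, group = group)
  Z[as.integer(rownames(agg)), ] <- agg
  adPush(tape, Z, x, function(g) list(g[group, , drop = FALSE]))
}

## softmax of the E x 1 column x within groups (overflow-safe)
adSegmentSoftmax <- function(tape, x, group) {
  xv <- as.vector(adValue(tape, x))
  group <- as.integer(group)
  mx <- stats::ave(xv, group, FUN = max)
  ex <- exp(xv - mx)
  a <- ex / stats::ave(ex, group, FUN = sum)
  adPush(tape, matrix(a, ncol = 1L), x, function(g) {
    gv <- as.vector(g)
    s <- stats::ave(gv * a, group, FUN = sum)
    list(matrix(a * (gv - s), ncol = 1L))
  })
}

## row-wise layer normalization with affine gamma/beta (1 x k)
adLayerNorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  X <- adValue(tape, x)
  gm <- as.vector(adValue(tape, gamma)); bt <- as.vector(adValue(tape, beta))
  mu <- rowMeans(X)
  va <- rowMeans((X - mu)^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- (X - mu) * inv
  y <- sweep(sweep(xhat, 2L, gm, "*"), 2L, bt, "+")
  adPush(tape, y, c(x, gamma, beta), function(g) {
    dxh <- sweep(g, 2L, gm, "*")
    dx <- inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

## mean binary cross-entropy over a K x 1 probability column; probabilities
## clamped to [eps, 1-eps], gradient zero where the clamp is active
adBCE <- function(tape, probs, labels, eps = 1e-7) {
  p <- as.vector(adValue(tape, probs))
  y <- as.vector(labels)
  K <- length(p)
  stopifnot(K > 0L, length(y) == K)
  pc <- pmin(pmax(p, eps), 1 - eps)
  L <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  adPush(tape, matrix(L, 1L, 1L), probs, function(g) {
    gv <- as.vector(g)[1L]
    d <- (-y / pc + (1 - y) / (1 - pc)) / K
    d[p < eps | p > 1 - eps] <- 0
    list(matrix(gv * d, ncol = 1L))
  })
}
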