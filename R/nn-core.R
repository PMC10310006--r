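# Minimal neural-network engine: dense and convolutional layers with exact
# analytic gradients, plus the AdamW optimizer and global-norm gradient
# clipping. Everything operates on plain matrices so the heavy lifting is
# done by BLAS. Parameter collections are nested named lists; gradient
# collections mirror their structure.

# ---- parameter-tree utilities -------------------------------------------

initMatrix <- function(nin, nout) {
  # He-style fan-in scaling, suitable for ReLU networks
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

zerosLike <- function(p) {
  if (is.list(p)) lapply(p, zerosLike)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

treeAdd <- function(a, b) {
  if (is.list(a)) Map(treeAdd, a, b) else a + b
}

treeScale <- function(a, s) {
  if (is.list(a)) lapply(a, treeScale, s = s) else a * s
}

treeSumSq <- function(a) {
  if (is.list(a)) sum(vapply(a, treeSumSq, numeric(1))) else sum(a * a)
}

#' Global-norm gradient clipping
#'
#' Rescales a gradient collection so its global L2 norm does not exceed
#' `maxNorm` (the clipping used by all training loops in the package).
#'
#' @param grads nested list of gradient arrays.
#' @param maxNorm positive scalar.
#' @return list with elements `grads` (possibly rescaled) and `norm` (the
#'   pre-clipping global norm).
#' @keywords internal
clipGradients <- function(grads, maxNorm = 1.0) {
  nrm <- sqrt(treeSumSq(grads))
  if (is.finite(nrm) && nrm > maxNorm)
    grads <- treeScale(grads, maxNorm / nrm)
  list(grads = grads, norm = nrm)
}

# ---- AdamW ---------------------------------------------------------------

adamWInit <- function(params) {
  list(m = zerosLike(params), v = zerosLike(params), t = 0L)
}

# One decoupled-weight-decay Adam step. `frozen` names parameter groups to
# skip, addressed by slash-separated paths into the parameter tree (e.g.
# "encoder" or "encoder/conv1"); a frozen path freezes its whole subtree.
adamWStep <- function(params, grads, state, lr, weightDecay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      frozen = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v, path) {
    if (!is.null(path) && path %in% frozen)
      return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      nms <- names(p)
      keys <- if (is.null(nms)) as.character(seq_along(p)) else nms
      out <- vector("list", length(p))
      for (i in seq_along(p)) {
        sub <- if (is.null(path)) keys[i] else paste(path, keys[i], sep = "/")
        out[[i]] <- rec(p[[i]], g[[i]], m[[i]], v[[i]], sub)
      }
      pl <- lapply(out, `[[`, "p"); names(pl) <- nms
      ml <- lapply(out, `[[`, "m"); names(ml) <- nms
      vl <- lapply(out, `[[`, "v"); names(vl) <- nms
      return(list(p = pl, m = ml, v = vl))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weightDecay * p)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v, NULL)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- dense layer ---------------------------------------------------------

linearInit <- function(nin, nout) list(W = initMatrix(nin, nout),
                                       b = numeric(nout))

linearForward <- function(X, p) {
  Y <- X %*% p$W
  sweep(Y, 2, p$b, "+")
}

linearBackward <- function(dY, X, p) {
  list(grads = list(W = crossprod(X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))
}

reluForward <- function(X) {
  X * (X > 0)
}

reluBackward <- function(dY, X) {
  dY * (X > 0)
}

# ---- 2-d convolution via im2col -----------------------------------------
# A conv "spec" precomputes, for a fixed input geometry, the gather indices
# that turn a batch of flattened padded images into the im2col matrix, so
# the forward pass is a single GEMM.

convSpec <- function(H, W, C, k = 3L, stride = 1L, pad = 1L, nFilters) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  P <- outH * outW
  K <- k * k * C
  # index of padded pixel (h, w, c) in the flattened padded image
  at <- function(h, w, c) h + (w - 1L) * Hp + (c - 1L) * Hp * Wp
  idx <- matrix(0L, P, K)
  col <- 0L
  for (c in seq_len(C)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
    col <- col + 1L
    oh <- rep(seq_len(outH), times = outW)
    ow <- rep(seq_len(outW), each = outH)
    idx[, col] <- at((oh - 1L) * stride + kh, (ow - 1L) * stride + kw, c)
  }
  # positions of the original pixels inside the padded vector
  oh <- rep(seq_len(H), times = W * C)
  ow <- rep(rep(seq_len(W), each = H), times = C)
  oc <- rep(seq_len(C), each = H * W)
  unpad <- at(oh + pad, ow + pad, oc)
  # group the K columns by spatial offset: the C channel planes of one
  # offset address disjoint padded pixels, so the backward scatter can
  # process them in a single assignment
  offCols <- lapply(seq_len(k * k), function(o) o + (seq_len(C) - 1L) * k * k)
  offTarget <- lapply(offCols, function(cols) as.integer(idx[, cols]))
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       outH = outH, outW = outW, P = P, K = K, nFilters = nFilters,
       Lpad = Hp * Wp * C, idx = idx, idxVec = as.integer(idx),
       unpad = unpad, offCols = offCols, offTarget = offTarget)
}

convInit <- function(spec) linearInit(spec$K, spec$nFilters)

# X: B x (H*W*C), images flattened column-major in (H, W, C) order.
# Returns Y: (B*P) x F plus the im2col matrix for the backward pass.
convForward <- function(X, spec, p) {
  B <- nrow(X)
  Xp <- matrix(0, B, spec$Lpad)
  Xp[, spec$unpad] <- X
  M <- Xp[, spec$idxVec]
  dim(M) <- c(B * spec$P, spec$K)   # pure reshape: b fastest, then p
  Y <- M %*% p$W
  Y <- Y + rep(p$b, each = nrow(Y))
  list(Y = Y, M = M, B = B)
}

convBackward <- function(dY, cache, spec, p) {
  M <- cache$M; B <- cache$B
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, p$W)            # (B*P) x K
  dXp <- matrix(0, B, spec$Lpad)
  for (o in seq_along(spec$offCols)) {
    tgt <- spec$offTarget[[o]]         # distinct within one spatial offset
    add <- dM[, spec$offCols[[o]], drop = FALSE]
    dim(add) <- c(B, length(tgt))
    dXp[, tgt] <- dXp[, tgt] + add
  }
  list(grads = list(W = dW, b = db), dX = dXp[, spec$unpad, drop = FALSE])
}

# global average pooling over the P spatial positions of a (B*P) x F map
poolForward <- function(Y, B, P) {
  Z <- rowsum(Y, rep_len(seq_len(B), B * P)) / P
  rownames(Z) <- NULL
  Z
}

poolBackward <- function(dZ, B, P) {
  dZ[rep_len(seq_len(B), B * P), , drop = FALSE] / P
}
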