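# Sequence layers: stacked LSTM and multi-head scaled-dot-product
# attention, both with exact analytic gradients. Sequences are numeric
# arrays of dimension (B, N, D): batch, position, feature.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- LSTM ----------------------------------------------------------------
# One layer holds Wx (D x 4H), Wh (H x 4H), b (4H); gate order i, f, o, g:
#   i_t = sigma(.), f_t = sigma(.), o_t = sigma(.), g_t = tanh(.)
#   c_t = f_t * c_{t-1} + i_t * g_t ;  h_t = o_t * tanh(c_t)
# Initial hidden and cell states are zero; the forget-gate bias starts at 1
# (standard practice, keeps early gradients alive).

lstmLayerInit <- function(nin, hidden) {
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1
  list(Wx = initMatrix(nin, 4L * hidden), Wh = initMatrix(hidden, 4L * hidden),
       b = b)
}

lstmStackInit <- function(nin, hidden, nLayers = 2L) {
  lapply(seq_len(nLayers), function(l)
    lstmLayerInit(if (l == 1L) nin else hidden, hidden))
}

# X: (B, N, D). Returns H: (B, N, hidden) of the top layer plus caches.
lstmForward <- function(X, params) {
  B <- dim(X)[1]; N <- dim(X)[2]
  caches <- vector("list", length(params))
  inp <- X
  for (l in seq_along(params)) {
    p <- params[[l]]
    Hd <- ncol(p$Wh)
    hid <- Hd / 4L  # columns of Wh are 4*hidden
    Hd <- as.integer(hid)
    h <- matrix(0, B, Hd); cc <- matrix(0, B, Hd)
    out <- array(0, c(B, N, Hd))
    steps <- vector("list", N)
    for (t in seq_len(N)) {
      xt <- matrix(inp[, t, ], B)
      Z <- sweep(xt %*% p$Wx + h %*% p$Wh, 2, p$b, "+")
      i <- sigmoid(Z[, seq_len(Hd), drop = FALSE])
      f <- sigmoid(Z[, Hd + seq_len(Hd), drop = FALSE])
      o <- sigmoid(Z[, 2L * Hd + seq_len(Hd), drop = FALSE])
      g <- tanh(Z[, 3L * Hd + seq_len(Hd), drop = FALSE])
      cPrev <- cc
      cc <- f * cPrev + i * g
      tc <- tanh(cc)
      hPrev <- h
      h <- o * tc
      out[, t, ] <- h
      steps[[t]] <- list(x = xt, hPrev = hPrev, cPrev = cPrev,
                         i = i, f = f, o = o, g = g, tc = tc)
    }
    caches[[l]] <- list(steps = steps, input = inp, hidden = Hd)
    inp <- out
  }
  list(H = inp, caches = caches)
}

# dH: gradient on the top layer's full output sequence (B, N, hidden).
lstmBackward <- function(dH, params, caches) {
  grads <- vector("list", length(params))
  dOut <- dH
  for (l in rev(seq_along(params))) {
    p <- params[[l]]
    cache <- caches[[l]]
    Hd <- cache$hidden
    B <- dim(dOut)[1]; N <- dim(dOut)[2]
    Din <- ncol(cache$steps[[1]]$x)
    dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
    dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
    db <- numeric(length(p$b))
    dX <- array(0, c(B, N, Din))
    dhNext <- matrix(0, B, Hd); dcNext <- matrix(0, B, Hd)
    for (t in rev(seq_len(N))) {
      s <- cache$steps[[t]]
      dh <- matrix(dOut[, t, ], B) + dhNext
      do_ <- dh * s$tc
      dc <- dh * s$o * (1 - s$tc^2) + dcNext
      di <- dc * s$g
      dg <- dc * s$i
      df <- dc * s$cPrev
      dcNext <- dc * s$f
      dZ <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  do_ * s$o * (1 - s$o),
                  dg * (1 - s$g^2))
      dWx <- dWx + crossprod(s$x, dZ)
      dWh <- dWh + crossprod(s$hPrev, dZ)
      db <- db + colSums(dZ)
      dX[, t, ] <- tcrossprod(dZ, p$Wx)
      dhNext <- tcrossprod(dZ, p$Wh)
    }
    grads[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    dOut <- dX
  }
  list(grads = grads, dX = dOut)
}

# ---- scaled dot-product attention ---------------------------------------

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / scale) V` for one head. Each row of the weight
#' matrix is a probability distribution over the key positions (rows are
#' non-negative and sum to 1). The conventional scale is `sqrt(d)` with `d`
#' the head width; `scaleMode = "linear"` divides by `d` instead.
#'
#' @param Q,K,V numeric matrices N x d (K, V share their row count).
#' @param scaleMode `"sqrt"` (default) or `"linear"`.
#' @return list with `output` (N x d) and `weights` (N x N attention map).
#' @examples
#' q <- matrix(rnorm(6), 2, 3)
#' a <- scaledDotAttention(q, q, q)
#' rowSums(a$weights)  # all 1
#' @export
scaledDotAttention <- function(Q, K, V, scaleMode = c("sqrt", "linear")) {
  scaleMode <- match.arg(scaleMode)
  if (NROW(Q) == 0L || NROW(K) == 0L) stop("empty attention sequence")
  d <- ncol(Q)
  sc <- if (scaleMode == "sqrt") sqrt(d) else d
  S <- tcrossprod(Q, K) / sc
  A <- softmaxRows(S)
  list(output = A %*% V, weights = A)
}

softmaxRows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# ---- multi-head attention ------------------------------------------------
# Query and context sequences are (B, N, D); nHeads must divide D.
# Self-attention: context == query. Co-attention: different streams.

mhaInit <- function(dModel) {
  list(Wq = initMatrix(dModel, dModel), bq = numeric(dModel),
       Wk = initMatrix(dModel, dModel), bk = numeric(dModel),
       Wv = initMatrix(dModel, dModel), bv = numeric(dModel),
       Wo = initMatrix(dModel, dModel), bo = numeric(dModel))
}

mhaForward <- function(Xq, Xc, p, nHeads, scaleMode = "sqrt") {
  B <- dim(Xq)[1]; N <- dim(Xq)[2]; D <- dim(Xq)[3]
  if (D %% nHeads != 0L) stop("model dim must be divisible by nHeads")
  dHead <- D %/% nHeads
  sc <- if (scaleMode == "sqrt") sqrt(dHead) else dHead
  Fq <- Xq; dim(Fq) <- c(B * N, D)   # pure reshape, b fastest
  Fc <- Xc; dim(Fc) <- c(B * N, D)
  Q <- sweep(Fq %*% p$Wq, 2, p$bq, "+")
  K <- sweep(Fc %*% p$Wk, 2, p$bk, "+")
  V <- sweep(Fc %*% p$Wv, 2, p$bv, "+")
  O <- matrix(0, B * N, D)
  Alist <- vector("list", B * nHeads)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(N) - 1L) * B
    for (h in seq_len(nHeads)) {
      cols <- (h - 1L) * dHead + seq_len(dHead)
      Qb <- Q[rows, cols, drop = FALSE]
      Kb <- K[rows, cols, drop = FALSE]
      A <- softmaxRows(tcrossprod(Qb, Kb) / sc)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Alist[[(b - 1L) * nHeads + h]] <- A
    }
  }
  Out <- O %*% p$Wo
  Out <- Out + rep(p$bo, each = nrow(Out))
  dim(Out) <- c(B, N, D)
  list(Y = Out,
       cache = list(Fq = Fq, Fc = Fc, Q = Q, K = K, V = V, O = O,
                    A = Alist, B = B, N = N, D = D,
                    nHeads = nHeads, dHead = dHead, sc = sc))
}

mhaBackward <- function(dY, p, cache) {
  B <- cache$B; N <- cache$N; D <- cache$D
  nHeads <- cache$nHeads; dHead <- cache$dHead; sc <- cache$sc
  dOut <- dY; dim(dOut) <- c(B * N, D)
  dWo <- crossprod(cache$O, dOut)
  dbo <- colSums(dOut)
  dO <- tcrossprod(dOut, p$Wo)
  dQ <- matrix(0, B * N, D); dK <- matrix(0, B * N, D)
  dV <- matrix(0, B * N, D)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(N) - 1L) * B
    for (h in seq_len(nHeads)) {
      cols <- (h - 1L) * dHead + seq_len(dHead)
      A <- cache$A[[(b - 1L) * nHeads + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sc
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) / sc
    }
  }
  grads <- list(Wq = crossprod(cache$Fq, dQ), bq = colSums(dQ),
                Wk = crossprod(cache$Fc, dK), bk = colSums(dK),
                Wv = crossprod(cache$Fc, dV), bv = colSums(dV),
                Wo = dWo, bo = dbo)
  dFq <- tcrossprod(dQ, p$Wq)
  dFc <- tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  dim(dFq) <- c(B, N, D)
  dim(dFc) <- c(B, N, D)
  list(grads = grads, dXq = dFq, dXc = dFc)
}

#' Multi-head attention over an embedding sequence
#'
#' Convenience wrapper exposing the forward pass of the package's
#' multi-head attention: per-head linear projections of query, key and
#' value, [scaledDotAttention()] per head, concatenation, and an output
#' projection. Self-attention passes the same sequence as query and
#' context; co-attention uses a different query stream.
#'
#' @param xQuery,xContext numeric arrays (B, N, D); `xContext` defaults to
#'   `xQuery` (self-attention).
#' @param params parameter list from the model (projection matrices); when
#'   `NULL` a fresh random initialization of width `dim(xQuery)[3]` is used.
#' @param nHeads number of attention heads (must divide D).
#' @param scaleMode `"sqrt"` or `"linear"` score scaling.
#' @return array (B, N, D) of attended features, with attention maps in
#'   attribute `"weights"` (a list of B x nHeads matrices).
#' @export
multiHeadAttention <- function(xQuery, xContext = xQuery, params = NULL,
                               nHeads = 4L, scaleMode = "sqrt") {
  if (is.null(params)) params <- mhaInit(dim(xQuery)[3])
  fw <- mhaForward(xQuery, xContext, params, nHeads, scaleMode)
  structure(fw$Y, weights = fw$cache$A)
}
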