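# Internal layer engine: forward/backward passes for the layer chain.
#
# Data conventions between layers:
#   image tensor  : array (H, W, C, B)
#   flat features : matrix (B x F)
#   sequence      : array (B, ts, id)
# Convolutions are implemented as cross-correlation (the deep-learning
# convention) via patch-matrix ("im2col") matrix products; under learned
# kernels this is flip-equivalent to true convolution.

.sigm <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- layer constructors (parameters drawn from the current RNG) ----

.convLayer <- function(inShape, outMaps, activation = "relu") {
  cin <- inShape[3L]
  list(type = "conv", inShape = as.integer(inShape),
       outMaps = as.integer(outMaps), activation = activation,
       W = .glorot(9L * cin, 9L * outMaps, c(9L * cin, outMaps)),
       b = numeric(outMaps))
}

.poolLayer <- function(mode = "max") list(type = "pool", mode = mode)

.flattenLayer <- function() list(type = "flatten")

.denseLayer <- function(inUnits, outUnits, activation = "relu") {
  list(type = "dense", activation = activation,
       W = .glorot(inUnits, outUnits), b = numeric(outUnits))
}

.dropoutLayer <- function(p) list(type = "dropout", p = p)

.reshapeSeqLayer <- function(ts, id)
  list(type = "reshapeSeq", ts = as.integer(ts), id = as.integer(id))

.lstmParams <- function(d, h) {
  list(Wx = .glorot(d, 4L * h, c(d, 4L * h)),
       Wh = .glorot(h, 4L * h, c(h, 4L * h)),
       b = numeric(4L * h))
}

.lstmLayer <- function(d, h, returnSeq = FALSE) {
  c(list(type = "lstm", d = as.integer(d), h = as.integer(h),
         returnSeq = returnSeq), .lstmParams(d, h))
}

.bilstmLayer <- function(d, h) {
  list(type = "bilstm", d = as.integer(d), h = as.integer(h),
       fwd = .lstmParams(d, h), bwd = .lstmParams(d, h))
}

# ---- conv ----

.convForward <- function(layer, x) {
  hh <- layer$inShape[1L]; ww <- layer$inShape[2L]; cin <- layer$inShape[3L]
  B <- dim(x)[4L]
  pad <- array(0, c(hh + 2L, ww + 2L, cin, B))
  pad[2:(hh + 1L), 2:(ww + 1L), , ] <- x
  P <- matrix(0, hh * ww * B, 9L * cin)
  j <- 0L
  for (ci in seq_len(cin)) for (dj in 0:2) for (di in 0:2) {
    j <- j + 1L
    P[, j] <- pad[(1:hh) + di, (1:ww) + dj, ci, ]
  }
  Z <- P %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  A <- if (layer$activation == "relu") pmax(Z, 0) else Z
  out <- A
  dim(out) <- c(hh, ww, B, layer$outMaps)
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(P = P, mask = (Z > 0), B = B))
}

.convBackward <- function(layer, dout, cache) {
  hh <- layer$inShape[1L]; ww <- layer$inShape[2L]; cin <- layer$inShape[3L]
  B <- cache$B
  dZ <- aperm(dout, c(1, 2, 4, 3))
  dim(dZ) <- c(hh * ww * B, layer$outMaps)
  if (layer$activation == "relu") dZ <- dZ * cache$mask
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- tcrossprod(dZ, layer$W)
  dpad <- array(0, c(hh + 2L, ww + 2L, cin, B))
  j <- 0L
  for (ci in seq_len(cin)) for (dj in 0:2) for (di in 0:2) {
    j <- j + 1L
    dpad[(1:hh) + di, (1:ww) + dj, ci, ] <-
      dpad[(1:hh) + di, (1:ww) + dj, ci, ] + dP[, j]
  }
  list(dx = dpad[2:(hh + 1L), 2:(ww + 1L), , , drop = FALSE],
       grads = list(W = dW, b = db))
}

# ---- pooling (2 x 2, stride 2) ----

.poolForward <- function(layer, x) {
  hh <- dim(x)[1L]; ww <- dim(x)[2L]
  if (hh %% 2L || ww %% 2L)
    stop("pooling requires even spatial dimensions; got ", hh, " x ", ww)
  ro <- seq(1L, hh, 2L); re <- ro + 1L
  co <- seq(1L, ww, 2L); ce <- co + 1L
  m1 <- x[ro, co, , , drop = FALSE]; m2 <- x[re, co, , , drop = FALSE]
  m3 <- x[ro, ce, , , drop = FALSE]; m4 <- x[re, ce, , , drop = FALSE]
  if (layer$mode == "avg") {
    out <- (m1 + m2 + m3 + m4) / 4
    return(list(out = out, cache = list(inDim = dim(x))))
  }
  out <- pmax(m1, m2, m3, m4)
  w1 <- m1 == out
  w2 <- !w1 & (m2 == out)
  w3 <- !w1 & !w2 & (m3 == out)
  w4 <- !(w1 | w2 | w3)
  list(out = out, cache = list(inDim = dim(x), w = list(w1, w2, w3, w4)))
}

.poolBackward <- function(layer, dout, cache) {
  d <- cache$inDim
  dx <- array(0, d)
  ro <- seq(1L, d[1L], 2L); re <- ro + 1L
  co <- seq(1L, d[2L], 2L); ce <- co + 1L
  if (layer$mode == "avg") {
    q <- dout / 4
    dx[ro, co, , ] <- q; dx[re, co, , ] <- q
    dx[ro, ce, , ] <- q; dx[re, ce, , ] <- q
  } else {
    w <- cache$w
    dx[ro, co, , ] <- dout * w[[1L]]; dx[re, co, , ] <- dout * w[[2L]]
    dx[ro, ce, , ] <- dout * w[[3L]]; dx[re, ce, , ] <- dout * w[[4L]]
  }
  list(dx = dx, grads = NULL)
}

# ---- flatten: (H, W, C, B) -> (B x HWC) ----

.flattenForward <- function(layer, x) {
  d <- dim(x)
  f <- prod(d[1:3])
  m <- x
  dim(m) <- c(f, d[4L])
  list(out = t(m), cache = list(inDim = d))
}

.flattenBackward <- function(layer, dout, cache) {
  dx <- t(dout)
  dim(dx) <- cache$inDim
  list(dx = dx, grads = NULL)
}

# ---- dense ----

.denseForward <- function(layer, x) {
  Z <- x %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  A <- if (layer$activation == "relu") pmax(Z, 0) else Z
  list(out = A, cache = list(x = x, mask = (Z > 0)))
}

.denseBackward <- function(layer, dout, cache) {
  dZ <- if (layer$activation == "relu") dout * cache$mask else dout
  list(dx = tcrossprod(dZ, layer$W),
       grads = list(W = crossprod(cache$x, dZ), b = colSums(dZ)))
}

# ---- dropout (inverted scaling; identity at evaluation time) ----

.dropoutForward <- function(layer, x, training) {
  if (!training || layer$p <= 0)
    return(list(out = x, cache = list(mask = NULL)))
  mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}

.dropoutBackward <- function(layer, dout, cache) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = NULL)
}

# ---- row-major sequence reshape: (B x L) -> (B, ts, id) ----

.reshapeSeqForward <- function(layer, x) {
  B <- nrow(x); L <- ncol(x)
  if (layer$ts * layer$id != L)
    stop("cannot reshape ", L, " features into ts = ", layer$ts,
         " steps of id = ", layer$id, " (product ", layer$ts * layer$id, ")")
  s <- x
  dim(s) <- c(B, layer$id, layer$ts)
  list(out = aperm(s, c(1, 3, 2)), cache = list(B = B, L = L))
}

.reshapeSeqBackward <- function(layer, dout, cache) {
  dx <- aperm(dout, c(1, 3, 2))
  dim(dx) <- c(cache$B, cache$L)
  list(dx = dx, grads = NULL)
}

# ---- LSTM ----
# Gate block order in the 4h columns: candidate (tanh), input gate,
# forget gate, output gate; cell update c_t = c_{t-1} * f + cand * gate,
# output h_t = tanh(c_t) * o.

.lstmCoreForward <- function(p, S, returnSeq) {
  B <- dim(S)[1L]; ts <- dim(S)[2L]
  h <- ncol(p$Wh)/4L
  hPrev <- matrix(0, B, h); cPrev <- matrix(0, B, h)
  steps <- vector("list", ts)
  outSeq <- if (returnSeq) array(0, c(B, ts, h)) else NULL
  for (t in seq_len(ts)) {
    Xt <- S[, t, , drop = FALSE]; dim(Xt) <- c(B, dim(S)[3L])
    G <- Xt %*% p$Wx + hPrev %*% p$Wh
    G <- G + rep(p$b, each = B)
    cand <- tanh(G[, 1:h, drop = FALSE])
    gi <- .sigm(G[, h + (1:h), drop = FALSE])
    gf <- .sigm(G[, 2L * h + (1:h), drop = FALSE])
    go <- .sigm(G[, 3L * h + (1:h), drop = FALSE])
    cNew <- cPrev * gf + cand * gi
    tc <- tanh(cNew)
    hNew <- tc * go
    steps[[t]] <- list(Xt = Xt, hPrev = hPrev, cPrev = cPrev, cand = cand,
                       gi = gi, gf = gf, go = go, tc = tc)
    if (returnSeq) outSeq[, t, ] <- hNew
    hPrev <- hNew; cPrev <- cNew
  }
  list(out = if (returnSeq) outSeq else hPrev,
       cache = list(steps = steps, B = B, ts = ts, h = h))
}

.lstmCoreBackward <- function(p, dout, cache, returnSeq) {
  B <- cache$B; ts <- cache$ts; h <- cache$h
  d <- nrow(p$Wx)
  dWx <- array(0, dim(p$Wx)); dWh <- array(0, dim(p$Wh))
  db <- numeric(4L * h)
  dS <- array(0, c(B, ts, d))
  dhNext <- matrix(0, B, h); dcNext <- matrix(0, B, h)
  for (t in rev(seq_len(ts))) {
    st <- cache$steps[[t]]
    dh <- dhNext
    if (returnSeq) {
      dh <- dh + matrix(dout[, t, ], B, h)
    } else if (t == ts) dh <- dh + dout
    dgo <- dh * st$tc
    dc <- dcNext + dh * st$go * (1 - st$tc^2)
    dgf <- dc * st$cPrev
    dcand <- dc * st$gi
    dgi <- dc * st$cand
    dG <- cbind(dcand * (1 - st$cand^2),
                dgi * st$gi * (1 - st$gi),
                dgf * st$gf * (1 - st$gf),
                dgo * st$go * (1 - st$go))
    dWx <- dWx + crossprod(st$Xt, dG)
    dWh <- dWh + crossprod(st$hPrev, dG)
    db <- db + colSums(dG)
    dS[, t, ] <- tcrossprod(dG, p$Wx)
    dhNext <- tcrossprod(dG, p$Wh)
    dcNext <- dc * st$gf
  }
  list(dS = dS, grads = list(Wx = dWx, Wh = dWh, b = db))
}

.lstmForward <- function(layer, x) {
  r <- .lstmCoreForward(layer[c("Wx", "Wh", "b")], x, layer$returnSeq)
  list(out = r$out, cache = r$cache)
}

.lstmBackward <- function(layer, dout, cache) {
  r <- .lstmCoreBackward(layer[c("Wx", "Wh", "b")], dout, cache,
                         layer$returnSeq)
  list(dx = r$dS, grads = r$grads)
}

# bidirectional LSTM, summed directions, final state of each direction
.bilstmForward <- function(layer, x) {
  ts <- dim(x)[2L]
  rf <- .lstmCoreForward(layer$fwd, x, FALSE)
  rb <- .lstmCoreForward(layer$bwd, x[, rev(seq_len(ts)), , drop = FALSE],
                         FALSE)
  list(out = rf$out + rb$out,
       cache = list(f = rf$cache, b = rb$cache, ts = ts))
}

.bilstmBackward <- function(layer, dout, cache) {
  rf <- .lstmCoreBackward(layer$fwd, dout, cache$f, FALSE)
  rb <- .lstmCoreBackward(layer$bwd, dout, cache$b, FALSE)
  dS <- rf$dS + rb$dS[, rev(seq_len(cache$ts)), , drop = FALSE]
  list(dx = dS,
       grads = list(fwd.Wx = rf$grads$Wx, fwd.Wh = rf$grads$Wh,
                    fwd.b = rf$grads$b, bwd.Wx = rb$grads$Wx,
                    bwd.Wh = rb$grads$Wh, bwd.b = rb$grads$b))
}

# ---- dispatch ----

.layerForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = .convForward(layer, x),
    pool = .poolForward(layer, x),
    flatten = .flattenForward(layer, x),
    dense = .denseForward(layer, x),
    dropout = .dropoutForward(layer, x, training),
    reshapeSeq = .reshapeSeqForward(layer, x),
    lstm = .lstmForward(layer, x),
    bilstm = .bilstmForward(layer, x),
    stop("unknown layer type: ", layer$type))
}

.layerBackward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = .convBackward(layer, dout, cache),
    pool = .poolBackward(layer, dout, cache),
    flatten = .flattenBackward(layer, dout, cache),
    dense = .denseBackward(layer, dout, cache),
    dropout = .dropoutBackward(layer, dout, cache),
    reshapeSeq = .reshapeSeqBackward(layer, dout, cache),
    lstm = .lstmBackward(layer, dout, cache),
    bilstm = .bilstmBackward(layer, dout, cache),
    stop("unknown layer type: ", layer$type))
}

# names of trainable tensors within a layer, in a fixed order
.layerParamNames <- function(layer) {
  switch(layer$type,
    conv = c("W", "b"),
    dense = c("W", "b"),
    lstm = c("Wx", "Wh", "b"),
    bilstm = c("fwd.Wx", "fwd.Wh", "fwd.b", "bwd.Wx", "bwd.Wh", "bwd.b"),
    character())
}

.layerGetParam <- function(layer, name) {
  if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
    layer[[parts[1L]]][[parts[2L]]]
  } else layer[[name]]
}

.layerSetParam <- function(layer, name, value) {
  if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
    layer[[parts[1L]]][[parts[2L]]] <- value
  } else layer[[name]] <- value
  layer
}
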