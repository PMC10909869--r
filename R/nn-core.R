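# Minimal CNN stack with exact backpropagation.
#
# Activations on spatial layers use a stacked representation:
#   list(x = matrix [B * P, C], spatial = dims, B = batch size)
# where P = prod(spatial) voxels per sample (sample-major row blocks, voxels
# in R's column-major array order) and C channels. Convolutions are im2col
# gathers followed by one BLAS matrix product; index maps are precomputed
# per (spatial shape, kernel) and cached.

.nf_cache <- new.env(parent = emptyenv())

# Index machinery for 'same'-padded stride-1 convolution with odd kernel k.
conv_indices <- function(spatial, k) {
  key <- paste0("conv:", paste(spatial, collapse = "x"), ":", k)
  if (!is.null(.nf_cache[[key]])) return(.nf_cache[[key]])
  nd <- length(spatial)
  p <- (k - 1L) / 2L
  pd <- spatial + 2L * p
  offs <- as.matrix(do.call(expand.grid, rep(list(0:(k - 1L)), nd)))
  pos <- as.matrix(do.call(expand.grid, lapply(spatial, seq_len)))
  # padded linear index of voxel (pos + off) in column-major order
  idx <- outer(pos[, 1], offs[, 1], "+")
  mult <- 1L
  for (a in 2:nd) {
    mult <- mult * pd[a - 1L]
    idx <- idx + outer(pos[, a] - 1L, offs[, a], "+") * mult
  }
  core <- as.vector(idx[, (ncol(idx) + 1L) %/% 2L])  # centre offset = identity
  res <- list(idx = idx, core = core, pdlen = prod(pd), K = k^nd)
  .nf_cache[[key]] <- res
  res
}

# Ceil-mode max-pool index map: out cell -> window member voxels (P + 1 is a
# sentinel for out-of-range members, backed by a -Inf pad).
pool_indices <- function(spatial, w) {
  key <- paste0("pool:", paste(spatial, collapse = "x"), ":", w)
  if (!is.null(.nf_cache[[key]])) return(.nf_cache[[key]])
  nd <- length(spatial)
  od <- as.integer(ceiling(spatial / w))
  P <- prod(spatial)
  offs <- as.matrix(do.call(expand.grid, rep(list(0:(w - 1L)), nd)))
  opos <- as.matrix(do.call(expand.grid, lapply(od, seq_len)))
  coord <- vector("list", nd)
  ok <- TRUE
  for (a in seq_len(nd)) {
    coord[[a]] <- outer((opos[, a] - 1L) * w, offs[, a], "+") + 1L
    ok <- ok & (coord[[a]] <= spatial[a])
  }
  idx <- coord[[1]]
  mult <- 1L
  for (a in 2:nd) {
    mult <- mult * spatial[a - 1L]
    idx <- idx + (coord[[a]] - 1L) * mult
  }
  idx[!ok] <- P + 1L
  res <- list(idx = idx, out_spatial = od, P = P)
  .nf_cache[[key]] <- res
  res
}

as_batch_tensor <- function(arrays) {
  spatial <- dim(arrays[[1]])
  x <- do.call(rbind, lapply(arrays, function(a) matrix(as.vector(a), ncol = 1L)))
  list(x = x, spatial = spatial, B = length(arrays))
}

# ---- layer constructors ----------------------------------------------------

layer_conv <- function(in_ch, out_ch, kernel = 3L, name = "conv") {
  # weights are allocated by init_conv once the dimensionality is known
  list(type = "conv", name = name, in_ch = in_ch, out_ch = out_ch,
       kernel = kernel, par = NULL, trainable = TRUE)
}

init_conv <- function(layer, nd) {
  K <- layer$kernel^nd
  fan_in <- K * layer$in_ch
  layer$par <- list(
    W = matrix(rnorm(fan_in * layer$out_ch, 0, sqrt(2 / fan_in)),
               fan_in, layer$out_ch),
    b = numeric(layer$out_ch))
  layer
}

layer_relu <- function(name = "relu") list(type = "relu", name = name, trainable = FALSE)

layer_pool <- function(size = 2L, name = "pool")
  list(type = "pool", name = name, size = size, trainable = FALSE)

layer_bn <- function(ch, name = "bn") {
  list(type = "bn", name = name, ch = ch,
       par = list(gamma = rep(1, ch), beta = rep(0, ch)),
       buf = list(rmean = rep(0, ch), rvar = rep(1, ch)),
       momentum = 0.9, eps = 1e-5, trainable = TRUE)
}

layer_flatten <- function(name = "flatten") list(type = "flatten", name = name, trainable = FALSE)

layer_dense <- function(n_in, n_out, name = "dense") {
  list(type = "dense", name = name, n_in = n_in, n_out = n_out,
       par = list(W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
                  b = numeric(n_out)),
       trainable = TRUE)
}

layer_dropout <- function(rate = 0.3, name = "dropout")
  list(type = "dropout", name = name, rate = rate, trainable = FALSE)

layer_sigmoid <- function(name = "sigmoid") list(type = "sigmoid", name = name, trainable = FALSE)

# ---- forward ---------------------------------------------------------------

# Batch-stacked conv index map: offsets the single-sample map into a
# stacked padded array [B * pdlen, C], so one gather per kernel offset
# serves the whole batch.
conv_indices_batch <- function(spatial, k, B) {
  key <- paste0("convB:", paste(spatial, collapse = "x"), ":", k, ":", B)
  if (!is.null(.nf_cache[[key]])) return(.nf_cache[[key]])
  ci <- conv_indices(spatial, k)
  P <- prod(spatial)
  off <- rep((seq_len(B) - 1L) * ci$pdlen, each = P)
  res <- list(idx = ci$idx[rep(seq_len(P), B), , drop = FALSE] + off,
              core = rep(ci$core, B) + off,
              pdlen_total = B * ci$pdlen, K = ci$K)
  .nf_cache[[key]] <- res
  res
}

fwd_conv <- function(layer, tn) {
  cb <- conv_indices_batch(tn$spatial, layer$kernel, tn$B)
  P <- prod(tn$spatial); C <- ncol(tn$x); K <- cb$K
  Xp <- matrix(0, cb$pdlen_total, C)
  Xp[cb$core, ] <- tn$x
  Xcol <- matrix(0, tn$B * P, K * C)
  for (q in seq_len(K))
    Xcol[, ((q - 1L) * C + 1L):(q * C)] <- Xp[cb$idx[, q], , drop = FALSE]
  y <- Xcol %*% layer$par$W
  y <- y + rep(layer$par$b, each = nrow(y))
  list(out = list(x = y, spatial = tn$spatial, B = tn$B),
       cache = list(Xcol = Xcol, in_C = C, cb = cb, B = tn$B, P = P))
}

bwd_conv <- function(layer, cache, dout) {
  dW <- crossprod(cache$Xcol, dout$x)
  db <- colSums(dout$x)
  dXcol <- tcrossprod(dout$x, layer$par$W)
  cb <- cache$cb; C <- cache$in_C; K <- cb$K
  dXp <- matrix(0, cb$pdlen_total, C)
  for (q in seq_len(K)) {
    ii <- cb$idx[, q]   # distinct within one kernel offset
    dXp[ii, ] <- dXp[ii, , drop = FALSE] +
      dXcol[, ((q - 1L) * C + 1L):(q * C), drop = FALSE]
  }
  list(din = list(x = dXp[cb$core, , drop = FALSE], spatial = NULL,
                  B = cache$B),
       grad = list(W = dW, b = db))
}

pool_indices_batch <- function(spatial, w, B) {
  key <- paste0("poolB:", paste(spatial, collapse = "x"), ":", w, ":", B)
  if (!is.null(.nf_cache[[key]])) return(.nf_cache[[key]])
  pi <- pool_indices(spatial, w)
  Pout <- nrow(pi$idx)
  off <- rep((seq_len(B) - 1L) * pi$P, each = Pout)
  idx <- pi$idx[rep(seq_len(Pout), B), , drop = FALSE] + off
  idx[pi$idx[rep(seq_len(Pout), B), ] == pi$P + 1L] <- B * pi$P + 1L  # sentinel
  res <- list(idx = idx, out_spatial = pi$out_spatial, P = pi$P, Pout = Pout)
  .nf_cache[[key]] <- res
  res
}

fwd_pool <- function(layer, tn) {
  pb <- pool_indices_batch(tn$spatial, layer$size, tn$B)
  C <- ncol(tn$x)
  nout <- tn$B * pb$Pout
  out <- matrix(0, nout, C)
  amax <- matrix(0L, nout, C)
  sel_rows <- seq_len(nout)
  for (ch in seq_len(C)) {
    xv <- c(tn$x[, ch], -Inf)
    M <- matrix(xv[pb$idx], nout)
    mc <- max.col(M, ties.method = "first")
    sel <- cbind(sel_rows, mc)
    out[, ch] <- M[sel]
    amax[, ch] <- pb$idx[sel]
  }
  list(out = list(x = out, spatial = pb$out_spatial, B = tn$B),
       cache = list(amax = amax, P = pb$P, Pout = pb$Pout, B = tn$B))
}

bwd_pool <- function(layer, cache, dout) {
  C <- ncol(dout$x)
  din <- matrix(0, cache$B * cache$P, C)
  for (ch in seq_len(C))
    din[cache$amax[, ch], ch] <- dout$x[, ch]
  list(din = list(x = din, spatial = NULL, B = cache$B), grad = NULL)
}

fwd_bn <- function(layer, tn, training) {
  x <- tn$x
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    va <- colMeans(xc * xc)
    layer$buf$rmean <- layer$momentum * layer$buf$rmean + (1 - layer$momentum) * mu
    layer$buf$rvar <- layer$momentum * layer$buf$rvar + (1 - layer$momentum) * va
  } else {
    mu <- layer$buf$rmean
    va <- layer$buf$rvar
    xc <- x - rep(mu, each = n)
  }
  istd <- 1 / sqrt(va + layer$eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(layer$par$gamma, each = n) + rep(layer$par$beta, each = n)
  list(out = list(x = y, spatial = tn$spatial, B = tn$B), layer = layer,
       cache = list(xhat = xhat, istd = istd, training = training))
}

bwd_bn <- function(layer, cache, dout) {
  dy <- dout$x
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    # standard batch-norm backward through batch statistics
    dxhat <- dy * rep(layer$par$gamma, each = n)
    t1 <- rep(colMeans(dxhat), each = n)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
    din <- (dxhat - t1 - t2) * rep(cache$istd, each = n)
  } else {
    din <- dy * rep(layer$par$gamma * cache$istd, each = n)
  }
  list(din = list(x = din, spatial = NULL, B = dout$B),
       grad = list(gamma = dgamma, beta = dbeta))
}

fwd_relu <- function(layer, v) {
  if (is.list(v)) {
    y <- pmax(v$x, 0)
    list(out = list(x = y, spatial = v$spatial, B = v$B),
         cache = list(pos = v$x > 0))
  } else list(out = pmax(v, 0), cache = list(pos = v > 0))
}

bwd_relu <- function(layer, cache, dout) {
  if (is.list(dout)) list(din = list(x = dout$x * cache$pos, B = dout$B), grad = NULL)
  else list(din = dout * cache$pos, grad = NULL)
}

fwd_flatten <- function(layer, tn) {
  P <- prod(tn$spatial); C <- ncol(tn$x)
  out <- matrix(0, tn$B, P * C)
  for (b in seq_len(tn$B))
    out[b, ] <- as.vector(tn$x[((b - 1L) * P + 1L):(b * P), , drop = FALSE])
  list(out = out, cache = list(P = P, C = C, spatial = tn$spatial, B = tn$B))
}

bwd_flatten <- function(layer, cache, dout) {
  din <- matrix(0, cache$B * cache$P, cache$C)
  for (b in seq_len(cache$B))
    din[((b - 1L) * cache$P + 1L):(b * cache$P), ] <-
      matrix(dout[b, ], cache$P, cache$C)
  list(din = list(x = din, spatial = cache$spatial, B = cache$B), grad = NULL)
}

fwd_dense <- function(layer, x) {
  y <- x %*% layer$par$W
  y <- y + matrix(layer$par$b, nrow(y), ncol(y), byrow = TRUE)
  list(out = y, cache = list(x = x))
}

bwd_dense <- function(layer, cache, dout) {
  list(din = tcrossprod(dout, layer$par$W),
       grad = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

fwd_dropout <- function(layer, x, training) {
  if (!training || layer$rate <= 0)
    return(list(out = x, cache = list(mask = NULL)))
  keep <- 1 - layer$rate
  mask <- matrix(rbinom(length(x), 1L, keep) / keep, nrow(x), ncol(x))
  list(out = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, cache, dout) {
  if (is.null(cache$mask)) list(din = dout, grad = NULL)
  else list(din = dout * cache$mask, grad = NULL)
}

fwd_sigmoid <- function(layer, x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = list(y = y))
}

bwd_sigmoid <- function(layer, cache, dout)
  list(din = dout * cache$y * (1 - cache$y), grad = NULL)

# ---- network forward / backward -------------------------------------------

# Runs `layers` on `input`; returns the final output, per-layer caches, and
# (optionally) every intermediate value, needed by Grad-CAM.
net_forward <- function(layers, input, training = FALSE, record = FALSE) {
  caches <- vector("list", length(layers))
  outputs <- if (record) vector("list", length(layers)) else NULL
  v <- input
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    r <- switch(lay$type,
      conv = fwd_conv(lay, v),
      pool = fwd_pool(lay, v),
      bn = fwd_bn(lay, v, training),
      relu = fwd_relu(lay, v),
      flatten = fwd_flatten(lay, v),
      dense = fwd_dense(lay, v),
      dropout = fwd_dropout(lay, v, training),
      sigmoid = fwd_sigmoid(lay, v),
      stop_nf("unknown layer type '%s'", lay$type))
    if (!is.null(r$layer)) layers[[l]] <- r$layer  # bn running stats
    caches[[l]] <- r$cache
    v <- r$out
    if (record) outputs[[l]] <- v
  }
  list(out = v, caches = caches, layers = layers, outputs = outputs)
}

# Backpropagates `dout` from the last layer down to (and including) layer
# `upto`; returns parameter gradients and the gradient at the cut.
net_backward <- function(layers, caches, dout, upto = 1L) {
  grads <- vector("list", length(layers))
  d <- dout
  for (l in rev(seq(upto, length(layers)))) {
    lay <- layers[[l]]
    r <- switch(lay$type,
      conv = bwd_conv(lay, caches[[l]], d),
      pool = bwd_pool(lay, caches[[l]], d),
      bn = bwd_bn(lay, caches[[l]], d),
      relu = bwd_relu(lay, caches[[l]], d),
      flatten = bwd_flatten(lay, caches[[l]], d),
      dense = bwd_dense(lay, caches[[l]], d),
      dropout = bwd_dropout(lay, caches[[l]], d),
      sigmoid = bwd_sigmoid(lay, caches[[l]], d))
    grads[l] <- list(r$grad)  # keep NULL slots for parameter-free layers
    d <- r$din
  }
  list(grads = grads, din = d)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(lay) {
    if (!is.null(lay$par) && isTRUE(lay$trainable))
      lay$opt <- list(m = lapply(lay$par, function(p) p * 0),
                      v = lapply(lay$par, function(p) p * 0), t = 0L)
    lay
  })
}

adam_step <- function(layers, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    if (is.null(lay$par) || !isTRUE(lay$trainable) || is.null(grads[[l]]))
      next
    lay$opt$t <- lay$opt$t + 1L
    for (pn in names(lay$par)) {
      g <- grads[[l]][[pn]]
      lay$opt$m[[pn]] <- beta1 * lay$opt$m[[pn]] + (1 - beta1) * g
      lay$opt$v[[pn]] <- beta2 * lay$opt$v[[pn]] + (1 - beta2) * g * g
      mhat <- lay$opt$m[[pn]] / (1 - beta1^lay$opt$t)
      vhat <- lay$opt$v[[pn]] / (1 - beta2^lay$opt$t)
      lay$par[[pn]] <- lay$par[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
    layers[[l]] <- lay
  }
  layers
}
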