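# Primitive differentiable layers over [D, H, W, C, N] arrays. Forward
# functions return caches that the matching backward functions consume; batch
# normalization additionally returns an updated layer (running moments).

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

new_conv3d <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                       W = NULL) {
  if (is.null(W)) W <- glorot_uniform(c(k, k, k, cin, cout),
                                      fan_in = cin * k^3, fan_out = cout * k^3)
  stopifnot(identical(dim(W), as.integer(c(k, k, k, cin, cout))))
  list(type = "conv", k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride),
       pad = as.integer(pad), W = W)
}

conv_fwd <- function(layer, x) {
  cpp_conv3d_fwd(x, dim(x), layer$W, layer$k, layer$cout,
                 layer$stride, layer$pad)
}

conv_bwd <- function(layer, x, gout, need_gx = TRUE) {
  cpp_conv3d_bwd(x, dim(x), layer$W, layer$k, layer$cout,
                 layer$stride, layer$pad, gout, need_gx)
}

new_bn <- function(C) {
  list(type = "bn", C = as.integer(C), gamma = rep(1, C), beta = rep(0, C),
       rm = rep(0, C), rv = rep(1, C), eps = 1e-5, momentum = 0.1)
}

# Per-channel sums over space and batch.
channel_sums <- function(v, S, C, N) {
  .rowSums(matrix(.colSums(matrix(v, S), S, C * N), C, N), C, N)
}

bn_fwd <- function(layer, x, training) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  xv <- as.numeric(x)
  if (training) {
    m <- S * N
    mu <- channel_sums(xv, S, C, N) / m
    ex2 <- channel_sums(xv * xv, S, C, N) / m
    v <- pmax(ex2 - mu^2, 0)
    layer$rm <- (1 - layer$momentum) * layer$rm + layer$momentum * mu
    layer$rv <- (1 - layer$momentum) * layer$rv + layer$momentum * v
  } else {
    mu <- layer$rm; v <- layer$rv
  }
  invsd <- 1 / sqrt(v + layer$eps)
  idx <- rep.int(seq_len(C), N)
  xhat <- (xv - rep(mu[idx], each = S)) * rep(invsd[idx], each = S)
  out <- xhat * rep(layer$gamma[idx], each = S) + rep(layer$beta[idx], each = S)
  dim(out) <- d
  list(out = out, layer = layer,
       cache = list(xhat = xhat, invsd = invsd, idx = idx, S = S, d = d,
                    training = training))
}

bn_bwd <- function(layer, cache, gout) {
  d <- cache$d; S <- cache$S; C <- d[4]; N <- d[5]; m <- S * N
  idx <- cache$idx
  go <- as.numeric(gout)
  dgamma <- channel_sums(go * cache$xhat, S, C, N)
  dbeta <- channel_sums(go, S, C, N)
  gi <- rep((layer$gamma * cache$invsd)[idx], each = S)
  if (cache$training) {
    mg <- dbeta / m
    mgx <- dgamma / m
    dx <- gi * (go - rep(mg[idx], each = S) -
                  cache$xhat * rep(mgx[idx], each = S))
  } else {
    dx <- gi * go
  }
  dim(dx) <- d
  list(gx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

# Spatial (channel-wise) dropout: drops whole feature maps per sample.
sdropout_fwd <- function(x, p, training) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  keep <- (runif(C * N) >= p) / (1 - p)
  out <- as.numeric(x) * rep(keep, each = S)
  dim(out) <- d
  list(out = out, mask = keep)
}

gap_fwd <- function(x) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  G <- t(matrix(.colSums(matrix(x, S), S, C * N) / S, C, N))
  list(G = G, S = S, d = d)
}

# Gradient of global average pooling: spreads each channel gradient evenly.
gap_bwd <- function(gG, cache) {
  gx <- rep(as.numeric(t(gG)) / cache$S, each = cache$S)
  dim(gx) <- cache$d
  gx
}

new_fc <- function(cin, cout) {
  list(type = "fc",
       W = glorot_uniform(c(cout, cin), fan_in = cin, fan_out = cout),
       b = rep(0, cout), lr_mult = 5)
}

fc_fwd <- function(layer, G) {
  sweep(G %*% t(layer$W), 2, layer$b, `+`)
}

fc_bwd <- function(layer, G, gscores) {
  list(gG = gscores %*% layer$W,
       grads = list(W = t(gscores) %*% G, b = colSums(gscores)))
}

softmax_xent <- function(scores, yidx) {
  n <- nrow(scores)
  e <- exp(scores - apply(scores, 1, max))
  p <- e / rowSums(e)
  ii <- cbind(seq_len(n), yidx)
  loss <- -mean(log(pmax(p[ii], 1e-300)))
  g <- p
  g[ii] <- g[ii] - 1
  list(loss = loss, grad = g / n, prob = p)
}
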