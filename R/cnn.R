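# Reduced residual CNN: hand-rolled training core.
#
# Architecture (input S x S grayscale, S divisible by 8):
#   stem  conv3x3(1 -> C) + ReLU, mean-pool 2x2
#   block1 [conv3x3(C->C) ReLU conv3x3(C->C) + skip] ReLU, mean-pool
#   block2 idem, mean-pool
#   block3 idem
#   global average pool -> dense(C -> n_classes) -> softmax
#
# Convolution/pooling kernels live in src/ (deterministic, single-threaded);
# the optimizer is Adam on a class-weighted softmax cross-entropy.

cnn_init_params <- function(channels, n_classes) {
  he <- function(fan_in, dims) {
    array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
  }
  C <- channels
  p <- list(stem_k = he(9, c(3, 3, 1, C)), stem_b = numeric(C))
  for (i in 1:3) {
    p[[sprintf("b%d_k1", i)]] <- he(9 * C, c(3, 3, C, C))
    p[[sprintf("b%d_b1", i)]] <- numeric(C)
    p[[sprintf("b%d_k2", i)]] <- he(9 * C, c(3, 3, C, C))
    p[[sprintf("b%d_b2", i)]] <- numeric(C)
  }
  p$fc_w <- matrix(stats::rnorm(C * n_classes, 0, sqrt(1 / C)), C, n_classes)
  p$fc_b <- numeric(n_classes)
  p
}

conv_fwd <- function(x, k, b) {
  cnn_conv3x3_fwd(x, dim(x), as.numeric(k), b)
}

resblock_fwd <- function(x, k1, b1, k2, b2) {
  h1 <- conv_fwd(x, k1, b1)
  a1 <- pmax(h1, 0); dim(a1) <- dim(h1)
  h2 <- conv_fwd(a1, k2, b2)
  y <- h2 + x
  out <- pmax(y, 0); dim(out) <- dim(y)
  list(out = out, cache = list(x = x, h1 = h1, a1 = a1, y = y))
}

resblock_bwd <- function(dout, cache, k1, k2) {
  dy <- dout * (cache$y > 0)
  dim(dy) <- dim(dout)
  g2 <- cnn_conv3x3_bwd(cache$a1, dy, dim(cache$a1), as.numeric(k2),
                        dim(dy)[3])
  da1 <- g2$dx * (cache$h1 > 0)
  dim(da1) <- dim(g2$dx)
  g1 <- cnn_conv3x3_bwd(cache$x, da1, dim(cache$x), as.numeric(k1),
                        dim(da1)[3])
  dx <- g1$dx + dy  # skip connection
  list(dx = dx, dk1 = g1$dk, db1 = g1$db, dk2 = g2$dk, db2 = g2$db)
}

# Forward pass over a batch array x (H, W, 1, B). Returns logits (B x k)
# and, when train = TRUE, the caches needed for the backward pass.
cnn_forward <- function(p, x, train = FALSE) {
  h0 <- conv_fwd(x, p$stem_k, p$stem_b)
  a0 <- pmax(h0, 0); dim(a0) <- dim(h0)
  p0 <- cnn_pool2_fwd(a0, dim(a0))
  r1 <- resblock_fwd(p0, p$b1_k1, p$b1_b1, p$b1_k2, p$b1_b2)
  p1 <- cnn_pool2_fwd(r1$out, dim(r1$out))
  r2 <- resblock_fwd(p1, p$b2_k1, p$b2_b1, p$b2_k2, p$b2_b2)
  p2 <- cnn_pool2_fwd(r2$out, dim(r2$out))
  r3 <- resblock_fwd(p2, p$b3_k1, p$b3_b1, p$b3_k2, p$b3_b2)
  d3 <- dim(r3$out)
  # global average pool -> (C, B)
  feat <- colMeans(matrix(r3$out, d3[1] * d3[2], d3[3] * d3[4]))
  feat <- matrix(feat, d3[3], d3[4])
  logits <- t(feat) %*% p$fc_w + matrix(p$fc_b, d3[4], length(p$fc_b),
                                        byrow = TRUE)
  if (!train) return(list(logits = logits))
  list(logits = logits,
       cache = list(x = x, h0 = h0, a0 = a0, p0 = p0, r1 = r1, p1 = p1,
                    r2 = r2, p2 = p2, r3 = r3, feat = feat, d3 = d3))
}

cnn_backward <- function(p, cache, dlogits) {
  d3 <- cache$d3
  g <- list()
  g$fc_w <- cache$feat %*% dlogits
  g$fc_b <- colSums(dlogits)
  dfeat <- p$fc_w %*% t(dlogits)               # (C, B)
  # un-GAP: spread gradient uniformly over H*W positions
  hw <- d3[1] * d3[2]
  dr3 <- array(rep(as.numeric(dfeat), each = hw) / hw, dim = d3)
  b3 <- resblock_bwd(dr3, cache$r3$cache, p$b3_k1, p$b3_k2)
  dp2 <- cnn_pool2_bwd(b3$dx, dim(cache$r2$out))
  b2 <- resblock_bwd(dp2, cache$r2$cache, p$b2_k1, p$b2_k2)
  dp1 <- cnn_pool2_bwd(b2$dx, dim(cache$r1$out))
  b1 <- resblock_bwd(dp1, cache$r1$cache, p$b1_k1, p$b1_k2)
  dp0 <- cnn_pool2_bwd(b1$dx, dim(cache$a0))
  da0 <- dp0 * (cache$h0 > 0)
  dim(da0) <- dim(dp0)
  g0 <- cnn_conv3x3_bwd(cache$x, da0, dim(cache$x), as.numeric(p$stem_k),
                        dim(da0)[3])
  g$stem_k <- g0$dk; g$stem_b <- g0$db
  for (i in 1:3) {
    bb <- switch(i, b1, b2, b3)
    g[[sprintf("b%d_k1", i)]] <- bb$dk1
    g[[sprintf("b%d_b1", i)]] <- bb$db1
    g[[sprintf("b%d_k2", i)]] <- bb$dk2
    g[[sprintf("b%d_b2", i)]] <- bb$db2
  }
  g
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# One Adam step over the parameter list; state holds first/second moments.
adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    gi <- as.numeric(g[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gi
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gi^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    pi <- p[[nm]]
    p[[nm]] <- pi - array(upd, dim = dim(pi) %||% length(pi))
  }
  list(p = p, state = state)
}
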