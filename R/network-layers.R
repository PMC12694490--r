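# Internal batched layer primitives.  Activations are arrays [batch, length,
# channels]; every forward returns a cache consumed by the matching backward.
# All gradients are exact analytic derivatives (checked against finite
# differences in the test suite).

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

as_BLC <- function(x, B, L, C) array(x, dim = c(B, L, C))
flatten_BL <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

# -- 1-D convolution, same padding ------------------------------------------

conv1d_forward <- function(X, W, b) {
  # X: [B, L, Cin]; W: [K, Cin, Cout]; b: Cout.  K assumed odd.
  d <- dim(X)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  half <- (K - 1L) %/% 2L
  Xp <- array(0, c(B, L + 2L * half, Cin))
  Xp[, half + seq_len(L), ] <- X
  M <- matrix(0, B * L, K * Cin)
  for (k in seq_len(K)) {
    M[, (k - 1L) * Cin + seq_len(Cin)] <-
      matrix(Xp[, (k - 1L) + seq_len(L), , drop = FALSE], B * L, Cin)
  }
  # stack W[k,,] blocks to match M's column order (k-major, channel inside)
  Wm <- do.call(rbind, lapply(seq_len(K), function(k) matrix(W[k, , ], Cin, Cout)))
  Z <- M %*% Wm
  Z <- Z + rep(b, each = B * L)
  list(out = as_BLC(Z, B, L, Cout),
       cache = list(M = M, Wm = Wm, dims = c(B, L, Cin, K, Cout)))
}

conv1d_backward <- function(dout, cache) {
  d <- cache$dims
  B <- d[1]; L <- d[2]; Cin <- d[3]; K <- d[4]; Cout <- d[5]
  half <- (K - 1L) %/% 2L
  dZ <- matrix(dout, B * L, Cout)
  dWm <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, cache$Wm)
  dXp <- array(0, c(B, L + 2L * half, Cin))
  for (k in seq_len(K)) {
    blk <- as_BLC(dM[, (k - 1L) * Cin + seq_len(Cin), drop = FALSE], B, L, Cin)
    idx <- (k - 1L) + seq_len(L)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + blk
  }
  dW <- array(0, c(K, Cin, Cout))
  for (k in seq_len(K)) {
    dW[k, , ] <- dWm[(k - 1L) * Cin + seq_len(Cin), , drop = FALSE]
  }
  list(dX = dXp[, half + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
relu_backward <- function(dout, mask) dout * mask

# -- max pooling over the length dimension ----------------------------------

maxpool_forward <- function(X, pool_size = 2L) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L %/% pool_size          # trailing remainder dropped
  out <- array(-Inf, c(B, Lout, C))
  arg <- array(0L, c(B, Lout, C))  # winning offset within each window
  for (o in seq_len(pool_size)) {
    cand <- X[, (seq_len(Lout) - 1L) * pool_size + o, , drop = FALSE]
    upd <- cand > out                # strict: ties keep the earliest position
    out[upd] <- cand[upd]
    arg[upd] <- o
  }
  list(out = out, cache = list(arg = arg, dims = d, pool_size = pool_size))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  B <- d[1]; L <- d[2]; C <- d[3]
  ps <- cache$pool_size
  Lout <- L %/% ps
  dX <- array(0, c(B, L, C))
  for (o in seq_len(ps)) {
    sel <- cache$arg == o
    idx <- (seq_len(Lout) - 1L) * ps + o
    slab <- array(0, c(B, Lout, C))
    slab[sel] <- dout[sel]
    dX[, idx, ] <- dX[, idx, , drop = FALSE] + slab
  }
  dX
}

# -- inverted dropout --------------------------------------------------------

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - rate
  mask <- array(stats::rbinom(length(X), 1L, keep) / keep, dim = dim(X) %||% length(X))
  list(out = X * mask, cache = mask)
}
dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# -- GRU (one direction, full sequence) -------------------------------------

gru_cell <- function(x, h_prev, p) {
  r <- sigmoid(x %*% p$W_r + h_prev %*% p$U_r + rep(p$b_r, each = nrow(x)))
  z <- sigmoid(x %*% p$W_z + h_prev %*% p$U_z + rep(p$b_z, each = nrow(x)))
  g <- tanh(x %*% p$W_g + (r * h_prev) %*% p$U_g + rep(p$b_g, each = nrow(x)))
  h <- (1 - z) * h_prev + z * g
  list(r = r, z = z, g = g, h = h)
}

gru_seq_forward <- function(X, p) {
  # X: [B, L, C]; returns H: [B, L, Hdim] plus per-step cache.
  d <- dim(X)
  B <- d[1]; L <- d[2]
  Hd <- ncol(p$U_r)
  H <- array(0, c(B, L, Hd))
  steps <- vector("list", L)
  h <- matrix(0, B, Hd)
  for (t in seq_len(L)) {
    st <- gru_cell(matrix(X[, t, ], B), h, p)
    steps[[t]] <- c(st, list(h_prev = h))
    h <- st$h
    H[, t, ] <- h
  }
  list(out = H, cache = list(steps = steps, X = X))
}

gru_zero_grads <- function(p) {
  lapply(p, function(w) {
    if (is.null(dim(w))) numeric(length(w)) else array(0, dim = dim(w))
  })
}

gru_seq_backward <- function(dH, cache, p) {
  X <- cache$X
  d <- dim(X)
  B <- d[1]; L <- d[2]; C <- d[3]
  g_ <- gru_zero_grads(p)
  dX <- array(0, c(B, L, C))
  dh <- matrix(0, B, ncol(p$U_r))
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    x_t <- matrix(X[, t, ], B)
    dh_t <- matrix(dH[, t, ], B) + dh
    dz <- dh_t * (st$g - st$h_prev)
    dg <- dh_t * st$z
    dh_prev <- dh_t * (1 - st$z)
    dg_pre <- dg * (1 - st$g^2)
    g_$W_g <- g_$W_g + crossprod(x_t, dg_pre)
    g_$U_g <- g_$U_g + crossprod(st$r * st$h_prev, dg_pre)
    g_$b_g <- g_$b_g + colSums(dg_pre)
    d_rh <- tcrossprod(dg_pre, p$U_g)
    dr <- d_rh * st$h_prev
    dh_prev <- dh_prev + d_rh * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    g_$W_z <- g_$W_z + crossprod(x_t, dz_pre)
    g_$U_z <- g_$U_z + crossprod(st$h_prev, dz_pre)
    g_$b_z <- g_$b_z + colSums(dz_pre)
    dh_prev <- dh_prev + tcrossprod(dz_pre, p$U_z)
    dr_pre <- dr * st$r * (1 - st$r)
    g_$W_r <- g_$W_r + crossprod(x_t, dr_pre)
    g_$U_r <- g_$U_r + crossprod(st$h_prev, dr_pre)
    g_$b_r <- g_$b_r + colSums(dr_pre)
    dh_prev <- dh_prev + tcrossprod(dr_pre, p$U_r)
    dX[, t, ] <- tcrossprod(dg_pre, p$W_g) + tcrossprod(dz_pre, p$W_z) +
      tcrossprod(dr_pre, p$W_r)
    dh <- dh_prev
  }
  list(grads = g_, dX = dX)
}

rev_L <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

bigru_seq_forward <- function(X, p_fwd, p_bwd) {
  fw <- gru_seq_forward(X, p_fwd)
  bw <- gru_seq_forward(rev_L(X), p_bwd)
  d <- dim(fw$out)
  S <- array(0, c(d[1], d[2], 2L * d[3]))
  S[, , seq_len(d[3])] <- fw$out
  S[, , d[3] + seq_len(d[3])] <- rev_L(bw$out)
  list(out = S, cache = list(fw = fw$cache, bw = bw$cache, Hd = d[3]))
}

bigru_seq_backward <- function(dS, cache, p_fwd, p_bwd) {
  Hd <- cache$Hd
  dHf <- dS[, , seq_len(Hd), drop = FALSE]
  dHb <- rev_L(dS[, , Hd + seq_len(Hd), drop = FALSE])
  bf <- gru_seq_backward(dHf, cache$fw, p_fwd)
  bb <- gru_seq_backward(dHb, cache$bw, p_bwd)
  list(grads_fwd = bf$grads, grads_bwd = bb$grads,
       dX = bf$dX + rev_L(bb$dX))
}

# -- additive attention pooling ---------------------------------------------

attention_forward <- function(S, p) {
  # S: [B, L, D]; p: W (D x A), b (A), v (A)
  d <- dim(S)
  B <- d[1]; L <- d[2]; D <- d[3]
  Sf <- flatten_BL(S)
  U <- tanh(Sf %*% p$W + rep(p$b, each = B * L))
  s <- matrix(U %*% p$v, B, L)
  s <- s - apply(s, 1L, max)       # softmax shift for stability
  e <- exp(s)
  alpha <- e / rowSums(e)
  pooled <- matrix(0, B, D)
  for (l in seq_len(L)) {
    pooled <- pooled + alpha[, l] * matrix(S[, l, ], B)
  }
  list(out = pooled, alpha = alpha,
       cache = list(S = S, Sf = Sf, U = U, alpha = alpha, dims = d))
}

attention_backward <- function(dpooled, cache, p) {
  d <- cache$dims
  B <- d[1]; L <- d[2]; D <- d[3]
  S <- cache$S
  alpha <- cache$alpha
  dS <- array(0, dim = d)
  dalpha <- matrix(0, B, L)
  for (l in seq_len(L)) {
    Sl <- matrix(S[, l, ], B)
    dalpha[, l] <- rowSums(dpooled * Sl)
    dS[, l, ] <- alpha[, l] * dpooled
  }
  ds <- alpha * (dalpha - rowSums(alpha * dalpha))
  ds_f <- as.vector(ds)            # [B*L], b-major then l: matches flatten_BL
  dv <- drop(crossprod(cache$U, ds_f))
  dU <- outer(ds_f, p$v)
  dU_pre <- dU * (1 - cache$U^2)
  dW <- crossprod(cache$Sf, dU_pre)
  db <- colSums(dU_pre)
  dS <- dS + as_BLC(tcrossprod(dU_pre, p$W), B, L, D)
  list(grads = list(W = dW, b = db, v = dv), dS = dS)
}

# -- mean pooling over steps (attention-ablated variant) --------------------

meanpool_forward <- function(S) {
  d <- dim(S)
  pooled <- matrix(0, d[1], d[3])
  for (l in seq_len(d[2])) pooled <- pooled + matrix(S[, l, ], d[1])
  list(out = pooled / d[2], cache = d)
}

meanpool_backward <- function(dpooled, d) {
  dS <- array(0, dim = d)
  for (l in seq_len(d[2])) dS[, l, ] <- dpooled / d[2]
  dS
}
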