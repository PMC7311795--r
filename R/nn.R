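# Minimal fully-connected network machinery (manual gradients, Adam).
# Shared by the VIB/baseline classifiers and the coarse reconstruction
# model. Everything is plain matrix arithmetic: single-threaded,
# deterministic under set.seed().

relu <- function(x) pmax(x, 0)

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# He-initialized MLP with ReLU hidden layers and a linear output layer.
# Parameters are a flat named list W1, b1, ..., WL, bL.
mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    params <- list()
    for (l in seq_len(L)) {
      params[[paste0("W", l)]] <- matrix(
        rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]),
        sizes[l], sizes[l + 1])
      params[[paste0("b", l)]] <- numeric(sizes[l + 1])
    }
    params
  })
}

mlp_nlayers <- function(net) sum(grepl("^W", names(net)))

mlp_forward <- function(net, X) {
  L <- mlp_nlayers(net)
  acts <- vector("list", L + 1L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% net[[paste0("W", l)]], 2,
               net[[paste0("b", l)]], "+")
    acts[[l + 1]] <- if (l < L) relu(z) else z
  }
  list(acts = acts, out = acts[[L + 1]])
}

# dout = dLoss/dOut (same shape as out). Returns gradients named like net.
mlp_backward <- function(net, fw, dout) {
  L <- mlp_nlayers(net)
  grads <- list()
  delta <- dout
  for (l in rev(seq_len(L))) {
    a_in <- fw$acts[[l]]
    grads[[paste0("W", l)]] <- crossprod(a_in, delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net[[paste0("W", l)]])) * (fw$acts[[l]] > 0)
    }
  }
  grads
}

# ---- convolution via im2col (valid padding, single shared index map) ----

# Column indices into an n x (h*w*c) activation matrix for every kernel
# position; dim (k*k*c) x (out_h*out_w). Channel blocks are column-major
# per channel: pixel (i, j, ch) sits at (ch-1)*h*w + (j-1)*h + i.
im2col_index <- function(h, w, c, k) {
  oh <- h - k + 1L; ow <- w - k + 1L
  off <- expand.grid(di = 0:(k - 1), dj = 0:(k - 1), ch = 0:(c - 1))
  pos <- expand.grid(oi = 1:oh, oj = 1:ow)
  idx <- matrix(0L, nrow(off), nrow(pos))
  for (m in seq_len(nrow(off))) {
    idx[m, ] <- off$ch[m] * h * w + (pos$oj + off$dj[m] - 1L) * h +
      (pos$oi + off$di[m])
  }
  idx
}

# 2x2 mean-pool index groups: 4 x (oh*ow*f) source columns.
pool_index <- function(h, w, f) {
  oh <- h %/% 2L; ow <- w %/% 2L
  base <- expand.grid(oi = 1:oh, oj = 1:ow, ch = 0:(f - 1))
  corner <- function(di, dj) {
    base$ch * h * w + (2L * base$oj - 2L + dj) * h + (2L * base$oi - 1L + di)
  }
  rbind(corner(0L, 0L), corner(1L, 0L), corner(0L, 1L), corner(1L, 1L))
}

conv_forward <- function(X, W, b, idx) {
  n <- nrow(X); k2c <- nrow(idx); P <- ncol(idx)
  f <- ncol(W)
  M <- matrix(aperm(array(X[, as.vector(idx), drop = FALSE],
                          c(n, k2c, P)), c(1, 3, 2)), n * P, k2c)
  Z <- sweep(M %*% W, 2, b, "+")
  A <- matrix(pmax(Z, 0), n, P * f)
  list(M = M, act = A, P = P, f = f)
}

# Returns gradients for W, b and (optionally) the layer input.
conv_backward <- function(dA, fw, W, idx, X_ncol, need_dX = TRUE) {
  n <- nrow(dA); P <- fw$P; f <- fw$f; k2c <- nrow(idx)
  dA <- dA * (fw$act > 0)
  dZ <- matrix(array(dA, c(n, P, f)), n * P, f)
  gW <- crossprod(fw$M, dZ)
  gb <- colSums(dZ)
  dX <- NULL
  if (need_dX) {
    dM <- dZ %*% t(W)
    dXcol <- matrix(aperm(array(dM, c(n, P, k2c)), c(1, 3, 2)), n, k2c * P)
    dX <- matrix(0, n, X_ncol)
    for (m in seq_len(k2c)) {
      cols <- idx[m, ]
      dX[, cols] <- dX[, cols] + dXcol[, m + (seq_len(P) - 1L) * k2c]
    }
  }
  list(gW = gW, gb = gb, dX = dX)
}

mean_pool <- function(A, pidx) {
  (A[, pidx[1, ], drop = FALSE] + A[, pidx[2, ], drop = FALSE] +
     A[, pidx[3, ], drop = FALSE] + A[, pidx[4, ], drop = FALSE]) / 4
}

mean_unpool <- function(dP, pidx, ncol_in) {
  dA <- matrix(0, nrow(dP), ncol_in)
  for (k in 1:4) dA[, pidx[k, ]] <- dA[, pidx[k, ]] + dP / 4
  dA
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(params = params, m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state$params <- params
  state
}
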