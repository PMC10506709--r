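# Low-level neural-network operations on N x L x C arrays (batch, window
# position, channels). Convolutions are expressed as im2col matrix products;
# 'same' zero padding keeps the window length, and kernels span the full
# channel depth, sliding only along the window axis.

conv_im2col <- function(X, k) {
  N <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(N, L + 2L * p, C))
  Xp[, p + seq_len(L), ] <- X
  cols <- matrix(0, N * L, k * C)
  for (j in seq_len(k)) {
    cols[, (j - 1L) * C + seq_len(C)] <-
      matrix(Xp[, (j - 1L) + seq_len(L), , drop = FALSE], N * L, C)
  }
  cols
}

conv_col2im <- function(dcols, N, L, C, k) {
  p <- (k - 1L) %/% 2L
  dXp <- array(0, c(N, L + 2L * p, C))
  for (j in seq_len(k)) {
    dXp[, (j - 1L) + seq_len(L), ] <- dXp[, (j - 1L) + seq_len(L), ] +
      array(dcols[, (j - 1L) * C + seq_len(C)], c(N, L, C))
  }
  dXp[, p + seq_len(L), , drop = FALSE]
}

pool_forward <- function(X, size) {
  Lo <- dim(X)[2] %/% size
  out <- X[, (seq_len(Lo) - 1L) * size + 1L, , drop = FALSE]
  arg <- array(1L, dim(out))
  if (size > 1L) {
    for (s in 2:size) {
      cand <- X[, (seq_len(Lo) - 1L) * size + s, , drop = FALSE]
      upd <- cand > out  # ties keep the earlier slot (deterministic)
      out[upd] <- cand[upd]
      arg[upd] <- s
    }
  }
  list(out = out, arg = arg, L_in = dim(X)[2])
}

pool_backward <- function(dout, arg, L_in, size) {
  N <- dim(dout)[1]; Lo <- dim(dout)[2]; C <- dim(dout)[3]
  dX <- array(0, c(N, L_in, C))
  for (s in seq_len(size)) {
    slab <- dout
    slab[arg != s] <- 0
    dX[, (seq_len(Lo) - 1L) * size + s, ] <- slab
  }
  dX
}

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot_uniform <- function(n_row, n_col, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n_row * n_col, -lim, lim), n_row, n_col)
}

# Forward pass. Returns sigmoid probabilities and, when `keep_cache`, the
# intermediates needed by cnn_backward. Dropout (inverted scaling) is applied
# after the last pooling block only when `training`.
cnn_forward <- function(weights, cfg, X, training = FALSE, keep_cache = FALSE) {
  N <- dim(X)[1]
  A <- X
  caches <- vector("list", cfg$n_conv_layers)
  for (l in seq_len(cfg$n_conv_layers)) {
    wl <- weights$conv[[l]]
    L <- dim(A)[2]; C <- dim(A)[3]
    cols <- conv_im2col(A, wl$k)
    Z <- sweep(cols %*% wl$W, 2L, wl$b, "+")
    Zarr <- array(Z, c(N, L, ncol(wl$W)))
    act <- Zarr > 0
    Zarr[!act] <- 0
    pl <- pool_forward(Zarr, cfg$pool_size)
    if (keep_cache) {
      caches[[l]] <- list(cols = cols, act = act, arg = pl$arg,
                          L_in = L, C_in = C)
    }
    A <- pl$out
  }
  flat <- matrix(A, N, prod(dim(A)[2:3]))
  drop_mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    drop_mask <- matrix(
      (runif(length(flat)) < keep) / keep, nrow(flat), ncol(flat)
    )
    flat <- flat * drop_mask
  }
  Z1 <- sweep(flat %*% weights$dense1$W, 2L, weights$dense1$b, "+")
  H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% weights$dense2$W, 2L, weights$dense2$b, "+")
  prob <- as.vector(sigmoid(Z2))
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, caches = caches, flat = flat, drop_mask = drop_mask,
       H1 = H1, pooled_dim = dim(A))
}

# Gradients of mean weighted binary cross-entropy wrt every parameter.
cnn_backward <- function(weights, cfg, fwd, y, sample_weights) {
  N <- length(y)
  g2 <- matrix(sample_weights * (fwd$prob - y) / N, ncol = 1L)
  grads <- list(conv = vector("list", cfg$n_conv_layers))
  grads$dense2 <- list(W = crossprod(fwd$H1, g2), b = colSums(g2))
  dH1 <- g2 %*% t(weights$dense2$W)
  dZ1 <- dH1 * (fwd$H1 > 0)
  grads$dense1 <- list(W = crossprod(fwd$flat, dZ1), b = colSums(dZ1))
  dflat <- dZ1 %*% t(weights$dense1$W)
  if (!is.null(fwd$drop_mask)) dflat <- dflat * fwd$drop_mask
  dA <- array(dflat, fwd$pooled_dim)
  for (l in rev(seq_len(cfg$n_conv_layers))) {
    cc <- fwd$caches[[l]]
    wl <- weights$conv[[l]]
    Lz <- cc$L_in
    dZ <- pool_backward(dA, cc$arg, Lz, cfg$pool_size)
    dZ[!cc$act] <- 0
    dZf <- matrix(dZ, N * Lz, ncol(wl$W))
    grads$conv[[l]] <- list(W = crossprod(cc$cols, dZf), b = colSums(dZf))
    if (l > 1L) {
      dcols <- dZf %*% t(wl$W)
      dA <- conv_col2im(dcols, N, Lz, cc$C_in, wl$k)
    }
  }
  grads
}

bce_loss <- function(prob, y, sample_weights, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  mean(sample_weights * -(y * log(p) + (1 - y) * log(1 - p)))
}

# flat iteration over the parameter tree, shared by the optimizer and tests;
# paths are lists because conv layers are indexed by position, not name
param_paths <- function(weights) {
  paths <- list()
  for (l in seq_along(weights$conv)) {
    paths <- c(paths, list(list("conv", l, "W"), list("conv", l, "b")))
  }
  c(paths, list(list("dense1", "W"), list("dense1", "b"),
                list("dense2", "W"), list("dense2", "b")))
}

get_param <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

set_param <- function(tree, path, value) {
  if (length(path) == 1L) {
    tree[[path[[1]]]] <- value
  } else {
    tree[[path[[1]]]] <- set_param(tree[[path[[1]]]], path[-1], value)
  }
  tree
}

rmsprop_init <- function(weights) {
  st <- weights
  for (path in param_paths(weights)) {
    st <- set_param(st, path, get_param(weights, path) * 0)
  }
  st
}

rmsprop_step <- function(weights, grads, state, lr, rho = 0.9, eps = 1e-7) {
  for (path in param_paths(weights)) {
    g <- get_param(grads, path)
    v <- rho * get_param(state, path) + (1 - rho) * g^2
    state <- set_param(state, path, v)
    w <- get_param(weights, path) - lr * g / (sqrt(v) + eps)
    weights <- set_param(weights, path, w)
  }
  list(weights = weights, state = state)
}
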