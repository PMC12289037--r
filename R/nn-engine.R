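# Minimal deterministic neural-network engine used by the DCGAN models.
#
# Layout convention: a batch of C-channel H x W images is a dense numeric
# matrix of dim (C*H*W) x B with the CHANNEL index fastest, i.e. row index
# c + C*((i-1) + H*(j-1)) for pixel (i, j) (column-major within a channel
# plane).  With this layout convolution outputs reshape into the same
# convention by a dim<- change alone, and batch-norm statistics per channel
# are row operations after a dim<- change to (C, H*W*B).
#
# Convolutions are evaluated tap-by-tap: for each of the k*k kernel
# positions the valid input pixels are gathered (one vector index), hit with
# an OC x C dense matrix product, and scatter-added into the output.  Zero
# padding falls out of the validity ranges; a transposed convolution is the
# same loop over the stride-dilated output grid, where each tap touches an
# arithmetic subsequence of output positions.  This keeps peak memory at a
# small multiple of the activation size and routes all heavy work through
# BLAS.

#' @importFrom stats rnorm
NULL

## ---- tap plans ------------------------------------------------------------

# index vector for rows (channel-fastest) covering channels 1..C at spatial
# positions (i0 in src_i0) x (j0 in src_j0), all 0-based spatial
tap_rows <- function(C, H, src_i0, src_j0) {
  ni <- length(src_i0)
  part <- rep(0:(C - 1L), times = ni) + C * rep(src_i0, each = C)
  rep(part, times = length(src_j0)) +
    rep(C * H * src_j0, each = C * ni) + 1L
}

# Standard convolution plan: for each kernel tap (ki, kj), the valid output
# rows/cols and the matching input rows/cols.
conv_plan <- function(H, W, C, OC, k, stride, pad) {
  OH <- (H + 2L * pad - k) %/% stride + 1L
  OW <- (W + 2L * pad - k) %/% stride + 1L
  stopifnot(OH >= 1L, OW >= 1L)
  taps <- list()
  for (kj in 0:(k - 1L)) {
    for (ki in 0:(k - 1L)) {
      oi0 <- 0:(OH - 1L)
      src_i0 <- oi0 * stride + ki - pad
      sel_i <- src_i0 >= 0L & src_i0 < H
      oj0 <- 0:(OW - 1L)
      src_j0 <- oj0 * stride + kj - pad
      sel_j <- src_j0 >= 0L & src_j0 < W
      if (!any(sel_i) || !any(sel_j)) next
      taps[[length(taps) + 1L]] <- list(
        in_idx = tap_rows(C, H, src_i0[sel_i], src_j0[sel_j]),
        out_idx = tap_rows(OC, OH, oi0[sel_i], oj0[sel_j]),
        n_sp = sum(sel_i) * sum(sel_j),
        wcols = C * (ki + k * kj) + 1:C)
    }
  }
  list(taps = taps, H = H, W = W, C = C, OC = OC, k = k,
       OH = OH, OW = OW, n_p = C * k * k, n_o = OH * OW)
}

# Transposed-convolution plan: output stride*(H-1) + k - 2*pad, treated as a
# stride-1 convolution over the stride-dilated input; for a given tap the
# output positions hitting real (non-dilation) pixels form an arithmetic
# sequence with step `stride`.
tconv_plan <- function(H, W, C, OC, k, stride, pad) {
  Hd <- stride * (H - 1L) + 1L
  Wd <- stride * (W - 1L) + 1L
  pe <- k - 1L - pad
  OH <- Hd + 2L * pe - k + 1L
  OW <- Wd + 2L * pe - k + 1L
  taps <- list()
  for (kj in 0:(k - 1L)) {
    for (ki in 0:(k - 1L)) {
      oi0 <- 0:(OH - 1L)
      di0 <- oi0 + ki - pe
      sel_i <- di0 >= 0L & di0 < Hd & di0 %% stride == 0L
      oj0 <- 0:(OW - 1L)
      dj0 <- oj0 + kj - pe
      sel_j <- dj0 >= 0L & dj0 < Wd & dj0 %% stride == 0L
      if (!any(sel_i) || !any(sel_j)) next
      taps[[length(taps) + 1L]] <- list(
        in_idx = tap_rows(C, H, di0[sel_i] %/% stride, dj0[sel_j] %/% stride),
        out_idx = tap_rows(OC, OH, oi0[sel_i], oj0[sel_j]),
        n_sp = sum(sel_i) * sum(sel_j),
        wcols = C * (ki + k * kj) + 1:C)
    }
  }
  list(taps = taps, H = H, W = W, C = C, OC = OC, k = k,
       OH = OH, OW = OW, n_p = C * k * k, n_o = OH * OW)
}

conv_forward_raw <- function(plan, X, W, b) {
  B <- ncol(X)
  C <- plan$C
  Y <- matrix(0, plan$OC * plan$n_o, B)
  for (tap in plan$taps) {
    Xg <- X[tap$in_idx, , drop = FALSE]
    dim(Xg) <- c(C, tap$n_sp * B)
    Yg <- W[, tap$wcols, drop = FALSE] %*% Xg
    dim(Yg) <- c(plan$OC * tap$n_sp, B)
    Y[tap$out_idx, ] <- Y[tap$out_idx, , drop = FALSE] + Yg
  }
  Y + b
}

conv_backward_raw <- function(plan, X, W, dY) {
  B <- ncol(dY)
  C <- plan$C
  dW <- matrix(0, plan$OC, plan$n_p)
  dX <- matrix(0, nrow(X), B)
  dYr <- dY
  dim(dYr) <- c(plan$OC, plan$n_o * B)
  db <- rowSums(dYr)
  for (tap in plan$taps) {
    dYg <- dY[tap$out_idx, , drop = FALSE]
    dim(dYg) <- c(plan$OC, tap$n_sp * B)
    Xg <- X[tap$in_idx, , drop = FALSE]
    dim(Xg) <- c(C, tap$n_sp * B)
    dW[, tap$wcols] <- dW[, tap$wcols, drop = FALSE] + tcrossprod(dYg, Xg)
    dXg <- crossprod(W[, tap$wcols, drop = FALSE], dYg)
    dim(dXg) <- c(C * tap$n_sp, B)
    dX[tap$in_idx, ] <- dX[tap$in_idx, , drop = FALSE] + dXg
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- layers ---------------------------------------------------------------

nn_dense <- function(n_in, n_out, init_sd = 0.02) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(rnorm(n_out * n_in, 0, init_sd), n_out, n_in),
                     b = numeric(n_out)))
}

# `transpose = TRUE` builds a transposed convolution; the weight tensor is
# stored in the orientation of the equivalent dilated convolution,
# OC x (C*k*k), which is all the engine ever needs.
nn_conv <- function(H, W, C, OC, k = 4L, stride = 2L, pad = 1L,
                    transpose = FALSE, init_sd = 0.02) {
  plan <- if (transpose) tconv_plan(H, W, C, OC, k, stride, pad)
          else conv_plan(H, W, C, OC, k, stride, pad)
  list(type = "conv", transpose = transpose, OC = OC, plan = plan,
       out_H = plan$OH, out_W = plan$OW,
       params = list(W = matrix(rnorm(OC * plan$n_p, 0, init_sd), OC, plan$n_p),
                     b = numeric(OC)))
}

nn_batchnorm <- function(C, HW, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", C = C, HW = HW, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C),
                     run_mean = numeric(C), run_var = rep(1, C)))
}

nn_act <- function(kind, alpha = 0.2) {
  stopifnot(kind %in% c("relu", "lrelu", "tanh", "sigmoid"))
  list(type = "act", kind = kind, alpha = alpha, params = list())
}

## ---- forward / backward ---------------------------------------------------

layer_forward <- function(layer, X, training = TRUE) {
  switch(layer$type,
    dense = {
      Y <- layer$params$W %*% X + layer$params$b
      list(Y = Y, cache = list(X = X), layer = layer)
    },
    conv = {
      Y <- conv_forward_raw(layer$plan, X, layer$params$W, layer$params$b)
      list(Y = Y, cache = list(X = X), layer = layer)
    },
    batchnorm = {
      C <- layer$C
      B <- ncol(X)
      Xr <- X
      dim(Xr) <- c(C, layer$HW * B)
      if (training) {
        mu <- rowMeans(Xr)
        xc <- Xr - mu
        v <- rowMeans(xc * xc)
        inv <- 1 / sqrt(v + layer$eps)
        xhat <- xc * inv
        Y <- layer$params$gamma * xhat + layer$params$beta
        m <- layer$momentum
        layer$params$run_mean <- m * layer$params$run_mean + (1 - m) * mu
        layer$params$run_var <- m * layer$params$run_var + (1 - m) * v
        dim(Y) <- dim(X)
        list(Y = Y, cache = list(xhat = xhat, inv = inv, training = TRUE),
             layer = layer)
      } else {
        inv <- 1 / sqrt(layer$params$run_var + layer$eps)
        Y <- layer$params$gamma * ((Xr - layer$params$run_mean) * inv) +
          layer$params$beta
        dim(Y) <- dim(X)
        list(Y = Y, cache = list(inv = inv, training = FALSE), layer = layer)
      }
    },
    act = {
      Y <- switch(layer$kind,
        relu = pmax(X, 0),
        lrelu = pmax(X, 0) + layer$alpha * pmin(X, 0),
        tanh = tanh(X),
        sigmoid = 1 / (1 + exp(-X)))
      list(Y = Y, cache = list(X = X, Y = Y), layer = layer)
    })
}

layer_backward <- function(layer, dY, cache) {
  switch(layer$type,
    dense = {
      list(dX = crossprod(layer$params$W, dY),
           grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
    },
    conv = {
      bk <- conv_backward_raw(layer$plan, cache$X, layer$params$W, dY)
      list(dX = bk$dX, grads = list(W = bk$dW, b = bk$db))
    },
    batchnorm = {
      C <- layer$C
      B <- ncol(dY)
      dYr <- dY
      dim(dYr) <- c(C, layer$HW * B)
      if (cache$training) {
        N <- layer$HW * B
        dbeta <- rowSums(dYr)
        dgamma <- rowSums(dYr * cache$xhat)
        dxhat <- dYr * layer$params$gamma
        dX <- (cache$inv / N) *
          (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
        dim(dX) <- dim(dY)
        list(dX = dX, grads = list(gamma = dgamma, beta = dbeta,
                                   run_mean = numeric(C), run_var = numeric(C)))
      } else {
        dX <- dYr * (layer$params$gamma * cache$inv)
        dim(dX) <- dim(dY)
        list(dX = dX,
             grads = list(gamma = numeric(C), beta = numeric(C),
                          run_mean = numeric(C), run_var = numeric(C)))
      }
    },
    act = {
      dX <- switch(layer$kind,
        relu = dY * (cache$X > 0),
        lrelu = dY * ifelse(cache$X > 0, 1, layer$alpha),
        tanh = dY * (1 - cache$Y^2),
        sigmoid = dY * cache$Y * (1 - cache$Y))
      list(dX = dX, grads = list())
    })
}

# Forward through a network (list with $layers).  Returns the output, the
# per-layer caches needed for backprop, and the network itself (batch-norm
# running statistics are updated when training = TRUE).
net_forward <- function(net, X, training = TRUE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    f <- layer_forward(net$layers[[i]], X, training = training)
    X <- f$Y
    caches[[i]] <- f$cache
    net$layers[[i]] <- f$layer
  }
  list(out = X, caches = caches, net = net)
}

net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    b <- layer_backward(net$layers[[i]], dOut, caches[[i]])
    dOut <- b$dX
    grads[[i]] <- b$grads
  }
  list(dX = dOut, grads = grads)
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(net) {
  state <- lapply(net$layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
  list(t = 0L, layers = state)
}

# Applies one Adam step; gradient entries for batch-norm running statistics
# are ignored (those update through the forward pass only).
adam_step <- function(net, grads, state, lr, beta1, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (length(g) == 0L) next
    for (nm in names(g)) {
      if (nm %in% c("run_mean", "run_var")) next
      st <- state$layers[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      state$layers[[i]][[nm]] <- st
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(net = net, state = state)
}
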