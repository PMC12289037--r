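# Shared fixtures and independent oracles, all built in code at test time.

# small labeled fundus phantom batch, preprocessed at the given size
phantom_batch <- function(n, size = 16L, seed = 1L, domain = "fundus") {
  raws <- make_dataset(phantom_config(n, size, domain = domain, seed = seed))
  preprocess_dataset(raws, pipeline_config(size))$images
}

pixmat <- function(images) silogan:::images_to_batch(images)

# a weight set whose generator emits the constant image x0 (|x0| < 1) for
# every latent input: all tensors zeroed, final transposed-conv bias atanh(x0)
constant_generator <- function(x0, latent_dim = 8L) {
  size <- as.integer(sqrt(length(x0)))
  ws <- net_weights(build_generator(latent_dim, size, seed = 1L))
  for (nm in names(ws$tensors)) ws$tensors[[nm]] <- ws$tensors[[nm]] * 0
  bias_keys <- grep("_conv\\.b$", names(ws$tensors), value = TRUE)
  last_b <- bias_keys[length(bias_keys)]
  stopifnot(length(ws$tensors[[last_b]]) == 1L)  # single output channel
  # single-channel output: one shared bias; only a constant x0 per image is
  # representable, so use a scalar target
  ws$tensors[[last_b]] <- atanh(x0[1L])
  ws
}

# a discriminator weight set with constant output sigmoid(bias)
constant_discriminator <- function(p, size = 16L) {
  ws <- net_weights(build_discriminator(size, seed = 1L))
  for (nm in names(ws$tensors)) ws$tensors[[nm]] <- ws$tensors[[nm]] * 0
  bias_keys <- grep("_dense\\.b$", names(ws$tensors), value = TRUE)
  ws$tensors[[bias_keys[length(bias_keys)]]] <- log(p / (1 - p))
  ws
}

# independent scalar binary-cross-entropy oracle (explicit loop, no reuse of
# package internals)
bce_oracle <- function(probs, target) {
  s <- 0
  for (p in probs) s <- s + (-(target * log(p) + (1 - target) * log(1 - p)))
  s / length(probs)
}

# independent blockwise CLAHE oracle: per-tile clipped-histogram
# equalization applied to the tile's own pixels, no interpolation
clahe_block_oracle <- function(v, clip_limit, grid) {
  H <- nrow(v); W <- ncol(v)
  gy <- grid[2L]; gx <- grid[1L]
  row_tile <- ceiling(seq_len(H) / (H / gy))
  col_tile <- ceiling(seq_len(W) / (W / gx))
  out <- matrix(0, H, W)
  maps <- list()
  for (a in seq_len(gy)) for (b in seq_len(gx)) {
    tile <- v[row_tile == a, col_tile == b]
    N <- length(tile)
    h <- rep(0, 256)
    for (val in tile) h[val + 1] <- h[val + 1] + 1
    thr <- clip_limit * N / 256
    excess <- sum(ifelse(h > thr, h - thr, 0))
    h <- ifelse(h > thr, thr, h) + excess / 256
    m <- round(cumsum(h) / N * 255)
    maps[[paste(a, b)]] <- m
    out[row_tile == a, col_tile == b] <- m[tile + 1]
  }
  list(out = out, maps = maps,
       row_tile = row_tile, col_tile = col_tile)
}

# direct eigendecomposition matrix-square-root oracle for the Frechet trace
# term: sum of sqrt of eigenvalues of the (nonsymmetric) product Sr %*% Sf
fid_oracle <- function(Xr, Xf) {
  d <- ncol(Xr)
  Sr <- stats::cov(Xr) + diag(1e-6, d)
  Sf <- stats::cov(Xf) + diag(1e-6, d)
  ev <- eigen(Sr %*% Sf, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(Re(ev), 0)))
  sum((colMeans(Xr) - colMeans(Xf))^2) +
    sum(diag(Sr)) + sum(diag(Sf)) - 2 * tr_sqrt
}

# uniform-noise pixel batch in [-1, 1]
noise_batch <- function(n, size = 16L, seed = 1L) {
  set.seed(seed)
  matrix(runif(size * size * n, -1, 1), size * size, n)
}
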