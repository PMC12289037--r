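# Quantitative evaluation: realism score, Frechet distance between embedded
# image distributions, and loss-variance summaries.

#' Realism score of a generator under a frozen discriminator
#'
#' Mean probability that a frozen, centrally trained discriminator assigns
#' to `n` generated images, using a fixed-seed latent sample; always in
#' [0, 1] and identical across repeated calls with the same seed.
#'
#' @param g_ws generator weight set.
#' @param d_ws frozen (centralized) discriminator weight set of the same
#'   image size.
#' @param n number of generated images (default 256).
#' @param seed seed for the latent draws.
#' @return scalar realism score in [0, 1].
#' @export
realism_score <- function(g_ws, d_ws, n = 256L, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (g_ws$arch$image_size != d_ws$arch$image_size)
    stop("generator and discriminator image sizes differ")
  X <- generate_images(g_ws, n, seed = seed)
  mean(discriminate_images(d_ws, X))
}

#' Frechet distance between two feature distributions
#'
#' `||mu_r - mu_f||^2 + Tr(S_r + S_f - 2 (S_r S_f)^{1/2})` with sample means
#' and covariances (n-1 denominator).  The trace term is computed through
#' the symmetric eigendecomposition of `S_r^{1/2} S_f S_r^{1/2}`; both
#' covariances are regularized with `1e-6 * I`, and a negative residual
#' above `-1e-6` is truncated to 0.  Symmetric in its arguments.
#'
#' @param real_features,fake_features `n x d` feature matrices, `n >= 2`,
#'   equal `d`.
#' @return scalar Frechet distance (>= 0 up to the stated tolerance).
#' @export
fid <- function(real_features, fake_features) {
  Xr <- as.matrix(real_features)
  Xf <- as.matrix(fake_features)
  if (ncol(Xr) != ncol(Xf))
    stop("feature dimensions differ: ", ncol(Xr), " vs ", ncol(Xf))
  if (nrow(Xr) < 2L || nrow(Xf) < 2L)
    stop("need at least 2 samples per side")
  if (any(!is.finite(Xr)) || any(!is.finite(Xf)))
    stop("non-finite features")
  d <- ncol(Xr)
  mur <- colMeans(Xr)
  muf <- colMeans(Xf)
  Sr <- stats::cov(Xr) + diag(1e-6, d)
  Sf <- stats::cov(Xf) + diag(1e-6, d)
  er <- eigen(Sr, symmetric = TRUE)
  Sr_half <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  M <- Sr_half %*% Sf %*% Sr_half
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  val <- sum((mur - muf)^2) + sum(diag(Sr)) + sum(diag(Sf)) - 2 * tr_sqrt
  if (val < 0 && val > -1e-6) val <- 0
  val
}

#' Fixed-seed random-projection convolutional embedder
#'
#' A deterministic feature map used for desk-scale Frechet-distance
#' evaluation: one 4 x 4 stride-2 convolution with `d` fixed random filters
#' (seeded, standard normal), ReLU, then spatial averaging per filter.  It
#' satisfies the embedding contract (same input, same features) without any
#' pretrained weights; production use can substitute any pretrained embedder
#' behind the same interface.
#'
#' @param image_size image side of the inputs.
#' @param d feature dimension (number of filters, default 16).
#' @param seed seed fixing the projection (part of the embedder identity).
#' @return a function mapping a `(S*S) x n` pixel matrix to an `n x d`
#'   feature matrix, with an `identifier` attribute.
#' @export
make_embedder <- function(image_size, d = 16L, seed = 7L) {
  set.seed(seed)
  layer <- nn_conv(image_size, image_size, 1L, as.integer(d), init_sd = 1)
  n_o <- layer$plan$n_o
  f <- function(X) {
    Y <- layer_forward(layer, X, training = FALSE)$Y
    Y <- pmax(Y, 0)
    B <- ncol(Y)
    dim(Y) <- c(d, n_o * B)
    feats <- vapply(seq_len(B), function(b)
      rowMeans(Y[, (b - 1L) * n_o + seq_len(n_o), drop = FALSE]),
      numeric(d))
    t(feats)
  }
  attr(f, "identifier") <- sprintf("randproj-conv-d%d-seed%d", d, seed)
  f
}

#' Mean and standard deviation of loss series per configuration
#'
#' @param series named list of numeric loss series (length >= 2 each).
#' @return data frame with columns `config`, `mean`, `sd` (sample sd,
#'   n-1 denominator), one row per series, keys preserved bijectively.
#' @export
loss_variance <- function(series) {
  if (is.numeric(series)) series <- list(series = series)
  for (nm in names(series)) {
    if (length(series[[nm]]) < 2L)
      stop("series '", nm, "' has length < 2")
  }
  data.frame(config = names(series),
             mean = vapply(series, mean, numeric(1)),
             sd = vapply(series, stats::sd, numeric(1)),
             row.names = NULL)
}
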