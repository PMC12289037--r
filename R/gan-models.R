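# DCGAN generator / discriminator construction and weight-set handling.

#' Build a DCGAN generator
#'
#' The generator maps a latent vector to a single-channel image in (-1, 1).
#' At `out_size = 128` the architecture is: dense layer with 16384 units
#' reshaped to 8 x 8 x 256, followed by four stride-2 transposed-convolution
#' blocks (4 x 4 kernels) with 128, 64, 32 and 1 filters; hidden blocks use
#' batch normalization and ReLU, the final block a tanh.  For smaller output
#' sizes the 8 x 8 x 256 stem is kept and blocks are dropped from the top of
#' the stack, i.e. `log2(out_size/8)` blocks taking the *last* entries of the
#' filter list (128, 64, 32, 1), so the tanh output block is always present.
#'
#' @param latent_dim length of the latent noise vector (default 200).
#' @param out_size output image side, one of 16, 32, 64, 128.
#' @param seed optional integer seed for the weight initialization
#'   (normal with sd 0.02, the DCGAN convention).
#' @return a network object; extract portable weights with [net_weights()].
#' @export
build_generator <- function(latent_dim = 200L, out_size = 128L, seed = NULL) {
  if (!out_size %in% c(16L, 32L, 64L, 128L))
    stop("unsupported out_size: ", out_size, " (must be 16, 32, 64 or 128)")
  if (!is.null(seed)) set.seed(seed)
  n_up <- as.integer(log2(out_size / 8))
  filters <- utils::tail(c(128L, 64L, 32L, 1L), n_up)
  layers <- list(nn_dense(latent_dim, 8L * 8L * 256L))
  H <- 8L; C <- 256L
  for (i in seq_along(filters)) {
    f <- filters[i]
    layers <- c(layers, list(nn_conv(H, H, C, f, transpose = TRUE)))
    H <- 2L * H
    if (i < length(filters)) {
      layers <- c(layers, list(nn_batchnorm(f, H * H), nn_act("relu")))
    } else {
      layers <- c(layers, list(nn_act("tanh")))
    }
    C <- f
  }
  structure(list(kind = "generator", latent_dim = as.integer(latent_dim),
                 image_size = as.integer(out_size), layers = layers),
            class = "silogan_net")
}

#' Build a DCGAN discriminator
#'
#' Maps a single-channel image to the probability that it is real.  At
#' `in_size = 128`: four stride-2 convolution blocks (4 x 4 kernels) with
#' 32, 64, 128, 256 filters and LeakyReLU(0.2), batch normalization on
#' blocks 2-4, then flatten (8 x 8 x 256 = 16384) -> dense(1) -> sigmoid.
#' Smaller inputs keep the *first* `log2(in_size/8)` filter counts.
#'
#' @param in_size input image side, one of 16, 32, 64, 128; must match the
#'   generator's `out_size`.
#' @param seed optional integer seed for weight initialization.
#' @return a network object.
#' @export
build_discriminator <- function(in_size = 128L, seed = NULL) {
  if (!in_size %in% c(16L, 32L, 64L, 128L))
    stop("unsupported in_size: ", in_size, " (must be 16, 32, 64 or 128)")
  if (!is.null(seed)) set.seed(seed)
  n_down <- as.integer(log2(in_size / 8))
  filters <- utils::head(c(32L, 64L, 128L, 256L), n_down)
  layers <- list()
  H <- as.integer(in_size); C <- 1L
  for (i in seq_along(filters)) {
    f <- filters[i]
    layers <- c(layers, list(nn_conv(H, H, C, f, transpose = FALSE)))
    H <- H %/% 2L
    if (i > 1L) layers <- c(layers, list(nn_batchnorm(f, H * H)))
    layers <- c(layers, list(nn_act("lrelu")))
    C <- f
  }
  layers <- c(layers, list(nn_dense(8L * 8L * C, 1L), nn_act("sigmoid")))
  structure(list(kind = "discriminator", image_size = as.integer(in_size),
                 layers = layers),
            class = "silogan_net")
}

## ---- weight sets ----------------------------------------------------------

#' Extract the portable weight set of a network
#'
#' A weight set is an ordered named list of numeric tensors together with an
#' architecture descriptor; it is the unit that federated averaging operates
#' on.  Batch-norm running statistics are part of the weight set and are
#' averaged like any other tensor.
#'
#' @param net a network from [build_generator()] or [build_discriminator()].
#' @return an object of class `silogan_weights` with fields `network`
#'   (`"generator"` or `"discriminator"`), `arch`, and `tensors`.
#' @export
net_weights <- function(net) {
  tensors <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (nm in names(l$params)) {
      tensors[[sprintf("L%02d_%s.%s", i, l$type, nm)]] <- l$params[[nm]]
    }
  }
  arch <- list(kind = net$kind, image_size = net$image_size)
  if (net$kind == "generator") arch$latent_dim <- net$latent_dim
  structure(list(network = net$kind, arch = arch, tensors = tensors),
            class = "silogan_weights")
}

#' Rebuild a network from a weight set
#'
#' @param ws a `silogan_weights` object.
#' @return a network object carrying exactly the tensors of `ws`.
#' @export
net_from_weights <- function(ws) {
  net <- if (ws$network == "generator") {
    build_generator(ws$arch$latent_dim, ws$arch$image_size)
  } else {
    build_discriminator(ws$arch$image_size)
  }
  net_set_weights(net, ws)
}

net_set_weights <- function(net, ws) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (nm in names(l$params)) {
      key <- sprintf("L%02d_%s.%s", i, l$type, nm)
      t <- ws$tensors[[key]]
      if (is.null(t)) stop("weight set is missing tensor ", key)
      if (length(t) != length(l$params[[nm]]))
        stop("tensor ", key, " has wrong size")
      dim(t) <- dim(l$params[[nm]])
      net$layers[[i]]$params[[nm]] <- t
    }
  }
  net
}

## ---- sampling -------------------------------------------------------------

#' Sample latent vectors
#'
#' @param n number of vectors.
#' @param latent_dim latent dimension (default 200).
#' @return a `latent_dim x n` matrix of standard-normal draws.
#' @export
sample_latent <- function(n, latent_dim = 200L) {
  matrix(rnorm(latent_dim * n), latent_dim, n)
}

#' Generate images from a generator weight set
#'
#' @param g_ws generator weight set.
#' @param n number of images.
#' @param seed optional seed for the latent draws.
#' @param training logical; if `TRUE` batch norm uses batch statistics,
#'   otherwise the stored running statistics (the evaluation default).
#' @return a `(size*size) x n` matrix of pixels in (-1, 1), channel layout of
#'   the engine (single channel: plain column-major pixels).
#' @export
generate_images <- function(g_ws, n, seed = NULL, training = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  net <- net_from_weights(g_ws)
  z <- sample_latent(n, g_ws$arch$latent_dim)
  net_forward(net, z, training = training)$out
}

#' Score images with a discriminator weight set
#'
#' @param d_ws discriminator weight set.
#' @param X a `(size*size) x n` pixel matrix in [-1, 1].
#' @return numeric vector of n probabilities in (0, 1).
#' @export
discriminate_images <- function(d_ws, X) {
  net <- net_from_weights(d_ws)
  as.numeric(net_forward(net, X, training = FALSE)$out)
}

## ---- batch <-> image conversion -------------------------------------------

# list of ProcessedImage -> (S*S) x n batch matrix
images_to_batch <- function(images) {
  stopifnot(length(images) >= 1L)
  vapply(images, function(im) as.numeric(im$pixels),
         numeric(length(images[[1L]]$pixels)))
}

# one batch column -> S x S matrix
batch_column_to_matrix <- function(x, size) {
  matrix(x, size, size)
}
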