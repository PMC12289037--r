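# Local (single-client) adversarial training.

#' Training configuration
#'
#' Defaults follow the DCGAN training settings used throughout the framework:
#' batch size 64, Adam with learning rate 2e-4 and beta1 = 0.5, latent
#' dimension 200, real-label smoothing 0.9, 5 local epochs.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate for both networks.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param label_smooth real-class target for the discriminator loss.
#' @param latent_dim latent noise dimension.
#' @param local_epochs epochs of local training per call.
#' @param seed optional integer seed making the run reproducible.
#' @param eps probability clamp used inside the losses.
#' @return a list of class `silogan_train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 2e-4,
                         adam_beta1 = 0.5, adam_beta2 = 0.999,
                         label_smooth = 0.9, latent_dim = 200L,
                         local_epochs = 5L, seed = NULL, eps = 1e-7) {
  stopifnot(batch_size >= 1L, learning_rate > 0,
            label_smooth > 0, label_smooth <= 1, local_epochs >= 0L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, label_smooth = label_smooth,
                 latent_dim = as.integer(latent_dim),
                 local_epochs = as.integer(local_epochs), seed = seed,
                 eps = eps),
            class = "silogan_train_config")
}

#' Train generator and discriminator locally on one data shard
#'
#' Runs `cfg$local_epochs` epochs of alternating batch-level updates: one
#' discriminator step (real batch against the smoothed target, generated
#' batch against 0) followed by one generator step (non-saturating loss on a
#' fresh latent batch), both with Adam.  With `local_epochs = 0` the weights
#' are returned unchanged.  Adam state is fresh at every call, as in
#' round-based federated training.
#'
#' @param g_ws,d_ws generator / discriminator weight sets (same image size).
#' @param records list of processed images, or a pixel matrix of dim
#'   `(size*size) x n` with values in [-1, 1].
#' @param cfg a [train_config()].
#' @return list with updated `G`, `D` weight sets and `trace`, a data frame
#'   with one row per batch (epoch, batch, d_loss, g_loss).
#' @export
local_train <- function(g_ws, d_ws, records, cfg = train_config()) {
  X <- if (is.matrix(records)) records else images_to_batch(records)
  n <- ncol(X)
  if (n < 1L) stop("empty shard: nothing to train on")
  if (g_ws$arch$image_size != d_ws$arch$image_size)
    stop("generator and discriminator image sizes differ")
  if (nrow(X) != g_ws$arch$image_size^2)
    stop("record pixel count does not match the network image size")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$local_epochs == 0L) {
    return(list(G = g_ws, D = d_ws,
                trace = data.frame(epoch = integer(), batch = integer(),
                                   d_loss = numeric(), g_loss = numeric())))
  }
  G <- net_from_weights(g_ws)
  D <- net_from_weights(d_ws)
  sg <- adam_init(G)
  sd <- adam_init(D)
  smooth <- cfg$label_smooth
  eps <- cfg$eps
  trace <- list()
  step <- 0L
  for (ep in seq_len(cfg$local_epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      Xb <- X[, idx, drop = FALSE]

      ## discriminator step
      z <- sample_latent(B, cfg$latent_dim)
      gf <- net_forward(G, z, training = TRUE)
      G <- gf$net
      fr <- net_forward(D, Xb, training = TRUE)
      D <- fr$net
      ff <- net_forward(D, gf$out, training = TRUE)
      D <- ff$net
      pr <- clamp_probs(as.numeric(fr$out), eps)
      pf <- clamp_probs(as.numeric(ff$out), eps)
      d_loss <- discriminator_loss(pr, pf, smooth = smooth, eps = eps)
      dLdpr <- matrix(-(smooth / pr - (1 - smooth) / (1 - pr)) / B, 1L)
      dLdpf <- matrix((1 / (1 - pf)) / B, 1L)
      br <- net_backward(D, fr$caches, dLdpr)
      bf <- net_backward(D, ff$caches, dLdpf)
      upd <- adam_step(D, add_grads(br$grads, bf$grads), sd,
                       cfg$learning_rate, cfg$adam_beta1, cfg$adam_beta2)
      D <- upd$net
      sd <- upd$state

      ## generator step (discriminator batch-norm state not committed)
      z2 <- sample_latent(B, cfg$latent_dim)
      gf2 <- net_forward(G, z2, training = TRUE)
      G <- gf2$net
      df <- net_forward(D, gf2$out, training = TRUE)
      p <- clamp_probs(as.numeric(df$out), eps)
      g_loss <- generator_loss(p, eps = eps)
      dLdp <- matrix(-(1 / p) / B, 1L)
      bd <- net_backward(D, df$caches, dLdp)
      bg <- net_backward(G, gf2$caches, bd$dX)
      upd <- adam_step(G, bg$grads, sg,
                       cfg$learning_rate, cfg$adam_beta1, cfg$adam_beta2)
      G <- upd$net
      sg <- upd$state

      if (!is.finite(d_loss) || !is.finite(g_loss)) {
        stop("non-finite loss at epoch ", ep, " batch ", bi,
             " (d_loss = ", d_loss, ", g_loss = ", g_loss, ")")
      }
      step <- step + 1L
      trace[[step]] <- data.frame(epoch = ep, batch = bi,
                                  d_loss = d_loss, g_loss = g_loss)
    }
  }
  list(G = net_weights(G), D = net_weights(D),
       trace = do.call(rbind, trace))
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}
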