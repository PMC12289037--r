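# Privacy-leakage audit: membership inference, model inversion, empirical
# epsilon, nearest-neighbour distance analysis, and a composite risk score.

#' Attack configuration
#'
#' @param split fraction of each class used to train the attack classifier
#'   (held-out remainder is scored); in (0, 1).
#' @param epochs,batch_size,lr attack-classifier training settings.
#' @param inversion_steps gradient-descent steps per inversion target.
#' @param inversion_step_size step size of the latent descent.
#' @param inversion_restarts random restarts per target (best kept).
#' @param seed integer seed; every attack is deterministic given it.
#' @return list of class `silogan_attack_config`.
#' @export
attack_config <- function(split = 0.5, epochs = 30L, batch_size = 32L,
                          lr = 1e-3, inversion_steps = 500L,
                          inversion_step_size = 0.05,
                          inversion_restarts = 5L, seed = 1L) {
  stopifnot(split > 0, split < 1, inversion_steps >= 1L,
            inversion_restarts >= 1L)
  structure(list(split = split, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 inversion_steps = as.integer(inversion_steps),
                 inversion_step_size = inversion_step_size,
                 inversion_restarts = as.integer(inversion_restarts),
                 seed = as.integer(seed)),
            class = "silogan_attack_config")
}

as_pixel_matrix <- function(x) {
  if (is.matrix(x)) x else images_to_batch(x)
}

# area under the ROC curve via the rank statistic (ties get average ranks)
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points at every distinct score threshold (score >= t predicts "real")
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = s[keep],
             tpr = tp[keep] / sum(y == 1),
             fpr = fp[keep] / sum(y == 0))
}

#' Membership inference attack
#'
#' Trains an adversarial convolutional classifier to distinguish real
#' training images from synthetic outputs (the framework's membership-style
#' audit; note this contrasts training data with synthetic data, not members
#' with non-members of the training set).  A fraction `cfg$split` of each
#' class trains the classifier; held-out accuracy (threshold 0.5) and AUC
#' are reported, together with the held-out ROC.
#'
#' @param train_real real training images (list or pixel matrix in [-1,1]).
#' @param synthetic generated images of the same size.
#' @param cfg an [attack_config()].
#' @return list with `accuracy`, `auc`, `roc` (data frame), `n_real_test`,
#'   `n_fake_test`.
#' @export
membership_inference <- function(train_real, synthetic,
                                 cfg = attack_config()) {
  Xr <- as_pixel_matrix(train_real)
  Xs <- as_pixel_matrix(synthetic)
  if (ncol(Xr) < 20L || ncol(Xs) < 20L)
    stop("need at least 20 images per side")
  if (max(ncol(Xr), ncol(Xs)) > 10L * min(ncol(Xr), ncol(Xs)))
    stop("class imbalance exceeds 10:1; attack undefined")
  size <- as.integer(sqrt(nrow(Xr)))
  set.seed(cfg$seed)
  ir <- sample.int(ncol(Xr))
  is_ <- sample.int(ncol(Xs))
  ntr_r <- floor(cfg$split * ncol(Xr))
  ntr_s <- floor(cfg$split * ncol(Xs))
  Xtr <- cbind(Xr[, ir[seq_len(ntr_r)], drop = FALSE],
               Xs[, is_[seq_len(ntr_s)], drop = FALSE])
  ytr <- c(rep(1, ntr_r), rep(0, ntr_s))
  Xte <- cbind(Xr[, ir[-seq_len(ntr_r)], drop = FALSE],
               Xs[, is_[-seq_len(ntr_s)], drop = FALSE])
  yte <- c(rep(1, ncol(Xr) - ntr_r), rep(0, ncol(Xs) - ntr_s))

  net <- build_discriminator(size, seed = cfg$seed + 1L)
  st <- adam_init(net)
  n <- ncol(Xtr)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    for (idx in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      B <- length(idx)
      f <- net_forward(net, Xtr[, idx, drop = FALSE], training = TRUE)
      net <- f$net
      p <- clamp_probs(as.numeric(f$out))
      y <- ytr[idx]
      dLdp <- matrix(-(y / p - (1 - y) / (1 - p)) / B, 1L)
      b <- net_backward(net, f$caches, dLdp)
      upd <- adam_step(net, b$grads, st, cfg$lr, 0.5)
      net <- upd$net
      st <- upd$state
    }
  }
  scores <- as.numeric(net_forward(net, Xte, training = FALSE)$out)
  list(accuracy = mean((scores > 0.5) == (yte == 1)),
       auc = auc_score(scores, yte),
       roc = roc_points(scores, yte),
       n_real_test = sum(yte == 1), n_fake_test = sum(yte == 0))
}

#' Empirical epsilon from attack distinguishability
#'
#' Estimates a differential-privacy-style leakage bound from the attack ROC
#' as `eps = max over thresholds of ln(TPR/FPR)`, with both rates floored at
#' `1/n` of their class's held-out size so the ratio is always defined; the
#' result is truncated below at 0.  A degenerate single-point ROC returns
#' the floor-based bound with a warning.  When class sizes are unknown,
#' points with zero FPR are skipped with a warning.
#'
#' @param mia result of [membership_inference()], or a data frame of ROC
#'   points with columns `fpr`, `tpr`.
#' @param n_pos,n_neg held-out class sizes used for the rate floor (taken
#'   from `mia` when it is a [membership_inference()] result).
#' @return scalar `epsilon_hat >= 0`.
#' @export
estimate_epsilon <- function(mia, n_pos = NULL, n_neg = NULL) {
  if (is.data.frame(mia)) {
    roc <- mia
  } else {
    roc <- mia$roc
    n_pos <- n_pos %||% mia$n_real_test
    n_neg <- n_neg %||% mia$n_fake_test
  }
  if (nrow(roc) == 0L) stop("empty ROC")
  if (nrow(roc) == 1L)
    warning("degenerate single-point ROC; returning floor-based bound")
  tpr <- roc$tpr
  fpr <- roc$fpr
  if (!is.null(n_pos)) tpr <- pmax(tpr, 1 / n_pos)
  if (!is.null(n_neg)) {
    fpr <- pmax(fpr, 1 / n_neg)
  } else if (any(fpr == 0)) {
    warning("unknown class size: skipping ROC points with zero FPR")
    tpr <- tpr[fpr > 0]
    fpr <- fpr[fpr > 0]
    if (length(fpr) == 0L) return(0)
  }
  max(0, max(log(tpr / fpr)))
}

#' Model inversion attack
#'
#' For each target image, optimizes latent vectors by plain gradient descent
#' on the pixel-space mean squared error between the generated image and the
#' target, with `cfg$inversion_restarts` random initializations advanced in
#' parallel; the best loss seen along the kept trajectory is monotone by
#' construction, and the best final value over restarts is kept.
#'
#' @param g_ws generator weight set.
#' @param targets target images in [-1, 1] (list or pixel matrix), size
#'   matching the generator.
#' @param cfg an [attack_config()].
#' @return list with `mean_loss` (mean over targets of the best MSE),
#'   `per_target`, and `trajectories` (per target, the monotone best-so-far
#'   loss sequence).
#' @export
model_inversion <- function(g_ws, targets, cfg = attack_config()) {
  Xt <- as_pixel_matrix(targets)
  if (nrow(Xt) != g_ws$arch$image_size^2)
    stop("target size does not match the generator output size")
  set.seed(cfg$seed)
  net <- net_from_weights(g_ws)
  R <- cfg$inversion_restarts
  npix <- nrow(Xt)
  per_target <- numeric(ncol(Xt))
  trajectories <- vector("list", ncol(Xt))
  for (m in seq_len(ncol(Xt))) {
    tgt <- Xt[, m]
    z <- sample_latent(R, g_ws$arch$latent_dim)
    best <- rep(Inf, R)
    traj <- numeric(cfg$inversion_steps)
    for (s in seq_len(cfg$inversion_steps)) {
      f <- net_forward(net, z, training = FALSE)
      resid <- f$out - tgt
      loss <- colMeans(resid^2)
      if (any(!is.finite(loss)))
        stop("non-convergent inversion (non-finite loss) at step ", s,
             " for target ", m)
      best <- pmin(best, loss)
      traj[s] <- min(best)
      dOut <- 2 * resid / npix
      dz <- net_backward(net, f$caches, dOut)$dX
      z <- z - cfg$inversion_step_size * dz
    }
    per_target[m] <- min(best)
    trajectories[[m]] <- traj
  }
  list(mean_loss = mean(per_target), per_target = per_target,
       trajectories = trajectories)
}

#' Nearest-neighbour distances between synthetic and real images
#'
#' For each synthetic image, the distance to its nearest real image under
#' the per-pixel root-mean-square metric in [-1, 1] space
#' (`sqrt(mean((x - y)^2))`), which makes values comparable across image
#' sizes.  Returns summary statistics over the synthetic set.
#'
#' @param real,synthetic image sets (lists or pixel matrices) of equal
#'   image size.
#' @return list with `mean`, `min`, `max` and `per_synthetic` distances.
#' @export
min_distance_analysis <- function(real, synthetic) {
  Xr <- as_pixel_matrix(real)
  Xs <- as_pixel_matrix(synthetic)
  if (ncol(Xr) == 0L || ncol(Xs) == 0L) stop("empty image set")
  if (nrow(Xr) != nrow(Xs)) stop("image sizes differ")
  npix <- nrow(Xr)
  d2 <- outer(colSums(Xs^2), colSums(Xr^2), "+") - 2 * crossprod(Xs, Xr)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0) / npix)
  list(mean = mean(dmin), min = min(dmin), max = max(dmin),
       per_synthetic = dmin)
}

#' Composite privacy risk score
#'
#' A documented convex combination on a 0-100 scale (higher = more
#' leakage): `100 * (w_auc * mia_auc + w_acc * mia_accuracy +
#' w_inv * (1 - min(inversion_loss, 1)) + w_dist * (1 - min(min_dist_mean,
#' 1)))` with default weights 0.4 / 0.2 / 0.2 / 0.2.  The weights are
#' explicit configuration, not a claim about any particular published
#' scale.
#'
#' @param mia_auc,mia_accuracy attack discrimination metrics in [0, 1].
#' @param inversion_loss mean inversion reconstruction MSE (>= 0).
#' @param min_dist_mean mean nearest-neighbour RMS distance (>= 0).
#' @param weights numeric vector of 4 non-negative weights summing to 1, in
#'   the order auc, accuracy, inversion, distance.
#' @return composite score in [0, 100].
#' @export
privacy_risk_score <- function(mia_auc, mia_accuracy, inversion_loss,
                               min_dist_mean,
                               weights = c(0.4, 0.2, 0.2, 0.2)) {
  vals <- c(mia_auc, mia_accuracy, inversion_loss, min_dist_mean)
  if (any(is.na(vals)) || any(!is.finite(vals)))
    stop("privacy_risk_score requires all four metrics")
  if (length(weights) != 4L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be 4 non-negative values summing to 1")
  100 * (weights[1] * mia_auc + weights[2] * mia_accuracy +
           weights[3] * (1 - min(inversion_loss, 1)) +
           weights[4] * (1 - min(min_dist_mean, 1)))
}

#' Full privacy audit of a trained generator
#'
#' Runs the four-part audit against the generator and its training data:
#' membership inference (real vs synthetic), empirical epsilon from the
#' attack ROC, model inversion on a subset of targets, nearest-neighbour
#' distance analysis, and the composite risk score.
#'
#' @param g_ws generator weight set.
#' @param train_images the generator's training images (list or matrix).
#' @param cfg an [attack_config()].
#' @param n_inversion_targets number of training images attacked by
#'   inversion (default 8).
#' @return a privacy report list (all fields finite), serializable to JSON.
#' @export
privacy_audit <- function(g_ws, train_images, cfg = attack_config(),
                          n_inversion_targets = 8L) {
  Xr <- as_pixel_matrix(train_images)
  synth <- generate_images(g_ws, ncol(Xr), seed = cfg$seed + 11L)
  mia <- membership_inference(Xr, synth, cfg)
  eps <- estimate_epsilon(mia)
  nt <- min(n_inversion_targets, ncol(Xr))
  inv <- model_inversion(g_ws, Xr[, seq_len(nt), drop = FALSE], cfg)
  md <- min_distance_analysis(Xr, synth)
  report <- list(mia_accuracy = mia$accuracy, mia_auc = mia$auc,
                 inversion_loss = inv$mean_loss, epsilon_hat = eps,
                 min_dist_mean = md$mean, min_dist_min = md$min,
                 min_dist_max = md$max)
  report$composite_score <- privacy_risk_score(report$mia_auc,
                                               report$mia_accuracy,
                                               report$inversion_loss,
                                               report$min_dist_mean)
  report
}
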