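# Adversarial losses with label smoothing.

check_probs <- function(p, what) {
  if (!is.numeric(p) || length(p) == 0L)
    stop(what, " must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(what, " contains values outside [0, 1]")
  p
}

clamp_probs <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Non-saturating generator loss
#'
#' `-mean(log D(G(z)))` over a batch of discriminator outputs on generated
#' images.  Probabilities are clamped to `[eps, 1-eps]` before the log.
#'
#' @param fake_probs discriminator probabilities on generated images, in
#'   (0, 1).
#' @param eps clamp epsilon (default 1e-7).
#' @return scalar loss.
#' @export
generator_loss <- function(fake_probs, eps = 1e-7) {
  p <- clamp_probs(check_probs(as.numeric(fake_probs), "fake_probs"), eps)
  -mean(log(p))
}

#' Label-smoothed discriminator loss
#'
#' Binary cross-entropy of the real batch against a smoothed target
#' (default 0.9 instead of 1.0, which tempers discriminator overconfidence)
#' plus binary cross-entropy of the fake batch against 0:
#' `-mean(s*log p_r + (1-s)*log(1-p_r)) - mean(log(1-p_f))`.
#'
#' @param real_probs discriminator probabilities on real images.
#' @param fake_probs discriminator probabilities on generated images.
#' @param smooth real-class target in (0, 1] (default 0.9).
#' @param eps clamp epsilon.
#' @return scalar loss.
#' @export
discriminator_loss <- function(real_probs, fake_probs, smooth = 0.9,
                               eps = 1e-7) {
  if (smooth <= 0 || smooth > 1) stop("smooth must be in (0, 1]")
  pr <- clamp_probs(check_probs(as.numeric(real_probs), "real_probs"), eps)
  pf <- clamp_probs(check_probs(as.numeric(fake_probs), "fake_probs"), eps)
  -mean(smooth * log(pr) + (1 - smooth) * log(1 - pr)) - mean(log(1 - pf))
}
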