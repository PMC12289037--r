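test_that("generator architecture follows the documented scaling rule", {
  expect_error(build_generator(8, 20), "out_size")

  g128 <- build_generator(8, 128, seed = 1)
  convs <- Filter(function(l) l$type == "conv", g128$layers)
  expect_length(convs, 4L)
  expect_equal(vapply(convs, function(l) l$OC, integer(1)),
               c(128L, 64L, 32L, 1L))
  expect_equal(vapply(convs, function(l) l$out_H, integer(1)),
               c(16L, 32L, 64L, 128L))        # upsampling path 8->...->128

  g32 <- build_generator(8, 32, seed = 1)
  convs32 <- Filter(function(l) l$type == "conv", g32$layers)
  expect_length(convs32, 2L)
  expect_equal(vapply(convs32, function(l) l$out_H, integer(1)),
               c(16L, 32L))

  # tanh output: strictly inside (-1, 1) for any z, at every supported size
  for (S in c(16L, 32L)) {
    g <- net_weights(build_generator(8, S, seed = 2))
    out <- generate_images(g, 3, seed = 1)
    expect_equal(dim(out), c(S * S, 3L))
    expect_true(all(out > -1 & out < 1))
  }
})

test_that("discriminator architecture mirrors the generator and outputs probabilities", {
  expect_error(build_discriminator(12), "in_size")

  d128 <- build_discriminator(128, seed = 1)
  convs <- Filter(function(l) l$type == "conv", d128$layers)
  expect_equal(vapply(convs, function(l) l$OC, integer(1)),
               c(32L, 64L, 128L, 256L))
  expect_equal(vapply(convs, function(l) l$out_H, integer(1)),
               c(64L, 32L, 16L, 8L))          # downsampling 128->...->8
  dense <- Filter(function(l) l$type == "dense", d128$layers)[[1]]
  expect_equal(dense$n_in, 16384L)            # flatten 8*8*256

  d32 <- build_discriminator(32, seed = 1)
  expect_length(Filter(function(l) l$type == "conv", d32$layers), 2L)
  dense32 <- Filter(function(l) l$type == "dense", d32$layers)[[1]]
  expect_equal(dense32$n_in, 8L * 8L * 64L)

  d <- net_weights(d32)
  p <- discriminate_images(d, matrix(rnorm(32 * 32 * 5), 32 * 32, 5))
  expect_true(all(p > 0 & p < 1))
})

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("silogan")
  set.seed(10)
  for (net in list(build_generator(6, 16, seed = 1),
                   build_generator(6, 32, seed = 2))) {
    X <- matrix(rnorm(6 * 3), 6, 3)
    f <- ns$net_forward(net, X, training = TRUE)
    bw <- ns$net_backward(net, f$caches, cos(f$out))
    eps <- 1e-6
    for (probe in 1:4) {
      li <- sample(seq_along(net$layers), 1)
      nms <- setdiff(names(net$layers[[li]]$params),
                     c("run_mean", "run_var"))
      if (length(nms) == 0) next
      nm <- sample(nms, 1)
      i <- sample(length(net$layers[[li]]$params[[nm]]), 1)
      np <- net; np$layers[[li]]$params[[nm]][i] <-
        np$layers[[li]]$params[[nm]][i] + eps
      nq <- net; nq$layers[[li]]$params[[nm]][i] <-
        nq$layers[[li]]$params[[nm]][i] - eps
      num <- (sum(sin(ns$net_forward(np, X, TRUE)$out)) -
                sum(sin(ns$net_forward(nq, X, TRUE)$out))) / (2 * eps)
      expect_equal(bw$grads[[li]][[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("adversarial losses match hand arithmetic and the scalar BCE oracle", {
  expect_equal(generator_loss(rep(1, 4)), 0, tolerance = 1e-6)
  expect_equal(generator_loss(exp(-1)), 1)
  expect_equal(generator_loss(c(0.5, 0.25)), 1.5 * log(2))
  expect_error(generator_loss(c(0.5, 1.2)), "outside")

  # hand-computed label-smoothing example
  expect_equal(discriminator_loss(0.9, 0.1, smooth = 0.9),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) - log(0.9))
  # perfect-discriminator limit without smoothing
  expect_lt(discriminator_loss(1 - 1e-9, 1e-9, smooth = 1), 1e-6)

  set.seed(8)
  for (i in 1:100) {
    pr <- runif(sample(1:8, 1), 0.01, 0.99)
    pf <- runif(sample(1:8, 1), 0.01, 0.99)
    expect_equal(discriminator_loss(pr, pf, smooth = 0.9),
                 bce_oracle(pr, 0.9) + bce_oracle(pf, 0),
                 tolerance = 1e-9)
    expect_equal(generator_loss(pf), bce_oracle(pf, 1), tolerance = 1e-9)
  }

  # BCE against target s is minimized over p exactly at p = s
  grid <- seq(0.01, 0.99, by = 0.005)
  losses <- vapply(grid, function(p)
    discriminator_loss(p, 0.5, smooth = 0.9), numeric(1))
  expect_equal(grid[which.min(losses)], 0.9, tolerance = 0.005)

  # with smooth = 1 the discriminator loss is exactly -V(D, G) of the
  # minimax objective at the sampled probabilities
  pr <- runif(16, 0.05, 0.95); pf <- runif(16, 0.05, 0.95)
  V <- mean(log(pr)) + mean(log(1 - pf))
  expect_equal(discriminator_loss(pr, pf, smooth = 1), -V, tolerance = 1e-12)
})

test_that("local training respects identity, bookkeeping and determinism", {
  imgs <- phantom_batch(64, 16, seed = 30)
  G <- net_weights(build_generator(64, 16, seed = 1))
  D <- net_weights(build_discriminator(16, seed = 2))

  # 0 epochs: identity
  out0 <- local_train(G, D, imgs, train_config(latent_dim = 64,
                                               local_epochs = 0))
  expect_identical(out0$G, G)
  expect_identical(out0$D, D)
  expect_equal(nrow(out0$trace), 0L)

  # 1 epoch on 64 images at batch 64: exactly ceiling(64/64) = 1 batch
  cfg <- train_config(latent_dim = 64, local_epochs = 1, seed = 5)
  fit <- local_train(G, D, imgs, cfg)
  expect_equal(nrow(fit$trace), 1L)
  expect_true(all(is.finite(fit$trace$d_loss)))
  expect_true(all(is.finite(fit$trace$g_loss)))

  # determinism under a fixed seed
  fit2 <- local_train(G, D, imgs, cfg)
  expect_identical(fit$G, fit2$G)
  expect_identical(fit$D, fit2$D)
  expect_identical(fit$trace, fit2$trace)

  expect_error(local_train(G, D, matrix(numeric(0), 256, 0), cfg), "empty")
})

test_that("training on a single image improves the generator's fit to it", {
  imgs <- phantom_batch(1, 16, seed = 31)
  X1 <- pixmat(imgs)
  G <- net_weights(build_generator(64, 16, seed = 3))
  D <- net_weights(build_discriminator(16, seed = 4))
  mse <- function(g) {
    out <- generate_images(g, 16, seed = 99, training = TRUE)
    mean((rowMeans(out) - X1)^2)
  }
  fit <- local_train(G, D, X1, train_config(batch_size = 1, latent_dim = 64,
                                            local_epochs = 200, seed = 6))
  expect_lt(mse(fit$G), 0.5 * mse(G))
  expect_true(all(is.finite(fit$trace$g_loss)))
})
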