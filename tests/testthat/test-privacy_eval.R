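test_that("membership inference separates noise from phantoms and is seeded", {
  P <- pixmat(phantom_batch(80, 16, seed = 50))
  N <- noise_batch(80, 16, seed = 51)
  cfg <- attack_config(epochs = 15, seed = 3)
  alt <- membership_inference(P, N, cfg)
  expect_gt(alt$auc, 0.95)
  expect_gt(alt$accuracy, 0.9)

  again <- membership_inference(P, N, cfg)
  expect_identical(alt[c("accuracy", "auc")], again[c("accuracy", "auc")])

  expect_error(membership_inference(P[, 1:10], N, cfg), "20 images")
  expect_error(membership_inference(P, N[, 1:19], cfg), "20 images")
})

test_that("the rank AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- c(rnorm(40, 0.2), rnorm(40, 0.8))
  labels <- rep(c(0, 1), each = 40)
  ours <- silogan:::auc_score(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("epsilon estimation follows the documented one-sided ROC rule", {
  # perfectly random attack: TPR = FPR along the diagonal
  diag_roc <- data.frame(threshold = seq(0.9, 0.1, by = -0.2),
                         tpr = seq(0.2, 1, by = 0.2),
                         fpr = seq(0.2, 1, by = 0.2))
  expect_equal(estimate_epsilon(diag_roc, n_pos = 50, n_neg = 50), 0)

  # single-threshold ROC at (FPR 0.45, TPR 0.9) gives ln 2
  one <- data.frame(threshold = 0.5, tpr = 0.9, fpr = 0.45)
  expect_warning(e <- estimate_epsilon(one), "degenerate")
  expect_equal(e, log(2))

  # nondecreasing in attack strength along a 1-parameter score family
  eps_of_shift <- vapply(seq(0, 2, by = 0.5), function(delta) {
    set.seed(9)
    s0 <- rnorm(200)
    s1 <- rnorm(200) + delta
    roc <- silogan:::roc_points(c(s0, s1), rep(c(0, 1), each = 200))
    estimate_epsilon(roc, n_pos = 200, n_neg = 200)
  }, numeric(1))
  expect_true(all(diff(eps_of_shift) >= -1e-9))
  expect_lt(eps_of_shift[1], 1.5)                    # chance level is small
  expect_gt(eps_of_shift[5], eps_of_shift[1])
})

test_that("model inversion recovers what a constant generator can emit", {
  x0 <- rep(0.4, 256)
  g <- constant_generator(x0, latent_dim = 8)
  out <- generate_images(g, 1, seed = 1)
  expect_equal(as.vector(out), x0, tolerance = 1e-12)

  cfg <- attack_config(inversion_steps = 40, inversion_restarts = 2, seed = 2)
  hit <- model_inversion(g, matrix(x0, ncol = 1), cfg)
  expect_lt(hit$mean_loss, 1e-3)

  # opposite target: the residual is constant in z, loss = mean(4 x0^2)
  miss <- model_inversion(g, matrix(-x0, ncol = 1), cfg)
  expect_equal(miss$mean_loss, mean(4 * x0^2), tolerance = 0.05 * mean(4 * x0^2))

  # the kept best-so-far trajectory never increases
  g2 <- net_weights(build_generator(8, 16, seed = 5))
  tr <- model_inversion(g2, matrix(x0, ncol = 1),
                        attack_config(inversion_steps = 30,
                                      inversion_restarts = 3, seed = 4))
  expect_true(all(diff(tr$trajectories[[1]]) <= 1e-12))
  # and real optimization makes progress on a reachable-ish target
  expect_lt(tr$trajectories[[1]][30], tr$trajectories[[1]][1])
})

test_that("nearest-neighbour distances match the brute-force oracle", {
  R <- pixmat(phantom_batch(20, 16, seed = 60))
  set.seed(61)
  S <- R[, sample(20, 20, replace = TRUE)] + matrix(rnorm(256 * 20, 0, 0.1),
                                                    256, 20)
  res <- min_distance_analysis(R, S)
  # O(n^2) double-loop reference scan
  ref <- vapply(seq_len(20), function(i) {
    best <- Inf
    for (j in seq_len(20)) {
      d <- sqrt(mean((S[, i] - R[, j])^2))
      if (d < best) best <- d
    }
    best
  }, numeric(1))
  expect_equal(res$per_synthetic, ref, tolerance = 1e-12)
  expect_equal(res$mean, mean(ref))

  # synthetic subset of real: zero distances
  sub <- min_distance_analysis(R, R[, 3:7])
  expect_lt(sub$mean, 1e-6)

  # analytic extreme: all -1 vs all +1 has per-pixel RMS distance 2
  expect_equal(min_distance_analysis(matrix(-1, 16, 1),
                                     matrix(1, 16, 1))$mean, 2)
  expect_error(min_distance_analysis(R, matrix(1, 64, 1)), "sizes differ")
})

test_that("the composite risk score obeys its boundary and monotonicity", {
  expect_equal(privacy_risk_score(1, 1, 0, 0), 100)
  # best case under the documented weights
  expect_equal(privacy_risk_score(0.5, 0.5, 1, 1),
               100 * (0.4 * 0.5 + 0.2 * 0.5))
  expect_gt(privacy_risk_score(0.9, 0.7, 0.2, 0.3),
            privacy_risk_score(0.8, 0.7, 0.2, 0.3))
  expect_error(privacy_risk_score(NA, 1, 0, 0), "requires")
  expect_error(privacy_risk_score(1, 1, 0, 0, weights = c(1, 1, 1, 1)),
               "summing")
})

test_that("a full privacy audit produces a finite, serializable report", {
  imgs <- phantom_batch(40, 16, seed = 70)
  g <- net_weights(build_generator(32, 16, seed = 1))
  cfg <- attack_config(epochs = 8, inversion_steps = 15,
                       inversion_restarts = 2, seed = 5)
  rep_ <- privacy_audit(g, imgs, cfg, n_inversion_targets = 2)
  expect_true(all(vapply(rep_, function(x) is.finite(x), logical(1))))
  expect_gte(rep_$composite_score, 0)
  expect_lte(rep_$composite_score, 100)
  json <- jsonlite::toJSON(rep_, auto_unbox = TRUE)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$mia_auc, rep_$mia_auc)
})
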