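# Cross-silo federated orchestration: pretraining, per-round client
# training, FedAvg aggregation of generator and discriminator, and
# round-level realism evaluation.  "Server" and "clients" are components of
# one process; all K clients participate in every round.

#' Federation configuration
#'
#' @param K number of clients.
#' @param rounds number of global rounds T (default 2).
#' @param local_epochs local epochs E per client per round (default 5).
#' @param aggregation `"weighted"` (coefficients `|Dk| / sum |Dj|`, the
#'   default) or `"uniform"` (`1/K`).
#' @param image_size image side for both networks.
#' @param train a [train_config()]; its `local_epochs` and `seed` are
#'   overridden per client.
#' @param baseline_epochs epochs for the centralized baseline GAN whose
#'   discriminator becomes the frozen realism scorer (default 5).
#' @param seed master seed; every stage derives its stream from it.
#' @return list of class `silogan_federation_config`.
#' @export
federation_config <- function(K = 3L, rounds = 2L, local_epochs = 5L,
                              aggregation = c("weighted", "uniform"),
                              image_size = 128L, train = train_config(),
                              baseline_epochs = 5L, seed = 1L) {
  aggregation <- match.arg(aggregation)
  stopifnot(K >= 1L, rounds >= 1L, local_epochs >= 0L)
  structure(list(K = as.integer(K), rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 aggregation = aggregation,
                 image_size = as.integer(image_size), train = train,
                 baseline_epochs = as.integer(baseline_epochs),
                 seed = as.integer(seed)),
            class = "silogan_federation_config")
}

#' Federated averaging of weight sets
#'
#' Elementwise convex combination of the tensors of `weight_sets`, with
#' coefficients `sizes / sum(sizes)` (weighted mode) or `1/K` (uniform).
#' Layer order is preserved; batch-norm running statistics are averaged with
#' the same coefficients as weights.
#'
#' @param weight_sets list of `silogan_weights` of identical architecture.
#' @param sizes client dataset sizes (required for weighted mode).
#' @param mode `"weighted"` or `"uniform"`.
#' @return aggregated `silogan_weights`.
#' @export
fedavg <- function(weight_sets, sizes = NULL,
                   mode = c("weighted", "uniform")) {
  mode <- match.arg(mode)
  K <- length(weight_sets)
  if (K < 1L) stop("need at least one weight set")
  ref <- weight_sets[[1L]]
  for (k in seq_len(K)) {
    ws <- weight_sets[[k]]
    if (!identical(names(ws$tensors), names(ref$tensors))) {
      bad <- names(ws$tensors)[which(names(ws$tensors) !=
                                       names(ref$tensors))[1L]]
      stop("architecture mismatch in weight set ", k, " at layer ",
           bad %||% "(missing tensor)")
    }
    for (nm in names(ref$tensors)) {
      if (length(ws$tensors[[nm]]) != length(ref$tensors[[nm]]))
        stop("architecture mismatch in weight set ", k, " at layer ", nm)
    }
  }
  w <- if (mode == "weighted") {
    if (is.null(sizes) || length(sizes) != K)
      stop("weighted mode needs one size per weight set")
    if (any(sizes <= 0)) stop("sizes must be positive")
    tot <- sum(sizes)
    if (tot <= 0) stop("zero total size")
    sizes / tot
  } else {
    rep(1 / K, K)
  }
  out <- ref
  for (nm in names(ref$tensors)) {
    acc <- ref$tensors[[nm]] * w[1L]
    if (K > 1L) for (k in 2:K) acc <- acc + weight_sets[[k]]$tensors[[nm]] * w[k]
    out$tensors[[nm]] <- acc
  }
  out
}

#' Centralized pretraining of the global networks
#'
#' Trains freshly initialized generator and discriminator on the full
#' pretraining dataset (the transfer domain) for `epochs` epochs; with
#' `epochs = 0` the freshly initialized weights are returned.
#'
#' @param records list of processed images or a pixel matrix.
#' @param epochs pretraining epochs (default 1).
#' @param cfg a [federation_config()].
#' @return list with `G`, `D` weight sets (tagged `pretrained = TRUE` when
#'   `epochs > 0`) and the training `trace`.
#' @export
pretrain_global <- function(records, epochs = 1L, cfg = federation_config()) {
  G <- net_weights(build_generator(cfg$train$latent_dim, cfg$image_size,
                                   seed = cfg$seed + 101L))
  D <- net_weights(build_discriminator(cfg$image_size,
                                       seed = cfg$seed + 102L))
  if (epochs == 0L)
    return(list(G = G, D = D, trace = NULL, pretrained = FALSE))
  tc <- cfg$train
  tc$local_epochs <- as.integer(epochs)
  tc$seed <- cfg$seed + 103L
  fit <- local_train(G, D, records, tc)
  list(G = fit$G, D = fit$D, trace = fit$trace, pretrained = TRUE)
}

#' Run one federated round
#'
#' Distributes the global weights, trains each client locally (client k is
#' seeded with `round_seed XOR k`), aggregates both networks with
#' [fedavg()], and scores the new global generator under the frozen
#' centralized discriminator when one is supplied.
#'
#' @param state list with `G`, `D` weight sets and round index `t`.
#' @param shard_records list of per-client record lists (or pixel matrices).
#' @param cfg a [federation_config()].
#' @param scorer optional frozen centralized discriminator weight set used
#'   for the realism score.
#' @return list with the advanced `state` and a `round_log` (per-client loss
#'   traces, shard sizes, realism of the aggregated generator).
#' @export
run_round <- function(state, shard_records, cfg, scorer = NULL) {
  K <- length(shard_records)
  sizes <- vapply(shard_records, function(s)
    if (is.matrix(s)) ncol(s) else length(s), integer(1))
  round_seed <- cfg$seed + 10007L * state$t
  Gs <- vector("list", K)
  Ds <- vector("list", K)
  client_logs <- vector("list", K)
  for (k in seq_len(K)) {
    tc <- cfg$train
    tc$local_epochs <- cfg$local_epochs
    tc$seed <- bitwXor(round_seed, k)
    fit <- tryCatch(local_train(state$G, state$D, shard_records[[k]], tc),
                    error = function(e)
                      stop("client ", k, " failed in round ", state$t + 1L,
                           ": ", conditionMessage(e), call. = FALSE))
    Gs[[k]] <- fit$G
    Ds[[k]] <- fit$D
    client_logs[[k]] <- list(client = k, size = sizes[k], trace = fit$trace)
  }
  state$G <- fedavg(Gs, sizes, mode = cfg$aggregation)
  state$D <- fedavg(Ds, sizes, mode = cfg$aggregation)
  state$t <- state$t + 1L
  realism <- if (is.null(scorer)) NA_real_ else
    realism_score(state$G, scorer, n = 256L, seed = round_seed + 1L)
  list(state = state,
       round_log = list(round = state$t, shard_sizes = sizes,
                        realism = realism, clients = client_logs))
}

#' Run a full federated experiment over a grid of client counts
#'
#' For the complete dataset: trains the centralized (unfederated) baseline
#' GAN whose discriminator becomes the frozen realism scorer; optionally
#' pretrains the global initialization on a second-domain dataset (1 epoch);
#' then, for each K in `K_grid`, partitions the data non-IID and runs
#' `cfg$rounds` federated rounds.  The same master seed yields the same
#' shards with and without pretraining.
#'
#' @param K_grid integer vector of client counts (e.g. `c(3, 5, 7, 10)`).
#' @param images list of processed, labeled images (the federated domain).
#' @param pretrain_images optional list of processed images from the
#'   transfer domain; `NULL` disables pretraining.
#' @param cfg a [federation_config()].
#' @param out_dir optional directory for history JSON, checkpoints and
#'   sample grids.
#' @return list with `baseline` (final losses and scorer), `pretrain`
#'   (or `NULL`), and `runs`: per K, the partition manifest, the realism of
#'   the initial global generator (`realism0`), round logs and final
#'   weights.
#' @export
run_experiment <- function(K_grid, images, pretrain_images = NULL,
                           cfg = federation_config(), out_dir = NULL) {
  labels <- vapply(images, function(im) im$label %||% 0L, integer(1))
  X <- images_to_batch(images)

  ## centralized baseline; its discriminator is the frozen realism scorer
  bG <- net_weights(build_generator(cfg$train$latent_dim, cfg$image_size,
                                    seed = cfg$seed + 201L))
  bD <- net_weights(build_discriminator(cfg$image_size,
                                        seed = cfg$seed + 202L))
  tc <- cfg$train
  tc$local_epochs <- cfg$baseline_epochs
  tc$seed <- cfg$seed + 203L
  baseline <- local_train(bG, bD, X, tc)
  scorer <- baseline$D

  pre <- NULL
  if (!is.null(pretrain_images))
    pre <- pretrain_global(pretrain_images, epochs = 1L, cfg = cfg)

  runs <- list()
  for (K in K_grid) {
    part <- partition_noniid(labels,
                             partition_config(K, seed = cfg$seed + K))
    shard_records <- lapply(part$shards, function(idx)
      X[, idx, drop = FALSE])
    state <- if (!is.null(pre)) list(G = pre$G, D = pre$D, t = 0L) else
      list(G = net_weights(build_generator(cfg$train$latent_dim,
                                           cfg$image_size,
                                           seed = cfg$seed + 301L)),
           D = net_weights(build_discriminator(cfg$image_size,
                                               seed = cfg$seed + 302L)),
           t = 0L)
    realism0 <- realism_score(state$G, scorer, n = 256L,
                              seed = cfg$seed + 1L)
    logs <- vector("list", cfg$rounds)
    for (t in seq_len(cfg$rounds)) {
      step <- run_round(state, shard_records, cfg, scorer = scorer)
      state <- step$state
      logs[[t]] <- step$round_log
    }
    runs[[as.character(K)]] <- list(K = K, manifest = part$manifest,
                                    realism0 = realism0,
                                    rounds = logs, G = state$G, D = state$D)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      save_weights(state$G, file.path(out_dir, sprintf("G_K%d.sgw", K)))
      save_weights(state$D, file.path(out_dir, sprintf("D_K%d.sgw", K)))
      save_sample_grid(state$G, file.path(out_dir,
                                          sprintf("samples_K%d.png", K)),
                       seed = cfg$seed + K)
    }
  }
  res <- list(baseline = list(trace = baseline$trace, D = scorer,
                              G = baseline$G),
              pretrain = pre, runs = runs)
  if (!is.null(out_dir)) {
    hist <- lapply(runs, function(r) list(
      K = r$K, shard_sizes = r$manifest$shard_sizes,
      realism = vapply(r$rounds, function(l) l$realism, numeric(1))))
    jsonlite::write_json(hist, file.path(out_dir, "history.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Save a grid of generated samples as a PNG
#'
#' @param g_ws generator weight set.
#' @param path output PNG path.
#' @param n number of samples (arranged in a near-square grid).
#' @param seed seed for the latent draws.
#' @return invisibly, `path`.
#' @export
save_sample_grid <- function(g_ws, path, n = 16L, seed = 1L) {
  S <- g_ws$arch$image_size
  X <- generate_images(g_ws, n, seed = seed)
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  grid <- matrix(0, nrows * S, ncols * S)
  for (k in seq_len(n)) {
    r0 <- ((k - 1L) %/% ncols) * S
    c0 <- ((k - 1L) %% ncols) * S
    grid[r0 + seq_len(S), c0 + seq_len(S)] <-
      (batch_column_to_matrix(X[, k], S) + 1) / 2
  }
  png::writePNG(pmin(pmax(grid, 0), 1), path)
  invisible(path)
}
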