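# Label-skew non-IID partitioning of a labeled dataset across clients.
#
# Each severity label is assigned to two randomly chosen clients; every
# sample of that label goes to one of the two uniformly at random.  A
# rebalancing pass then transfers random samples from the currently largest
# shard to the currently smallest until every shard holds at least
# T = ceiling(min_frac * n) records.

#' Partition configuration
#'
#' @param K number of clients (any >= 1; the framework's experiment grid
#'   uses 3, 5, 7, 10).
#' @param min_frac minimum shard size as a fraction of the dataset
#'   (default 0.01); the threshold is `ceiling(min_frac * n)`.
#' @param seed integer seed.
#' @return list of class `silogan_partition_config`.
#' @export
partition_config <- function(K, min_frac = 0.01, seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  if (min_frac < 0) stop("min_frac must be >= 0")
  structure(list(K = as.integer(K), min_frac = min_frac,
                 seed = as.integer(seed)),
            class = "silogan_partition_config")
}

#' Assign samples to clients by label
#'
#' For each label present in `labels`, two distinct clients are drawn
#' uniformly (when `K >= 2`); each sample of that label is then assigned to
#' one of the two with probability 1/2.  With `K = 1` everything goes to
#' client 1 (documented degenerate case).  Labels are visited in sorted
#' order, so the assignment is fully determined by the RNG state.
#'
#' @param labels integer vector of per-record labels in 0..4.
#' @param K number of clients.
#' @return list of `K` integer index vectors (shards), pairwise disjoint
#'   with union `seq_along(labels)`; pre-rebalance, each label is held by at
#'   most two clients.
#' @export
assign_by_label <- function(labels, K) {
  n <- length(labels)
  if (n == 0L) stop("empty dataset cannot be partitioned")
  if (any(!labels %in% 0:4)) stop("labels must be integers in 0..4")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  shards <- rep(list(integer(0)), K)
  if (K == 1L) {
    shards[[1L]] <- seq_len(n)
    return(shards)
  }
  for (l in sort(unique(labels))) {
    idx <- which(labels == l)
    holders <- sample.int(K, 2L)
    pick <- sample(c(1L, 2L), length(idx), replace = TRUE)
    shards[[holders[1L]]] <- c(shards[[holders[1L]]], idx[pick == 1L])
    shards[[holders[2L]]] <- c(shards[[holders[2L]]], idx[pick == 2L])
  }
  shards
}

#' Rebalance shards to a minimum size
#'
#' While any shard is below the threshold `T`, transfers a batch of
#' uniformly chosen samples from the currently largest shard to the
#' currently smallest (ties broken by lowest client id, re-evaluated every
#' iteration).  The batch size is `min(T - |smallest|, |largest| - T)`, so
#' the donor never drops below `T` and the loop terminates.  Total size is
#' conserved.
#'
#' @param shards list of integer index vectors.
#' @param threshold minimum shard size `T`; must satisfy
#'   `length(shards) * T <= sum(sizes)`.
#' @return rebalanced list of shards.
#' @export
rebalance <- function(shards, threshold) {
  T <- as.integer(threshold)
  n <- sum(lengths(shards))
  if (length(shards) * T > n)
    stop("infeasible threshold: K * T = ", length(shards) * T, " > n = ", n)
  repeat {
    sizes <- lengths(shards)
    if (all(sizes >= T)) break
    kmax <- which.max(sizes)
    kmin <- which.min(sizes)
    need <- min(T - sizes[kmin], sizes[kmax] - T)
    move <- shards[[kmax]][sample.int(sizes[kmax], need)]
    shards[[kmax]] <- setdiff(shards[[kmax]], move)
    shards[[kmin]] <- c(shards[[kmin]], move)
  }
  shards
}

#' Non-IID partition of a labeled dataset
#'
#' Composition of [assign_by_label()] and [rebalance()] with threshold
#' `ceiling(min_frac * n)`, reproducible from `cfg$seed`.  Optionally writes
#' one record file per client plus a JSON manifest of shard sizes and
#' per-label counts.
#'
#' @param labels integer vector of per-record labels in 0..4.
#' @param cfg a [partition_config()].
#' @param images optional list of processed images matching `labels`,
#'   written as per-client record files when `out_dir` is given.
#' @param out_dir optional output directory.
#' @return list with `shards` (list of index vectors), `threshold`, and
#'   `manifest` (shard sizes and per-label counts).
#' @export
partition_noniid <- function(labels, cfg, images = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "silogan_partition_config"))
  n <- length(labels)
  T <- as.integer(ceiling(cfg$min_frac * n))
  if (cfg$K * T > n)
    stop("infeasible config: K * ceiling(min_frac * n) exceeds n")
  set.seed(cfg$seed)
  shards <- assign_by_label(labels, cfg$K)
  shards <- rebalance(shards, T)
  manifest <- list(
    n = n, K = cfg$K, threshold = T, seed = cfg$seed,
    shard_sizes = unname(lengths(shards)),
    label_counts = lapply(shards, function(s)
      as.list(table(factor(labels[s], levels = 0:4)))))
  if (!is.null(out_dir) && !is.null(images)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(cfg$K)) {
      write_records(file.path(out_dir, sprintf("client_%02d.sgr", k)),
                    images[shards[[k]]])
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(shards = shards, threshold = T, manifest = manifest)
}
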