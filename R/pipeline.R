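# Deterministic preprocessing of raw images into training-ready tensors.
#
# The pipeline (in order): tensorize -> resize to target_size -> grayscale ->
# CLAHE (8-bit) -> normalize to [0,1] -> gamma correction -> quantize to
# n_levels gray shades -> rescale to [-1,1].

#' Pipeline configuration
#'
#' @param target_size output image side in pixels; a power of two >= 16
#'   (default 128).
#' @param clahe_clip_limit CLAHE clip limit as a multiple of the uniform
#'   per-bin count (default 2.0).
#' @param clahe_tile_grid integer pair, CLAHE tile grid (default 8 x 8).
#' @param gamma gamma-correction exponent applied to [0,1] intensities
#'   (default 1.2; values > 1 darken midtones).
#' @param n_levels number of gray levels after quantization (default 16).
#' @return list of class `silogan_pipeline_config`.
#' @export
pipeline_config <- function(target_size = 128L, clahe_clip_limit = 2.0,
                            clahe_tile_grid = c(8L, 8L), gamma = 1.2,
                            n_levels = 16L) {
  target_size <- as.integer(target_size)
  if (target_size < 16L || bitwAnd(target_size, target_size - 1L) != 0L)
    stop("target_size must be a power of two >= 16")
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (n_levels < 2L) stop("n_levels must be >= 2")
  structure(list(target_size = target_size,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 gamma = gamma, n_levels = as.integer(n_levels)),
            class = "silogan_pipeline_config")
}

#' Construct a raw image record
#'
#' @param pixels `H x W` matrix or `H x W x 3` array; either 8-bit values in
#'   [0, 255] or unit-scaled values in [0, 1].
#' @param label optional integer severity grade 0-4.
#' @param source_id identifier string.
#' @return list of class `silogan_raw`.
#' @export
raw_image <- function(pixels, label = NULL, source_id = "") {
  d <- dim(pixels)
  if (is.null(d) || length(d) < 2L || d[1L] < 1L || d[2L] < 1L)
    stop("pixels must be a matrix or 3-d array")
  if (length(d) == 3L && !d[3L] %in% c(1L, 3L))
    stop("invalid channel count: ", d[3L])
  if (!is.null(label)) {
    label <- as.integer(label)
    if (!label %in% 0:4) stop("label must be an integer in 0..4")
  }
  structure(list(pixels = pixels, label = label,
                 source_id = as.character(source_id)),
            class = "silogan_raw")
}

#' Convert an image to grayscale
#'
#' Three-channel input is reduced with fixed ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114); single-channel input is returned unchanged.
#'
#' @param img a [raw_image()] or a matrix / `H x W x {1,3}` array.
#' @return same type as the input, single-channel.
#' @export
to_grayscale <- function(img) {
  if (inherits(img, "silogan_raw")) {
    img$pixels <- to_grayscale(img$pixels)
    return(img)
  }
  d <- dim(img)
  if (length(d) == 2L) return(img)
  if (length(d) == 3L && d[3L] == 1L) return(matrix(img, d[1L], d[2L]))
  if (length(d) == 3L && d[3L] == 3L)
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  stop("invalid channel count: expected 1 or 3 channels")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization of an 8-bit single-channel image with
#' clipped amplification.  Per tile, a 256-bin histogram is clipped at
#' `clip_limit * N/256` (N = tile pixel count), the clipped excess is
#' redistributed uniformly across all bins, and the tile mapping is
#' `m(v) = round(cdf(v)/N * 255)`.  Pixels are remapped by bilinear
#' interpolation between the mappings of the four neighbouring tile centers
#' (clamped at the borders), so a pixel at a tile center receives exactly its
#' own tile's mapping.  Unit-scaled input in [0, 1] is processed at 8 bits
#' and returned on the unit scale.
#'
#' @param img single-channel matrix, 8-bit ([0, 255]) or unit-scaled.
#' @param clip_limit positive clip limit (default 2.0).
#' @param tile_grid integer pair `(gx, gy)`: tiles along columns and rows.
#' @return matrix of the same shape and scale.
#' @export
apply_clahe <- function(img, clip_limit = 2.0, tile_grid = c(8L, 8L)) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  if (!is.matrix(img)) stop("apply_clahe expects a single-channel matrix")
  unit <- max(img) <= 1 && min(img) >= 0
  v <- if (unit) round(img * 255) else pmin(pmax(round(img), 0), 255)
  storage.mode(v) <- "integer"
  H <- nrow(v); W <- ncol(v)
  gy <- min(as.integer(tile_grid[2L]), H)
  gx <- min(as.integer(tile_grid[1L]), W)
  row_tile <- ceiling(seq_len(H) / (H / gy))
  col_tile <- ceiling(seq_len(W) / (W / gx))
  maps <- vector("list", gy * gx)   # maps[[a + gy*(b-1)]]: tile row a, col b
  cy <- numeric(gy); cx <- numeric(gx)
  for (a in seq_len(gy)) cy[a] <- mean(which(row_tile == a))
  for (b in seq_len(gx)) cx[b] <- mean(which(col_tile == b))
  for (a in seq_len(gy)) {
    ri <- which(row_tile == a)
    for (b in seq_len(gx)) {
      ci <- which(col_tile == b)
      tile <- v[ri, ci]
      N <- length(tile)
      h <- tabulate(tile + 1L, nbins = 256L)
      thr <- clip_limit * N / 256
      excess <- sum(pmax(h - thr, 0))
      h <- pmin(h, thr) + excess / 256
      maps[[a + gy * (b - 1L)]] <- round(cumsum(h) / N * 255)
    }
  }
  out <- matrix(0, H, W)
  # regions between adjacent tile centers (Zuiderveld-style block loop)
  ybreaks <- c(0, cy, H + 1)
  xbreaks <- c(0, cx, W + 1)
  for (ry in 0:gy) {
    rows <- which(seq_len(H) > ybreaks[ry + 1L] &
                    seq_len(H) <= ybreaks[ry + 2L])
    if (ry == 0 && any(seq_len(H) <= cy[1L]))
      rows <- which(seq_len(H) <= cy[1L])
    if (length(rows) == 0L) next
    a1 <- max(ry, 1L); a2 <- min(ry + 1L, gy)
    wy <- if (a1 == a2) rep(0, length(rows))
          else (rows - cy[a1]) / (cy[a2] - cy[a1])
    for (rx in 0:gx) {
      cols <- which(seq_len(W) > xbreaks[rx + 1L] &
                      seq_len(W) <= xbreaks[rx + 2L])
      if (rx == 0 && any(seq_len(W) <= cx[1L]))
        cols <- which(seq_len(W) <= cx[1L])
      if (length(cols) == 0L) next
      b1 <- max(rx, 1L); b2 <- min(rx + 1L, gx)
      wx <- if (b1 == b2) rep(0, length(cols))
            else (cols - cx[b1]) / (cx[b2] - cx[b1])
      sub <- v[rows, cols, drop = FALSE] + 1L
      g11 <- matrix(maps[[a1 + gy * (b1 - 1L)]][sub], length(rows))
      g12 <- matrix(maps[[a1 + gy * (b2 - 1L)]][sub], length(rows))
      g21 <- matrix(maps[[a2 + gy * (b1 - 1L)]][sub], length(rows))
      g22 <- matrix(maps[[a2 + gy * (b2 - 1L)]][sub], length(rows))
      out[rows, cols] <- outer(1 - wy, 1 - wx) * g11 +
        outer(1 - wy, wx) * g12 + outer(wy, 1 - wx) * g21 +
        outer(wy, wx) * g22
    }
  }
  if (unit) out / 255 else out
}

#' Quantize a unit-scaled image to a fixed number of gray levels
#'
#' Maps every value to the nearest of `k/(n_levels-1)`, k = 0..n_levels-1,
#' with ties broken by rounding half up: `floor(x*(n-1) + 0.5)/(n-1)`.
#' So 0.5 at 16 levels maps to 8/15, not 7/15.
#'
#' @param img01 numeric array with values in [0, 1].
#' @param n_levels number of levels (default 16).
#' @return array of the same shape on the grid `{k/(n_levels-1)}`.
#' @export
quantize_levels <- function(img01, n_levels = 16L) {
  if (n_levels < 2L) stop("n_levels must be >= 2")
  if (any(!is.finite(img01)) || any(img01 < 0) || any(img01 > 1))
    stop("quantize_levels expects values in [0, 1]")
  m <- n_levels - 1L
  floor(img01 * m + 0.5) / m
}

#' Preprocess one raw image
#'
#' Applies the full pipeline: resize (bilinear, anti-aliased) to
#' `cfg$target_size`, grayscale, CLAHE at 8 bits, normalization to [0,1],
#' gamma correction `x^gamma`, quantization to `cfg$n_levels` shades, and
#' rescaling `x -> 2x - 1`.  The label is carried through unchanged.
#' Degenerate inputs (side below 8 pixels, or constant intensity) are
#' skipped: the function logs a message and returns `NULL`.
#'
#' @param raw a [raw_image()].
#' @param cfg a [pipeline_config()].
#' @return a processed image (list with `pixels` of dim `(S, S, 1)` in
#'   [-1, 1] with at most `n_levels` distinct values, `label`, `source_id`),
#'   or `NULL` for a skipped degenerate input.
#' @export
preprocess <- function(raw, cfg = pipeline_config()) {
  stopifnot(inherits(raw, "silogan_raw"))
  px <- raw$pixels
  d <- dim(px)
  if (d[1L] < 8L || d[2L] < 8L) {
    message("skipping degenerate image '", raw$source_id, "': too small")
    return(NULL)
  }
  if (max(px) == min(px)) {
    message("skipping degenerate image '", raw$source_id, "': constant")
    return(NULL)
  }
  eightbit <- max(px) > 1
  S <- cfg$target_size
  px <- EBImage::resize(px, w = S, h = S, antialias = TRUE)
  px <- to_grayscale(px)
  px8 <- if (eightbit) pmin(pmax(round(px), 0), 255) else
    pmin(pmax(round(px * 255), 0), 255)
  px8 <- apply_clahe(px8, cfg$clahe_clip_limit, cfg$clahe_tile_grid)
  p01 <- px8 / 255
  p01 <- p01^cfg$gamma
  pq <- quantize_levels(p01, cfg$n_levels)
  out <- 2 * pq - 1
  structure(list(pixels = array(out, c(S, S, 1L)), label = raw$label,
                 source_id = raw$source_id),
            class = "silogan_processed")
}

#' Preprocess a list of raw images
#'
#' @param raws list of [raw_image()] objects.
#' @param cfg a [pipeline_config()].
#' @return list with `images` (processed images) and `skipped` (count of
#'   degenerate inputs that were logged and dropped).
#' @export
preprocess_dataset <- function(raws, cfg = pipeline_config()) {
  out <- list()
  skipped <- 0L
  for (r in raws) {
    p <- preprocess(r, cfg)
    if (is.null(p)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- p
  }
  list(images = out, skipped = skipped)
}

#' Load a directory of PNG/JPEG images with an optional label sidecar
#'
#' @param dir directory containing `.png`, `.jpg` or `.jpeg` files.
#' @param labels_csv optional CSV path with columns `filename,label`.
#' @return list of [raw_image()] objects (unit-scaled pixels), sorted by
#'   filename.
#' @export
load_image_dir <- function(dir, labels_csv = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no PNG/JPEG images found in ", dir)
  labels <- NULL
  if (!is.null(labels_csv)) {
    tab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
    labels <- stats::setNames(as.integer(tab$label), tab$filename)
  }
  lapply(files, function(f) {
    px <- EBImage::readImage(file.path(dir, f))
    px <- drop(EBImage::imageData(px))
    if (length(dim(px)) == 3L) px <- aperm(px, c(2L, 1L, 3L)) else px <- t(px)
    lab <- if (!is.null(labels) && f %in% names(labels)) labels[[f]] else NULL
    raw_image(px, label = lab, source_id = f)
  })
}
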