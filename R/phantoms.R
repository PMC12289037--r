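# Synthetic phantom image generation.
#
# Two grayscale domains stand in for the external datasets the framework is
# designed around: "fundus" phantoms emulate severity-graded retinal scans
# (circular field of view, vessel-like curves, lesion counts that grow with
# the severity grade), "ct" phantoms emulate abdominal CT slices (elliptical
# body outline with interior organ-like ellipses, no lesions).  The two
# domains share low-level statistics (smooth grayscale anatomy on a dark
# background) but not high-level structure, which is what makes the CT
# domain a meaningful transfer-pretraining source.

#' Phantom dataset configuration
#'
#' @param n_images number of images (>= 0).
#' @param image_size image side in pixels (default 128).
#' @param label_probs probability of each severity grade 0-4; non-negative,
#'   summing to 1.
#' @param lesion_rate function mapping a grade to the expected lesion count;
#'   must satisfy `lesion_rate(0) == 0` and be nondecreasing.  Default
#'   `3 * label`.
#' @param domain `"fundus"` (labeled) or `"ct"` (unlabeled).
#' @param seed integer seed.
#' @return list of class `silogan_phantom_config`.
#' @export
phantom_config <- function(n_images, image_size = 128L,
                           label_probs = rep(0.2, 5),
                           lesion_rate = function(label) 3 * label,
                           domain = c("fundus", "ct"), seed = 1L) {
  domain <- match.arg(domain)
  if (n_images < 0L) stop("n_images must be >= 0")
  if (length(label_probs) != 5L || any(label_probs < 0) ||
      abs(sum(label_probs) - 1) > 1e-9)
    stop("label_probs must be 5 non-negative values summing to 1")
  lam <- vapply(0:4, lesion_rate, numeric(1))
  if (lam[1L] != 0 || any(diff(lam) < 0))
    stop("lesion_rate must be 0 at grade 0 and nondecreasing")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 label_probs = label_probs, lesion_rate = lesion_rate,
                 domain = domain, seed = as.integer(seed)),
            class = "silogan_phantom_config")
}

#' Generate one phantom image
#'
#' Draws from the R random number stream in effect (seed it with
#' `set.seed()` for reproducibility).  Fundus phantoms carry a
#' `Poisson(lesion_rate(label))` number of lesions, each independently a
#' bright exudate-like disc or a dark hemorrhage-like blob; the realized
#' count is attached as attribute `n_lesions`.
#'
#' @param label severity grade 0-4 (ignored for the `"ct"` domain).
#' @param image_size image side in pixels.
#' @param domain `"fundus"` or `"ct"`.
#' @param lesion_rate see [phantom_config()].
#' @return a [raw_image()] with 8-bit pixels; exterior of the field-of-view
#'   mask is constant 0.
#' @export
make_phantom_image <- function(label, image_size = 128L,
                               domain = c("fundus", "ct"),
                               lesion_rate = function(label) 3 * label) {
  domain <- match.arg(domain)
  S <- as.integer(image_size)
  if (domain == "fundus") {
    if (!is.numeric(label) || !label %in% 0:4)
      stop("label must be an integer in 0..4")
    img <- fundus_phantom(as.integer(label), S, lesion_rate)
  } else {
    img <- ct_phantom(S)
  }
  img
}

fundus_phantom <- function(label, S, lesion_rate) {
  cx <- (S + 1) / 2
  i <- matrix(seq_len(S), S, S)
  j <- t(i)
  r <- sqrt((i - cx)^2 + (j - cx)^2)
  R <- 0.45 * S
  mask <- r <= R
  base <- 150 * (1 - 0.4 * (r / R)^2)
  px <- matrix(0, S, S)
  px[mask] <- base[mask] + rnorm(sum(mask), 0, 3)

  # 2-4 vessel-like random-walk curves radiating from near the center
  n_vessels <- sample(2:4, 1L)
  for (v in seq_len(n_vessels)) {
    pos <- c(cx, cx) + runif(2, -0.05 * S, 0.05 * S)
    ang <- runif(1, 0, 2 * pi)
    for (s in seq_len(as.integer(1.2 * S))) {
      ang <- ang + rnorm(1, 0, 0.25)
      pos <- pos + c(cos(ang), sin(ang))
      pi_ <- round(pos[1L]); pj <- round(pos[2L])
      if (pi_ < 1 || pi_ > S || pj < 1 || pj > S) break
      if (r[pi_, pj] > 0.95 * R) break
      px[pi_, pj] <- 60
      if (pi_ < S) px[pi_ + 1L, pj] <- 60
    }
  }

  # severity-dependent lesions inside the field of view
  n_lesions <- stats::rpois(1L, lesion_rate(label))
  for (l in seq_len(n_lesions)) {
    repeat {
      li <- cx + runif(1, -0.8 * R, 0.8 * R)
      lj <- cx + runif(1, -0.8 * R, 0.8 * R)
      if (sqrt((li - cx)^2 + (lj - cx)^2) <= 0.8 * R) break
    }
    rad <- max(1, runif(1, 2, 5) * S / 128)
    val <- if (runif(1) < 0.5) 230 else 40   # bright exudate / dark hemorrhage
    hit <- (i - li)^2 + (j - lj)^2 <= rad^2 & mask
    px[hit] <- val
  }
  px <- pmin(pmax(px, 0), 255)
  px[!mask] <- 0
  out <- raw_image(px, label = label,
                   source_id = sprintf("fundus_l%d", label))
  attr(out, "n_lesions") <- n_lesions
  out
}

ct_phantom <- function(S) {
  cx <- (S + 1) / 2
  i <- matrix(seq_len(S), S, S)
  j <- t(i)
  a <- 0.42 * S; b <- 0.32 * S
  e <- ((i - cx) / b)^2 + ((j - cx) / a)^2   # body taller than wide? wide body
  body <- e <= 1
  px <- matrix(0, S, S)
  px[body] <- 110 + rnorm(sum(body), 0, 4)
  rim <- e <= 1 & e >= (1 - 3 / min(a, b))^2
  px[rim] <- 210
  n_org <- sample(3:6, 1L)
  for (o in seq_len(n_org)) {
    oi <- cx + runif(1, -0.5, 0.5) * b
    oj <- cx + runif(1, -0.5, 0.5) * a
    oa <- runif(1, 0.06, 0.18) * S
    ob <- runif(1, 0.06, 0.18) * S
    val <- runif(1, 50, 190)
    hit <- ((i - oi) / ob)^2 + ((j - oj) / oa)^2 <= 1 & body
    px[hit] <- val
  }
  px <- pmin(pmax(px, 0), 255)
  px[!body] <- 0
  out <- raw_image(px, label = NULL, source_id = "ct")
  attr(out, "n_lesions") <- 0L
  out
}

#' Generate a phantom dataset
#'
#' Reproducible from `cfg$seed`.  Fundus images receive severity grades
#' drawn from `cfg$label_probs`; CT images are unlabeled.
#'
#' @param cfg a [phantom_config()].
#' @return list of [raw_image()] objects of length `cfg$n_images`.
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "silogan_phantom_config"))
  set.seed(cfg$seed)
  n <- cfg$n_images
  if (n == 0L) return(list())
  labels <- if (cfg$domain == "fundus")
    sample(0:4, n, replace = TRUE, prob = cfg$label_probs) else rep(NA, n)
  lapply(seq_len(n), function(k) {
    img <- if (cfg$domain == "fundus") {
      make_phantom_image(labels[k], cfg$image_size, "fundus", cfg$lesion_rate)
    } else {
      make_phantom_image(0L, cfg$image_size, "ct")
    }
    img$source_id <- sprintf("%s_%05d", cfg$domain, k)
    img
  })
}

#' Write a phantom dataset as PNG files plus a labels CSV
#'
#' @param raws list of [raw_image()] objects (8-bit pixels).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_phantom_dataset <- function(raws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  labs <- list()
  for (k in seq_along(raws)) {
    f <- sprintf("img_%05d.png", k)
    png::writePNG(raws[[k]]$pixels / 255, file.path(dir, f))
    paths <- c(paths, file.path(dir, f))
    if (!is.null(raws[[k]]$label))
      labs[[length(labs) + 1L]] <- data.frame(filename = f,
                                              label = raws[[k]]$label)
  }
  if (length(labs)) {
    csv <- file.path(dir, "labels.csv")
    utils::write.csv(do.call(rbind, labs), csv, row.names = FALSE)
    paths <- c(paths, csv)
  }
  invisible(paths)
}
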