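# Weight checkpoints: JSON architecture descriptor + float32 tensor payload.

#' Save a weight set to a checkpoint file
#'
#' The file holds a length-prefixed JSON header (network tag, architecture,
#' tensor names and dimensions) followed by the concatenated float32 tensor
#' data, little-endian.
#'
#' @param ws a `silogan_weights` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_weights <- function(ws, path) {
  hdr <- list(network = ws$network, arch = ws$arch,
              tensors = lapply(ws$tensors, function(t)
                as.integer(if (is.null(dim(t))) length(t) else dim(t))))
  hj <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SGW1"), con)
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  for (t in ws$tensors)
    writeBin(as.numeric(t), con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a weight set from a checkpoint file
#'
#' @param path checkpoint written by [save_weights()].
#' @return a `silogan_weights` object (float32 precision).
#' @export
load_weights <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || rawToChar(magic) != "SGW1")
    stop("not a checkpoint file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                            simplifyVector = TRUE)
  tensors <- list()
  for (nm in names(hdr$tensors)) {
    d <- as.integer(hdr$tensors[[nm]])
    x <- readBin(con, "numeric", prod(d), size = 4L, endian = "little")
    if (length(x) != prod(d)) stop("truncated tensor ", nm, " in ", path)
    if (length(d) > 1L) dim(x) <- d
    tensors[[nm]] <- x
  }
  arch <- hdr$arch
  arch$image_size <- as.integer(arch$image_size)
  if (!is.null(arch$latent_dim)) arch$latent_dim <- as.integer(arch$latent_dim)
  structure(list(network = hdr$network, arch = arch, tensors = tensors),
            class = "silogan_weights")
}
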