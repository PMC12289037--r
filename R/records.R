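# Binary record container for processed images.
#
# Format "SGR1" (little-endian throughout):
#   bytes 0-3   magic "SGR1"
#   bytes 4-7   int32 record count
#   then per record a uint32 byte-length prefix followed by the payload:
#     int32 label (-1 encodes absent), int32 H, int32 W, int32 C,
#     int32 source-id byte length, source-id bytes (UTF-8),
#     H*W*C float32 pixels (column-major, channel last).
# This is the package's documented stand-in for a TFRecord file: a
# length-prefixed record stream behind the same read/write contract.

#' Write processed images to a record file
#'
#' Pixels are stored as float32; labels and record order are preserved
#' exactly, so `read_records(write_records(path, x))` reproduces pixels
#' (float32-exact), labels and order.
#'
#' @param path output file path.
#' @param images list of processed images (see [preprocess()]).
#' @return the number of records written, invisibly checkable against
#'   `length(images)`.
#' @export
write_records <- function(path, images) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SGR1"), con)
  writeBin(as.integer(length(images)), con, size = 4L, endian = "little")
  for (im in images) {
    d <- dim(im$pixels)
    if (length(d) == 2L) d <- c(d, 1L)
    sid <- charToRaw(enc2utf8(im$source_id %||% ""))
    label <- if (is.null(im$label)) -1L else as.integer(im$label)
    payload_len <- 4L * 5L + length(sid) + 4L * prod(d)
    writeBin(as.integer(payload_len), con, size = 4L, endian = "little")
    writeBin(c(label, as.integer(d), length(sid)), con, size = 4L,
             endian = "little")
    if (length(sid)) writeBin(sid, con)
    writeBin(as.numeric(im$pixels), con, size = 4L, endian = "little")
  }
  length(images)
}

#' Read a record file written by [write_records()]
#'
#' @param path record file path.
#' @return list of processed images (pixels as `(H, W, C)` float arrays,
#'   `label` `NULL` when absent, `source_id`).  A corrupt file raises a parse
#'   error naming the byte offset at which reading failed.
#' @export
read_records <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  offset <- 0L
  fail <- function(what) stop("record parse error at byte offset ", offset,
                              ": ", what, call. = FALSE)
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || rawToChar(magic) != "SGR1") fail("bad magic")
  offset <- 4L
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n < 0L) fail("bad record count")
  offset <- offset + 4L
  out <- vector("list", n)
  for (r in seq_len(n)) {
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(len) != 1L || is.na(len) || len < 24L)
      fail(paste0("bad length prefix for record ", r))
    offset <- offset + 4L
    hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
    if (length(hdr) != 5L) fail(paste0("truncated header in record ", r))
    offset <- offset + 20L
    label <- if (hdr[1L] < 0L) NULL else hdr[1L]
    d <- hdr[2:4]
    slen <- hdr[5L]
    sid <- ""
    if (slen > 0L) {
      sraw <- readBin(con, "raw", slen)
      if (length(sraw) != slen) fail(paste0("truncated source id in record ", r))
      sid <- rawToChar(sraw)
      offset <- offset + slen
    }
    npx <- prod(d)
    if (20L + slen + 4L * npx != len)
      fail(paste0("inconsistent payload length in record ", r))
    px <- readBin(con, "numeric", npx, size = 4L, endian = "little")
    if (length(px) != npx) fail(paste0("truncated pixels in record ", r))
    offset <- offset + 4L * npx
    out[[r]] <- structure(list(pixels = array(px, d), label = label,
                               source_id = sid),
                          class = "silogan_processed")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-trip a double vector through float32 (the precision records store)
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", length(x), size = 4L, endian = "little")
}
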