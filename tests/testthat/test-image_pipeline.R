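test_that("grayscale conversion uses BT.601 weights and fixes 1-channel input", {
  m <- matrix(runif(64, 0, 255), 8, 8)
  expect_identical(to_grayscale(m), m)

  white <- array(255, c(4, 4, 3))
  expect_true(all(to_grayscale(white) == 255))

  red <- array(0, c(4, 4, 3))
  red[, , 1] <- 255
  expect_equal(to_grayscale(red)[1, 1], 0.299 * 255, tolerance = 1e-12)

  bad <- array(1, c(4, 4, 2))
  expect_error(to_grayscale(bad), "channel")
})

test_that("CLAHE is deterministic, range-preserving, constant on constants", {
  expect_error(apply_clahe(matrix(1, 8, 8), clip_limit = 0), "positive")

  const <- matrix(117, 16, 16)
  out <- apply_clahe(const, 2, c(4, 4))
  expect_equal(max(out) - min(out), 0)

  set.seed(3)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  o1 <- apply_clahe(img, 2, c(4, 4))
  o2 <- apply_clahe(img, 2, c(4, 4))
  expect_identical(o1, o2)
  expect_gte(min(o1), 0)
  expect_lte(max(o1), 255)

  # unit-scaled input comes back on the unit scale
  u <- apply_clahe(img / 255, 2, c(4, 4))
  expect_lte(max(u), 1)
})

test_that("CLAHE matches the blockwise clipped-equalization oracle", {
  # 18x18 linear-gradient fixture, 2x2 tiles of 9x9 -> integer tile centers
  # at rows/cols 5 and 14, where the interpolation weight collapses onto a
  # single tile mapping
  v <- matrix(0L, 18, 18)
  for (i in 1:18) for (j in 1:18) v[i, j] <- ((i - 1) * 18 + (j - 1)) %/% 2
  impl <- apply_clahe(v, 4, c(2, 2))
  ora <- clahe_block_oracle(v, 4, c(2, 2))
  centers <- c(5L, 14L)
  for (i in centers) for (j in centers) {
    expect_equal(impl[i, j], ora$out[i, j], tolerance = 1e-12)
  }
  # elsewhere, interpolation can deviate at most by the largest disagreement
  # between adjacent tile mappings over the values present
  tol <- 0
  for (a in 1:2) {
    tol <- max(tol, max(abs(ora$maps[[paste(a, 1)]] - ora$maps[[paste(a, 2)]])))
    tol <- max(tol, max(abs(ora$maps[[paste(1, a)]] - ora$maps[[paste(2, a)]])))
  }
  expect_lte(max(abs(impl - ora$out)), tol)
})

test_that("quantization projects onto the level grid with round-half-up", {
  expect_equal(quantize_levels(0), 0)
  expect_equal(quantize_levels(1), 1)
  expect_equal(quantize_levels(0.5, 16), 8 / 15)      # half-up, not 7/15
  expect_equal(quantize_levels(0.5, 3), 1 / 2)

  set.seed(1)
  x <- matrix(runif(400), 20, 20)
  q <- quantize_levels(x, 16)
  expect_lte(length(unique(as.vector(q))), 16)
  expect_true(all(q %in% ((0:15) / 15)))
  expect_identical(quantize_levels(q, 16), q)          # projection

  expect_error(quantize_levels(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(quantize_levels(-0.1), "\\[0, 1\\]")
})

test_that("preprocess satisfies the output contract on phantom inputs", {
  raws <- make_dataset(phantom_config(6, 64, seed = 11))
  for (S in c(16L, 32L)) {
    cfg <- pipeline_config(S)
    res <- preprocess_dataset(raws, cfg)
    expect_equal(res$skipped, 0L)
    for (im in res$images) {
      expect_equal(dim(im$pixels), c(S, S, 1L))
      expect_gte(min(im$pixels), -1)
      expect_lte(max(im$pixels), 1)
      expect_lte(length(unique(as.vector(im$pixels))), 16L)
    }
    expect_equal(vapply(res$images, function(im) im$label, integer(1)),
                 vapply(raws, function(r) r$label, integer(1)))
  }
})

test_that("preprocess equals the hand-composed scalar pipeline on a checkerboard", {
  # 16x16 checkerboard of 64/192; 8x8 CLAHE tiles each hold two of each
  # value, so all tile mappings coincide and the pipeline reduces to scalar
  # maps composed by hand
  v <- matrix(64, 16, 16)
  v[(row(v) + col(v)) %% 2 == 0] <- 192
  raw <- raw_image(v, label = 2L, source_id = "checker")
  cfg <- pipeline_config(16, clahe_clip_limit = 256, gamma = 2)
  out <- preprocess(raw, cfg)

  # oracle, step by step: CLAHE mapping m(v) = round(cdf/N*255) with
  # cdf(64) = N/2, cdf(192) = N -> 128 and 255; then /255, ^2, quantize
  # half-up to 15ths, rescale 2x-1
  o64 <- 2 * (floor((128 / 255)^2 * 15 + 0.5) / 15) - 1
  o192 <- 2 * (floor((255 / 255)^2 * 15 + 0.5) / 15) - 1
  expect_equal(o64, -7 / 15)   # frozen hand value
  expect_equal(o192, 1)
  px <- out$pixels[, , 1]
  expect_equal(px[v == 64], rep(o64, sum(v == 64)))
  expect_equal(px[v == 192], rep(o192, sum(v == 192)))
  expect_equal(out$label, 2L)
})

test_that("preprocess is deterministic and skips degenerate inputs with a log", {
  raws <- make_dataset(phantom_config(3, 32, seed = 4))
  a <- preprocess(raws[[1]], pipeline_config(16))
  b <- preprocess(raws[[1]], pipeline_config(16))
  expect_identical(a, b)

  expect_message(
    res <- preprocess(raw_image(matrix(7, 32, 32)), pipeline_config(16)),
    "constant")
  expect_null(res)
  expect_message(
    res2 <- preprocess(raw_image(matrix(runif(16), 4, 4)), pipeline_config(16)),
    "too small")
  expect_null(res2)

  mixed <- c(raws, list(raw_image(matrix(7, 32, 32))))
  expect_message(out <- preprocess_dataset(mixed, pipeline_config(16)))
  expect_equal(out$skipped, 1L)
  expect_length(out$images, 3L)
})

test_that("the final rescale is a bijection undone exactly on the level grid", {
  img <- phantom_batch(2, 16, seed = 9)[[1]]
  inter <- (img$pixels + 1) / 2          # the [0,1] intermediate
  expect_equal(quantize_levels(inter, 16), inter, tolerance = 1e-12)
  expect_equal(2 * inter - 1, img$pixels)
})

test_that("record files round-trip pixels, labels and order losslessly", {
  tmp <- withr::local_tempfile(fileext = ".sgr")
  expect_equal(write_records(tmp, list()), 0L)
  expect_length(read_records(tmp), 0L)

  imgs <- phantom_batch(10, 16, seed = 21)
  imgs[[3]]$label <- NULL                 # interleave labeled/unlabeled
  imgs[[7]]$label <- NULL
  expect_equal(write_records(tmp, imgs), 10L)
  back <- read_records(tmp)
  expect_length(back, 10L)
  for (k in seq_along(imgs)) {
    expect_equal(as.vector(back[[k]]$pixels),
                 silogan:::as_float32(imgs[[k]]$pixels))
    expect_identical(back[[k]]$label, imgs[[k]]$label)
    expect_identical(back[[k]]$source_id, imgs[[k]]$source_id)
    expect_equal(dim(back[[k]]$pixels), c(16L, 16L, 1L))
  }
})

test_that("corrupt record files fail with a byte offset", {
  tmp <- withr::local_tempfile(fileext = ".sgr")
  write_records(tmp, phantom_batch(2, 16, seed = 5))
  bytes <- readBin(tmp, "raw", file.info(tmp)$size)
  writeBin(bytes[1:40], tmp)               # truncate mid-record
  expect_error(read_records(tmp), "byte offset")
  writeBin(as.raw(c(1, 2, 3, 4)), tmp)     # bad magic
  expect_error(read_records(tmp), "byte offset 0")
})
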