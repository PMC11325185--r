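test_that("PNG and TIFF round-trips are lossless at both bit depths", {
  set.seed(11)
  for (ext in c("png", "tif")) {
    for (depth in c(8L, 16L)) {
      maxv <- 2^depth - 1
      mat <- matrix(sample(0:maxv, 31 * 17, replace = TRUE), nrow = 17)
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_image(raster_image(mat + 0), path, depth)
      back <- read_image(path)
      expect_identical(back$pixels, mat + 0.0)
    }
  }
  # constant image round trip
  path <- withr::local_tempfile(fileext = ".png")
  write_image(matrix(7, 5, 9), path, 8L)
  expect_true(all(read_image(path)$pixels == 7))
})

test_that("write_image clips and rounds half-to-even at the file boundary", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(matrix(300, 3, 3), path, 8L)
  expect_true(all(read_image(path)$pixels == 255))
  write_image(matrix(127.5, 3, 3), path, 8L)
  expect_true(all(read_image(path)$pixels == 128))
  write_image(matrix(126.5, 3, 3), path, 8L)  # half-to-even rounds down
  expect_true(all(read_image(path)$pixels == 126))
  write_image(matrix(-5, 3, 3), path, 16L)
  expect_true(all(read_image(path)$pixels == 0))
})

test_that("unsupported raster formats are rejected", {
  jpg <- withr::local_tempfile(fileext = ".jpg")
  writeBin(as.raw(c(0xFF, 0xD8, 0xFF, 0xE0)), jpg)
  expect_error(read_image(jpg), "unsupported format")
  expect_error(read_image(withr::local_tempfile(fileext = ".png")), "not found")
  # hand-built RGB (colour type 2) PNG must be refused
  rgb <- withr::local_tempfile(fileext = ".png")
  ihdr <- c(quadmosaic:::uint32_be(2), quadmosaic:::uint32_be(2),
            as.raw(c(8, 2, 0, 0, 0)))
  stream <- as.raw(c(0, rep(10, 6), 0, rep(20, 6)))
  writeBin(c(quadmosaic:::png_signature,
             quadmosaic:::png_chunk("IHDR", ihdr),
             quadmosaic:::png_chunk("IDAT", memCompress(stream, "gzip")),
             quadmosaic:::png_chunk("IEND", raw(0))), rgb)
  expect_error(read_image(rgb), "unsupported format")
})

test_that("PNG reader reconstructs filtered scanlines", {
  # exercise Sub/Up/Average/Paeth unfiltering against the filter definitions
  set.seed(4)
  prev <- sample(0:255, 12)
  cur_recon <- sample(0:255, 12)
  for (ftype in 1:4) {
    filt <- integer(12)
    for (i in 1:12) {
      left <- if (i > 1) cur_recon[i - 1] else 0L
      ul <- if (i > 1) prev[i - 1] else 0L
      pred <- switch(ftype, left, prev[i], (left + prev[i]) %/% 2L,
                     quadmosaic:::paeth_predict(left, prev[i], ul))
      filt[i] <- (cur_recon[i] - pred) %% 256L
    }
    expect_identical(quadmosaic:::png_unfilter_row(ftype, filt, prev, 1L),
                     cur_recon)
  }
})

test_that("pixel scale is read from a JSON sidecar", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(matrix(1, 4, 4), path, 8L)
  expect_null(read_image(path)$pixel_scale)
  jsonlite::write_json(list(pixel_scale_um = 0.87), paste0(path, ".json"),
                       auto_unbox = TRUE)
  expect_equal(read_image(path)$pixel_scale, 0.87)
})

test_that("centroid CSV round-trips preserve order and coordinates", {
  cs <- centroid_set(c(3.5, 10.123456, 0.25), c(4.5, 2.654321, 90),
                     label = c("cone", "rod", "any"), source = "manual")
  path <- withr::local_tempfile(fileext = ".csv")
  write_centroids(cs, path)
  back <- read_centroids(path, source = "manual")
  expect_equal(back$x, cs$x, tolerance = 1e-6)
  expect_equal(back$y, cs$y, tolerance = 1e-6)
  expect_identical(back$label, cs$label)
})

test_that("centroid CSV contract: labels default, malformed rows, negatives", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "3.5,4.5"), path)
  cs <- read_centroids(path)
  expect_equal(nrow(cs), 1L)
  expect_identical(cs$label, "any")

  writeLines(c("x,y", "1,2", "a,b"), path)
  expect_error(read_centroids(path), "line 3")

  writeLines(c("x,y", "-1,2"), path)
  expect_error(read_centroids(path), "[Nn]egative")

  expect_error(centroid_set(c(1, 1), c(2, 2 + 1e-9)), "duplicate")
})
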