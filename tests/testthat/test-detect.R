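test_that("gaussian_blur: identity at radius 0, DC preservation, unit kernel", {
  set.seed(2)
  img <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(gaussian_blur(img, 0)$pixels, img)
  expect_true(all(abs(gaussian_blur(matrix(7, 12, 12), 3)$pixels - 7) < 1e-12))
  k <- quadmosaic:::gaussian_kernel_1d(2)
  expect_equal(sum(k), 1)
  expect_equal(k, rev(k))
  # 2-D impulse response: mass conserved and symmetric (interior impulse)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  resp <- gaussian_blur(imp, 2)$pixels
  expect_equal(sum(resp), 1, tolerance = 1e-9)
  expect_equal(resp, t(resp), tolerance = 1e-12)
  expect_equal(resp, resp[21:1, 21:1], tolerance = 1e-12)
})

test_that("trough_threshold finds the valley of a bimodal histogram", {
  set.seed(31)
  v <- c(rnorm(8192, 60, 10), rnorm(8192, 180, 10))
  img <- matrix(v, 128, 128)
  cut <- trough_threshold(img)
  expect_identical(attr(cut, "method"), "trough")
  expect_gt(cut, 90); expect_lt(cut, 150)

  two <- matrix(rep(c(0, 255), 128), 16, 16)
  cut2 <- trough_threshold(two)
  expect_gt(cut2, 0); expect_lt(cut2, 255)

  uni <- matrix(rnorm(4096, 100, 15), 64, 64)
  expect_warning(cut3 <- trough_threshold(uni), "Otsu")
  expect_identical(attr(cut3, "method"), "otsu")
  expect_equal(as.numeric(cut3), as.numeric(otsu_threshold(uni)))

  expect_error(trough_threshold(matrix(5, 4, 4)), "constant")
})

test_that("binarize selects the requested side of the cutoff", {
  img <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(as.vector(binarize(img, 2)), c(FALSE, FALSE, TRUE))
  expect_equal(as.vector(binarize(img, 2, invert = TRUE)), c(TRUE, FALSE, FALSE))
  # complementarity away from cutoff-equal pixels
  set.seed(5)
  r <- matrix(runif(64), 8, 8)
  expect_equal(binarize(r, 0.5), !binarize(r, 0.5, invert = TRUE))
  expect_false(any(binarize(img, 5)))
})

test_that("watershed_split separates touching disks and counts regions", {
  m1 <- disk_mask(40, 19.5, 19.5, 8)
  lab1 <- watershed_split(m1)
  expect_equal(max(lab1), 1L)

  # two overlapping disks, centres 14 px apart
  m2 <- disk_mask(48, 16.5, 23.5, 8) | disk_mask(48, 30.5, 23.5, 8)
  lab2 <- watershed_split(m2)
  expect_equal(max(lab2), 2L)
  # a watershed line separates them: the two labels are disconnected
  left <- unique(lab2[unclass(lab2) > 0 &
                      col(lab2) <= 18])
  right <- unique(lab2[unclass(lab2) > 0 & col(lab2) >= 30])
  expect_false(any(left %in% right))
  line_cols <- col(lab2)[m2 & unclass(lab2) == 0]
  expect_true(length(line_cols) > 0)           # the 1-px line exists
  expect_true(all(line_cols >= 20 & line_cols <= 28))

  empty <- matrix(FALSE, 10, 10)
  expect_equal(max(watershed_split(empty)), 0L)
})

test_that("find_cell_centroids returns one in-box centroid per label", {
  lab <- matrix(0L, 30, 30)
  lab[11:20, 11:20] <- 1L   # rows/cols 10..19 in 0-based coordinates
  lab[2:5, 25:28] <- 2L
  cs <- find_cell_centroids(structure(lab, class = "label_mask"))
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$x[1], 14.5); expect_equal(cs$y[1], 14.5)
  expect_true(cs$x[2] >= 24 && cs$x[2] <= 27)
  expect_true(cs$y[2] >= 1 && cs$y[2] <= 4)
  # regional-maxima mode picks the brightest pixel of the label
  inten <- matrix(0, 30, 30); inten[13, 17] <- 9
  cs2 <- find_cell_centroids(structure(lab, class = "label_mask"),
                             mode = "regional-maxima", intensity = inten)
  expect_equal(c(cs2$x[1], cs2$y[1]), c(16, 12))
})

test_that("detect_cells finds an isolated disk and honours polarity", {
  set.seed(12)
  img <- matrix(50, 64, 64) + matrix(rnorm(4096, 0, 5), 64, 64)
  img[disk_mask(64, 31.5, 31.5, 6)] <- 200 + rnorm(sum(disk_mask(64, 31.5, 31.5, 6)), 0, 5)
  cs <- detect_cells(img, detection_params(invert = FALSE))
  expect_equal(nrow(cs), 1L)
  expect_lt(sqrt((cs$x - 31.5)^2 + (cs$y - 31.5)^2), 1)

  expect_error(detect_cells(matrix(3, 32, 32)), "constant")
})

test_that("detect_cells is translation-equivariant and shift-invariant in intensity", {
  sim <- generate_mosaic(mosaic_spec(size = 128, seed = 9))
  enh <- enhance_quadrants(sim$qset)
  base <- suppressWarnings(detect_cells(enh))

  # adding a constant leaves centroids unchanged (trough shifts equally)
  shifted_int <- suppressWarnings(detect_cells(enh$pixels + 13.7))
  expect_equal(nrow(shifted_int), nrow(base))
  expect_equal(shifted_int$x, base$x, tolerance = 1e-9)
  expect_equal(shifted_int$y, base$y, tolerance = 1e-9)

  # integer translation moves interior centroids by the same vector
  dx <- 7L; dy <- 4L
  n <- nrow(enh$pixels)
  trans <- enh$pixels[c((dy + 1):n, rep(n, dy)), c((dx + 1):n, rep(n, dx))]
  moved <- suppressWarnings(detect_cells(trans))
  margin <- 20
  interior <- base$x - dx > margin & base$x - dx < n - 1 - margin &
              base$y - dy > margin & base$y - dy < n - 1 - margin
  for (i in which(interior)) {
    d <- sqrt((moved$x - (base$x[i] - dx))^2 + (moved$y - (base$y[i] - dy))^2)
    expect_lt(min(d), 1.0)
  }
})

test_that("watershed never merges below the component count", {
  set.seed(14)
  for (i in 1:5) {
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    # smooth the noise into blobs
    mask <- as_blobs <- gaussian_blur(mask * 1, 2)$pixels > 0.4
    lab <- watershed_split(mask, min_area = 4)
    comp <- quadmosaic:::cpp_label_components(mask, 4L)
    comp_sizes <- tabulate(comp[comp > 0])
    expect_gte(max(lab), sum(comp_sizes >= 4))
  }
})
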