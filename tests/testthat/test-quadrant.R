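make_qset <- function(mats, azimuths = c(45, 135, 225, 315)) {
  quadrant_frame_set(mats, azimuths)
}

test_that("normalize_quadrant_means equalises means and is idempotent", {
  mats <- lapply(c(10, 20, 30, 40), function(m) matrix(m, 8, 8))
  # add structure so relative contrast can be checked
  mats[[2]][1, 1] <- 40
  qset <- make_qset(mats)
  bal <- normalize_quadrant_means(qset)
  means <- vapply(bal$channels, mean, numeric(1))
  grand <- mean(vapply(qset$channels, mean, numeric(1)))
  expect_equal(means, setNames(rep(grand, 4), names(means)), tolerance = 1e-9)
  # relative contrast preserved: ratios within a channel unchanged
  expect_equal(bal$channels[[2]][1, 1] / bal$channels[[2]][2, 2],
               mats[[2]][1, 1] / mats[[2]][2, 2])
  # idempotent
  bal2 <- normalize_quadrant_means(bal)
  expect_equal(bal2$channels, bal$channels, tolerance = 1e-12)
  # already-equal means: unchanged
  eq <- make_qset(lapply(1:4, function(i) matrix(5, 4, 4)))
  expect_equal(normalize_quadrant_means(eq)$channels, eq$channels)
})

test_that("degenerate channels are rejected", {
  mats <- lapply(1:4, function(i) matrix(10, 4, 4))
  mats[[3]] <- matrix(0, 4, 4)
  expect_error(quadrant_frame_set(mats), "mean")
})

test_that("split_image implements difference over sum with a defined-zero mask", {
  A <- matrix(3, 5, 5); B <- matrix(1, 5, 5)
  s <- split_image(A, B)
  expect_true(all(s$pixels == 0.5))
  expect_false(any(s$undefined_mask))

  s0 <- split_image(B, B)
  expect_true(all(s0$pixels == 0))

  A[2, 2] <- 0; B2 <- B; B2[2, 2] <- 0
  s2 <- split_image(A, B2)
  expect_equal(s2$pixels[2, 2], 0)
  expect_true(s2$undefined_mask[2, 2])
  expect_equal(sum(s2$undefined_mask), 1L)

  expect_error(split_image(matrix(1, 2, 2), matrix(1, 3, 3)), "mismatch")
})

test_that("split images are antisymmetric, bounded and scale-invariant", {
  set.seed(21)
  for (i in 1:20) {
    A <- matrix(runif(64, 0, 50), 8, 8)
    B <- matrix(runif(64, 0, 50), 8, 8)
    s_ab <- split_image(A, B); s_ba <- split_image(B, A)
    expect_equal(s_ab$pixels, -s_ba$pixels, tolerance = 1e-12)
    expect_true(all(abs(s_ab$pixels) <= 1))
    k <- runif(1, 0.1, 10)
    expect_equal(split_image(k * A, k * B)$pixels, s_ab$pixels, tolerance = 1e-12)
  }
})

test_that("directional_splits honours the side mapping", {
  set.seed(8)
  mats <- lapply(1:4, function(i) matrix(runif(36, 1, 9), 6, 6))
  qset <- make_qset(mats)
  splits <- directional_splits(qset)
  expect_named(splits, c("0", "45", "90", "135"))
  expect_equal(vapply(splits, function(s) s$axis_angle, numeric(1)),
               c(`0` = 0, `45` = 45, `90` = 90, `135` = 135))
  # explicit recomputation of the vertical split from the documented sides
  A <- mats[[1]] + mats[[4]]  # azimuths 45 + 315
  B <- mats[[2]] + mats[[3]]  # azimuths 135 + 225
  expect_equal(splits[["90"]]$pixels, (A - B) / (A + B))

  # swapping the two sides of one axis negates that split only
  mp <- default_axis_mapping()
  mp[["45"]] <- list(pos = mp[["45"]]$neg, neg = mp[["45"]]$pos)
  flipped <- directional_splits(qset, mp)
  expect_equal(flipped[["45"]]$pixels, -splits[["45"]]$pixels)
  expect_equal(flipped[["90"]]$pixels, splits[["90"]]$pixels)

  # identical channels: all four splits vanish
  same <- make_qset(lapply(1:4, function(i) mats[[1]]))
  expect_true(all(vapply(directional_splits(same),
                         function(s) all(s$pixels == 0), logical(1))))

  bad <- default_axis_mapping()
  bad[["0"]]$pos <- c(45, 90)
  expect_error(directional_splits(qset, bad), "unknown channel")
})

test_that("rotating rasters and azimuths together maps S_0 onto S_90", {
  # rotate the scene by 90 degrees: rasters rotate and every detector
  # azimuth advances by 90, so the horizontal split of the rotated set must
  # equal the rotated vertical split of the original (and vice versa).
  spec <- mosaic_spec(size = 48, background_amplitude = 0, noise_sd = 0, seed = 1)
  cells <- centroid_set(15, 30, label = "cone", source = "manual")  # off-centre
  attr(cells, "radii") <- 6
  chans <- lapply(spec$azimuths, function(az) render_quadrant_channel(cells, az, spec))
  qset <- quadrant_frame_set(chans, spec$azimuths)
  splits <- directional_splits(qset)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  rot_qset <- quadrant_frame_set(lapply(qset$channels, rot90),
                                 (qset$azimuths + 90) %% 360)
  splits_rot <- directional_splits(rot_qset)
  expect_equal(splits_rot[["0"]]$pixels, rot90(splits[["90"]]$pixels),
               tolerance = 1e-12)
  expect_false(all(splits[["90"]]$pixels == 0))  # non-vacuous
})
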