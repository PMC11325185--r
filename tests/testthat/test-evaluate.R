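test_that("match_centroids implements the greedy taxonomy", {
  # identity: everything matches
  set.seed(1)
  pts <- random_points(30, 100, 5)
  manual <- centroid_set(pts[, 1], pts[, 2], source = "manual")
  auto <- centroid_set(pts[, 1], pts[, 2], source = "automatic")
  m <- match_centroids(auto, manual, 3)
  expect_equal(m$false_negatives, 0L)
  expect_equal(m$false_positives, 0L)
  expect_equal(m$merged, 0L)
  expect_equal(m$true_positives, 30L)

  # one auto missing -> one FN, no FP
  manual2 <- centroid_set(c(0, 20), c(0, 0), source = "manual")
  auto2 <- centroid_set(0, 0, source = "automatic")
  m2 <- match_centroids(auto2, manual2, 3)
  expect_equal(c(m2$true_positives, m2$false_negatives, m2$false_positives),
               c(1L, 1L, 0L))

  # two manual bound to one auto -> merged, both TPs
  manual3 <- centroid_set(c(0, 2), c(0, 0), source = "manual")
  auto3 <- centroid_set(1, 0, source = "automatic")
  m3 <- match_centroids(auto3, manual3, 3)
  expect_equal(m3$merged, 1L)
  expect_equal(m3$true_positives, 2L)
  expect_equal(m3$false_negatives, 0L)

  expect_error(match_centroids(auto3, manual3, -1), "radius")
})

test_that("matching is permutation invariant and conserves counts", {
  set.seed(77)
  for (i in 1:50) {
    nm <- sample(1:20, 1); na <- sample(0:20, 1)
    mx <- runif(nm, 0, 40); my <- runif(nm, 0, 40)
    ax <- runif(na, 0, 40); ay <- runif(na, 0, 40)
    manual <- centroid_set(mx, my, source = "manual")
    auto <- centroid_set(ax, ay, source = "automatic")
    m <- match_centroids(auto, manual, 4)
    expect_equal(m$true_positives + m$false_negatives, nm)
    # shuffle both inputs
    pm <- sample(nm); pa <- if (na > 0) sample(na) else integer(0)
    m2 <- match_centroids(centroid_set(ax[pa], ay[pa], source = "automatic"),
                          centroid_set(mx[pm], my[pm], source = "manual"), 4)
    expect_equal(m2$false_negatives, m$false_negatives)
    expect_equal(m2$false_positives, m$false_positives)
    expect_equal(m2$merged, m$merged)
  }
})

test_that("FN and FP are non-increasing in the match radius", {
  set.seed(99)
  for (i in 1:20) {
    nm <- sample(2:15, 1); na <- sample(1:15, 1)
    manual <- centroid_set(runif(nm, 0, 30), runif(nm, 0, 30), source = "manual")
    auto <- centroid_set(runif(na, 0, 30), runif(na, 0, 30), source = "automatic")
    radii <- sort(runif(4, 0.5, 12))
    res <- lapply(radii, function(r) match_centroids(auto, manual, r))
    fn <- vapply(res, `[[`, integer(1), "false_negatives")
    fp <- vapply(res, `[[`, integer(1), "false_positives")
    expect_true(all(diff(fn) <= 0))
    expect_true(all(diff(fp) <= 0))
  }
})

test_that("the default radius adapts to the manual spacing", {
  manual <- centroid_set(c(0, 10, 20, 30), c(0, 0, 0, 0), source = "manual")
  expect_equal(default_match_radius(manual), 5)
  m <- match_centroids(centroid_set(1, 0), manual)
  expect_equal(m$match_radius, 5)
  expect_error(default_match_radius(centroid_set(1, 1)), "radius")
})

test_that("summarize_match rounds rates under both conventions", {
  mk <- function(n, fn, fp = NA_integer_)
    list(n_manual = n, n_auto = n - fn + ifelse(is.na(fp), 0, fp),
         true_positives = n - fn, false_negatives = fn, false_positives = fp,
         merged = 0L, match_radius = 3)
  r <- summarize_match(mk(752, 8), decimals = 0L)
  expect_equal(r$fn_rate, 1)
  expect_identical(r$fn_rate_label, "1%")
  r2 <- summarize_match(mk(221, 52, 8), decimals = 1L)
  expect_equal(r2$fn_rate, 23.5)
  expect_equal(r2$fp_rate, 3.6)
  # 10/867 = 1.1534%: truncation gives 1.1, half-up gives 1.2
  r3 <- summarize_match(mk(867, 10), decimals = 1L)
  expect_equal(r3$fn_rate, 1.2)
  expect_equal(r3$alt_rounding$fn_rate, 1.1)
  r3t <- summarize_match(mk(867, 10), decimals = 1L, rounding = "truncate")
  expect_equal(r3t$fn_rate, 1.1)
  # zero false negatives
  expect_identical(summarize_match(mk(100, 0), decimals = 0L)$fn_rate_label, "0%")
  expect_error(summarize_match(mk(0, 0)), "n_manual")
})
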