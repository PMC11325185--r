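#' Isotropic Gaussian blur
#'
#' Separable Gaussian smoothing with `sigma = radius` (the blur "radius" of
#' common imaging tools is mapped to the Gaussian sigma; this convention is
#' documented so results are reproducible). Boundaries use replicate
#' padding; `radius = 0` is the identity.
#'
#' @param img [raster_image] or numeric matrix.
#' @param radius blur radius in pixels (`>= 0`).
#' @return A [raster_image].
#' @export
gaussian_blur <- function(img, radius = 2) {
  mat <- as_pixel_matrix(img)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(raster_image(mat))
  half <- max(1L, ceiling(3 * radius))
  k <- stats::dnorm(seq(-half, half), sd = radius)
  k <- k / sum(k)
  acc <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_replicate(mat, 0L, i - half - 1L)
  out <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(acc, i - half - 1L, 0L)
  raster_image(out)
}

# Sampled, normalised 1-D Gaussian kernel (exposed for tests).
gaussian_kernel_1d <- function(radius) {
  half <- max(1L, ceiling(3 * radius))
  k <- stats::dnorm(seq(-half, half), sd = radius)
  k / sum(k)
}

#' Otsu's threshold
#'
#' Maximises between-class variance over a 256-bin histogram spanning the
#' intensity range. Returned value is the upper edge of the chosen bin, so
#' `> cutoff` separates the classes.
#'
#' @param img [raster_image] or numeric matrix with at least two distinct
#'   values.
#' @return The cutoff intensity.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(as_pixel_matrix(img))
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("constant image: no threshold exists")
  h <- intensity_histogram(v, lo, hi, 256L)
  counts <- h$counts
  n <- sum(counts)
  omega <- cumsum(counts) / n
  mu <- cumsum(counts * h$mids) / n
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)  # first maximiser
  h$edges[k + 1L]
}

intensity_histogram <- function(v, lo, hi, nbins) {
  edges <- seq(lo, hi, length.out = nbins + 1L)
  idx <- clip_range(findInterval(v, edges, rightmost.closed = TRUE), 1L, nbins)
  counts <- tabulate(idx, nbins)
  list(counts = counts, edges = edges,
       mids = (edges[-1] + edges[-(nbins + 1L)]) / 2)
}

moving_average_reflect <- function(x, window = 5L) {
  half <- window %/% 2L
  n <- length(x)
  pad <- c(x[half:1], x, x[n:(n - half + 1L)])
  out <- stats::filter(pad, rep(1 / window, window), sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Histogram-trough threshold
#'
#' Emulates choosing the threshold "at the trough between the two peaks" of
#' the intensity histogram: a 256-bin histogram over `[min, max]` is
#' smoothed with a 5-bin moving average (reflected ends); the two highest
#' local maxima separated by at least 10 bins are located, and the cutoff
#' is the intensity of the lowest smoothed bin strictly between them (ties
#' resolved to the median tied bin). The pair only counts as a genuine
#' two-peak histogram when the trough dips below `prominence` times the
#' lower peak — on a unimodal histogram the "second peak" is merely
#' sampling flutter on the flank of the mode and the trough is nearly as
#' tall as it is. Without a genuine trough the function falls back to
#' [otsu_threshold()] with a warning.
#'
#' @param img [raster_image] or numeric matrix with `>= 2` distinct values.
#' @param min_separation minimum peak separation in bins.
#' @param prominence maximum trough-to-lower-peak ratio for the pair to
#'   count as two peaks.
#' @return The cutoff intensity, with attribute `method` set to `"trough"`
#'   or `"otsu"`.
#' @export
trough_threshold <- function(img, min_separation = 10L, prominence = 0.75) {
  v <- as.vector(as_pixel_matrix(img))
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("constant image: no threshold exists")
  h <- intensity_histogram(v, lo, hi, 256L)
  s <- moving_average_reflect(h$counts, 5L)
  n <- length(s)
  # local maxima: strictly above the previous bin, at least level with the
  # next (first bin of a plateau); ends compare against -Inf
  left <- c(-Inf, s[-n]); right <- c(s[-1], -Inf)
  peaks <- which(s > left & s >= right)
  cutoff <- NULL
  if (length(peaks) >= 2L) {
    p1 <- peaks[which.max(s[peaks])]
    far <- setdiff(peaks[abs(peaks - p1) >= min_separation], p1)
    if (length(far) > 0L) {
      p2 <- far[which.max(s[far])]
      between <- (min(p1, p2) + 1L):(max(p1, p2) - 1L)
      vals <- s[between]
      if (min(vals) < prominence * min(s[p1], s[p2])) {
        tied <- between[vals == min(vals)]
        k <- tied[(length(tied) + 1L) %/% 2L]  # median tied index
        cutoff <- h$mids[k]
        attr(cutoff, "method") <- "trough"
      }
    }
  }
  if (is.null(cutoff)) {
    warning("histogram is not bimodal; falling back to Otsu's threshold")
    cutoff <- otsu_threshold(img)
    attr(cutoff, "method") <- "otsu"
  }
  cutoff
}

#' Binarise an image at a cutoff
#'
#' Foreground is `pixels > cutoff`, or `pixels < cutoff` when
#' `invert = TRUE` (for images in which cells are the dark side of the
#' trough).
#'
#' @param img [raster_image] or numeric matrix.
#' @param cutoff threshold intensity.
#' @param invert select the low side of the cutoff instead of the high side.
#' @return A logical matrix.
#' @export
binarize <- function(img, cutoff, invert = FALSE) {
  mat <- as_pixel_matrix(img)
  if (invert) mat < as.numeric(cutoff) else mat > as.numeric(cutoff)
}

#' Watershed separation of a binary mask
#'
#' ImageJ-style binary watershed: the exact Euclidean distance transform of
#' the foreground is smoothed (Gaussian, `sigma = seed_sigma`), its regional
#' maxima become seeds, and the inverted distance map is flooded from the
#' seeds within the mask (4-connected growth), leaving a one-pixel watershed
#' line between touching cells. Adjacent regions whose separating saddle is
#' shallower than `min_depth` below the lower of their two distance peaks
#' are merged back (the maxima-tolerance behaviour of ImageJ's binary
#' watershed, which prevents a single convex blob from being split by
#' spurious secondary maxima). Regions smaller than `min_area` are discarded
#' and the remaining labels renumbered 1..K.
#'
#' @param mask logical matrix (foreground = TRUE).
#' @param min_area minimum region area in px^2.
#' @param seed_sigma Gaussian sigma for distance-map smoothing before seed
#'   extraction.
#' @param min_depth minimum saddle depth (in distance-map units, i.e. px)
#'   for a split between neighbouring regions to stand; the half-pixel
#'   default is the quantisation scale of the distance map, so only
#'   noise-level secondary maxima are suppressed.
#' @return A `label_mask`: integer matrix, 0 = background, 1..K = regions.
#' @export
watershed_split <- function(mask, min_area = 4L, seed_sigma = 1, min_depth = 0.5) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) {
    return(structure(matrix(0L, nrow(mask), ncol(mask)), class = "label_mask"))
  }
  d <- sqrt(cpp_edt_sq(mask))
  ds <- if (seed_sigma > 0) as_pixel_matrix(gaussian_blur(d, seed_sigma)) else d
  seeds <- cpp_regional_maxima(ds, mask)
  lab <- cpp_watershed(-ds, seeds, mask)
  if (min_depth > 0) lab <- merge_shallow_saddles(lab, ds, mask, min_depth)
  sizes <- tabulate(lab[lab > 0L], nbins = max(max(lab), 1L))
  keep <- which(sizes >= min_area)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  structure(lab, class = "label_mask")
}

# Merge watershed regions separated by saddles shallower than min_depth
# below the lower of the two peaks; absorbed watershed-line pixels join the
# merged region. Iterates until no pair qualifies.
merge_shallow_saddles <- function(lab, ds, mask, min_depth) {
  nr <- nrow(lab); nc <- ncol(lab)
  repeat {
    k <- max(lab)
    if (k < 2L) break
    peaks <- vapply(seq_len(k), function(l) max(ds[lab == l]), numeric(1))
    line_idx <- which(mask & lab == 0L)
    if (length(line_idx) == 0L) break
    r <- (line_idx - 1L) %% nr + 1L
    c <- (line_idx - 1L) %/% nr + 1L
    nbr <- function(dr, dc) {
      rr <- clip_range(r + dr, 1L, nr); cc <- clip_range(c + dc, 1L, nc)
      lab[cbind(rr, cc)]
    }
    neigh <- cbind(nbr(-1L, 0L), nbr(1L, 0L), nbr(0L, -1L), nbr(0L, 1L))
    # saddle height per adjacent label pair
    saddle <- list()
    pair_line <- list()
    for (i in seq_along(line_idx)) {
      ls <- unique(neigh[i, ])
      ls <- ls[ls > 0L]
      if (length(ls) < 2L) next
      for (a in seq_along(ls)) for (b in seq_along(ls)) if (a < b) {
        key <- paste(sort(c(ls[a], ls[b])), collapse = "-")
        h <- ds[line_idx[i]]
        if (is.null(saddle[[key]]) || h > saddle[[key]]) saddle[[key]] <- h
        pair_line[[key]] <- c(pair_line[[key]], line_idx[i])
      }
    }
    if (length(saddle) == 0L) break
    # union-find over labels for qualifying pairs
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    merged_any <- FALSE
    absorb <- integer(0)
    for (key in names(saddle)) {
      ab <- as.integer(strsplit(key, "-")[[1]])
      if (saddle[[key]] > min(peaks[ab]) - min_depth) {
        ra <- find(ab[1]); rb <- find(ab[2])
        if (ra != rb) { parent[max(ra, rb)] <- min(ra, rb); merged_any <- TRUE }
        absorb <- c(absorb, pair_line[[key]])
      }
    }
    if (!merged_any) break
    root <- vapply(seq_len(k), find, integer(1))
    new_id <- match(root, sort(unique(root)))
    lab[lab > 0L] <- new_id[lab[lab > 0L]]
    # absorb line pixels that separated now-merged regions
    for (i in unique(absorb)) {
      ri <- (i - 1L) %% nr + 1L; ci <- (i - 1L) %/% nr + 1L
      ls <- c(if (ri > 1L) lab[ri - 1L, ci], if (ri < nr) lab[ri + 1L, ci],
              if (ci > 1L) lab[ri, ci - 1L], if (ci < nc) lab[ri, ci + 1L])
      ls <- unique(ls[ls > 0L])
      if (length(ls) == 1L) lab[i] <- ls
    }
  }
  lab
}

#' Centroids of labelled regions
#'
#' One point per label: either the area centroid of the region's pixels
#' (`"component-centroid"`, the default) or the brightest pixel of a
#' reference intensity image within the region (`"regional-maxima"`,
#' emulating a maxima-based cell finder).
#'
#' @param lm integer label matrix (0 = background) as returned by
#'   [watershed_split()].
#' @param mode centroid definition.
#' @param intensity reference image, required for `"regional-maxima"`.
#' @return A [centroid_set] (source `"automatic"`), ordered by label.
#' @export
find_cell_centroids <- function(lm, mode = c("component-centroid", "regional-maxima"),
                                intensity = NULL) {
  mode <- match.arg(mode)
  lab <- unclass(lm)
  stopifnot(is.matrix(lab))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(centroid_set())
  rows <- (idx - 1L) %% nrow(lab)      # 0-based y
  cols <- (idx - 1L) %/% nrow(lab)     # 0-based x
  labs <- lab[idx]
  if (mode == "component-centroid") {
    xs <- tapply(cols, labs, mean)
    ys <- tapply(rows, labs, mean)
  } else {
    if (is.null(intensity))
      stop("regional-maxima mode requires an intensity image")
    iv <- as_pixel_matrix(intensity)[idx]
    pick <- tapply(seq_along(idx), labs, function(ii) ii[which.max(iv[ii])])
    xs <- cols[pick]; ys <- rows[pick]
  }
  centroid_set(as.numeric(xs), as.numeric(ys), source = "automatic")
}

#' Detection parameters
#'
#' Bundles the tunables of [detect_cells()] with validation. Defaults
#' mirror the published routine where printed (blur radius 2 px) and the
#' package's documented conventions elsewhere.
#'
#' @param blur_radius Gaussian blur radius (sigma) in px, `>= 0`.
#' @param threshold `"auto"` (histogram trough), `"otsu"`, or a fixed
#'   numeric cutoff.
#' @param min_area minimum region area in px^2, `>= 1`.
#' @param maxima_mode centroid definition, see [find_cell_centroids()].
#' @param invert binarisation polarity, see [binarize()]. The default
#'   `TRUE` selects the low side of the trough: in a MinIP of four embossed
#'   directional images every cell is darkened by at least one direction,
#'   so cell interiors are the dark blobs against the mid-grey background.
#' @return A `detection_params` list.
#' @export
detection_params <- function(blur_radius = 2, threshold = "auto",
                             min_area = 4L, maxima_mode = "component-centroid",
                             invert = TRUE) {
  if (blur_radius < 0) stop("blur_radius must be >= 0")
  if (min_area < 1) stop("min_area must be >= 1")
  if (is.character(threshold) && !threshold %in% c("auto", "otsu"))
    stop("threshold must be \"auto\", \"otsu\" or a numeric cutoff")
  maxima_mode <- match.arg(maxima_mode, c("component-centroid", "regional-maxima"))
  structure(list(blur_radius = blur_radius, threshold = threshold,
                 min_area = as.integer(min_area), maxima_mode = maxima_mode,
                 invert = isTRUE(invert)),
            class = "detection_params")
}

#' Detect cell centroids in an enhanced image
#'
#' The simple detection routine: Gaussian blur, histogram-trough threshold,
#' binarisation, watershed separation of touching cells, then one centroid
#' per labelled region. Per-stage statistics (cutoff used, region counts
#' before and after the area filter) are attached as the `detect_log`
#' attribute and optionally reported via `message()`.
#'
#' @param img an `enhanced_image`, [raster_image] or numeric matrix.
#' @param params a [detection_params()] bundle.
#' @param verbose emit per-stage messages.
#' @return A [centroid_set] with a `detect_log` attribute.
#' @export
detect_cells <- function(img, params = detection_params(), verbose = FALSE) {
  stopifnot(inherits(params, "detection_params"))
  mat <- if (inherits(img, "enhanced_image")) img$pixels else as_pixel_matrix(img)
  blurred <- gaussian_blur(mat, params$blur_radius)
  cutoff <- if (is.numeric(params$threshold)) params$threshold
            else if (params$threshold == "otsu") otsu_threshold(blurred)
            else trough_threshold(blurred)
  mask <- binarize(blurred, cutoff, invert = params$invert)
  pre_regions <- max(cpp_label_components(mask, 4L))
  lab <- watershed_split(mask, min_area = params$min_area)
  cents <- find_cell_centroids(lab, mode = params$maxima_mode, intensity = blurred)
  log <- list(cutoff = as.numeric(cutoff),
              threshold_method = attr(cutoff, "method") %||% "fixed",
              n_components = pre_regions,
              n_regions = max(unclass(lab), 0L))
  if (verbose)
    message(sprintf("detect_cells: cutoff %.3f (%s), %d components -> %d regions",
                    log$cutoff, log$threshold_method, log$n_components, log$n_regions))
  attr(cents, "detect_log") <- log
  cents
}

`%||%` <- function(a, b) if (is.null(a)) b else a
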