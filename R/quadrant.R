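#' Quadrant frame set
#'
#' The raw input of the pipeline: four co-registered, averaged grayscale
#' channels recorded simultaneously by four off-axis (non-confocal)
#' detectors, together with each detector's azimuth. Azimuths are measured
#' counter-clockwise from the +x axis with y pointing up (standard math
#' orientation); the default layout centres the detectors on the diagonals
#' at 45, 135, 225 and 315 degrees.
#'
#' @param channels list of four [raster_image]s or numeric matrices with
#'   identical dimensions and non-negative pixels.
#' @param azimuths numeric vector of four pairwise-distinct detector
#'   azimuths in `[0, 360)` degrees.
#' @return A `quadrant_frame_set`.
#' @export
quadrant_frame_set <- function(channels, azimuths = c(45, 135, 225, 315)) {
  if (length(channels) != 4L) stop("exactly 4 channels are required")
  mats <- lapply(channels, as_pixel_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all four channels must have identical dimensions")
  if (any(vapply(mats, min, numeric(1)) < 0))
    stop("channel intensities must be non-negative")
  azimuths <- as.numeric(azimuths) %% 360
  if (length(azimuths) != 4L || anyDuplicated(azimuths))
    stop("azimuths must be four pairwise-distinct angles in [0, 360)")
  if (any(vapply(mats, mean, numeric(1)) <= 0))
    stop("each channel mean must be > 0")
  names(mats) <- paste0("Q", seq_len(4L))
  structure(list(channels = mats, azimuths = azimuths),
            class = "quadrant_frame_set")
}

#' @export
print.quadrant_frame_set <- function(x, ...) {
  cat(sprintf("<quadrant_frame_set %d x %d px, azimuths %s>\n",
              ncol(x$channels[[1]]), nrow(x$channels[[1]]),
              paste(x$azimuths, collapse = "/")))
  invisible(x)
}

#' Balance channel means
#'
#' Rescales each channel multiplicatively so that all four means equal the
#' grand mean of the input channel means, emulating the photomultiplier-gain
#' balancing performed by the instrument operator during acquisition.
#' Relative contrast within each channel is preserved; the operation is
#' idempotent.
#'
#' @param qset a [quadrant_frame_set].
#' @param eps channels with mean `<= eps` raise a degenerate-channel error.
#' @return A balanced [quadrant_frame_set].
#' @export
normalize_quadrant_means <- function(qset, eps = 1e-9) {
  stopifnot(inherits(qset, "quadrant_frame_set"))
  means <- vapply(qset$channels, mean, numeric(1))
  if (any(means <= eps))
    stop("degenerate channel: mean <= ", format(eps))
  grand <- mean(means)
  qset$channels <- lapply(seq_len(4L), function(i)
    qset$channels[[i]] * (grand / means[i]))
  names(qset$channels) <- paste0("Q", seq_len(4L))
  qset
}

#' Split-detection image from two detector groups
#'
#' Computes the pixel-wise normalised difference `S = (A - B) / (A + B)`,
#' the classical split-detection contrast. Pixels where `A + B = 0` are set
#' to 0 and flagged in `undefined_mask` (rather than NaN), so downstream
#' filters stay total.
#'
#' @param A,B [raster_image]s or non-negative numeric matrices of identical
#'   dimensions (each may already be a sum of channels).
#' @param axis_angle optional split-axis angle in degrees, recorded on the
#'   result; the contrast gradient runs orthogonal to this axis.
#' @return A `split_image`: list with `pixels` in `[-1, 1]`, `axis_angle`,
#'   and logical `undefined_mask`.
#' @export
split_image <- function(A, B, axis_angle = NA_real_) {
  A <- as_pixel_matrix(A); B <- as_pixel_matrix(B)
  if (!identical(dim(A), dim(B))) stop("shape mismatch between A and B")
  if (min(A) < 0 || min(B) < 0) stop("inputs must be non-negative")
  denom <- A + B
  undef <- denom == 0
  s <- (A - B) / ifelse(undef, 1, denom)
  s[undef] <- 0
  structure(list(pixels = s, axis_angle = axis_angle, undefined_mask = undef),
            class = "split_image")
}

#' @export
print.split_image <- function(x, ...) {
  cat(sprintf("<split_image %d x %d px, axis %s deg, %d undefined px>\n",
              ncol(x$pixels), nrow(x$pixels), format(x$axis_angle),
              sum(x$undefined_mask)))
  invisible(x)
}

#' Default axis-to-detector mapping
#'
#' With detectors centred on the diagonals, a cardinal split axis cleanly
#' separates two detector pairs, while a diagonal axis passes through two
#' detectors and leaves a single opposing pair on each side. The axis angle
#' names the dividing line, so the vertical (90 degree) axis performs the
#' legacy left-versus-right split.
#'
#' @param azimuths the four detector azimuths (degrees); the default layout
#'   is 45/135/225/315.
#' @return Named list with one entry per axis (`"0"`, `"45"`, `"90"`,
#'   `"135"`), each a list of `pos` and `neg` detector azimuths.
#' @export
default_axis_mapping <- function(azimuths = c(45, 135, 225, 315)) {
  if (!setequal(azimuths %% 360, c(45, 135, 225, 315)))
    stop("the default mapping requires detector azimuths 45/135/225/315; ",
         "supply an explicit mapping for other layouts")
  list(`0`   = list(pos = c(45, 135), neg = c(225, 315)),
       `45`  = list(pos = 135,        neg = 315),
       `90`  = list(pos = c(45, 315), neg = c(135, 225)),
       `135` = list(pos = 45,         neg = 225))
}

#' Directional split-detection images along four axes
#'
#' Forms, for each split axis, the difference-over-sum of the summed
#' channels on its two sides, yielding the legacy vertical split plus the
#' horizontal and two diagonal splits afforded by quadrant detection.
#'
#' @param qset a [quadrant_frame_set] (typically mean-balanced first).
#' @param mapping per-axis side mapping as produced by
#'   [default_axis_mapping()]; sides must be disjoint, non-empty and refer
#'   to azimuths present in `qset`.
#' @return Named list of four [split_image]s keyed by axis angle.
#' @export
directional_splits <- function(qset, mapping = default_axis_mapping(qset$azimuths)) {
  stopifnot(inherits(qset, "quadrant_frame_set"))
  if (length(mapping) != 4L) stop("mapping must cover exactly four axes")
  chan_by_az <- function(az) {
    idx <- match(az %% 360, qset$azimuths)
    if (anyNA(idx))
      stop("mapping references unknown channel azimuth: ",
           paste(az[is.na(idx)], collapse = ", "))
    idx
  }
  out <- lapply(names(mapping), function(axis_name) {
    side <- mapping[[axis_name]]
    if (length(side$pos) == 0L || length(side$neg) == 0L)
      stop("axis ", axis_name, ": both sides must be non-empty")
    if (length(intersect(side$pos %% 360, side$neg %% 360)) > 0L)
      stop("axis ", axis_name, ": sides must be disjoint")
    ip <- chan_by_az(side$pos); im <- chan_by_az(side$neg)
    A <- Reduce(`+`, qset$channels[ip])
    B <- Reduce(`+`, qset$channels[im])
    split_image(A, B, axis_angle = as.numeric(axis_name))
  })
  names(out) <- names(mapping)
  out
}
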