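#' Map a split image to display range
#'
#' Affine map of the signed contrast `[-1, 1]` onto the 8-bit display range
#' `[0, 255]`: `p = 127.5 * (s + 1)`. Undefined (zero-denominator) pixels
#' map to the mid-grey 127.5.
#'
#' @param s a [split_image].
#' @return A [raster_image] with values in `[0, 255]`.
#' @export
to_display_range <- function(s) {
  stopifnot(inherits(s, "split_image"))
  p <- 127.5 * (s$pixels + 1)
  p[s$undefined_mask] <- 127.5
  raster_image(p)
}

#' Quantise to 8-bit levels
#'
#' Rounds half-to-even after clipping to `[0, 255]`, mirroring a single
#' pass through an 8-bit editing stage. Applied once, between display
#' mapping and emboss filtering, in the standard pipeline.
#'
#' @param img [raster_image] or matrix.
#' @return A [raster_image] with integer-valued pixels in `[0, 255]`.
#' @export
quantize_8bit <- function(img) {
  raster_image(round(clip_range(as_pixel_matrix(img), 0, 255)))
}

#' Directional emboss filter
#'
#' A mid-grey-offset directional finite difference:
#' `E(x, y) = clip_0_255(128 + (amount/100) * (I(x, y) - I(x + dx, y + dy)))`
#' with `(dx, dy) = (round(height * cos(angle)), round(-height * sin(angle)))`.
#' Angles are degrees counter-clockwise from +x in math orientation; since
#' image y runs downward, `dy` carries the minus sign. Out-of-bounds samples
#' replicate the nearest edge pixel, so a constant image maps to constant
#' 128 and edges gain no spurious dark frame.
#'
#' @param img [raster_image] or numeric matrix.
#' @param height integer pixel offset `>= 1` (the filter's "height").
#' @param amount gain in percent (`> 0`); 150 reproduces a 150% setting.
#' @param angle direction in degrees.
#' @return A [raster_image] with values in `[0, 255]`.
#' @export
emboss <- function(img, height = 5L, amount = 150, angle = 0) {
  mat <- as_pixel_matrix(img)
  if (height < 1) stop("height must be >= 1")
  if (amount <= 0) stop("amount must be > 0")
  dx <- round(height * cospi(angle / 180))
  dy <- round(-height * sinpi(angle / 180))
  if (abs(dx) >= ncol(mat) || abs(dy) >= nrow(mat))
    stop("emboss height (", height, ") offsets beyond the image extent")
  e <- 128 + (amount / 100) * (mat - shift_replicate(mat, dx, dy))
  raster_image(clip_range(e, 0, 255))
}

#' Emboss angle orthogonal to a split axis
#'
#' The split axis names the dividing line between the detector groups; the
#' contrast gradient, and therefore the emboss direction, is orthogonal to
#' it. `polarity` selects which of the two orthogonal directions is used
#' (the side of the dark cell border, which depends on the physical
#' detector layout).
#'
#' @param axis_angle one of 0, 45, 90, 135 (degrees).
#' @param polarity `+1` or `-1`.
#' @return The emboss direction `(axis_angle + polarity * 90) mod 360`.
#' @export
emboss_angle_for_axis <- function(axis_angle, polarity = 1L) {
  if (!axis_angle %in% c(0, 45, 90, 135))
    stop("invalid split axis: ", axis_angle)
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  (axis_angle + polarity * 90) %% 360
}

#' Emboss the four directional split images
#'
#' Maps each split image to display range, optionally quantises to 8-bit
#' (the default, mirroring the 8-bit editing stage of the original
#' workflow), then applies the emboss filter orthogonally to each split
#' axis with shared height and amount.
#'
#' Default per-axis emboss polarity
#'
#' Under [default_axis_mapping()] the bright border of each split image
#' lies at `axis + 90` degrees for the 0 and 45 degree axes and at
#' `axis - 90` for the 90 and 135 degree axes (the side holding the
#' positive detector group). Embossing along each axis's own bright-border
#' direction darkens every cell interior consistently in all four images,
#' which is what makes the MinIP fusion render cells as uniform dark blobs.
#'
#' @param axis_angle one of 0, 45, 90, 135.
#' @return `+1` or `-1`.
#' @export
default_emboss_polarity <- function(axis_angle) {
  if (!axis_angle %in% c(0, 45, 90, 135))
    stop("invalid split axis: ", axis_angle)
  if (axis_angle %in% c(0, 45)) 1L else -1L
}

#' @param splits list of four [split_image]s with pairwise-distinct axes.
#' @param height,amount emboss parameters shared across axes (defaults 5 px
#'   and 150%).
#' @param polarity emboss direction selector, `+1` or `-1` (see
#'   [emboss_angle_for_axis()]); a single value applied to all axes, a
#'   vector of four per-axis values, or `NULL` (default) for the per-axis
#'   [default_emboss_polarity()].
#' @param quantize quantise the display images to 8 bits before embossing;
#'   set `FALSE` for an all-float pipeline.
#' @return List of four embossed [raster_image]s; each carries its axis and
#'   emboss angle as attributes.
#' @export
enhance_stack <- function(splits, height = 5L, amount = 150, polarity = NULL,
                          quantize = TRUE) {
  if (length(splits) != 4L) stop("expected four split images")
  axes <- vapply(splits, function(s) s$axis_angle, numeric(1))
  if (anyDuplicated(axes)) stop("split axes must be pairwise distinct")
  pol <- if (is.null(polarity)) vapply(axes, default_emboss_polarity, integer(1))
         else rep_len(as.integer(polarity), 4L)
  out <- lapply(seq_along(splits), function(i) {
    s <- splits[[i]]
    disp <- to_display_range(s)
    if (quantize) disp <- quantize_8bit(disp)
    ang <- emboss_angle_for_axis(s$axis_angle, pol[i])
    e <- emboss(disp, height = height, amount = amount, angle = ang)
    attr(e, "axis_angle") <- s$axis_angle
    attr(e, "emboss_angle") <- ang
    e
  })
  names(out) <- names(splits)
  out
}

#' Minimum intensity projection
#'
#' Per-pixel minimum over a stack of images: the fusion step that combines
#' the four embossed directional images into one, keeping each cell's dark
#' border from whichever direction rendered it.
#'
#' @param stack non-empty list of [raster_image]s or matrices with
#'   identical dimensions.
#' @return An `enhanced_image`: list with `pixels` and `provenance` (the
#'   source axis angles, when available).
#' @export
minip <- function(stack) {
  if (length(stack) == 0L) stop("empty stack")
  mats <- lapply(stack, as_pixel_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch within stack")
  px <- Reduce(pmin, mats)
  prov <- vapply(stack, function(im) {
    a <- attr(im, "axis_angle")
    if (is.null(a)) NA_real_ else a
  }, numeric(1))
  structure(list(pixels = px, provenance = prov), class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image %d x %d px, MinIP of axes %s>\n",
              ncol(x$pixels), nrow(x$pixels),
              paste(format(x$provenance), collapse = "/")))
  invisible(x)
}

#' Full enhancement chain for a quadrant frame set
#'
#' Convenience wrapper: balance channel means, compute the four directional
#' splits, emboss each orthogonally to its axis, and fuse by MinIP.
#'
#' @inheritParams enhance_stack
#' @param qset a [quadrant_frame_set].
#' @param mapping axis mapping, see [directional_splits()].
#' @return An `enhanced_image`.
#' @export
enhance_quadrants <- function(qset, mapping = default_axis_mapping(qset$azimuths),
                              height = 5L, amount = 150, polarity = NULL,
                              quantize = TRUE) {
  qset <- normalize_quadrant_means(qset)
  splits <- directional_splits(qset, mapping)
  minip(enhance_stack(splits, height = height, amount = amount,
                      polarity = polarity, quantize = quantize))
}
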