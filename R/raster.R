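#' Raster image container
#'
#' A minimal grayscale image container: a numeric matrix of intensities plus
#' an optional physical pixel scale. The matrix is stored in row-major image
#' orientation: `pixels[r, c]` is the pixel in image row `r` (from the top)
#' and column `c` (from the left).
#'
#' Coordinate convention used throughout the package: `x` is the column and
#' `y` the row, the origin is the top-left pixel, `y` increases downward, and
#' pixel centres sit at integer coordinates starting from 0 — pixel
#' `(x, y) = (0, 0)` is `pixels[1, 1]`.
#'
#' @param pixels numeric matrix of finite, typically non-negative intensities.
#' @param pixel_scale optional physical scale in micrometres per pixel.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_scale = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("all pixel intensities must be finite")
  if (!is.null(pixel_scale)) {
    pixel_scale <- as.numeric(pixel_scale)
    if (length(pixel_scale) != 1L || !is.finite(pixel_scale) || pixel_scale <= 0)
      stop("`pixel_scale` must be a single positive number (um/px)")
  }
  structure(list(pixels = pixels, pixel_scale = pixel_scale),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d px", ncol(x$pixels), nrow(x$pixels)))
  if (!is.null(x$pixel_scale)) cat(sprintf(", %.4g um/px", x$pixel_scale))
  cat(sprintf(", range [%.4g, %.4g]>\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

# Coerce raster_image-or-matrix to a plain numeric matrix.
as_pixel_matrix <- function(img) {
  if (inherits(img, "raster_image")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a raster_image or a numeric matrix")
}

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shift an image by an integer offset with replicate padding
#'
#' Returns a matrix whose value at pixel `(x, y)` is the input at
#' `(x + dx, y + dy)`, with out-of-bounds samples taken from the nearest
#' edge pixel.
#'
#' @param mat numeric matrix.
#' @param dx,dy integer offsets in the x (column) and y (row) directions.
#' @return A matrix with the same dimensions as `mat`.
#' @keywords internal
shift_replicate <- function(mat, dx, dy) {
  nr <- nrow(mat); nc <- ncol(mat)
  rows <- clip_range(seq_len(nr) + as.integer(dy), 1L, nr)
  cols <- clip_range(seq_len(nc) + as.integer(dx), 1L, nc)
  mat[rows, cols, drop = FALSE]
}
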