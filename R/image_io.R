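#' Read a grayscale image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG into a [raster_image].
#' Stored integer intensities are kept as-is (converted to double, never
#' rescaled). If a JSON sidecar `<path>.json` exists with a
#' `pixel_scale_um` field, the pixel scale is attached.
#'
#' @param path path to a `.tif`, `.tiff` or `.png` file.
#' @return A [raster_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mat <- switch(ext,
                png = read_png_gray(path),
                tif = ,
                tiff = read_tiff_gray(path),
                stop("unsupported format: .", ext,
                     " (expected single-channel 8/16-bit TIFF or PNG)"))
  scale <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$pixel_scale_um)) scale <- as.numeric(meta$pixel_scale_um)
  }
  raster_image(mat + 0.0, pixel_scale = scale)
}

#' Write a grayscale image
#'
#' Writes a [raster_image] (or numeric matrix) losslessly as single-channel
#' TIFF or PNG, chosen by file extension. Values outside
#' `[0, 2^bit_depth - 1]` are clipped; non-integer values are rounded
#' half-to-even. Quantisation happens only here, at the file boundary.
#'
#' @param img a [raster_image] or numeric matrix.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 16L) {
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  mat <- as_pixel_matrix(img)
  mat <- round(clip_range(mat, 0, 2^bit_depth - 1))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = write_png_gray(mat, path, bit_depth),
         tif = ,
         tiff = write_tiff_gray(mat, path, bit_depth),
         stop("unsupported format: .", ext))
  invisible(path)
}

#' Centroid set
#'
#' A set of sub-pixel cell-centre coordinates with per-point cell-type
#' labels, represented as a data frame with columns `x`, `y`, `label` plus
#' `source` and `pixel_scale` attributes. Coordinates follow the package
#' convention (x = column, y = row, origin top-left, 0-based).
#'
#' @param x,y numeric coordinate vectors (pixels), equal length, `>= 0`.
#' @param label per-point cell type: `"cone"`, `"rod"` or `"any"` (recycled).
#' @param source `"automatic"` or `"manual"`.
#' @param pixel_scale optional um/px.
#' @return A `centroid_set` (data frame).
#' @export
centroid_set <- function(x = numeric(), y = numeric(), label = "any",
                         source = c("automatic", "manual"), pixel_scale = NULL) {
  source <- match.arg(source)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("centroid coordinates must be finite")
  if (any(x < 0) || any(y < 0)) stop("negative coordinates are not allowed")
  label <- rep_len(as.character(label), length(x))
  bad <- !label %in% c("cone", "rod", "any")
  if (any(bad)) stop("unknown label(s): ", paste(unique(label[bad]), collapse = ", "))
  if (length(x) > 1L) {
    d <- stats::dist(cbind(x, y))
    if (min(d) < 1e-6) stop("duplicate points closer than 1e-6 px")
  }
  df <- data.frame(x = x, y = y, label = label, stringsAsFactors = FALSE)
  structure(df, source = source, pixel_scale = pixel_scale,
            class = c("centroid_set", "data.frame"))
}

#' Read centroids from CSV
#'
#' Expects a comma-separated UTF-8 file with a header and columns
#' `x,y[,label]`. A missing label column maps every point to `"any"`.
#'
#' @param path CSV path.
#' @param source provenance tag for the resulting set.
#' @return A [centroid_set].
#' @export
read_centroids <- function(path, source = c("automatic", "manual")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("malformed centroid CSV: header must contain columns x,y")
  xs <- suppressWarnings(as.numeric(df$x))
  ys <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad) > 0L)
    stop("malformed centroid row at line ", bad[1] + 1L, " of ", path)
  label <- if ("label" %in% names(df)) df$label else "any"
  centroid_set(xs, ys, label = label, source = source)
}

#' Write centroids to CSV
#'
#' @param cs a [centroid_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(cs, path) {
  stopifnot(inherits(cs, "centroid_set"))
  df <- data.frame(x = cs$x, y = cs$y, label = cs$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
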