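# Minimal baseline TIFF codec: single-channel grayscale, 8/16-bit,
# uncompressed. The writer emits little-endian, single-strip files; the
# reader accepts either byte order and multi-strip layouts but rejects
# compressed or multi-sample images.

tiff_tag_entry <- function(tag, type, count, value_or_offset) {
  # type 3 = SHORT, 4 = LONG; values that fit are stored inline, left-justified
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3L) c(writeBin(as.integer(value_or_offset), raw(), size = 2,
                               endian = "little"), as.raw(c(0, 0)))
    else writeBin(as.integer(value_or_offset), raw(), size = 4, endian = "little"))
}

write_tiff_gray <- function(mat, path, bit_depth) {
  h <- nrow(mat); w <- ncol(mat)
  n_entries <- 9L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  n_bytes <- h * w * (bit_depth %/% 8L)
  entries <- c(
    tiff_tag_entry(256L, 4L, 1L, w),            # ImageWidth
    tiff_tag_entry(257L, 4L, 1L, h),            # ImageLength
    tiff_tag_entry(258L, 3L, 1L, bit_depth),    # BitsPerSample
    tiff_tag_entry(259L, 3L, 1L, 1L),           # Compression: none
    tiff_tag_entry(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    tiff_tag_entry(273L, 4L, 1L, data_offset),  # StripOffsets
    tiff_tag_entry(277L, 3L, 1L, 1L),           # SamplesPerPixel
    tiff_tag_entry(278L, 4L, 1L, h),            # RowsPerStrip
    tiff_tag_entry(279L, 4L, 1L, n_bytes)       # StripByteCounts
  )
  vals <- as.integer(t(mat))  # row-major
  pix <- if (bit_depth == 8L) as.raw(vals)
         else writeBin(vals, raw(), size = 2, endian = "little")
  out <- c(charToRaw("II"), writeBin(42L, raw(), size = 2, endian = "little"),
           writeBin(ifd_offset, raw(), size = 4, endian = "little"),
           writeBin(n_entries, raw(), size = 2, endian = "little"),
           entries,
           writeBin(0L, raw(), size = 4, endian = "little"),  # no next IFD
           pix)
  writeBin(out, path)
  invisible(path)
}

read_uint <- function(bytes, pos, size, endian) {
  b <- as.numeric(bytes[pos:(pos + size - 1L)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1L))
}

read_tiff_gray <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  order_mark <- rawToChar(bytes[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (read_uint(bytes, 3L, 2L, endian) != 42) stop("not a TIFF file: ", path)
  ifd <- read_uint(bytes, 5L, 4L, endian)
  n_entries <- read_uint(bytes, ifd + 1L, 2L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    pos <- ifd + 3L + (i - 1L) * 12L
    tag <- read_uint(bytes, pos, 2L, endian)
    type <- read_uint(bytes, pos + 2L, 2L, endian)
    count <- read_uint(bytes, pos + 4L, 4L, endian)
    size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
    if (is.na(size)) next  # skip rationals and other types we never need
    inline <- count * size <= 4L
    base <- if (inline) pos + 8L else read_uint(bytes, pos + 8L, 4L, endian) + 1L
    vals <- vapply(seq_len(count) - 1L, function(k)
      read_uint(bytes, base + k * size, size, endian), numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("corrupt TIFF: missing tag ", tag)
      v <- default
    }
    v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 1L)
  if (length(bits) != 1L || !bits %in% c(8, 16))
    stop("unsupported format: TIFF bit depth must be 8 or 16, single channel")
  if (need(259L, 1L) != 1) stop("unsupported format: compressed TIFF")
  if (need(277L, 1L) != 1)
    stop("unsupported format: only single-channel grayscale TIFF is supported")
  photometric <- need(262L, 1L)
  if (!photometric %in% c(0, 1))
    stop("unsupported format: TIFF photometric interpretation ", photometric)
  offsets <- need(273L)
  counts <- need(279L, h * w * bits / 8)
  raw_px <- do.call(c, lapply(seq_along(offsets), function(i)
    bytes[(offsets[i] + 1L):(offsets[i] + counts[i])]))
  vals <- if (bits == 8) as.integer(raw_px)
          else readBin(raw_px, "integer", n = length(raw_px) / 2L, size = 2L,
                       signed = FALSE, endian = endian)
  if (length(vals) != h * w) stop("corrupt TIFF pixel data")
  if (photometric == 0) vals <- (2^bits - 1) - vals  # WhiteIsZero
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
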