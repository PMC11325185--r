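# Minimal grayscale PNG codec (colour type 0, bit depth 8/16, no interlace).
# PNG's IDAT payload is a zlib stream, which base R's memCompress/memDecompress
# ("gzip" type) produce and consume; chunk CRCs are computed in C.

png_signature <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))

uint32_be <- function(n) {
  n <- as.numeric(n)
  as.raw(c(n %/% 16777216, n %/% 65536, n %/% 256, n) %% 256)
}

be_to_uint32 <- function(b) {
  sum(as.numeric(b) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body)
  c(uint32_be(length(data)), body, uint32_be(crc))
}

# mat: integer-valued numeric matrix already clipped to [0, 2^depth - 1]
write_png_gray <- function(mat, path, bit_depth) {
  h <- nrow(mat); w <- ncol(mat)
  vals <- as.integer(t(mat))  # row-major pixel order
  if (bit_depth == 8L) {
    rows <- matrix(as.raw(vals), nrow = w, ncol = h)
  } else {
    hi <- vals %/% 256L; lo <- vals %% 256L
    rows <- matrix(as.raw(rbind(hi, lo)), nrow = 2L * w, ncol = h)
  }
  stream <- as.vector(rbind(as.raw(0L), rows))  # filter byte 0 per scanline
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(c(bit_depth, 0, 0, 0, 0)))
  out <- c(png_signature,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(stream, "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

paeth_predict <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

# Undo one scanline's filter. cur, prev: integer vectors of reconstructed
# bytes (prev all 0 for the first row). bpp: bytes per pixel.
png_unfilter_row <- function(ftype, cur, prev, bpp) {
  n <- length(cur)
  if (ftype == 0L) return(cur)
  if (ftype == 2L) return((cur + prev) %% 256L)
  out <- integer(n)
  for (i in seq_len(n)) {
    left <- if (i > bpp) out[i - bpp] else 0L
    up <- prev[i]
    ul <- if (i > bpp) prev[i - bpp] else 0L
    pred <- switch(as.character(ftype),
                   "1" = left,
                   "3" = (left + up) %/% 2L,
                   "4" = paeth_predict(left, up, ul),
                   stop("invalid PNG filter type ", ftype))
    out[i] <- (cur[i] + pred) %% 256L
  }
  out
}

read_png_gray <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8L || !identical(bytes[1:8], png_signature))
    stop("not a PNG file: ", path)
  pos <- 9L
  idat <- list()
  ihdr <- NULL
  while (pos + 8L <= length(bytes)) {
    len <- be_to_uint32(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    pos <- pos + 12L + len  # length + type + data + crc
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
  }
  if (is.null(ihdr)) stop("corrupt PNG: missing IHDR")
  w <- be_to_uint32(ihdr[1:4]); h <- be_to_uint32(ihdr[5:8])
  bit_depth <- as.integer(ihdr[9]); colour_type <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (colour_type != 0L)
    stop("unsupported format: only single-channel grayscale PNG is supported")
  if (!bit_depth %in% c(8L, 16L))
    stop("unsupported format: PNG bit depth must be 8 or 16")
  if (interlace != 0L) stop("unsupported format: interlaced PNG")
  stream <- as.integer(memDecompress(do.call(c, idat), "gzip"))
  bpp <- bit_depth %/% 8L
  rowbytes <- w * bpp
  if (length(stream) != h * (rowbytes + 1L)) stop("corrupt PNG pixel stream")
  mat <- matrix(0, nrow = h, ncol = w)
  prev <- integer(rowbytes)
  for (r in seq_len(h)) {
    off <- (r - 1L) * (rowbytes + 1L)
    recon <- png_unfilter_row(stream[off + 1L], stream[(off + 2L):(off + 1L + rowbytes)],
                              prev, bpp)
    prev <- recon
    mat[r, ] <- if (bpp == 1L) recon
                else recon[seq(1L, rowbytes, 2L)] * 256L + recon[seq(2L, rowbytes, 2L)]
  }
  mat
}
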