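# Shared fixtures and independent oracles for the test suite.

# Naive per-pixel emboss reference: the independent oracle the fast
# implementation is checked against. Deliberately written as a double loop
# with explicit edge clamping.
naive_emboss <- function(mat, height, amount, angle) {
  nr <- nrow(mat); nc <- ncol(mat)
  dx <- round(height * cospi(angle / 180))
  dy <- round(-height * sinpi(angle / 180))
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- min(max(r + dy, 1L), nr)
      c2 <- min(max(c + dx, 1L), nc)
      v <- 128 + (amount / 100) * (mat[r, c] - mat[r2, c2])
      out[r, c] <- min(max(v, 0), 255)
    }
  }
  out
}

# A single centred cell rendered through the full quadrant forward model.
single_cell_fixture <- function(size = 64, radius = 5, noise_sd = 0, seed = 1) {
  spec <- mosaic_spec(size = size, background_amplitude = 0,
                      noise_sd = noise_sd, seed = seed)
  centre <- (size - 1) / 2
  cells <- centroid_set(centre, centre, label = "cone", source = "manual")
  attr(cells, "radii") <- radius
  set.seed(seed)
  chans <- lapply(spec$azimuths, function(az)
    render_quadrant_channel(cells, az, spec, noise = noise_sd > 0))
  list(qset = quadrant_frame_set(chans, spec$azimuths),
       centre = centre, radius = radius, spec = spec)
}

# Binary disk mask helper (0-based centre coordinates).
disk_mask <- function(size, cx, cy, r) {
  X <- matrix(0:(size - 1), size, size, byrow = TRUE)
  Y <- matrix(0:(size - 1), size, size)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

# Random centroid scatter within a box, min spacing enforced by rejection.
random_points <- function(n, size, min_spacing = 0) {
  pts <- matrix(numeric(0), ncol = 2)
  guard <- 0L
  while (nrow(pts) < n && guard < 50000L) {
    guard <- guard + 1L
    p <- stats::runif(2, 0, size)
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_spacing)
      pts <- rbind(pts, p)
  }
  pts
}
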