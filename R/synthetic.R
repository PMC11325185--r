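#' Synthetic mosaic specification
#'
#' Describes a synthetic photoreceptor mosaic and its quadrant-detection
#' forward model: circular cells whose shading follows a hemispherical-cap
#' surface viewed by four off-axis detectors (producing the opposed
#' bright/dark semicircle contrast of split detection), a shared
#' low-spatial-frequency background emulating retinal pigment epithelium
#' back-scatter, and per-channel noise.
#'
#' Defaults describe a parafoveal mosaic at the density reported for the
#' conditions this model emulates: a centre-to-centre pitch of 16 px
#' (roughly 750 cells in a 400 px square) with 5 px cell radii, so cell
#' borders remain resolvable between neighbours.
#'
#' @param size image side in px (square), `>= 32`.
#' @param placement `"hex"` (jittered hexagonal lattice) or `"poisson"`
#'   (Poisson-disc via dart throwing).
#' @param pitch hex lattice pitch in px.
#' @param jitter_sd positional jitter sd in px (hex mode); must not exceed
#'   0.2 * pitch.
#' @param min_spacing minimum centre spacing in px (poisson mode).
#' @param n_cells target cell count (poisson mode; `NULL` = saturate).
#' @param radius_mean,radius_sd cone-like cell radius distribution in px.
#' @param rod_fraction fraction of cells drawn from the rod-like population.
#' @param rod_radius_mean,rod_radius_sd rod-like radius distribution in px.
#' @param rim_amplitude shading amplitude in intensity units.
#' @param base_level background intensity level.
#' @param background_amplitude sd of the low-frequency background field
#'   (0 disables it).
#' @param background_wavelength characteristic background scale in px; the
#'   field is white noise smoothed with `sigma = background_wavelength / 4`.
#' @param noise_sd additive Gaussian noise sd per channel.
#' @param poisson_noise replace each clean pixel value by a Poisson draw
#'   with that mean (photon noise) before additive noise.
#' @param azimuths four detector azimuths in degrees.
#' @param seed integer seed recorded in the spec and used by default.
#' @return A `mosaic_spec` list.
#' @export
mosaic_spec <- function(size = 176L, placement = c("hex", "poisson"),
                        pitch = 16, jitter_sd = 1, min_spacing = 13,
                        n_cells = NULL,
                        radius_mean = 5, radius_sd = 0.5,
                        rod_fraction = 0, rod_radius_mean = 2,
                        rod_radius_sd = 0.25,
                        rim_amplitude = 60, base_level = 100,
                        background_amplitude = 10, background_wavelength = 40,
                        noise_sd = 2, poisson_noise = FALSE,
                        azimuths = c(45, 135, 225, 315), seed = 1L) {
  placement <- match.arg(placement)
  if (size < 32) stop("size must be >= 32")
  if (pitch <= 0 || min_spacing <= 0) stop("spacing must be > 0")
  if (placement == "hex" && jitter_sd > 0.2 * pitch)
    stop("jitter_sd must be <= 0.2 * pitch")
  if (radius_mean <= 0 || rod_radius_mean <= 0) stop("radii must be > 0")
  if (rim_amplitude < 0 || background_amplitude < 0 || noise_sd < 0)
    stop("amplitudes must be >= 0")
  if (rod_fraction < 0 || rod_fraction > 1) stop("rod_fraction must be in [0, 1]")
  structure(list(size = as.integer(size), placement = placement, pitch = pitch,
                 jitter_sd = jitter_sd, min_spacing = min_spacing,
                 n_cells = n_cells, radius_mean = radius_mean,
                 radius_sd = radius_sd, rod_fraction = rod_fraction,
                 rod_radius_mean = rod_radius_mean, rod_radius_sd = rod_radius_sd,
                 rim_amplitude = rim_amplitude, base_level = base_level,
                 background_amplitude = background_amplitude,
                 background_wavelength = background_wavelength,
                 noise_sd = noise_sd, poisson_noise = poisson_noise,
                 azimuths = azimuths %% 360, seed = as.integer(seed)),
            class = "mosaic_spec")
}

#' Place cell centres
#'
#' Hex mode lays centres on a hexagonal lattice of the given pitch (a
#' margin of one maximal cell radius keeps cells inside the frame) and
#' jitters them; Poisson mode throws darts with a minimum-spacing
#' constraint. Deterministic for a given seed.
#'
#' @param spec a [mosaic_spec].
#' @param seed overrides `spec$seed`.
#' @return A [centroid_set] with ground-truth labels and a `radii`
#'   attribute (per-cell radius in px).
#' @export
place_cells <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "mosaic_spec"))
  set.seed(seed)
  margin <- spec$radius_mean + 3 * spec$radius_sd + 1
  lo <- margin; hi <- spec$size - 1 - margin
  if (hi <= lo) stop("image too small for the requested cell size")
  if (spec$placement == "hex") {
    dy <- spec$pitch * sqrt(3) / 2
    ys <- seq(lo, hi, by = dy)
    pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
      off <- if (i %% 2L == 0L) spec$pitch / 2 else 0
      xs <- seq(lo + off, hi, by = spec$pitch)
      cbind(xs, ys[i])
    }))
    if (spec$jitter_sd > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$jitter_sd), ncol = 2L)
    pts[, 1L] <- clip_range(pts[, 1L], 0, spec$size - 1)
    pts[, 2L] <- clip_range(pts[, 2L], 0, spec$size - 1)
  } else {
    target <- spec$n_cells
    budget <- 2000L + 200L * (target %||% 100L)
    acc <- matrix(numeric(0), ncol = 2L)
    tries <- 0L
    while (tries < budget && (is.null(target) || nrow(acc) < target)) {
      tries <- tries + 1L
      p <- stats::runif(2L, lo, hi)
      if (nrow(acc) == 0L ||
          min(sqrt((acc[, 1L] - p[1L])^2 + (acc[, 2L] - p[2L])^2)) >= spec$min_spacing)
        acc <- rbind(acc, p)
    }
    if (!is.null(target) && nrow(acc) < target)
      stop("infeasible density: rejection budget exhausted at ",
           nrow(acc), " of ", target, " cells")
    pts <- acc
  }
  n <- nrow(pts)
  is_rod <- stats::runif(n) < spec$rod_fraction
  radii <- ifelse(is_rod,
                  stats::rnorm(n, spec$rod_radius_mean, spec$rod_radius_sd),
                  stats::rnorm(n, spec$radius_mean, spec$radius_sd))
  radii <- pmax(radii, 0.75)
  cs <- centroid_set(pts[, 1L], pts[, 2L],
                     label = ifelse(is_rod, "rod", "cone"), source = "manual")
  attr(cs, "radii") <- radii
  cs
}

# Low-spatial-frequency background: Gaussian-smoothed white noise,
# standardised to zero mean, unit sd, then scaled by the spec amplitude.
make_background <- function(spec) {
  if (spec$background_amplitude == 0)
    return(matrix(0, spec$size, spec$size))
  w <- matrix(stats::rnorm(spec$size^2), spec$size, spec$size)
  f <- as_pixel_matrix(gaussian_blur(w, spec$background_wavelength / 4))
  spec$background_amplitude * (f - mean(f)) / stats::sd(f)
}

#' Render one quadrant-detector channel
#'
#' Forward model: each cell is a hemispherical cap of its radius; the
#' channel at detector azimuth `a` sees
#' `base + amplitude * max(0, n . d)` per pixel, where `n` is the cap's
#' unit surface normal and `d` the lateral unit vector at azimuth `a`
#' (math orientation, y up). The lateral normal component at in-cell polar
#' angle `phi` and fractional radius `rho/r` gives
#' `n . d = (rho / r) * cos(phi - a)`, i.e. a bright half facing the
#' detector and nothing on the far half: the split-detection semicircle
#' phenomenology. Pixels outside every cell carry only
#' `base + background (+ noise)`.
#'
#' @param cells [centroid_set] with a `radii` attribute (see
#'   [place_cells()]).
#' @param azimuth detector azimuth in degrees.
#' @param spec a [mosaic_spec].
#' @param background optional shared background field matrix (from the
#'   generator); `NULL` for none.
#' @param noise add per-channel noise as configured in `spec` (draws from
#'   the current RNG stream).
#' @return A [raster_image].
#' @export
render_quadrant_channel <- function(cells, azimuth, spec, background = NULL,
                                    noise = FALSE) {
  n <- spec$size
  img <- matrix(spec$base_level, n, n)
  radii <- attr(cells, "radii")
  if (is.null(radii)) radii <- rep(spec$radius_mean, length(cells$x))
  a <- azimuth * pi / 180
  for (i in seq_along(cells$x)) {
    cx <- cells$x[i]; cy <- cells$y[i]; r <- radii[i]
    c0 <- max(0L, floor(cx - r)); c1 <- min(n - 1L, ceiling(cx + r))
    r0 <- max(0L, floor(cy - r)); r1 <- min(n - 1L, ceiling(cy + r))
    if (c1 < c0 || r1 < r0) next
    xs <- c0:c1; ys <- r0:r1
    dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
    rho <- sqrt(dx * dx + dy * dy)
    inside <- rho < r
    # math orientation: u = x, v = -y (image y runs downward)
    ndotd <- (dx * cos(a) + (-dy) * sin(a)) / r
    contrib <- spec$rim_amplitude * pmax(0, ndotd)
    block <- img[ys + 1L, xs + 1L, drop = FALSE]
    img[ys + 1L, xs + 1L] <- block + ifelse(inside, contrib, 0)
  }
  if (!is.null(background)) img <- img + background
  if (noise) {
    if (spec$poisson_noise) img <- matrix(stats::rpois(n * n, pmax(img, 0)), n, n)
    if (spec$noise_sd > 0) img <- img + stats::rnorm(n * n, sd = spec$noise_sd)
  }
  raster_image(pmax(img, 0))
}

#' Generate a synthetic quadrant frame set with ground truth
#'
#' Places cells, draws one shared background field, and renders the four
#' detector channels with independent noise. Bit-identical for a given
#' seed.
#'
#' @param spec a [mosaic_spec].
#' @param seed overrides `spec$seed`.
#' @return List with `qset` (a [quadrant_frame_set]), `truth` (the
#'   ground-truth [centroid_set] with radii), and `background` (the shared
#'   field as a matrix, for suppression analyses).
#' @export
generate_mosaic <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "mosaic_spec"))
  cells <- place_cells(spec, seed = seed)  # seeds the RNG stream
  background <- make_background(spec)
  channels <- lapply(spec$azimuths, function(az)
    render_quadrant_channel(cells, az, spec, background = background,
                            noise = TRUE))
  list(qset = quadrant_frame_set(channels, azimuths = spec$azimuths),
       truth = cells, background = background, seed = as.integer(seed))
}
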