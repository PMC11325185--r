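#' Pipeline configuration
#'
#' Collects every tunable of the simulate/split/enhance/detect/evaluate
#' chain with validated defaults. Defaults follow the published parameter
#' values where printed (emboss height 5 px, amount 150%, blur radius
#' 2 px); everything else follows the package's documented conventions.
#'
#' @param azimuths detector azimuths (degrees).
#' @param mapping axis-side mapping or `NULL` for [default_axis_mapping()].
#' @param emboss_height,emboss_amount emboss filter parameters.
#' @param emboss_polarity `NULL` for the per-axis default (see
#'   [default_emboss_polarity()]), or `+1`/`-1` (scalar or per-axis vector
#'   of four).
#' @param quantize_8bit quantise split displays to 8 bits before embossing.
#' @param blur_radius,threshold,min_area,maxima_mode,invert detection
#'   parameters, see [detection_params()].
#' @param match_radius evaluation radius in px or `"auto"`.
#' @param bit_depth bit depth for written image artifacts.
#' @param seed seed for simulation requests.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(azimuths = c(45, 135, 225, 315), mapping = NULL,
                            emboss_height = 5L, emboss_amount = 150,
                            emboss_polarity = NULL, quantize_8bit = TRUE,
                            blur_radius = 2, threshold = "auto",
                            min_area = 4L, maxima_mode = "component-centroid",
                            invert = TRUE, match_radius = "auto",
                            bit_depth = 8L, seed = 1L) {
  if (emboss_height < 1) stop("emboss_height must be >= 1")
  if (emboss_amount <= 0) stop("emboss_amount must be > 0")
  if (!is.null(emboss_polarity) && !all(emboss_polarity %in% c(-1, 1)))
    stop("emboss_polarity must be +1 or -1 (scalar or per-axis)")
  dp <- detection_params(blur_radius, threshold, min_area, maxima_mode, invert)
  structure(list(azimuths = azimuths, mapping = mapping,
                 emboss_height = as.integer(emboss_height),
                 emboss_amount = emboss_amount,
                 emboss_polarity = if (is.null(emboss_polarity)) NULL
                                   else as.integer(emboss_polarity),
                 quantize_8bit = isTRUE(quantize_8bit),
                 detection = dp, match_radius = match_radius,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key-value config file
#'
#' Parses a minimal `key: value` file (one pair per line, `#` comments,
#' comma-separated values become vectors) and merges it over the
#' [pipeline_config()] defaults.
#'
#' @param path config file path.
#' @return A `pipeline_config`.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    val <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!anyNA(num)) num
              else if (all(val %in% c("true", "false", "TRUE", "FALSE")))
                as.logical(toupper(val))
              else val
    kv[[m[2]]] <- parsed
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, kv)
}

#' Run the full enhancement and detection pipeline
#'
#' One command replacing the original two-tool (image editor + ImageJ)
#' workflow: takes either four channel image paths or a simulation request,
#' then balances means, computes the four directional splits, embosses,
#' fuses by MinIP, detects centroids, and (when a manual annotation is
#' given) writes the agreement report. A run manifest records the
#' configuration, seed, package version and MD5 of every artifact.
#'
#' @param config a [pipeline_config()].
#' @param channels named list/vector of four image paths (`q1`..`q4`, in
#'   azimuth order), or a [quadrant_frame_set]; mutually exclusive with
#'   `simulate`.
#' @param simulate a [mosaic_spec] to generate inputs (ground truth is then
#'   used as the manual set unless `manual` is given).
#' @param manual optional manual-annotation CSV path or [centroid_set].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage products
#'   (`qset`, `splits`, `embossed`, `minip`, `centroids`, `report`,
#'   `manifest`) and the artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), channels = NULL,
                         simulate = NULL, manual = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  qset <- stage("input", {
    if (!is.null(simulate)) {
      sim <- generate_mosaic(simulate, seed = config$seed)
      truth <- sim$truth  # promise evaluates in this frame, so this sticks
      sim$qset
    } else if (inherits(channels, "quadrant_frame_set")) {
      channels
    } else if (!is.null(channels)) {
      want <- paste0("q", 1:4)
      missing_ch <- setdiff(want, tolower(names(channels)))
      if (length(missing_ch) > 0L)
        stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
      imgs <- lapply(want, function(k) read_image(channels[[match(k, tolower(names(channels)))]]))
      quadrant_frame_set(imgs, azimuths = config$azimuths)
    } else stop("supply either `channels` or `simulate`")
  })
  mapping <- config$mapping %||% default_axis_mapping(qset$azimuths)
  splits <- stage("split", directional_splits(normalize_quadrant_means(qset), mapping))
  embossed <- stage("enhance",
    enhance_stack(splits, height = config$emboss_height,
                  amount = config$emboss_amount,
                  polarity = config$emboss_polarity,
                  quantize = config$quantize_8bit))
  fused <- stage("minip", minip(embossed))
  cents <- stage("detect", detect_cells(fused, config$detection))

  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  for (i in seq_along(splits)) {
    nm <- names(splits)[i]
    put(sprintf("split_%s.tif", nm), function(p)
      write_image(to_display_range(splits[[i]]), p, config$bit_depth))
    put(sprintf("embossed_%s.tif", nm), function(p)
      write_image(embossed[[i]], p, config$bit_depth))
  }
  put("minip.tif", function(p)
    write_image(raster_image(fused$pixels), p, config$bit_depth))
  put("centroids.csv", function(p) write_centroids(cents, p))

  report <- NULL
  manual_set <- if (!is.null(manual)) {
    if (inherits(manual, "centroid_set")) manual
    else read_centroids(manual, source = "manual")
  } else truth
  if (!is.null(manual_set)) {
    m <- stage("evaluate",
               match_centroids(cents, manual_set, radius = config$match_radius))
    report <- summarize_match(m)
    put("report.json", function(p)
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA, null = "null"))
  }
  cfg_plain <- unclass(config)[setdiff(names(config), "mapping")]
  cfg_plain$detection <- unclass(cfg_plain$detection)
  manifest <- list(package = "quadmosaic",
                   version = as.character(utils::packageVersion("quadmosaic")),
                   seed = config$seed,
                   config = cfg_plain,
                   detect_log = attr(cents, "detect_log"),
                   artifacts = as.list(tools::md5sum(unlist(paths))))
  put("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA, null = "null"))
  invisible(list(qset = qset, splits = splits, embossed = embossed,
                 minip = fused, centroids = cents, truth = truth,
                 report = report, manifest = manifest, paths = paths))
}
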