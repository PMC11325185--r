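#' Match automatic against manual centroids
#'
#' Greedy nearest-pair matching of an automatically detected centroid set
#' against a manual annotation, producing the false-negative /
#' false-positive / merged taxonomy. All auto-manual pairs with distance
#' `<= radius` are sorted by ascending distance (ties broken by manual then
#' auto index, making the result order-independent); a pair is accepted
#' whenever its manual point is still unmatched. An auto point may be bound
#' by more than one manual point: each such binding counts as a true
#' positive, and auto points bound by two or more manual points are
#' reported as `merged` ("two cells mislabelled as one"). Manual points
#' left unbound are false negatives; auto points with no bound manual point
#' are false positives.
#'
#' @param auto,manual [centroid_set]s (or data frames with `x`, `y`).
#' @param radius match radius in px, or `"auto"` (the default): half the
#'   median nearest-neighbour distance of the manual set, which adapts the
#'   overlap criterion to the local cell spacing.
#' @return A `match_result`: list with counts `n_manual`, `n_auto`,
#'   `true_positives`, `false_negatives`, `false_positives`, `merged`, the
#'   `match_radius` used, unrounded `fn_rate`/`fp_rate` (percent of
#'   `n_manual`), `recall`, `precision`, and the accepted `pairs`.
#' @export
match_centroids <- function(auto, manual, radius = "auto") {
  ax <- auto$x; ay <- auto$y
  mx <- manual$x; my <- manual$y
  n_auto <- length(ax); n_manual <- length(mx)
  if (identical(radius, "auto") || is.null(radius)) {
    radius <- default_match_radius(manual)
  }
  radius <- as.numeric(radius)
  if (!is.finite(radius) || radius <= 0) stop("match radius must be > 0")

  bound_auto <- rep(NA_integer_, n_manual)
  if (n_auto > 0L && n_manual > 0L) {
    dx <- outer(mx, ax, `-`); dy <- outer(my, ay, `-`)
    d <- sqrt(dx * dx + dy * dy)
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ord <- order(d[cand], cand[, 1L], cand[, 2L])
      cand <- cand[ord, , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        m <- cand[i, 1L]
        if (is.na(bound_auto[m])) bound_auto[m] <- cand[i, 2L]
      }
    }
  }
  per_auto <- tabulate(bound_auto[!is.na(bound_auto)], nbins = n_auto)
  tp <- sum(!is.na(bound_auto))
  fn <- n_manual - tp
  fp <- sum(per_auto == 0L)
  merged <- sum(per_auto >= 2L)
  pairs <- data.frame(manual = which(!is.na(bound_auto)),
                      auto = bound_auto[!is.na(bound_auto)])
  structure(list(n_manual = n_manual, n_auto = n_auto,
                 true_positives = tp, false_negatives = fn,
                 false_positives = fp, merged = merged,
                 match_radius = radius,
                 fn_rate = if (n_manual > 0) 100 * fn / n_manual else NA_real_,
                 fp_rate = if (n_manual > 0) 100 * fp / n_manual else NA_real_,
                 recall = if (n_manual > 0) tp / n_manual else NA_real_,
                 precision = if (n_auto > 0) (n_auto - fp) / n_auto else NA_real_,
                 pairs = pairs),
            class = "match_result")
}

#' Spacing-adaptive default match radius
#'
#' Half the median nearest-neighbour distance of the manual set.
#'
#' @param manual a [centroid_set] with at least two points.
#' @return Radius in px.
#' @export
default_match_radius <- function(manual) {
  if (length(manual$x) < 2L)
    stop("automatic match radius needs >= 2 manual points; supply a radius")
  d <- as.matrix(stats::dist(cbind(manual$x, manual$y)))
  diag(d) <- Inf
  0.5 * stats::median(apply(d, 1L, min))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("<match_result: %d manual / %d auto, TP %d, FN %d (%.1f%%), ",
                     "FP %d (%.1f%%), merged %d, radius %.2f px>\n"),
              x$n_manual, x$n_auto, x$true_positives, x$false_negatives,
              x$fn_rate, x$false_positives, x$fp_rate, x$merged, x$match_radius))
  invisible(x)
}

round_half_up <- function(x, digits = 0L) floor(x * 10^digits + 0.5) / 10^digits
round_truncate <- function(x, digits = 0L) floor(x * 10^digits) / 10^digits

#' Summarise a match result as printable rates
#'
#' Converts the count taxonomy into percentage rates of the manual total,
#' rounded to `decimals` places. Rounding is half-up by default;
#' `rounding = "truncate"` drops the excess digits instead (both
#' conventions appear in published reports, so the summary also carries the
#' alternate-convention values).
#'
#' @param m a `match_result`, or any list with `n_manual`,
#'   `false_negatives`, `false_positives` (and optionally the other counts).
#' @param decimals 0 or 1 decimal places.
#' @param rounding `"half-up"` or `"truncate"`.
#' @return A JSON-serialisable list of counts, formatted rates (e.g.
#'   `"3.6%"`), numeric rates under the chosen convention, and
#'   `alt_rounding` with the other convention's numeric rates.
#' @export
summarize_match <- function(m, decimals = 1L, rounding = c("half-up", "truncate")) {
  rounding <- match.arg(rounding)
  if (is.null(m$n_manual) || m$n_manual <= 0) stop("n_manual must be > 0")
  if (!decimals %in% c(0L, 1L)) stop("decimals must be 0 or 1")
  fn_raw <- 100 * m$false_negatives / m$n_manual
  fp_raw <- if (is.null(m$false_positives)) NA_real_
            else 100 * m$false_positives / m$n_manual
  rnd <- if (rounding == "half-up") round_half_up else round_truncate
  alt <- if (rounding == "half-up") round_truncate else round_half_up
  fmt <- function(x) {
    if (is.na(x)) return(NA_character_)
    paste0(formatC(x, format = "f", digits = decimals), "%")
  }
  list(n_manual = m$n_manual,
       n_auto = m$n_auto %||% NA_integer_,
       true_positives = m$true_positives %||% (m$n_manual - m$false_negatives),
       false_negatives = m$false_negatives,
       false_positives = m$false_positives %||% NA_integer_,
       merged = m$merged %||% NA_integer_,
       match_radius = m$match_radius %||% NA_real_,
       rounding = rounding,
       decimals = decimals,
       fn_rate = rnd(fn_raw, decimals),
       fp_rate = if (is.na(fp_raw)) NA_real_ else rnd(fp_raw, decimals),
       fn_rate_label = fmt(rnd(fn_raw, decimals)),
       fp_rate_label = fmt(if (is.na(fp_raw)) NA_real_ else rnd(fp_raw, decimals)),
       alt_rounding = list(
         fn_rate = alt(fn_raw, decimals),
         fp_rate = if (is.na(fp_raw)) NA_real_ else alt(fp_raw, decimals)))
}
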