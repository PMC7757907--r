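#' Min-max normalisation of a raster
#'
#' Rescales valid cells to [0, 1] via (x - min) / (max - min). By default
#' the extrema come from the raster itself; `min_override`/`max_override`
#' supply dataset-wide extrema instead (e.g. a global host-area maximum),
#' so tiles normalised against the full dataset remain comparable. A
#' degenerate range (max = min) yields all zeros with a warning.
#'
#' @param raster A `raster_grid` with at least one valid cell.
#' @param min_override,max_override Optional fixed extrema.
#' @return The normalised `raster_grid` (unitless).
#' @export
normalize <- function(raster, min_override = NULL, max_override = NULL) {
  stopifnot(is_raster_grid(raster))
  v <- raster$values
  if (all(is.na(v))) stop("raster has no valid cells")
  lo <- if (is.null(min_override)) min(v, na.rm = TRUE) else min_override
  hi <- if (is.null(max_override)) max(v, na.rm = TRUE) else max_override
  if (hi == lo) {
    warning("degenerate range (max = min); normalised raster set to 0")
    raster$values <- ifelse(is.na(v), NA_real_, 0)
  } else {
    raster$values <- (v - lo) / (hi - lo)
  }
  raster$units <- ""
  raster
}

#' Overall habitat suitability
#'
#' Merges normalised climatic suitability `n(cs)` and normalised host
#' availability `n(h)` into S = (n(cs) + n(h)) / 2, the equally weighted
#' mean; dividing by 2 keeps S in [0, 1]. Nodata in either input propagates
#' to the output.
#'
#' @param cs Normalised climatic-suitability `raster_grid` in [0, 1].
#' @param h Normalised host-availability `raster_grid` in [0, 1].
#' @return The overall-suitability `raster_grid`.
#' @export
overall_suitability <- function(cs, h) {
  stopifnot(is_raster_grid(cs), is_raster_grid(h))
  if (!same_geometry(cs, h))
    stop("inputs are not co-registered; resample/reproject them first")
  rng <- range(c(cs$values, h$values), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("inputs must be normalised to [0, 1]")
  out <- cs
  out$values <- (cs$values + h$values) / 2
  out$units <- ""
  out
}

#' Suitability class scheme
#'
#' The conventional four-class reclassification of a [0, 1] suitability
#' surface. The printed class bounds (<= 0.15; 0.16-0.30; 0.31-0.60;
#' >= 0.61) leave the values between them unassigned; the scheme closes the
#' gaps with half-open intervals (0.15, 0.30], (0.30, 0.60], (0.60, 1] so
#' the classes partition [0, 1] exactly.
#'
#' @param breaks Strictly increasing boundary values within (0, 1).
#' @param labels One label per class (length = breaks + 1).
#' @return A `class_scheme` object.
#' @export
class_scheme <- function(breaks = c(0.15, 0.30, 0.60),
                         labels = c("not suitable", "low suitability",
                                    "medium suitability",
                                    "high suitability")) {
  if (any(diff(breaks) <= 0) || any(breaks <= 0) || any(breaks >= 1))
    stop("`breaks` must be strictly increasing within (0, 1)")
  if (length(labels) != length(breaks) + 1)
    stop("need one label per class (breaks + 1)")
  structure(list(breaks = breaks, labels = labels), class = "class_scheme")
}

#' Classify a suitability raster
#'
#' Assigns integer classes 1..K by the scheme's half-open intervals:
#' class 1 iff v <= first break, class k iff break[k-1] < v <= break[k],
#' top class iff v > last break. Values outside [0, 1] abort (they indicate
#' an upstream bug, not a data condition).
#'
#' @param map A `raster_grid` with values in [0, 1].
#' @param scheme A [class_scheme()].
#' @return A `raster_grid` of integer classes (NA where input is nodata),
#'   with the labels attached as attribute `labels`.
#' @export
classify <- function(map, scheme = class_scheme()) {
  stopifnot(is_raster_grid(map), inherits(scheme, "class_scheme"))
  v <- map$values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1))
    stop("values outside [0, 1]; classify expects a normalised surface")
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  # left.open: intervals (b[k-1], b[k]], so a value on a break classes below
  cls[ok] <- findInterval(v[ok], scheme$breaks, left.open = TRUE) + 1
  out <- map
  out$values <- cls
  out$units <- "class"
  attr(out, "labels") <- scheme$labels
  out
}
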