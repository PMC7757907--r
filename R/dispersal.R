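#' Convert statute miles to kilometres
#'
#' @param miles Distance in statute miles.
#' @return Distance in kilometres (1 mile = 1.609344 km).
#' @export
miles_to_km <- function(miles) miles * 1.609344

#' Derive Gaussian dispersal-kernel parameters
#'
#' The maximum natural dispersal distance is read as the 3-sigma point of a
#' zero-mean Gaussian displacement distribution, so sigma = D_max / 3. The
#' kernel is written c1 * exp(-c2 * x^2) with c1 = 1 / (sigma * sqrt(2 pi))
#' (the 1-D pdf height at the mean) and c2 = 1 / (2 sigma^2). With
#' `paper_rounding` (the default) c1 is rounded to 2 decimals and c2 to 3,
#' reproducing the conventional printed constants 0.03 and 0.003 for the
#' peach fruit fly's 40.2 km (25 mile) capacity; unrounded values are kept
#' for sensitivity analyses. `unit_height` forces c1 = 1 (a kernel of unit
#' peak rather than pdf height).
#'
#' @param D_max Maximum dispersal distance, km (> 0); default 40.2.
#' @param k1,k2 Weights of climatic suitability and host availability in
#'   the habitat term (defaults 0.5 each: equally informative inputs).
#' @param paper_rounding Round c1/c2 to the conventional printed precision.
#' @param unit_height Force c1 = 1.
#' @return A `dispersal_params` object with fields `D_max`, `mu` (0),
#'   `sigma`, `c1`, `c2`, `k1`, `k2`, `paper_rounding`.
#' @export
derive_params <- function(D_max = 40.2, k1 = 0.5, k2 = 0.5,
                          paper_rounding = TRUE, unit_height = FALSE) {
  if (!is.numeric(D_max) || D_max <= 0) stop("`D_max` must be > 0")
  if (k1 <= 0 || k2 <= 0) stop("weights must be positive")
  sigma <- D_max / 3
  c1 <- 1 / (sigma * sqrt(2 * pi))
  c2 <- 1 / (2 * sigma^2)
  if (paper_rounding) {
    c1 <- round(c1, 2)
    c2 <- round(c2, 3)
  }
  if (unit_height) c1 <- 1
  structure(list(D_max = D_max, mu = 0, sigma = sigma, c1 = c1, c2 = c2,
                 k1 = k1, k2 = k2, paper_rounding = paper_rounding),
            class = "dispersal_params")
}

#' @export
print.dispersal_params <- function(x, ...) {
  cat(sprintf(
    "dispersal_params: D_max = %g km, sigma = %g km, c1 = %g, c2 = %g, k1 = %g, k2 = %g\n",
    x$D_max, x$sigma, x$c1, x$c2, x$k1, x$k2))
  invisible(x)
}

#' Gaussian dispersal kernel
#'
#' c1 * exp(-c2 * x^2): even in x, maximal (= c1) at the source, decaying
#' with squared distance.
#'
#' @param x Distance from the source, km (vectorised).
#' @param params A [derive_params()] object.
#' @return Kernel values.
#' @export
gaussian_kernel <- function(x, params) {
  stopifnot(inherits(params, "dispersal_params"))
  params$c1 * exp(-params$c2 * x^2)
}

#' Distance from every cell to its nearest source
#'
#' Great-circle (haversine) distance from each cell centre to the closest
#' source point.
#'
#' @param grid A `raster_grid` defining the geometry.
#' @param sources An `occurrence_set` or data frame with `lon`/`lat`.
#' @return A `raster_grid` of distances in km (nodata follows `grid`).
#' @export
distance_to_nearest_source <- function(grid, sources) {
  stopifnot(is_raster_grid(grid))
  src <- if (inherits(sources, "occurrence_set")) sources$records else sources
  if (is.null(src$lon) || nrow(src) == 0) stop("need at least one source")
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- rep(cc$lon, each = nr)      # column-major cell order
  lat <- rep(cc$lat, times = nc)
  d <- rep(Inf, nr * nc)
  for (s in seq_len(nrow(src)))
    d <- pmin(d, gc_distance_km(lon, lat, src$lon[s], src$lat[s]))
  out <- grid
  out$values <- matrix(d, nr, nc)
  out$values[is.na(grid$values)] <- NA_real_
  out$units <- "km"
  out
}

#' Likelihood of natural dispersal
#'
#' Per cell, l = [(k1 n(cs) + k2 n(h)) / (k1 + k2)] * c1 exp(-c2 x^2),
#' where x is the distance to the nearest source: the weighted habitat term
#' (in [0, 1]) damped by the Gaussian kernel of the closest source. Because
#' the kernel decreases with distance, taking the closest source equals
#' taking the maximum over all per-source kernels. l is bounded by c1.
#'
#' @param cs_norm Normalised climatic suitability (`raster_grid`, [0, 1]).
#' @param h_norm Normalised host availability (`raster_grid`, [0, 1]).
#' @param sources Source locations (`occurrence_set` or lon/lat data frame).
#' @param params A [derive_params()] object.
#' @return A `raster_grid` of dispersal likelihood.
#' @export
dispersal_likelihood <- function(cs_norm, h_norm, sources, params) {
  stopifnot(is_raster_grid(cs_norm), is_raster_grid(h_norm),
            inherits(params, "dispersal_params"))
  if (!same_geometry(cs_norm, h_norm))
    stop("cs and host rasters are not co-registered")
  x <- distance_to_nearest_source(cs_norm, sources)
  habitat <- (params$k1 * cs_norm$values + params$k2 * h_norm$values) /
    (params$k1 + params$k2)
  out <- cs_norm
  out$values <- habitat * gaussian_kernel(x$values, params)
  out$units <- ""
  out
}

#' Run the spread model over one or more generations
#'
#' Generation 1 is [dispersal_likelihood()] from the original sources — the
#' model's standard single-generation run (one generation is roughly 46
#' days for this fly). As an explicitly flagged extension, with `n_gen > 1`
#' every cell whose likelihood reaches `reseed_threshold` becomes an
#' additional source for the next generation, so reachable likelihood can
#' only grow between generations.
#'
#' @param cs_norm,h_norm,sources,params As in [dispersal_likelihood()].
#' @param n_gen Number of generations (>= 1, default 1).
#' @param reseed_threshold Likelihood at or above which a cell seeds the
#'   next generation (only used when `n_gen > 1`).
#' @return List of `raster_grid`s, one per generation.
#' @export
run_generations <- function(cs_norm, h_norm, sources, params,
                            n_gen = 1L, reseed_threshold = NULL) {
  if (n_gen < 1) stop("`n_gen` must be >= 1")
  if (n_gen > 1 && is.null(reseed_threshold))
    stop("`reseed_threshold` is required when n_gen > 1")
  src <- if (inherits(sources, "occurrence_set")) sources$records else sources
  src <- src[c("lon", "lat")]
  out <- vector("list", n_gen)
  for (g in seq_len(n_gen)) {
    out[[g]] <- dispersal_likelihood(cs_norm, h_norm, src, params)
    if (g < n_gen) {
      v <- out[[g]]$values
      hit <- which(!is.na(v) & v >= reseed_threshold)
      if (length(hit)) {
        cc <- cell_centers(cs_norm)
        nr <- nrow(v)
        add <- data.frame(lon = cc$lon[((hit - 1L) %/% nr) + 1L],
                          lat = cc$lat[((hit - 1L) %% nr) + 1L])
        src <- unique(rbind(src, add))
      }
    }
  }
  out
}
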