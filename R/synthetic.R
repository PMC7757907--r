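#' Synthetic study scenario
#'
#' Defines a fully seeded synthetic study region: spatially autocorrelated
#' predictor fields with controlled collinear pairs, a known logistic
#' "true suitability" surface built from a linear-quadratic combination of
#' the predictors, presence points sampled proportionally to that surface,
#' and a non-negative host-availability field. The defaults are the
#' package's reference study conditions: a 100 x 100 grid of 0.05 degree
#' cells (a roughly 550 km square), 12 candidate predictors of which 8
#' carry signal, three deliberately collinear pairs above the 0.7 pruning
#' cutoff, 150 presences, and a compact, sharply bounded suitable range
#' covering 6 percent of the landscape (the intercept of the true surface
#' is calibrated per realisation so this fraction of cells exceeds
#' suitability 0.5).
#'
#' @param grid_shape Integer (rows, cols); each dimension must be >= 4.
#' @param cell_size Cell size in decimal degrees.
#' @param origin Lon/lat of the grid's upper-left corner.
#' @param n_predictors Number of predictor layers.
#' @param collinear_pairs List of `c(i, j, target_r)` triples: layer j is
#'   rebuilt to correlate with layer i at exactly `target_r` (|r| <= 1).
#' @param linear,quadratic Per-predictor true linear and quadratic weights
#'   (on standardised predictors) defining the true suitability surface.
#' @param intercept Intercept of the true linear predictor, or `NA`
#'   (default) to calibrate it from `suitable_fraction`.
#' @param suitable_fraction When `intercept` is `NA`: the fraction of cells
#'   whose true suitability exceeds 0.5.
#' @param presence_n Number of presence points to sample (>= 1).
#' @param noise_sd White-noise standard deviation added to the smooth
#'   standardised fields (dimensionless).
#' @param host_max Maximum host harvested area, hectares.
#' @param seed Integer seed; identical scenarios are bit-identical.
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(
    grid_shape = c(100L, 100L),
    cell_size = 0.05,
    origin = c(30, 16),
    n_predictors = 12L,
    collinear_pairs = list(c(1, 2, 0.85), c(7, 8, 0.9), c(9, 10, 0.75)),
    linear = c(12, -9, 9, 0, 7.2, -9, 7.2, 0, 0, 0, 0, 0),
    quadratic = c(0, -3, 0, -6, 0, 0, 0, -4.5, 0, 0, 0, 0),
    intercept = NA_real_,
    suitable_fraction = 0.06,
    presence_n = 150L,
    noise_sd = 0.02,
    host_max = 12000,
    seed = 4242L) {
  if (length(grid_shape) != 2L || any(grid_shape < 4))
    stop("degenerate grid: both dimensions must be >= 4")
  if (presence_n < 1) stop("`presence_n` must be >= 1")
  if (length(linear) != n_predictors || length(quadratic) != n_predictors)
    stop("`linear` and `quadratic` must have one weight per predictor")
  if (is.na(intercept) &&
      (suitable_fraction <= 0 || suitable_fraction >= 1))
    stop("`suitable_fraction` must be in (0, 1)")
  for (p in collinear_pairs) {
    if (length(p) != 3 || abs(p[3]) > 1 || p[1] == p[2] ||
        any(p[1:2] < 1) || any(p[1:2] > n_predictors))
      stop("collinear pair must be c(i, j, target_r) with |target_r| <= 1")
  }
  structure(list(
    grid_shape = as.integer(grid_shape), cell_size = cell_size,
    origin = origin, n_predictors = as.integer(n_predictors),
    collinear_pairs = collinear_pairs, linear = linear,
    quadratic = quadratic, intercept = intercept,
    suitable_fraction = suitable_fraction,
    presence_n = as.integer(presence_n), noise_sd = noise_sd,
    host_max = host_max, seed = as.integer(seed)),
    class = "synthetic_scenario")
}

# One standardised smooth random field: a handful of low-frequency sinusoid
# and gradient basis surfaces with random phases, plus white noise, then
# empirically standardised. Consumes the current RNG stream.
smooth_field <- function(nr, nc, noise_sd, n_basis = 6) {
  x <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  y <- matrix(rep(seq(0, 1, length.out = nr), times = nc), nr, nc)
  f <- stats::runif(2) - 0.5            # mild planar trend
  field <- f[1] * x + f[2] * y
  for (k in seq_len(n_basis)) {
    fr <- stats::runif(2, 0.5, 2.5)     # cycles per domain: large patches
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.4, 1)
    field <- field + amp * sin(2 * pi * (fr[1] * x + fr[2] * y) + ph)
  }
  field <- field + noise_sd * stats::rnorm(nr * nc)
  (field - mean(field)) / stats::sd(field)
}

# Standardise a vector/matrix empirically.
standardize <- function(v) (v - mean(v)) / stats::sd(v)

#' Generate a co-registered synthetic predictor stack
#'
#' Fields are smooth standardised surfaces mapped to realistic bioclimatic
#' units: the first half of the layers play a temperature role (deg C), the
#' second half a precipitation role (mm). For each requested collinear pair
#' `(i, j, r)`, layer j is rebuilt as `r * z_i + sqrt(1 - r^2) * z_perp`,
#' where `z_perp` is an independent smooth field empirically orthogonalised
#' against layer i, so the realised Pearson correlation equals the target
#' exactly (up to floating point) while the field stays smooth.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `predictor_stack` with layers `bio1..bioN` and roles set.
#' @export
generate_predictor_stack <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  set.seed(scenario$seed)
  np <- scenario$n_predictors
  z <- vector("list", np)
  for (i in seq_len(np))
    z[[i]] <- smooth_field(nr, nc, scenario$noise_sd)
  for (p in scenario$collinear_pairs) {
    i <- p[1]; j <- p[2]; r <- p[3]
    zi <- standardize(z[[i]])
    raw <- smooth_field(nr, nc, scenario$noise_sd)
    perp <- standardize(raw - mean(raw * zi) / mean(zi * zi) * zi)
    z[[j]] <- r * zi + sqrt(1 - r^2) * perp
  }
  roles <- rep(c("temperature", "precipitation"), each = ceiling(np / 2))[
    seq_len(np)]
  layers <- vector("list", np)
  for (i in seq_len(np)) {
    v <- if (roles[i] == "temperature") 22 + 6 * z[[i]] else
      pmax(0, 800 + 250 * z[[i]])
    layers[[i]] <- raster_grid(matrix(v, nr, nc),
                               origin = scenario$origin,
                               cellsize = scenario$cell_size,
                               units = if (roles[i] == "temperature")
                                 "degC" else "mm")
  }
  names(layers) <- paste0("bio", seq_len(np))
  predictor_stack(layers, roles = roles)
}

#' Known true-suitability surface
#'
#' Per-cell logistic(eta) with eta the linear-quadratic combination of the
#' empirically standardised predictors: eta = intercept + sum(a_i z_i +
#' b_i z_i^2). Values lie strictly in (0, 1); with all weights zero and
#' intercept 0 the surface is uniformly 0.5. Instead of a fixed intercept,
#' `suitable_fraction` calibrates it per realisation so exactly that
#' fraction of valid cells exceeds suitability 0.5 (intercept = minus the
#' corresponding upper quantile of the zero-intercept eta), which keeps the
#' extent of the suitable range constant across random landscapes.
#'
#' @param stack A `predictor_stack`.
#' @param coefficients List with `linear`, `quadratic` (lengths matching
#'   the stack) and either `intercept` or `suitable_fraction` (intercept
#'   defaults to 0 when both are absent or `intercept` is `NA` without a
#'   fraction).
#' @return A `raster_grid` of true suitability.
#' @export
generate_true_suitability <- function(stack, coefficients) {
  stopifnot(inherits(stack, "predictor_stack"))
  a <- coefficients$linear; b <- coefficients$quadratic
  if (length(a) != n_layers(stack) || length(b) != n_layers(stack))
    stop("coefficient lengths must match the number of layers")
  g <- stack$layers[[1]]
  eta <- matrix(0, nrow(g$values), ncol(g$values))
  for (i in seq_len(n_layers(stack))) {
    v <- stack$layers[[i]]$values
    mu <- mean(v, na.rm = TRUE); sd <- stats::sd(as.vector(v), na.rm = TRUE)
    zz <- if (sd > 0) (v - mu) / sd else v * 0
    eta <- eta + a[i] * zz + b[i] * zz^2
  }
  c0 <- coefficients$intercept
  if (is.null(c0) || is.na(c0)) {
    frac <- coefficients$suitable_fraction
    c0 <- if (is.null(frac) || is.na(frac)) 0 else
      -stats::quantile(eta, 1 - frac, na.rm = TRUE, names = FALSE)
  }
  raster_grid(stats::plogis(eta + c0), origin = g$origin,
              cellsize = g$cellsize, units = "probability")
}

# Scenario -> coefficient list for generate_true_suitability().
scenario_coefficients <- function(scenario) {
  list(linear = scenario$linear, quadratic = scenario$quadratic,
       intercept = scenario$intercept,
       suitable_fraction = scenario$suitable_fraction)
}

#' Sample presence points proportional to suitability
#'
#' Draws `n` distinct cells without replacement with probability
#' proportional to the suitability value, and returns their cell centres as
#' an `occurrence_set` (no sub-cell jitter, so downstream thinning tests are
#' exact). Status labels are drawn native/invaded at roughly the 40:68
#' mix typical of a combined native-plus-invaded record compilation.
#'
#' @param true_suitability A `raster_grid` with non-negative values.
#' @param n Number of presences; at most the number of valid cells.
#' @param seed Seed for the draw.
#' @return An `occurrence_set`.
#' @export
sample_presences <- function(true_suitability, n, seed = 1L) {
  stopifnot(is_raster_grid(true_suitability))
  v <- true_suitability$values
  idx <- which(!is.na(v))
  if (n > length(idx)) stop("`n` exceeds the number of valid cells")
  w <- v[idx]
  if (all(w == 0)) stop("all-zero suitability: nothing to sample")
  set.seed(seed)
  pick <- idx[sample.int(length(idx), n, replace = FALSE, prob = w)]
  cc <- cell_centers(true_suitability)
  nr <- nrow(v)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  status <- sample(c("native", "invaded"), n, replace = TRUE,
                   prob = c(40, 68))
  rec <- data.frame(id = sprintf("syn%04d", seq_len(n)),
                    lon = cc$lon[col], lat = cc$lat[row],
                    status = status, source = "synthetic",
                    stringsAsFactors = FALSE)
  log_step(new_occurrence_set(rec), "sample_presences", n, n)
}

#' Synthetic host-availability raster
#'
#' A smooth field thresholded at its 40th percentile and squared, rescaled
#' so the maximum equals `scenario$host_max` hectares: crops cover patches
#' of the landscape, most cells grow none, and the minimum is exactly 0 (so
#' normalisation is exercised with a zero minimum, as with real harvested-
#' area data).
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `raster_grid` in hectares.
#' @export
generate_host_raster <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  set.seed(scenario$seed + 1000L)
  f <- smooth_field(nr, nc, scenario$noise_sd)
  f <- pmax(0, f - stats::quantile(f, 0.4))^2
  f <- f / max(f) * scenario$host_max
  raster_grid(matrix(f, nr, nc), origin = scenario$origin,
              cellsize = scenario$cell_size, units = "ha")
}

#' Apply a climate-scenario perturbation to a stack
#'
#' Emulates a projected climate: temperature-role layers are shifted by
#' `temp_offset` (deg C, e.g. 2.0 for a high-emission mid-century pathway)
#' and precipitation-role layers are multiplied by `precip_scale`; geometry
#' and other layers are unchanged.
#'
#' @param stack A `predictor_stack` with roles set.
#' @param temp_offset Additive temperature offset, deg C.
#' @param precip_scale Multiplicative precipitation factor (>= 0).
#' @return The perturbed `predictor_stack`.
#' @export
perturb_scenario <- function(stack, temp_offset = 0, precip_scale = 1) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (!is.finite(temp_offset) || !is.finite(precip_scale))
    stop("offsets must be finite")
  if (precip_scale < 0) stop("`precip_scale` must be non-negative")
  out <- stack
  for (i in seq_len(n_layers(stack))) {
    role <- stack$roles[i]
    if (role == "temperature")
      out$layers[[i]]$values <- stack$layers[[i]]$values + temp_offset
    else if (role == "precipitation")
      out$layers[[i]]$values <- stack$layers[[i]]$values * precip_scale
  }
  out
}

#' Write all fixtures of a scenario to a directory
#'
#' Writes one ASCII grid per predictor layer, the true-suitability and host
#' rasters, the presence CSV and a JSON copy of the scenario settings.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the generated objects.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack <- generate_predictor_stack(scenario)
  truth <- generate_true_suitability(stack, scenario_coefficients(scenario))
  occ <- sample_presences(truth, scenario$presence_n,
                          seed = scenario$seed + 1L)
  host <- generate_host_raster(scenario)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_ascii_grid(truth, file.path(dir, "true_suitability.asc"))
  write_ascii_grid(host, file.path(dir, "host.asc"))
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  cfg <- unclass(scenario)
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stack = stack, truth = truth, occurrences = occ,
                 host = host))
}
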