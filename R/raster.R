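#' Gridded raster field
#'
#' Lightweight in-memory raster: a numeric matrix of cell values on a regular
#' lon/lat grid (WGS84 decimal degrees), with the upper-left corner and the
#' square cell size defining the geotransform. `NA` cells are nodata.
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param origin Length-2 numeric, lon/lat of the upper-left *corner* of the
#'   grid, decimal degrees.
#' @param cellsize Cell edge length in decimal degrees (> 0).
#' @param units Free-text unit label for the cell values.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin, cellsize, units = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (length(origin) != 2L || !is.numeric(origin) || anyNA(origin))
    stop("`origin` must be numeric lon/lat of the upper-left corner")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, origin = as.numeric(origin),
         cellsize = as.numeric(cellsize), units = as.character(units)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d cells, %.6g deg, origin (%.4f, %.4f)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              x$origin[1], x$origin[2]))
  cat(sprintf("  valid cells: %d; range [%.6g, %.6g]%s\n",
              length(v), if (length(v)) min(v) else NA,
              if (length(v)) max(v) else NA,
              if (nzchar(x$units)) paste0(" ", x$units) else ""))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Cell-centre coordinates of a raster grid
#'
#' @param grid A `raster_grid`.
#' @return List with `lon` (per column) and `lat` (per row) cell-centre
#'   coordinate vectors.
#' @export
cell_centers <- function(grid) {
  stopifnot(is_raster_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(lon = grid$origin[1] + (seq_len(nc) - 0.5) * grid$cellsize,
       lat = grid$origin[2] - (seq_len(nr) - 0.5) * grid$cellsize)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Collection of co-registered raster layers
#'
#' @param layers Named list of `raster_grid` objects sharing one geometry.
#' @param roles Optional character vector (one per layer) giving each layer's
#'   climatic role, e.g. `"temperature"`, `"precipitation"` or `"other"`;
#'   used by scenario perturbation.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, roles = NULL) {
  if (!is.list(layers) || length(layers) == 0)
    stop("`layers` must be a non-empty named list of raster_grid objects")
  nm <- names(layers)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("layer names must be present and unique")
  for (l in layers)
    if (!is_raster_grid(l)) stop("every layer must be a raster_grid")
  ref <- layers[[1]]
  for (i in seq_along(layers))
    if (!same_geometry(ref, layers[[i]]))
      stop(sprintf("layer '%s' is not co-registered with '%s'", nm[i], nm[1]))
  if (is.null(roles)) roles <- rep("other", length(layers))
  if (length(roles) != length(layers))
    stop("`roles` must have one entry per layer")
  structure(list(layers = layers, roles = stats::setNames(roles, nm)),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers (%s)\n", length(x$layers),
              paste(utils::head(names(x$layers), 6), collapse = ", ")))
  print(x$layers[[1]])
  invisible(x)
}

n_layers <- function(stack) length(stack$layers)

#' Flatten a stack to a cells-by-layers value matrix
#'
#' Cells are in R's column-major order of the underlying value matrices.
#' @param stack A `predictor_stack`.
#' @return Numeric matrix, one column per layer.
#' @export
stack_values <- function(stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  vapply(stack$layers, function(l) as.vector(l$values),
         numeric(length(stack$layers[[1]]$values)))
}

#' Jointly-valid cell mask of a stack
#'
#' @param stack A `predictor_stack`.
#' @return Logical matrix, TRUE where every layer has data.
#' @export
valid_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]]$values)
  for (l in stack$layers[-1]) m <- m & !is.na(l$values)
  m
}

# Map lon/lat to (row, col); coordinates outside the grid give NA.
coords_to_rowcol <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$origin[1]) / grid$cellsize) + 1L
  row <- floor((grid$origin[2] - lat) / grid$cellsize) + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract per-layer values at point locations
#'
#' @param stack A `predictor_stack`.
#' @param lon,lat Point coordinates, decimal degrees.
#' @return Data frame with one column per layer; points falling outside the
#'   grid raise an error.
#' @export
extract_values <- function(stack, lon, lat) {
  stopifnot(inherits(stack, "predictor_stack"), length(lon) == length(lat))
  rc <- coords_to_rowcol(stack$layers[[1]], lon, lat)
  if (anyNA(rc)) stop("some points fall outside the raster extent")
  idx <- rc[, "row"] + (rc[, "col"] - 1L) * nrow(stack$layers[[1]]$values)
  out <- lapply(stack$layers, function(l) l$values[idx])
  as.data.frame(out, optional = TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster with explicit nodata (-9999); deterministic
#' output so identical grids yield identical files.
#'
#' @param grid A `raster_grid`.
#' @param path Output file path (conventionally `.asc`).
#' @param digits Significant digits written per value.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  stopifnot(is_raster_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$cellsize),
    sprintf("cellsize %.10g", grid$cellsize),
    "NODATA_value -9999")
  v <- grid$values
  v[is.na(v)] <- -9999
  rows <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param units Unit label to attach.
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, units = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
              cellsize = hdr$cellsize, units = units)
}
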