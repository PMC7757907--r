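#' @importFrom geosphere distHaversine
NULL

# Mean Earth radius (IUGG), km; all great-circle distances in the package
# use this value.
EARTH_RADIUS_KM <- 6371.0088

# Vectorised great-circle distance in km between (lon1,lat1) and (lon2,lat2).
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

new_occurrence_set <- function(records, provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(step = character(), n_in = integer(),
                             n_kept = integer(), n_removed = integer(),
                             stringsAsFactors = FALSE)
  structure(list(records = records, provenance = provenance),
            class = "occurrence_set")
}

log_step <- function(set, step, n_in, n_kept) {
  set$provenance <- rbind(set$provenance, data.frame(
    step = step, n_in = n_in, n_kept = n_kept, n_removed = n_in - n_kept,
    stringsAsFactors = FALSE))
  set
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records\n", nrow(x$records)))
  if (nrow(x$provenance)) {
    cat("filters applied:\n")
    for (i in seq_len(nrow(x$provenance)))
      cat(sprintf("  %-12s %d -> %d (%d removed)\n", x$provenance$step[i],
                  x$provenance$n_in[i], x$provenance$n_kept[i],
                  x$provenance$n_removed[i]))
  }
  invisible(x)
}

#' Load presence records from CSV
#'
#' Expects columns `id,lon,lat,status,source`. Rows whose coordinates do not
#' parse as numbers or fall outside WGS84 bounds (|lon| <= 180, |lat| <= 90)
#' are dropped and logged — the programmatic analogue of visually screening a
#' plotted map for gross georeferencing errors. Duplicate coordinates are
#' retained here; removing them is an explicit, separately logged step
#' ([deduplicate()]).
#'
#' @param path CSV file path.
#' @return An `occurrence_set` with a provenance log.
#' @export
load_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("occurrence file is empty: ", path)
  need <- c("id", "lon", "lat", "status", "source")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence file lacks required columns: ",
         paste(missing, collapse = ", "))
  df <- df[need]
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  n_in <- nrow(df)
  ok <- !is.na(df$lon) & !is.na(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  kept <- df[ok, , drop = FALSE]
  if (anyDuplicated(kept$id)) stop("record ids must be unique")
  rownames(kept) <- NULL
  set <- new_occurrence_set(kept)
  log_step(set, "load", n_in, nrow(kept))
}

#' Remove exact coordinate duplicates
#'
#' Keeps the first record at each identical (lon, lat) pair; exact equality
#' is used on purpose — near-duplicates are the business of spatial thinning,
#' which has an explicit distance, not of an undocumented fuzz radius.
#'
#' @param set An `occurrence_set`.
#' @return The deduplicated `occurrence_set`, removal logged.
#' @export
deduplicate <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  n_in <- nrow(set$records)
  keep <- !duplicated(set$records[c("lon", "lat")])
  set$records <- set$records[keep, , drop = FALSE]
  rownames(set$records) <- NULL
  log_step(set, "deduplicate", n_in, nrow(set$records))
}

#' Spatially thin records to a minimum separation
#'
#' Greedy single pass in input order: a record is kept iff its great-circle
#' (haversine) distance to every previously kept record is at least `min_km`.
#' This guarantees every retained pair is `>= min_km` apart and makes runs
#' reproducible (input order = file order). The 10 km default mirrors the
#' common practice of filtering occurrences to reduce spatial autocorrelation
#' before fitting a niche model.
#'
#' @param set An `occurrence_set`.
#' @param min_km Minimum pairwise distance, kilometres (> 0).
#' @return The thinned `occurrence_set`, removals logged.
#' @export
thin_spatial <- function(set, min_km = 10) {
  stopifnot(inherits(set, "occurrence_set"))
  if (!is.numeric(min_km) || min_km <= 0) stop("`min_km` must be > 0")
  df <- set$records
  n_in <- nrow(df)
  kept <- logical(n_in)
  for (i in seq_len(n_in)) {
    prior <- which(kept)
    if (length(prior) == 0) {
      kept[i] <- TRUE
    } else {
      d <- gc_distance_km(df$lon[prior], df$lat[prior], df$lon[i], df$lat[i])
      kept[i] <- all(d >= min_km)
    }
  }
  set$records <- df[kept, , drop = FALSE]
  rownames(set$records) <- NULL
  log_step(set, sprintf("thin_%gkm", min_km), n_in, nrow(set$records))
}

#' Write an occurrence set to CSV
#'
#' @param set An `occurrence_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(set, path) {
  stopifnot(inherits(set, "occurrence_set"))
  utils::write.csv(set$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
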