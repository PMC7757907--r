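#' Pairwise Pearson correlations between stack layers
#'
#' Correlations are computed over the jointly valid (complete-case) cells so
#' every pair is measured on one consistent sample. For large grids a seeded
#' random subsample of `max_cells` cells can be used. A constant layer has no
#' defined correlation; its entries are flagged `NA` in `undefined`, reported
#' as 0 in the matrix (so elimination treats it as uncorrelated) and a
#' warning is raised.
#'
#' @param stack A `predictor_stack` with at least two layers.
#' @param max_cells Maximum number of cells used (default all).
#' @param seed Seed for the subsample draw.
#' @return A `correlation_report`: `matrix` (symmetric, unit diagonal),
#'   `undefined` (logical matrix), `layers`, `dropped` (empty here),
#'   `cutoff` (`NA` here).
#' @export
pearson_matrix <- function(stack, max_cells = Inf, seed = 1L) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (n_layers(stack) < 2) stop("need at least two layers")
  vals <- stack_values(stack)
  ok <- stats::complete.cases(vals)
  if (sum(ok) < 3) stop("need at least 3 jointly valid cells")
  vals <- vals[ok, , drop = FALSE]
  if (is.finite(max_cells) && nrow(vals) > max_cells) {
    set.seed(seed)
    vals <- vals[sample.int(nrow(vals), max_cells), , drop = FALSE]
  }
  sds <- apply(vals, 2, stats::sd)
  const <- sds == 0
  m <- suppressWarnings(stats::cor(vals))
  undefined <- is.na(m)
  if (any(const)) {
    warning("constant layer(s): ", paste(colnames(vals)[const], collapse = ", "),
            "; their correlations are undefined and treated as 0")
    m[is.na(m)] <- 0
  }
  diag(m) <- 1
  structure(list(matrix = m, undefined = undefined,
                 layers = names(stack$layers), dropped = character(0),
                 cutoff = NA_real_),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d layers", length(x$layers)))
  if (length(x$dropped))
    cat(sprintf("; %d dropped at |r| > %g: %s", length(x$dropped), x$cutoff,
                paste(x$dropped, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Eliminate collinear layers above a correlation cutoff
#'
#' Iterative worst-pair heuristic: while any retained pair exceeds the
#' cutoff in absolute correlation, take the pair with the largest |r| and
#' drop the member whose mean absolute correlation against all other retained
#' layers is larger (ties broken by layer name order, for determinism).
#' After completion no retained pair exceeds the cutoff. The 0.7 default is
#' the conventional collinearity threshold for niche-model predictors.
#'
#' @param report A `correlation_report` from [pearson_matrix()].
#' @param cutoff Absolute-correlation threshold in (0, 1).
#' @return The report with `dropped` filled (in elimination order) and the
#'   matrix restricted to the retained layers.
#' @export
eliminate_correlated <- function(report, cutoff = 0.7) {
  stopifnot(inherits(report, "correlation_report"))
  m <- report$matrix
  dropped <- character(0)
  repeat {
    a <- abs(m); diag(a) <- 0
    if (nrow(a) < 2 || max(a) <= cutoff) break
    ij <- which(a == max(a), arr.ind = TRUE)[1, ]
    cand <- rownames(m)[ij]
    mean_abs <- vapply(ij, function(k) mean(abs(m)[k, -k]), numeric(1))
    # drop the member more correlated with everything else
    pick <- if (mean_abs[1] > mean_abs[2]) 1L
            else if (mean_abs[2] > mean_abs[1]) 2L
            else order(cand)[1]  # tie: drop the name sorting first
    loser <- cand[pick]
    dropped <- c(dropped, loser)
    keep <- rownames(m) != loser
    m <- m[keep, keep, drop = FALSE]
  }
  report$dropped <- dropped
  report$matrix <- m
  report$cutoff <- cutoff
  report
}

#' Retained layer names after elimination
#'
#' @param report A `correlation_report` processed by [eliminate_correlated()].
#' @return Character vector of retained layer names.
#' @export
retained_layers <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  setdiff(report$layers, report$dropped)
}

#' Subset a stack to named layers
#'
#' @param stack A `predictor_stack`.
#' @param names Layer names to keep.
#' @return The subset `predictor_stack`.
#' @export
subset_stack <- function(stack, names) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (!all(names %in% names(stack$layers)))
    stop("unknown layer(s): ",
         paste(setdiff(names, names(stack$layers)), collapse = ", "))
  predictor_stack(stack$layers[names], roles = unname(stack$roles[names]))
}
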