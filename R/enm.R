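#' @useDynLib flyrisk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Feature specification for the maximum-entropy model
#'
#' Feature classes define the allowed shapes of the fitted response curves:
#' linear (x), quadratic (x^2) and hinge (piecewise-linear ramps at evenly
#' spaced knots, in both directions). Variables are rescaled to [0,1] before
#' feature construction so every feature is itself in [0,1].
#'
#' @param classes Subset of `c("linear", "quadratic", "hinge")`.
#' @param hinge_knots Interior knots per variable per direction (>= 1).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(classes = c("linear", "quadratic", "hinge"),
                         hinge_knots = 20L) {
  classes <- match.arg(classes, c("linear", "quadratic", "hinge"),
                       several.ok = TRUE)
  if (length(classes) == 0) stop("at least one feature class is required")
  if ("hinge" %in% classes && hinge_knots < 1)
    stop("`hinge_knots` must be >= 1 when hinge features are enabled")
  structure(list(classes = classes, hinge_knots = as.integer(hinge_knots)),
            class = "feature_spec")
}

# Per-variable [0,1] scaling bounds from a data frame of raw values.
variable_scaling <- function(df) {
  data.frame(variable = names(df),
             min = vapply(df, min, numeric(1), na.rm = TRUE),
             max = vapply(df, max, numeric(1), na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

scale_variables <- function(df, scaling, clamp = TRUE) {
  out <- df
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    rng <- scaling$max[i] - scaling$min[i]
    x <- if (rng > 0) (df[[v]] - scaling$min[i]) / rng else df[[v]] * 0
    if (clamp) x <- pmin(1, pmax(0, x))
    out[[v]] <- x
  }
  out[scaling$variable]
}

#' Build the model feature matrix from scaled variables
#'
#' @param scaled Data frame of variables already rescaled to [0,1].
#' @param spec A [feature_spec()].
#' @return Numeric matrix with named columns; attribute `variable` maps each
#'   column to its source variable. Constant variables contribute no columns
#'   (with a warning).
#' @export
build_features <- function(scaled, spec = feature_spec(),
                           drop_constant = TRUE) {
  stopifnot(inherits(spec, "feature_spec"))
  cols <- list(); owner <- character(0)
  K <- spec$hinge_knots
  knots <- seq_len(K) / (K + 1)
  for (v in names(scaled)) {
    x <- scaled[[v]]
    if (drop_constant && max(x) == min(x)) {
      warning("variable '", v, "' is constant; its features are dropped")
      next
    }
    if ("linear" %in% spec$classes) {
      cols[[paste0(v, ".lin")]] <- x; owner <- c(owner, v)
    }
    if ("quadratic" %in% spec$classes) {
      cols[[paste0(v, ".quad")]] <- x^2; owner <- c(owner, v)
    }
    if ("hinge" %in% spec$classes) {
      for (k in knots) {
        cols[[sprintf("%s.hf%.3f", v, k)]] <- pmax(0, (x - k) / (1 - k))
        cols[[sprintf("%s.hr%.3f", v, k)]] <- pmax(0, (k - x) / k)
        owner <- c(owner, v, v)
      }
    }
  }
  if (length(cols) == 0) stop("no usable features (all variables constant)")
  F <- do.call(cbind, cols)
  colnames(F) <- names(cols)
  attr(F, "variable") <- owner
  F
}

#' Sample background (pseudo-absence) points from a stack
#'
#' Uniform draw without replacement over the jointly valid cells; all valid
#' cells are returned when fewer than `n` exist. Cell centres are used as
#' point coordinates.
#'
#' @param stack A `predictor_stack`.
#' @param n Number of points (default 10000).
#' @param seed Seed for the draw.
#' @return Data frame with `lon`, `lat` and one column per layer.
#' @export
sample_background <- function(stack, n = 10000L, seed = 1L) {
  stopifnot(inherits(stack, "predictor_stack"), n >= 1)
  mask <- valid_mask(stack)
  idx <- which(mask)
  if (length(idx) == 0) stop("no valid cells to sample background from")
  if (length(idx) > n) {
    set.seed(seed)
    idx <- idx[sample.int(length(idx), n)]
  }
  g <- stack$layers[[1]]
  cc <- cell_centers(g)
  nr <- nrow(g$values)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  vals <- as.data.frame(lapply(stack$layers, function(l) l$values[idx]),
                        optional = TRUE)
  cbind(data.frame(lon = cc$lon[col], lat = cc$lat[row]), vals)
}

# L1 penalty per feature column, following the reference behaviour: a base
# value per feature class times the feature's standard deviation at the
# presences (floored, so features constant at presences still carry a
# positive penalty and cannot run away), scaled by 1/sqrt(m) (m = presence
# count) and by the regularization multiplier.
feature_penalties <- function(Fp, reg_multiplier,
                              base = c(lq = 0.2, hinge = 0.5),
                              sd_floor = c(lq = 0.05, hinge = 0.15)) {
  m <- nrow(Fp)
  is_hinge <- grepl("\\.h[fr]", colnames(Fp))
  b <- ifelse(is_hinge, base[["hinge"]], base[["lq"]])
  fl <- ifelse(is_hinge, sd_floor[["hinge"]], sd_floor[["lq"]])
  sdp <- pmax(apply(Fp, 2, stats::sd), fl)
  b * sdp * reg_multiplier / sqrt(m)
}

#' Fit the presence-background maximum-entropy model
#'
#' Estimates a Gibbs density q(x) = exp(lambda . f(x)) / Z over the point
#' universe (background plus presences, the reference behaviour), choosing
#' coefficients that maximise the L1-penalized mean presence log-density
#'
#'   (1/m) sum_presences log q(x_i)  -  sum_j beta_j |lambda_j|,
#'
#' by cyclic coordinate descent with soft-thresholding (compiled core). The
#' per-feature penalties beta_j are a per-class base value times the
#' feature's (floored) standard deviation at the presences, scaled by
#' 1/sqrt(m) and multiplied by `reg_multiplier`; a multiplier of 2 (the
#' default) doubles the smoothing relative to the base settings, the usual
#' prescription against overfitting with small presence samples.
#'
#' @param presences Data frame of predictor values at presence points (one
#'   column per variable; extra `lon`/`lat` columns are ignored).
#' @param background Data frame of predictor values at background points
#'   (same variables).
#' @param spec A [feature_spec()].
#' @param reg_multiplier Scalar L1 penalty multiplier (default 2).
#' @param tol Convergence tolerance on the objective per full cycle.
#' @param max_iter Maximum coordinate-descent cycles.
#' @return A `maxent_model`: coefficients, penalties, scaling bounds, the
#'   background normalizer `logZ`, the entropy `H` (nats) of the fitted raw
#'   distribution, the objective `trace`, per-variable gain credits and fit
#'   metadata. Non-convergence sets `converged = FALSE` with a warning.
#' @export
fit_maxent <- function(presences, background, spec = feature_spec(),
                       reg_multiplier = 2, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(spec, "feature_spec"))
  vars <- setdiff(names(background), c("lon", "lat"))
  if (length(vars) == 0) stop("background has no predictor columns")
  if (!all(vars %in% names(presences)))
    stop("presences lack predictor column(s): ",
         paste(setdiff(vars, names(presences)), collapse = ", "))
  pres <- presences[vars]; bg <- background[vars]
  m <- nrow(pres)
  if (m < 2) stop("need at least 2 presences")
  if (anyNA(pres) || anyNA(bg)) stop("NA predictor values are not allowed")

  universe <- rbind(bg, pres)  # presences are part of the normalization
  scaling <- variable_scaling(universe)
  su <- scale_variables(universe, scaling)
  sp <- scale_variables(pres, scaling)
  Fu <- build_features(su, spec)
  Fp <- build_features(sp, spec, drop_constant = FALSE)[, colnames(Fu),
                                                        drop = FALSE]
  fp <- colMeans(Fp)
  beta <- feature_penalties(Fp, reg_multiplier)

  fit <- maxent_ccd(Fu, fp, beta, tol, as.integer(max_iter))
  if (!fit$converged)
    warning("coordinate descent did not converge in ", max_iter, " cycles")

  q <- exp(fit$eta - fit$logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))

  lambda <- stats::setNames(fit$lambda, colnames(Fu))
  credit <- stats::setNames(fit$credit, colnames(Fu))
  structure(list(
    spec = spec, variables = vars, scaling = scaling,
    lambda = lambda, beta = stats::setNames(beta, colnames(Fu)),
    feature_variable = stats::setNames(attr(Fu, "variable"), colnames(Fu)),
    reg_multiplier = reg_multiplier,
    logZ = fit$logZ, H = H,
    n_presence = m, n_background = nrow(bg), n_universe = nrow(universe),
    trace = fit$trace, credit = credit, converged = fit$converged,
    universe_q = q),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d variables, %d features (%d nonzero), reg x%g\n",
    length(x$variables), length(x$lambda), sum(x$lambda != 0),
    x$reg_multiplier))
  cat(sprintf("  presences %d, background %d; entropy H = %.4f nats%s\n",
              x$n_presence, x$n_background, x$H,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Linear predictor lambda . f(x) for new raw predictor values.
model_eta <- function(model, newdata) {
  s <- scale_variables(newdata[model$variables], model$scaling, clamp = TRUE)
  F <- build_features(s, model$spec, drop_constant = FALSE)
  keep <- intersect(colnames(F), names(model$lambda))
  drop(F[, keep, drop = FALSE] %*% model$lambda[keep])
}

#' Predict from a fitted maximum-entropy model
#'
#' `type = "raw"` gives the Gibbs density q(x) relative to the training
#' universe (sums to 1 over that universe); `"logistic"` applies the
#' entropy-calibrated transform p = e^H q / (1 + e^H q), which maps a
#' typical background cell (q equal to the uniform density) to 0.5 and is
#' read as a relative probability of presence. Predictor values outside the
#' training range are clamped to the [0,1] scaling bounds.
#'
#' @param object A `maxent_model`.
#' @param newdata Data frame of predictor values, or a `predictor_stack`.
#' @param type `"logistic"` (default), `"raw"` or `"link"` (lambda . f).
#' @param ... Unused.
#' @return Numeric vector, or a `raster_grid` when `newdata` is a stack.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "predictor_stack"))
    return(predict_logistic_stack(object, newdata, type))
  eta <- model_eta(object, newdata)
  switch(type,
         link = eta,
         raw = exp(eta - object$logZ),
         logistic = {
           qe <- exp(object$H + eta - object$logZ)
           qe / (1 + qe)
         })
}

predict_logistic_stack <- function(model, stack, type = "logistic") {
  miss <- setdiff(model$variables, names(stack$layers))
  if (length(miss))
    stop("stack lacks model variable(s): ", paste(miss, collapse = ", "))
  g <- stack$layers[[1]]
  mask <- valid_mask(subset_stack(stack, model$variables))
  idx <- which(mask)
  df <- as.data.frame(lapply(stack$layers[model$variables],
                             function(l) l$values[idx]), optional = TRUE)
  p <- predict.maxent_model(model, df, type = type)
  out <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  out[idx] <- p
  raster_grid(out, origin = g$origin, cellsize = g$cellsize,
              units = if (type == "logistic") "probability" else type)
}

#' Logistic suitability surface over a predictor stack
#'
#' Convenience wrapper for [predict.maxent_model()] with `type = "logistic"`.
#'
#' @param model A `maxent_model`.
#' @param stack A `predictor_stack` holding the model's variables.
#' @return A `raster_grid` of logistic suitability in (0, 1).
#' @export
predict_logistic <- function(model, stack) {
  predict.maxent_model(model, stack, type = "logistic")
}

#' Random 75/25-style presence split
#'
#' @param set An `occurrence_set` or data frame.
#' @param train_frac Training fraction; train size is `round(train_frac * n)`.
#' @param seed Seed for the partition.
#' @return List with `train` and `test`, same class as the input.
#' @export
split_presences <- function(set, train_frac = 0.75, seed = 1L) {
  df <- if (inherits(set, "occurrence_set")) set$records else set
  n <- nrow(df)
  if (n < 4) stop("need at least 4 records to split")
  set.seed(seed)
  n_train <- round(train_frac * n)
  tr <- sort(sample.int(n, n_train))
  wrap <- function(d) {
    rownames(d) <- NULL
    if (inherits(set, "occurrence_set")) new_occurrence_set(d, set$provenance)
    else d
  }
  list(train = wrap(df[tr, , drop = FALSE]),
       test = wrap(df[-tr, , drop = FALSE]))
}

#' Rank-sum (Mann-Whitney) AUC
#'
#' Probability that a random presence outscores a random background point,
#' with half credit for ties; invariant under monotone transforms of the
#' scores.
#'
#' @param scores_presence Numeric scores at presences.
#' @param scores_background Numeric scores at background points.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores_presence, scores_background) {
  m <- length(scores_presence); n <- length(scores_background)
  if (m == 0 || n == 0) stop("both score vectors must be non-empty")
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Per-variable percent contribution
#'
#' Each accepted coordinate-descent update's objective gain is credited to
#' the variable owning the updated feature; credits are normalised to sum to
#' 100. A model with zero total gain returns uniform contributions with a
#' warning.
#'
#' @param model A `maxent_model`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  by_var <- tapply(model$credit, model$feature_variable[names(model$credit)],
                   sum)
  out <- stats::setNames(rep(0, length(model$variables)), model$variables)
  out[names(by_var)] <- pmax(0, by_var)
  total <- sum(out)
  if (total <= 0) {
    warning("zero total gain; contributions reported as uniform")
    return(stats::setNames(rep(100 / length(out), length(out)), names(out)))
  }
  100 * out / total
}

# Training gain: mean presence log-density relative to a uniform background
# (reference-style regularized training gain, without the penalty term).
model_gain <- function(model, presences) {
  eta <- model_eta(model, presences)
  mean(eta) - model$logZ + log(model$n_universe)
}

#' Jackknife variable-importance analysis
#'
#' For each variable, fits a model without it and a model with it alone, and
#' reports the training gain and the test AUC of each sub-model (plus the
#' full model, row `"full"`). A sub-model that fails to fit is reported as
#' `NA` without aborting the rest.
#'
#' @param train_presences,background Data frames of predictor values.
#' @param test_presences Data frame used for the AUC columns.
#' @param spec A [feature_spec()].
#' @param reg_multiplier,tol,max_iter Passed to [fit_maxent()].
#' @return Data frame with columns `variable`, `gain_without`, `gain_only`,
#'   `auc_without`, `auc_only`.
#' @export
jackknife <- function(train_presences, background, test_presences,
                      spec = feature_spec(), reg_multiplier = 2,
                      tol = 1e-6, max_iter = 500L) {
  vars <- setdiff(names(background), c("lon", "lat"))
  if (length(vars) < 2) stop("jackknife needs at least 2 variables")
  fit_one <- function(keep) {
    tryCatch({
      mdl <- fit_maxent(train_presences[keep], background[keep],
                        spec, reg_multiplier, tol, max_iter)
      list(gain = model_gain(mdl, train_presences[keep]),
           auc = auc(predict.maxent_model(mdl, test_presences, "raw"),
                     predict.maxent_model(mdl, background, "raw")))
    }, error = function(e) list(gain = NA_real_, auc = NA_real_))
  }
  rows <- lapply(vars, function(v) {
    wo <- fit_one(setdiff(vars, v))
    on <- fit_one(v)
    data.frame(variable = v, gain_without = wo$gain, gain_only = on$gain,
               auc_without = wo$auc, auc_only = on$auc,
               stringsAsFactors = FALSE)
  })
  full <- fit_one(vars)
  out <- do.call(rbind, rows)
  rbind(out, data.frame(variable = "full", gain_without = full$gain,
                        gain_only = full$gain, auc_without = full$auc,
                        auc_only = full$auc, stringsAsFactors = FALSE))
}

#' 10 percent training-presence threshold
#'
#' The 10th percentile (linear interpolation) of the logistic predictions at
#' the training presences: the conservative cutoff below which the lowest
#' tenth of training presences fall. Reported for optional masking; not
#' applied automatically.
#'
#' @param model A `maxent_model`.
#' @param training_presences Data frame of predictor values at training
#'   presences.
#' @param prob Percentile (default 0.1).
#' @return The logistic threshold value.
#' @export
threshold_10pct <- function(model, training_presences, prob = 0.1) {
  p <- predict.maxent_model(model, training_presences, type = "logistic")
  unname(stats::quantile(p, probs = prob, type = 7))
}

#' Mask cells below a suitability threshold
#'
#' @param raster A `raster_grid` of logistic suitability.
#' @param threshold Cells with value strictly below it are set to 0.
#' @return The masked `raster_grid`.
#' @export
apply_threshold <- function(raster, threshold) {
  stopifnot(is_raster_grid(raster))
  v <- raster$values
  v[!is.na(v) & v < threshold] <- 0
  raster$values <- v
  raster
}
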