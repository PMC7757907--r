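default_config_fields <- function() list(
  occurrences = NULL,      # path to CSV or an occurrence_set
  stack = NULL,            # directory of .asc layers or a predictor_stack
  host = NULL,             # path to .asc or a raster_grid
  out_dir = NULL,
  min_km = 10,
  cor_cutoff = 0.7,
  cor_max_cells = Inf,
  features = c("linear", "quadratic", "hinge"),
  hinge_knots = 20L,
  reg_multiplier = 2,
  background_n = 10000L,
  train_frac = 0.75,
  apply_threshold = FALSE,
  class_breaks = c(0.15, 0.30, 0.60),
  host_min = NULL,         # dataset-wide host extrema for normalisation
  host_max = NULL,
  D_max = 40.2,
  k1 = 0.5, k2 = 0.5,
  paper_rounding = TRUE,
  n_gen = 1L,
  reseed_threshold = NULL,
  seed = 1L)

#' Build a validated pipeline configuration
#'
#' Flat key-value settings for [run_pipeline()], defaulting to the study's
#' standard settings (10 km thinning, |r| > 0.7 pruning, linear + quadratic
#' + hinge features with regularization multiplier 2, 75/25 split, 10,000
#' background points, 0.15/0.30/0.60 class breaks, D_max = 40.2 km,
#' k1 = k2 = 0.5). Unknown keys are a fatal error, so typos cannot silently
#' fall back to defaults.
#'
#' @param ... Named settings overriding the defaults.
#' @return A `run_config` object.
#' @export
run_config <- function(...) {
  cfg <- default_config_fields()
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(!nzchar(names(user)))))
    stop("all config settings must be named")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  stopifnot(cfg$min_km > 0, cfg$cor_cutoff > 0, cfg$cor_cutoff < 1,
            cfg$reg_multiplier > 0, cfg$background_n >= 1,
            cfg$train_frac > 0, cfg$train_frac < 1, cfg$D_max > 0)
  structure(cfg, class = "run_config")
}

#' Load and validate a co-registered predictor stack
#'
#' Accepts a directory of single-band `.asc` layers (layer name = file
#' name) or an existing `predictor_stack`; asserts all layers (and the host
#' raster, if given) share one geometry, and unifies the nodata mask: a
#' cell missing in any layer becomes nodata in all layers, with a warning
#' when this changes anything.
#'
#' @param x Directory path or `predictor_stack`.
#' @param host Optional `raster_grid` (or path) checked for co-registration.
#' @return The validated `predictor_stack`.
#' @export
validate_stack <- function(x, host = NULL) {
  stack <- if (inherits(x, "predictor_stack")) x else {
    files <- sort(list.files(x, pattern = "\\.asc$", full.names = TRUE))
    if (length(files) == 0) stop("no .asc layers found in ", x)
    layers <- lapply(files, read_ascii_grid)
    names(layers) <- sub("\\.asc$", "", basename(files))
    predictor_stack(layers)
  }
  if (!is.null(host)) {
    h <- if (is_raster_grid(host)) host else read_ascii_grid(host)
    if (!same_geometry(stack$layers[[1]], h))
      stop("host raster is not co-registered with the predictor stack")
  }
  mask <- valid_mask(stack)
  changed <- FALSE
  for (i in seq_len(n_layers(stack))) {
    extra <- !mask & !is.na(stack$layers[[i]]$values)
    if (any(extra)) {
      stack$layers[[i]]$values[extra] <- NA_real_
      changed <- TRUE
    }
  }
  if (changed)
    warning("layer nodata masks differed; unified to the common mask")
  stack
}

#' Run the full invasion-risk pipeline
#'
#' Thin occurrences, prune collinear predictors, fit the maximum-entropy
#' model on a seeded train/test split, predict the logistic climatic
#' suitability, classify it, merge it with normalised host availability
#' into overall habitat suitability, and run the Gaussian dispersal model
#' from the thinned records. All outputs (rasters as ASCII grids, tables as
#' CSV, a JSON manifest of settings, seeds and per-stage counts) are
#' written under `config$out_dir` when it is set.
#'
#' @param config A [run_config()].
#' @return List with the fitted model, evaluation (AUC, contributions,
#'   threshold), and the suitability / class / overall / dispersal rasters.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  occ <- stage("occurrences", {
    o <- config$occurrences
    if (inherits(o, "occurrence_set")) o else load_occurrences(o)
  })
  occ <- stage("thin", thin_spatial(deduplicate(occ), config$min_km))

  stack <- stage("stack", validate_stack(config$stack, config$host))
  report <- stage("select_vars", {
    r <- pearson_matrix(stack, max_cells = config$cor_max_cells,
                        seed = config$seed)
    eliminate_correlated(r, config$cor_cutoff)
  })
  stack_sel <- subset_stack(stack, retained_layers(report))

  spl <- stage("split", split_presences(occ, config$train_frac,
                                        seed = config$seed + 1L))
  bg <- stage("background", sample_background(stack_sel, config$background_n,
                                              seed = config$seed + 2L))
  pres_train <- stage("extract", extract_values(
    stack_sel, spl$train$records$lon, spl$train$records$lat))
  pres_test <- extract_values(stack_sel, spl$test$records$lon,
                              spl$test$records$lat)

  spec <- feature_spec(config$features, config$hinge_knots)
  model <- stage("fit", fit_maxent(pres_train, bg, spec,
                                   config$reg_multiplier))
  suit <- stage("predict", predict_logistic(model, stack_sel))
  test_auc <- auc(predict.maxent_model(model, pres_test, "logistic"),
                  predict.maxent_model(model, bg, "logistic"))
  thr <- threshold_10pct(model, pres_train)
  if (isTRUE(config$apply_threshold)) suit <- apply_threshold(suit, thr)

  scheme <- class_scheme(config$class_breaks)
  classes <- stage("classify", classify(suit, scheme))

  host <- if (is_raster_grid(config$host)) config$host
          else read_ascii_grid(config$host, units = "ha")
  hn <- stage("normalize_host",
              normalize(host, config$host_min, config$host_max))
  S <- stage("merge", overall_suitability(suit, hn))

  params <- derive_params(config$D_max, config$k1, config$k2,
                          config$paper_rounding)
  disp <- stage("disperse", run_generations(
    suit, hn, occ, params, n_gen = config$n_gen,
    reseed_threshold = config$reseed_threshold))

  result <- list(
    occurrences = occ, correlation = report, model = model,
    evaluation = list(test_auc = test_auc,
                      percent_contribution = percent_contribution(model),
                      threshold_10pct = thr),
    suitability = suit, classes = classes, host_norm = hn, overall = S,
    dispersal = disp, params = params, config = config)

  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_occurrences(result$occurrences, file.path(dir, "occurrences_thinned.csv"))
  utils::write.csv(result$correlation$matrix,
                   file.path(dir, "correlation_matrix.csv"))
  write_ascii_grid(result$suitability, file.path(dir, "suitability.asc"))
  write_ascii_grid(result$classes, file.path(dir, "suitability_classes.asc"))
  write_ascii_grid(result$overall, file.path(dir, "overall_suitability.asc"))
  for (g in seq_along(result$dispersal))
    write_ascii_grid(result$dispersal[[g]],
                     file.path(dir, sprintf("dispersal_gen%d.asc", g)))
  cfg <- unclass(result$config)
  cfg <- cfg[!vapply(cfg, function(x)
    is.null(x) || inherits(x, c("occurrence_set", "predictor_stack",
                                "raster_grid")), logical(1))]
  manifest <- list(
    settings = cfg,
    version = as.character(utils::packageVersion("flyrisk")),
    dropped_layers = result$correlation$dropped,
    counts = list(
      records = nrow(result$occurrences$records),
      provenance = result$occurrences$provenance,
      valid_cells = sum(!is.na(result$suitability$values))),
    evaluation = result$evaluation[c("test_auc", "threshold_10pct")],
    dispersal_params = unclass(result$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' End-to-end synthetic benchmark
#'
#' Generates the default synthetic scenario (reseeded from `seed`), runs
#' the full occurrence-thinning, variable-pruning, model-fitting pipeline,
#' and returns the held-out discrimination and truth-recovery statistics:
#' the rank-sum AUC of the 25% test presences against the background, and
#' the Spearman correlation between the predicted logistic surface and the
#' known true suitability.
#'
#' @param seed Integer master seed (scenario and all pipeline draws derive
#'   from it).
#' @param scenario Optional [synthetic_scenario()] overriding the default
#'   (its own seed is replaced by `seed`).
#' @param background_n Background sample size (default 10000).
#' @return List: `auc`, `spearman`, `n_test`, `n_train`, `n_thinned`,
#'   `dropped_layers`, and the fitted `model`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, scenario = NULL,
                                    background_n = 10000L) {
  seed <- as.integer(seed)
  if (is.null(scenario)) scenario <- synthetic_scenario(seed = seed)
  else scenario$seed <- seed

  stack <- generate_predictor_stack(scenario)
  truth <- generate_true_suitability(stack,
                                     scenario_coefficients(scenario))
  occ <- sample_presences(truth, scenario$presence_n, seed = seed + 1L)
  occ <- thin_spatial(deduplicate(occ), min_km = 10)

  report <- eliminate_correlated(pearson_matrix(stack), cutoff = 0.7)
  stack_sel <- subset_stack(stack, retained_layers(report))

  spl <- split_presences(occ, 0.75, seed = seed + 2L)
  bg <- sample_background(stack_sel, background_n, seed = seed + 3L)
  pres_train <- extract_values(stack_sel, spl$train$records$lon,
                               spl$train$records$lat)
  pres_test <- extract_values(stack_sel, spl$test$records$lon,
                              spl$test$records$lat)
  model <- fit_maxent(pres_train, bg, feature_spec(), reg_multiplier = 2)

  pred <- predict_logistic(model, stack_sel)
  ok <- !is.na(pred$values) & !is.na(truth$values)
  rho <- stats::cor(pred$values[ok], truth$values[ok], method = "spearman")
  list(auc = auc(predict.maxent_model(model, pres_test, "logistic"),
                 predict.maxent_model(model, bg, "logistic")),
       spearman = rho,
       n_test = nrow(pres_test), n_train = nrow(pres_train),
       n_thinned = nrow(occ$records),
       dropped_layers = report$dropped,
       model = model)
}
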