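test_that("identical scenarios produce bit-identical fixtures", {
  sc <- small_scenario(seed = 11L)
  s1 <- generate_predictor_stack(sc)
  s2 <- generate_predictor_stack(sc)
  expect_identical(s1, s2)
  t1 <- generate_true_suitability(s1, flyrisk:::scenario_coefficients(sc))
  o1 <- sample_presences(t1, 25, seed = 5L)
  o2 <- sample_presences(t1, 25, seed = 5L)
  expect_identical(o1$records, o2$records)
  expect_identical(generate_host_raster(sc)$values,
                   generate_host_raster(sc)$values)
})

test_that("collinear pairs hit their target correlation", {
  sc <- small_scenario(seed = 3L,
                       collinear_pairs = list(c(1, 2, 0.95), c(3, 4, -0.6)))
  st <- generate_predictor_stack(sc)
  v <- stack_values(st)
  expect_gte(cor(v[, 1], v[, 2]), 0.90)
  expect_lte(cor(v[, 1], v[, 2]), 1.0)
  expect_equal(cor(v[, 3], v[, 4]), -0.6, tolerance = 0.05)
})

test_that("layer count, roles and degenerate grids behave", {
  sc <- synthetic_scenario(grid_shape = c(20L, 20L), n_predictors = 19L,
                           collinear_pairs = list(),
                           linear = rep(0, 19), quadratic = rep(0, 19),
                           seed = 2L)
  st <- generate_predictor_stack(sc)
  expect_length(st$layers, 19L)
  expect_setequal(unique(unname(st$roles)),
                  c("temperature", "precipitation"))
  expect_error(synthetic_scenario(grid_shape = c(3L, 50L)), "degenerate")
  expect_error(synthetic_scenario(collinear_pairs = list(c(1, 2, 1.5))),
               "target_r")
})

test_that("true suitability is logistic in the standardised predictors", {
  sc <- small_scenario(seed = 4L, collinear_pairs = list())
  st <- generate_predictor_stack(sc)
  zero <- list(linear = rep(0, 12), quadratic = rep(0, 12), intercept = 0)
  expect_true(all(generate_true_suitability(st, zero)$values == 0.5))

  one <- list(linear = c(2, rep(0, 11)), quadratic = rep(0, 12),
              intercept = 0)
  tr <- generate_true_suitability(st, one)
  x <- as.vector(st$layers[[1]]$values)
  expect_true(all(diff(tr$values[order(x)][c(1, 450, 900)]) > 0))
  # spot-check one cell against a hand-computed logistic(eta)
  z <- (x - mean(x)) / sd(x)
  expect_equal(tr$values[17], plogis(2 * z[17]), tolerance = 1e-12)

  expect_error(generate_true_suitability(
    st, list(linear = 1, quadratic = 0)), "lengths")
})

test_that("intercept calibration fixes the suitable fraction", {
  sc <- small_scenario(seed = 9L)
  st <- generate_predictor_stack(sc)
  tr <- generate_true_suitability(st, flyrisk:::scenario_coefficients(sc))
  expect_equal(mean(tr$values > 0.5), sc$suitable_fraction,
               tolerance = 0.01)
})

test_that("presence sampling respects support, weighting and seeds", {
  v <- matrix(0, 10, 10)
  v[c(3, 14, 55, 78, 91)] <- c(0.2, 0.9, 0.4, 1, 0.6)
  g <- raster_grid(v, c(0, 1), 0.1)
  occ <- sample_presences(g, 5, seed = 1L)
  got <- extract_values(predictor_stack(list(s = g)),
                        occ$records$lon, occ$records$lat)$s
  expect_setequal(round(got, 6), c(0.2, 0.9, 0.4, 1, 0.6))

  expect_error(sample_presences(raster_grid(matrix(0, 5, 5), c(0, 1), 0.1),
                                3), "all-zero")
  expect_error(sample_presences(g, 200), "exceeds")

  sc <- small_scenario(seed = 21L)
  st <- generate_predictor_stack(sc)
  tr <- generate_true_suitability(st, flyrisk:::scenario_coefficients(sc))
  occ <- sample_presences(tr, 60, seed = 8L)
  s_at <- extract_values(predictor_stack(list(s = tr)),
                         occ$records$lon, occ$records$lat)$s
  expect_gt(mean(s_at), mean(tr$values))
})

test_that("presence density converges to the normalised suitability", {
  # chi-square goodness of fit on a coarse 3x3 binning, fixed seed
  sc <- synthetic_scenario(grid_shape = c(60L, 60L), seed = 31L,
                           suitable_fraction = 0.5,
                           linear = c(1, rep(0, 11)),
                           quadratic = rep(0, 12))
  st <- generate_predictor_stack(sc)
  tr <- generate_true_suitability(st, flyrisk:::scenario_coefficients(sc))
  occ <- sample_presences(tr, 600, seed = 32L)
  rc <- flyrisk:::coords_to_rowcol(tr, occ$records$lon, occ$records$lat)
  bin <- function(i) pmin(3L, (i - 1L) %/% 20L + 1L)
  lv <- as.vector(outer(1:3, 1:3, paste))
  obs <- table(factor(paste(bin(rc[, 1]), bin(rc[, 2])), levels = lv))
  expected <- vapply(strsplit(lv, " "), function(b) {
    br <- as.integer(b[1]); bc <- as.integer(b[2])
    sum(tr$values[(20 * (br - 1) + 1):(20 * br),
                  (20 * (bc - 1) + 1):(20 * bc)])
  }, numeric(1))
  p <- suppressWarnings(
    chisq.test(as.vector(obs), p = expected / sum(expected))$p.value)
  expect_gt(p, 1e-3)
})

test_that("host raster is non-negative, zero-reaching and deterministic", {
  sc <- small_scenario(seed = 13L)
  h <- generate_host_raster(sc)
  expect_identical(min(h$values), 0)
  expect_true(all(h$values >= 0))
  expect_equal(max(h$values), sc$host_max)
})

test_that("scenario perturbation shifts temperature and scales rain", {
  sc <- small_scenario(seed = 6L)
  st <- generate_predictor_stack(sc)
  expect_identical(perturb_scenario(st, 0, 1), st)

  warm <- perturb_scenario(st, 2.0, 1)
  is_t <- st$roles == "temperature"
  for (i in which(is_t))
    expect_equal(mean(warm$layers[[i]]$values) -
                   mean(st$layers[[i]]$values), 2.0, tolerance = 1e-12)

  dry <- perturb_scenario(st, 0, 0.8)
  for (i in which(!is_t))
    expect_equal(sum(dry$layers[[i]]$values) /
                   sum(st$layers[[i]]$values), 0.8, tolerance = 1e-12)
  expect_identical(dry$layers[[which(is_t)[1]]],
                   st$layers[[which(is_t)[1]]])
  expect_error(perturb_scenario(st, 0, -1), "non-negative")
})

test_that("write_scenario emits every fixture as plain text", {
  dir <- tempfile("scn")
  sc <- small_scenario(seed = 17L)
  write_scenario(sc, dir)
  files <- list.files(dir)
  expect_true(all(c("bio1.asc", "bio12.asc", "true_suitability.asc",
                    "host.asc", "occurrences.csv", "scenario.json")
                  %in% files))
  occ <- load_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ$records), sc$presence_n)
})
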