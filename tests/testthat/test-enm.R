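make_1d <- function(m = 40, n_bg = 400, signal = TRUE, seed = 1L) {
  # presences drawn from the upper range of a single predictor
  set.seed(seed)
  bg <- data.frame(x = runif(n_bg))
  pres <- if (signal) data.frame(x = runif(m, 0.7, 1))
          else data.frame(x = runif(m))
  list(pres = pres, bg = bg)
}

test_that("feature construction matches the hinge definitions", {
  spec <- feature_spec(hinge_knots = 3L)
  df <- data.frame(v = c(0, 1, 0.75))
  F <- build_features(df, spec)
  expect_true(all(F >= 0 & F <= 1))
  expect_equal(unname(F[1, "v.lin"]), 0)
  expect_equal(unname(F[2, "v.lin"]), 1)
  expect_equal(unname(F[2, "v.quad"]), 1)
  fwd <- grep("\\.hf", colnames(F)); rev <- grep("\\.hr", colnames(F))
  expect_true(all(F[1, fwd] == 0))   # x = 0: forward hinges all 0
  expect_true(all(F[2, fwd] == 1))   # x = 1: forward hinges all 1
  expect_true(all(F[2, rev] == 0))
  expect_equal(unname(F[3, "v.hf0.500"]), (0.75 - 0.5) / (1 - 0.5))
  expect_warning(Fk <- build_features(data.frame(v = c(0, 1),
                                                 k = c(0.5, 0.5)), spec),
                 "constant")
  expect_false(any(grepl("^k\\.", colnames(Fk))))
})

test_that("background sampling clamps, is seeded and uniform", {
  v <- matrix(NA_real_, 8, 8); v[c(1, 9, 20, 33, 60)] <- 1
  st <- predictor_stack(list(a = raster_grid(v, c(0, 1), 0.1)))
  bg <- sample_background(st, n = 10000, seed = 1L)
  expect_equal(nrow(bg), 5)

  sc <- small_scenario(seed = 23L)
  st <- generate_predictor_stack(sc)
  expect_identical(sample_background(st, 50, seed = 4L),
                   sample_background(st, 50, seed = 4L))

  # empirical cell-frequency uniformity over repeated draws
  counts <- table(unlist(lapply(1:200, function(i)
    sample_background(st, 45, seed = i)$lon)))
  p <- suppressWarnings(chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 1e-3)
})

test_that("no signal yields a near-uniform model, huge penalties a null one", {
  d <- make_1d(signal = FALSE, seed = 3L)
  m <- fit_maxent(d$pres, d$bg, feature_spec(hinge_knots = 5L))
  expect_lt(max(abs(m$lambda)), 0.75)
  p <- predict(m, d$bg, type = "logistic")
  expect_lt(max(abs(p - 0.5)), 0.2)

  m0 <- fit_maxent(d$pres, d$bg, feature_spec(hinge_knots = 5L),
                   reg_multiplier = 1e6)
  expect_true(all(m0$lambda == 0))
  expect_true(all(abs(predict(m0, d$bg, type = "logistic") - 0.5) < 1e-12))
})

test_that("1-D fits recover the signal and match a grid-search oracle", {
  d <- make_1d(signal = TRUE, seed = 5L)
  spec <- feature_spec("linear")
  m <- fit_maxent(d$pres, d$bg, spec)
  lam <- unname(m$lambda["x.lin"])
  expect_gt(lam, 0)

  # independent 1-D oracle: scan the penalized objective on a lambda grid
  uni <- rbind(d$bg, d$pres)
  sc <- flyrisk:::variable_scaling(uni)
  f_u <- flyrisk:::scale_variables(uni, sc)$x
  f_p <- flyrisk:::scale_variables(d$pres, sc)$x
  Fp <- build_features(flyrisk:::scale_variables(d$pres, sc), spec,
                       drop_constant = FALSE)
  beta <- flyrisk:::feature_penalties(Fp, 2)
  obj <- function(l) mean(f_p) * l - log(sum(exp(l * f_u))) - beta * abs(l)
  grid <- seq(-10, 10, by = 0.01)
  l_star <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(lam, l_star, tolerance = 0.05)
  expect_gte(obj(lam), obj(l_star) - 1e-6)
})

test_that("the Gibbs density normalises and the objective never decreases", {
  d <- make_1d(seed = 7L)
  m <- fit_maxent(d$pres, d$bg, feature_spec(hinge_knots = 10L))
  expect_equal(sum(m$universe_q), 1, tolerance = 1e-9)
  expect_true(all(diff(m$trace) >= -1e-9))
  expect_gte(m$H, 0)
  expect_true(all(m$beta > 0))
})

test_that("rank-sum AUC handles ties and known cases", {
  expect_equal(auc(c(1, 1), c(0, 0)), 1)
  expect_equal(auc(c(0.3, 0.3), c(0.3, 0.3, 0.3)), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  # invariance under a monotone transform of the scores
  set.seed(2)
  sp <- runif(20); sb <- runif(50)
  expect_equal(auc(sp, sb), auc(qlogis(sp), qlogis(sb)))
})

test_that("logistic output is a monotone map of the raw density", {
  d <- make_1d(seed = 11L)
  m <- fit_maxent(d$pres, d$bg, feature_spec(hinge_knots = 5L))
  raw <- predict(m, d$bg, type = "raw")
  lgs <- predict(m, d$bg, type = "logistic")
  expect_true(all(diff(lgs[order(raw)]) >= 0))
  expect_equal(auc(predict(m, d$pres, "raw"), raw),
               auc(predict(m, d$pres, "logistic"), lgs))
})

test_that("presence splitting is seeded, exact and exhaustive", {
  df <- data.frame(id = 1:74, lon = runif(74), lat = runif(74))
  sp <- split_presences(df, 0.75, seed = 3L)
  expect_equal(nrow(sp$train), 56)  # round(0.75 * 74)
  expect_equal(nrow(sp$test), 18)
  sp2 <- split_presences(df, 0.75, seed = 3L)
  expect_identical(sp, sp2)
  expect_setequal(c(sp$train$id, sp$test$id), df$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
})

test_that("percent contribution credits gains to the right variables", {
  d <- make_1d(seed = 13L)
  m1 <- fit_maxent(d$pres, d$bg, feature_spec("linear"))
  expect_equal(unname(percent_contribution(m1)), 100)

  set.seed(14)
  pres2 <- cbind(d$pres, noise = runif(nrow(d$pres)))
  bg2 <- cbind(d$bg, noise = runif(nrow(d$bg)))
  m2 <- fit_maxent(pres2, bg2, feature_spec(c("linear", "quadratic")))
  pc <- percent_contribution(m2)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_gt(pc[["x"]], pc[["noise"]])
  if (all(m2$lambda[m2$feature_variable == "noise"] == 0))
    expect_equal(pc[["noise"]], 0)
})

test_that("jackknife isolates the signal variable", {
  set.seed(15)
  d <- make_1d(m = 60, seed = 15L)
  pres <- cbind(d$pres, z = runif(60))
  bg <- cbind(d$bg, z = runif(nrow(d$bg)))
  sp <- split_presences(pres, 0.75, seed = 1L)
  jk <- jackknife(sp$train, bg, sp$test, feature_spec(hinge_knots = 5L))
  expect_equal(nrow(jk), 3)  # 2 variables + full = 4 sub-model fits
  full_gain <- jk$gain_without[jk$variable == "full"]
  x_only <- jk$gain_only[jk$variable == "x"]
  z_gone <- jk$gain_without[jk$variable == "z"]
  expect_equal(x_only, full_gain, tolerance = 0.15)
  expect_equal(z_gone, full_gain, tolerance = 0.15)
  expect_gt(jk$auc_only[jk$variable == "x"],
            jk$auc_only[jk$variable == "z"])
})

test_that("the 10 percent training threshold is the interpolated decile", {
  d <- make_1d(seed = 17L)
  m <- fit_maxent(d$pres, d$bg, feature_spec(hinge_knots = 5L))
  p <- predict(m, d$pres, type = "logistic")
  expect_equal(threshold_10pct(m, d$pres),
               unname(quantile(p, 0.1, type = 7)))
  # linear-interpolation oracle on a fixed vector
  expect_equal(unname(quantile(seq(0.1, 1, by = 0.1), 0.1, type = 7)), 0.19)

  g <- raster_grid(matrix(seq(0, 1, length.out = 25), 5, 5), c(0, 1), 0.1)
  masked <- apply_threshold(g, 0.5)
  expect_true(all(masked$values[g$values < 0.5] == 0))
  expect_identical(masked$values[g$values >= 0.5], g$values[g$values >= 0.5])
})
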