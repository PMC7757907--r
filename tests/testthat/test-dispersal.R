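test_that("kernel parameters derive from the 3-sigma dispersal capacity", {
  p <- derive_params(40.2)
  expect_identical(p$sigma, 13.4)
  expect_identical(p$c1, 0.03)
  expect_identical(p$c2, 0.003)
  expect_identical(p$mu, 0)

  u <- derive_params(40.2, paper_rounding = FALSE)
  expect_equal(u$c1, 1 / (13.4 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(u$c2, 1 / (2 * 13.4^2), tolerance = 1e-12)
  expect_equal(u$c1, 0.0297718, tolerance = 1e-6)
  expect_equal(u$c2, 0.0027846, tolerance = 1e-5)

  p3 <- derive_params(3, paper_rounding = FALSE)
  expect_equal(p3$sigma, 1)
  expect_equal(p3$c2, 0.5)
  expect_equal(p3$c1, 0.3989423, tolerance = 1e-6)

  expect_identical(derive_params(40.2, unit_height = TRUE)$c1, 1)
  expect_error(derive_params(-1), "D_max")
})

test_that("25 miles converts to the 40.2 km dispersal capacity", {
  expect_equal(round(miles_to_km(25), 1), 40.2)
})

test_that("the Gaussian kernel is even, peaked at the source, and decays", {
  p <- derive_params(40.2)
  expect_equal(gaussian_kernel(0, p), 0.03)
  expect_equal(gaussian_kernel(13.4, p), 0.017506, tolerance = 1e-4)
  x <- c(0.5, 3, 17, 60)
  expect_equal(gaussian_kernel(x, p), gaussian_kernel(-x, p))
  expect_true(all(diff(gaussian_kernel(c(0, 5, 10, 20, 40, 80), p)) < 0))
  # beyond the maximum dispersal distance the kernel is < 2% of its peak
  expect_lte(gaussian_kernel(3 * p$sigma, p) / p$c1, 0.02)
})

test_that("nearest-source distances match a brute-force haversine scan", {
  g <- raster_grid(matrix(0, 12, 12), c(30, 12), 0.05)
  src <- data.frame(lon = c(30.12, 30.49), lat = c(11.93, 11.62))
  d <- distance_to_nearest_source(g, src)
  cc <- cell_centers(g)
  for (cell in c(1, 40, 77, 144)) {
    row <- (cell - 1) %% 12 + 1; col <- (cell - 1) %/% 12 + 1
    oracle <- min(haversine_oracle(src$lon, src$lat,
                                   cc$lon[col], cc$lat[row]))
    expect_equal(d$values[row, col], oracle, tolerance = 1e-9)
  }
  # a cell containing a source is within half a cell diagonal of it
  rc <- flyrisk:::coords_to_rowcol(g, src$lon[1], src$lat[1])
  half_diag <- haversine_oracle(0, 0, 0.05 / sqrt(2), 0.05 / sqrt(2))
  expect_lte(d$values[rc[1], rc[2]], half_diag)
  expect_error(distance_to_nearest_source(g, data.frame(lon = numeric(0),
                                                        lat = numeric(0))),
               "source")
})

test_that("one degree of latitude is 111.19 km", {
  expect_equal(haversine_oracle(0, 0, 0, 1), 111.1949, tolerance = 1e-4)
  expect_equal(flyrisk:::gc_distance_km(0, 0, 0, 1), 111.1949,
               tolerance = 1e-4)
})

test_that("dispersal likelihood is the habitat term times the kernel", {
  p <- derive_params(40.2)
  ones <- raster_grid(matrix(1, 9, 9), c(0, 1), 0.05)
  zeros <- raster_grid(matrix(0, 9, 9), c(0, 1), 0.05)
  cc <- cell_centers(ones)
  src <- data.frame(lon = cc$lon[5], lat = cc$lat[5])  # exact cell centre

  l <- dispersal_likelihood(ones, ones, src, p)
  expect_equal(l$values[5, 5], 0.03)              # perfect habitat at source
  expect_true(all(l$values <= p$c1 + 1e-15))
  expect_true(all(dispersal_likelihood(zeros, zeros, src, p)$values == 0))

  # exact recomputation: l = habitat x kernel everywhere
  set.seed(21)
  cs <- raster_grid(matrix(runif(81), 9), c(0, 1), 0.05)
  h <- raster_grid(matrix(runif(81), 9), c(0, 1), 0.05)
  l2 <- dispersal_likelihood(cs, h, src, p)
  x <- distance_to_nearest_source(cs, src)
  expect_equal(l2$values,
               (0.5 * cs$values + 0.5 * h$values) / 1 *
                 gaussian_kernel(x$values, p),
               tolerance = 1e-15)

  # holding habitat constant, likelihood never grows with distance
  row5 <- l$values[5, 5:9]
  expect_true(all(diff(row5) <= 0))
  col5 <- l$values[5:9, 5]
  expect_true(all(diff(col5) <= 0))
})

test_that("generations reseed only when the threshold is reachable", {
  p <- derive_params(40.2)
  ones <- raster_grid(matrix(1, 9, 9), c(0, 1), 0.05)
  src <- data.frame(lon = 0.2, lat = 0.8)
  g1 <- run_generations(ones, ones, src, p, n_gen = 1)
  expect_length(g1, 1)
  expect_equal(g1[[1]]$values,
               dispersal_likelihood(ones, ones, src, p)$values)

  unreachable <- run_generations(ones, ones, src, p, n_gen = 2,
                                 reseed_threshold = 1.1 * p$c1)
  expect_equal(unreachable[[2]]$values, unreachable[[1]]$values)

  grow <- run_generations(ones, ones, src, p, n_gen = 2,
                          reseed_threshold = 0.5 * p$c1)
  expect_true(all(grow[[2]]$values >= grow[[1]]$values - 1e-15))
  expect_gt(sum(grow[[2]]$values), sum(grow[[1]]$values))
  expect_error(run_generations(ones, ones, src, p, n_gen = 2), "threshold")
})
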