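test_that("quartile classification matches brute-force rank classes", {
  g <- raster_grid(matrix(sample(1:100), 10, 10))
  qc <- quantile_classes(g)
  # brute force: compare each value against the three type-7 quantiles
  thr <- vapply(c(0.25, 0.5, 0.75), function(p)
    quantile_oracle(as.numeric(g$values), p), numeric(1))
  expected <- matrix(1L + vapply(as.numeric(g$values),
                                 function(x) sum(thr < x), integer(1)),
                     10, 10)
  expect_equal(qc$classes$values, expected)
  # with values 1..100 the quartile bins hold 25 cells each
  expect_equal(unname(table(qc$classes$values)), rep(25L, 4),
               ignore_attr = TRUE)
  # four distinct values map to the four classes
  g4 <- raster_grid(matrix(c(1, 2, 3, 4), 2, 2))
  expect_setequal(as.vector(quantile_classes(g4)$classes$values), 1:4)
  # constant grids collapse with a warning
  expect_warning(qcc <- quantile_classes(raster_grid(matrix(3, 4, 4))),
                 "distinct")
  expect_true(all(qcc$classes$values == 1L))
})

test_that("class frequencies stay near 25% on continuous grids", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- raster_grid(matrix(rnorm(900), 30, 30))
    cls <- quantile_classes(g)$classes$values
    freq <- as.numeric(table(factor(cls, levels = 1:4))) / 900
    expect_true(all(abs(freq - 0.25) < 0.05))
  }
})

test_that("conditional model honours the climatic semantics", {
  rule <- default_con_rule()
  # wettest cell: top precipitation class, bottom temperature class
  expect_equal(rule[4, 1], 4L)
  # driest cell: bottom precipitation, top temperature
  expect_equal(rule[1, 4], 1L)
  # monotone: non-decreasing in P, non-increasing in T
  expect_true(all(apply(rule, 2, diff) >= 0))
  expect_true(all(apply(rule, 1, diff) <= 0))
  # a non-monotone custom rule is rejected unless explicitly allowed
  bad <- rule; bad[1, 1] <- 4L
  cfg <- synthetic_config(seed = 2, grid_shape = c(12L, 12L))
  cl <- generate_climate(cfg)
  expect_error(monthly_con(cl, 1, rule = bad), "monotonicity")
  expect_silent(monthly_con(cl, 1, rule = bad, allow_custom = TRUE))
})

test_that("CON equals a cell-wise lookup of the quartile classes", {
  cfg <- synthetic_config(seed = 8, grid_shape = c(20L, 20L))
  cl <- generate_climate(cfg)
  m <- 6
  res <- monthly_con(cl, m)
  pc <- quantile_classes(minmax_rescale(cl$p[[m]]))$classes$values
  tc <- quantile_classes(minmax_rescale(cl$t[[m]]))$classes$values
  rule <- default_con_rule()
  oracle <- matrix(rule[cbind(as.vector(pc), as.vector(tc))], 20, 20)
  expect_equal(res$con$values, oracle)
})

test_that("flow weighting shifts classes by accumulation quartile", {
  # CON grid with uniform class frequencies; ACC ramps west to east
  con <- raster_grid(matrix(rep(1:4, times = 4), 4, 4))
  acc <- raster_grid(matrix(rep(seq(0, 1, length.out = 4), each = 4),
                            4, 4))
  out <- suppressWarnings(weighted_con(con, acc))
  # middle ACC quartiles leave the class unchanged
  expect_equal(out$wcon$values[, 2], con$values[, 2])
  expect_equal(out$wcon$values[, 3], con$values[, 3])
  # bottom quartile lowers, top raises, clamped to 1..4
  expect_equal(out$wcon$values[, 1], pmax(con$values[, 1] - 1L, 1L))
  expect_equal(out$wcon$values[, 4], pmin(con$values[, 4] + 1L, 4L))
  expect_error(weighted_con(con, raster_grid(matrix(0, 2, 2))),
               "geometry")
})

test_that("the drought index is stable under uniform climate shifts and
           identical months collapse", {
  cfg <- synthetic_config(seed = 5, grid_shape = c(16L, 16L),
                          p_seasonal_amp = 0, t_seasonal_amp = 0,
                          climate_noise_sd = 0)
  dem <- fill_sinks(generate_terrain(cfg))
  cl <- generate_climate(cfg)
  fl <- flow_accumulation(dem)
  idx <- suppressWarnings(build_drought_index(cl, fl))
  for (m in 2:12)
    expect_equal(idx$wcon[[m]]$values, idx$wcon[[1]]$values)

  # adding a constant to P leaves all (rank-based) classes unchanged
  cfg2 <- synthetic_config(seed = 5, grid_shape = c(16L, 16L))
  cl2 <- generate_climate(cfg2)
  shifted <- monthly_climate(
    lapply(cl2$p, function(g) raster_like(g, g$values + 250)), cl2$t)
  i1 <- suppressWarnings(build_drought_index(cl2, fl))
  i2 <- suppressWarnings(build_drought_index(shifted, fl))
  for (m in 1:12)
    expect_equal(i2$con[[m]]$values, i1$con[[m]]$values)
})

test_that("a wet river valley scores wetter wCON than the interfluves", {
  # tilted valley DEM concentrates accumulation along the centre column;
  # the top-quartile ACC rule must lift those cells relative to their CON
  nr <- 16; nc <- 17
  z <- outer(seq(15, 0, length.out = nr), abs(seq(-8, 8)),
             function(down, side) down + 3 * side)
  dem <- fill_sinks(raster_grid(z))
  fl <- flow_accumulation(dem)
  cfg <- synthetic_config(seed = 3, grid_shape = c(nr, as.integer(nc)))
  cl <- generate_climate(cfg)
  idx <- suppressWarnings(build_drought_index(cl, fl))
  valley <- unlist(lapply(idx$wcon, function(g) g$values[, 9]))
  ridge <- unlist(lapply(idx$wcon, function(g) g$values[, c(1, nc)]))
  con_valley <- unlist(lapply(idx$con, function(g) g$values[, 9]))
  con_ridge <- unlist(lapply(idx$con, function(g) g$values[, c(1, nc)]))
  # weighting moves the valley up relative to its own CON more than the
  # ridges, so the valley-minus-ridge contrast grows
  expect_gte(mean(valley) - mean(con_valley),
             mean(ridge) - mean(con_ridge))
  expect_gte(mean(valley - con_valley), 0)
})
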