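test_that("sink filling leaves drainable surfaces untouched and closes
           pits", {
  plane <- raster_grid(outer(seq(20, 2, length.out = 10),
                             seq(0.1, 1.3, length.out = 10), `+`),
                       cell_size = 150)
  expect_equal(fill_sinks(plane)$values, plane$values)

  bowl <- raster_grid(matrix(5, 3, 3))
  bowl$values[2, 2] <- 1
  filled <- fill_sinks(bowl, epsilon = 0)
  expect_equal(filled$values[2, 2], 5)
  filled <- fill_sinks(bowl, epsilon = 1e-4)
  expect_gte(filled$values[2, 2], 5)

  expect_error(fill_sinks(raster_grid(matrix(NA_real_, 3, 3))), "nodata")
})

test_that("every cell of a filled random DEM reaches the boundary
           descending", {
  # BFS path-existence oracle, independent of the filling algorithm
  has_descending_path <- function(z) {
    nr <- nrow(z); nc <- ncol(z)
    ok <- matrix(FALSE, nr, nc)
    ok[1, ] <- TRUE; ok[nr, ] <- TRUE; ok[, 1] <- TRUE; ok[, nc] <- TRUE
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (r in 1:nr) for (c in 1:nc) {
        if (ok[r, c]) next
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if ((dr | dc) && rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              ok[rr, cc] && z[rr, cc] < z[r, c]) {
            ok[r, c] <- TRUE; changed <- TRUE
          }
        }
      }
    }
    all(ok)
  }
  for (seed in 1:12) {
    dem <- random_dem(seed)
    filled <- fill_sinks(dem)
    expect_true(all(filled$values >= dem$values))
    expect_true(has_descending_path(filled$values))
    # idempotence
    expect_equal(fill_sinks(filled)$values, filled$values)
  }
})

test_that("D8 accumulation reproduces the chain, conserves mass, and
           matches the routing oracle", {
  chain <- raster_grid(matrix(5:1, 1, 5))
  expect_equal(flow_accumulation(chain)$acc$values, matrix(1:5, 1, 5))

  for (seed in 1:10) {
    dem <- fill_sinks(random_dem(seed, 5, 5))
    fl <- flow_accumulation(dem)
    expect_equal(fl$acc$values, acc_oracle_d8(dem), tolerance = 1e-10)
    # conservation: everything injected leaves through off-grid drains
    out_cells <- which(fl$receiver == 0L)
    expect_equal(sum(fl$acc$values[out_cells]), 25)
    # accumulation never decreases downstream
    for (i in seq_along(fl$receiver)) {
      r <- fl$receiver[i]
      if (!is.na(r) && r > 0)
        expect_gte(fl$acc$values[r], fl$acc$values[i])
    }
  }
})

test_that("weighted accumulation conserves the total input weight", {
  for (seed in 1:5) {
    dem <- fill_sinks(random_dem(seed, 8, 8))
    set.seed(seed + 100)
    w <- raster_like(dem, matrix(runif(64, 0, 30), 8, 8))
    fl <- flow_accumulation(dem, w)
    expect_equal(sum(fl$acc$values[fl$receiver == 0L]), sum(w$values),
                 tolerance = 1e-9)
    expect_true(all(fl$acc$values >= w$values - 1e-12))
  }
})

test_that("Rho8 routing is seeded, reproducible, and strictly downslope", {
  dem <- fill_sinks(random_dem(21, 10, 10))
  a <- flow_accumulation(dem, algorithm = "rho8", seed = 7)
  b <- flow_accumulation(dem, algorithm = "rho8", seed = 7)
  expect_identical(a$receiver, b$receiver)
  c2 <- flow_accumulation(dem, algorithm = "rho8", seed = 8)
  expect_false(identical(a$receiver, c2$receiver))
  z <- as.numeric(dem$values)
  routed <- which(a$receiver > 0L)
  expect_true(all(z[a$receiver[routed]] < z[routed]))
  expect_equal(sum(a$acc$values[a$receiver == 0L]), 100)
})

test_that("stream extraction finds the valley main stem", {
  # V-shaped valley draining south along the centre column
  nr <- 9; nc <- 9
  z <- outer(seq(8, 0, length.out = nr), abs(seq(-4, 4)),
             function(down, side) down + 2 * side)
  dem <- fill_sinks(raster_grid(z))
  fl <- flow_accumulation(dem)
  ms <- extract_main_stem(fl, threshold = 3)
  stem_cols <- which(ms$stem$values, arr.ind = TRUE)[, "col"]
  expect_true(all(stem_cols == 5))   # valley floor column
  # threshold at the minimum weight: everything is stream
  ms_all <- extract_main_stem(fl, threshold = 1)
  expect_true(all(ms_all$stream$values))
  expect_true(all(ms_all$component$values))
  expect_error(extract_main_stem(fl, threshold = Inf), "empty")
})

test_that("watershed delineation matches brute-force path following", {
  for (seed in c(2, 5)) {
    dem <- fill_sinks(random_dem(seed, 7, 7))
    fl <- flow_accumulation(dem)
    # global outlet = off-grid-draining cell with the largest throughput
    out_cells <- which(fl$receiver == 0L)
    pp_idx <- out_cells[which.max(fl$acc$values[out_cells])]
    pp <- c(((pp_idx - 1) %% 7) + 1, ((pp_idx - 1) %/% 7) + 1)
    ws <- delineate_watershed(fl, pp)
    # oracle: walk every cell's receiver chain, note if it hits the outlet
    reaches <- vapply(seq_along(fl$receiver), function(i) {
      j <- i
      while (!is.na(j) && j > 0L) {
        if (j == pp_idx) return(TRUE)
        j <- fl$receiver[j]
      }
      FALSE
    }, logical(1))
    expect_equal(as.vector(ws$values), reaches)
  }
  # a local high point drains nothing but itself
  dome <- raster_grid(matrix(c(1, 1, 1, 1, 9, 1, 1, 1, 1), 3, 3))
  fl <- flow_accumulation(fill_sinks(dome))
  ws <- delineate_watershed(fl, c(2, 2))
  expect_equal(sum(ws$values), 1)
  expect_true(ws$values[2, 2])
  expect_error(delineate_watershed(fl, c(9, 9)), "outside")
})
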