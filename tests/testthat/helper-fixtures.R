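# Shared fixtures: tiny, fast configurations used across test files.

small_cfg <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, grid_shape = c(16L, 16L), n_sites = 5L,
                   samples_per_site = 6L, ...)
}

# one hand-written sample row, valid under the default QC windows
sample_row <- function(sample_id = "X1", site_id = "SITE1",
                       category = "human", taxon = "Homo sapiens",
                       period = "EN", d13C = -20, d15N = 10,
                       CN_atomic = 3.2, collagen_yield = 5,
                       pct_C = 40, pct_N = 14, is_infant = FALSE,
                       source = "new", region = "Alfold",
                       culture = "Koros") {
  data.frame(sample_id = sample_id, site_id = site_id, lab_id = "L1",
             taxon = taxon, category = category, period = period,
             culture = culture, region = region, bone_element = "rib",
             d13C = d13C, d15N = d15N, collagen_yield = collagen_yield,
             pct_C = pct_C, pct_N = pct_N, CN_atomic = CN_atomic,
             is_infant = is_infant, source = source,
             stringsAsFactors = FALSE)
}

# small random DEM wrapped as a raster
random_dem <- function(seed, nr = 8, nc = 8, cell = 150) {
  set.seed(seed)
  raster_grid(matrix(runif(nr * nc, 0, 10), nr, nc), cell_size = cell)
}

# independent quantile oracle: sort and linearly interpolate between
# order statistics at position 1 + p * (n - 1)  (the type-7 definition,
# written out directly rather than through stats::quantile)
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + p * (n - 1)
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force D8 routing oracle: follow every cell's steepest-descent
# path to where it leaves the grid, depositing its weight at each cell
# visited along the way
acc_oracle_d8 <- function(dem, w = NULL) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (is.null(w)) w <- matrix(1, nr, nc)
  dr <- c(-1, -1, -1, 0, 1, 1, 1, 0)
  dc <- c(-1, 0, 1, 1, 1, 0, -1, -1)
  dist <- sqrt(dr^2 + dc^2)
  acc <- matrix(0, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    r <- r0; c <- c0
    repeat {
      acc[r, c] <- acc[r, c] + w[r0, c0]
      drops <- rep(NA_real_, 8)
      for (k in 1:8) {
        rr <- r + dr[k]; cc <- c + dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
          drops[k] <- (z[r, c] - z[rr, cc]) / dist[k]
      }
      if (all(is.na(drops)) || max(drops, na.rm = TRUE) <= 0) break
      k <- which.max(drops)
      r <- r + dr[k]; c <- c + dc[k]
    }
  }
  acc
}
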