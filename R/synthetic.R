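#' Configuration for the synthetic study-region generator
#'
#' Bundles every tunable of the synthetic emulation: terrain, seasonal
#' climate, soil mosaic, site placement, and the isotope sample tables.
#' One seed fixes all outputs bit-for-bit.
#'
#' Isotope defaults mirror the study conditions of a Neolithic
#' Carpathian-Basin collagen dataset: fauna baselines near
#' \eqn{\delta^{13}}C = -20.5 permil (VPDB) and \eqn{\delta^{15}}N =
#' 7.3 permil (AIR), human values one trophic step above the local fauna
#' with offsets (\eqn{\Delta\delta^{13}}C, \eqn{\Delta\delta^{15}}N) =
#' (0.35, 3.1) permil, and within-site noise of 0.5 permil, comparable to
#' observed interquartile ranges of such assemblages.
#'
#' @param seed integer; fixes all generated outputs.
#' @param grid_shape integer vector `(rows, cols)`, at least 8 x 8 for
#'   terrain.
#' @param cell_size cell edge (m); 150 m mimics the resolution of the
#'   environmental model.
#' @param n_sites number of archaeological sites to place.
#' @param samples_per_site humans and fauna drawn per site.
#' @param fauna_baseline_d13C,fauna_baseline_d15N fauna baseline means
#'   (permil).
#' @param trophic_offset_d13C,trophic_offset_d15N human minus fauna offsets
#'   (permil).
#' @param group_effects named list mapping `"region|period"` to a numeric
#'   pair `(delta_d13C, delta_d15N)` added to the fauna baseline.
#' @param noise_sd_d13C,noise_sd_d15N within-site sd (permil).
#' @param frac_qc_fail fraction of samples given failing preservation
#'   fields (atomic C/N pushed outside the accepted window).
#' @param frac_infant fraction of humans flagged as infants (with a
#'   nursing \eqn{\delta^{15}}N enrichment of +2 permil).
#' @param relief_amplitude sd (m) of the smoothed terrain noise; 0 gives a
#'   pure tilted plane.
#' @param tilt fall (m per cell) of the regional slope towards the
#'   south-west outlet corner.
#' @param smoothing_passes number of 3x3 mean-filter passes applied to the
#'   terrain noise.
#' @param p_base,p_seasonal_amp mean and seasonal amplitude of monthly
#'   precipitation (mm).
#' @param t_base,t_seasonal_amp mean and seasonal amplitude of monthly
#'   temperature (deg C).
#' @param climate_gradient west-east relative gradient applied to P
#'   (drier east) and additively to T.
#' @param climate_noise_sd cell-level climate noise sd (mm / deg C).
#' @param n_soil_patches number of nearest-seed soil patches; with 9 or
#'   more, every soil class 10..90 is represented.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             grid_shape = c(64L, 64L),
                             cell_size = 150,
                             n_sites = 30L,
                             samples_per_site = 10L,
                             fauna_baseline_d13C = -20.5,
                             fauna_baseline_d15N = 7.3,
                             trophic_offset_d13C = 0.35,
                             trophic_offset_d15N = 3.1,
                             group_effects = default_group_effects(),
                             noise_sd_d13C = 0.5,
                             noise_sd_d15N = 0.5,
                             frac_qc_fail = 0.08,
                             frac_infant = 0.05,
                             relief_amplitude = 40,
                             tilt = 1.0,
                             smoothing_passes = 4L,
                             p_base = 45,
                             p_seasonal_amp = 20,
                             t_base = 11,
                             t_seasonal_amp = 10,
                             climate_gradient = 0.2,
                             climate_noise_sd = 2,
                             n_soil_patches = 12L) {
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  if (frac_qc_fail < 0 || frac_qc_fail > 1 || frac_infant < 0 ||
      frac_infant > 1) stop("fractions must lie in [0, 1]")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$grid_shape <- as.integer(grid_shape)
  structure(cfg, class = "synthetic_config")
}

#' Default regional/diachronic isotope shifts
#'
#' Encodes the qualitative structure of the emulated study area: fauna
#' and humans in the eastern plain (Alfold) run ~0.5 permil higher in
#' \eqn{\delta^{15}}N than west of the Danube (Transdanubia), and
#' \eqn{\delta^{13}}C rises slightly from the Early to the Late Neolithic.
#'
#' @return Named list keyed `"region|period"` of `(d13C, d15N)` shifts.
#' @export
default_group_effects <- function() {
  list(
    "Alfold|EN" = c(0.0, 0.5), "Alfold|MN" = c(0.2, 0.6),
    "Alfold|LN" = c(0.3, 0.7),
    "Transdanubia|EN" = c(0.0, 0.0), "Transdanubia|MN" = c(0.2, 0.1),
    "Transdanubia|LN" = c(0.3, 0.2)
  )
}

# seed offsets keep the generator streams independent of each other
.seed_offsets <- c(terrain = 101L, climate = 202L, soils = 303L,
                   sites = 404L, isotopes = 505L)

#' Generate a synthetic drainable terrain
#'
#' Smoothed Gaussian noise superimposed on a linear regional tilt falling
#' towards the south-west corner, so the surface always drains to a single
#' global outlet on the boundary — the precondition the hydrological
#' operators assume after sink filling.
#'
#' @param cfg a [synthetic_config()].
#' @return A [raster_grid()] DEM (m).
#' @export
generate_terrain <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  if (nr < 8 || nc < 8) stop("terrain grid must be at least 8 x 8")
  with_seed(cfg$seed + .seed_offsets[["terrain"]], {
    z <- matrix(stats::rnorm(nr * nc, sd = cfg$relief_amplitude), nr, nc)
    for (i in seq_len(cfg$smoothing_passes)) z <- mean_filter3(z)
    # tilt falls to the south-west: row nr (south), col 1 (west) lowest
    tiltf <- outer(seq_len(nr) - nr, seq_len(nc) - 1,
                   function(r, c) -cfg$tilt * r + cfg$tilt * c)
    raster_grid(z + tiltf + 100, cell_size = cfg$cell_size)
  })
}

# 3x3 mean filter with edge replication
mean_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc)]
  out / 9
}

#' Generate synthetic monthly climate fields
#'
#' Twelve precipitation (mm, non-negative) and twelve temperature (deg C)
#' grids with a sinusoidal seasonal cycle (P peaking in early summer, T in
#' July), a west-east gradient, optional orographic coupling to the DEM,
#' and seeded cell noise.
#'
#' @param cfg a [synthetic_config()].
#' @param dem optional DEM for orographic coupling (wetter/cooler uplands);
#'   must share the grid geometry.
#' @return A `monthly_climate` object: lists `p` and `t` of 12
#'   [raster_grid()]s each.
#' @export
generate_climate <- function(cfg, dem = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  if (!is.null(dem)) {
    if (!all(dim(dem$values) == c(nr, nc)))
      stop("DEM shape does not match cfg$grid_shape")
    relief <- dem$values - mean(dem$values, na.rm = TRUE)
  } else relief <- matrix(0, nr, nc)
  ew <- matrix(rep((seq_len(nc) - 1) / max(1, nc - 1), each = nr), nr, nc)
  with_seed(cfg$seed + .seed_offsets[["climate"]], {
    p <- vector("list", 12); t <- vector("list", 12)
    for (m in 1:12) {
      pseas <- cfg$p_seasonal_amp * sin(2 * pi * (m - 3) / 12)
      tseas <- cfg$t_seasonal_amp * cos(2 * pi * (m - 7) / 12)
      pm <- cfg$p_base * (1 + pseas / max(cfg$p_base, 1e-9)) *
        (1 - cfg$climate_gradient * ew) + 0.02 * relief +
        matrix(stats::rnorm(nr * nc, sd = cfg$climate_noise_sd), nr, nc)
      tm <- cfg$t_base + tseas + 3 * cfg$climate_gradient * ew -
        0.0065 * relief +
        matrix(stats::rnorm(nr * nc, sd = cfg$climate_noise_sd / 2), nr, nc)
      p[[m]] <- raster_grid(pmax(pm, 0), cell_size = cfg$cell_size)
      t[[m]] <- raster_grid(tm, cell_size = cfg$cell_size)
    }
    monthly_climate(p, t)
  })
}

#' Bundle of 12 monthly precipitation and temperature grids
#' @param p,t lists of 12 [raster_grid()]s each (P in mm, T in deg C).
#' @return A `monthly_climate` object.
#' @export
monthly_climate <- function(p, t) {
  stopifnot(length(p) == 12, length(t) == 12)
  for (m in 1:12)
    if (!same_geometry(p[[m]], t[[m]]))
      stop("P and T grids for month ", m, " differ in geometry")
  structure(list(p = p, t = t), class = "monthly_climate")
}

#' Soil class codes used in the categorical soil raster
#'
#' Nine morphological soil units coded 10..90: 10 skeletal, 20 sand,
#' 30 lithomorphic, 40 brown forest, 50 Chernozem, 60 salt-affected,
#' 70 meadow, 80 peat, 90 alluvial.
#' @export
SOIL_CLASSES <- seq(10L, 90L, by = 10L)

#' Generate a patchy categorical soil raster
#'
#' Nearest-seed (Voronoi) tessellation of the grid into contiguous
#' patches, each assigned one of the nine soil class codes. With
#' `n_soil_patches >= 9` the first nine patches carry each class once, so
#' all classes are present on a sufficiently large grid.
#'
#' @param cfg a [synthetic_config()].
#' @return A categorical [raster_grid()] with values in [SOIL_CLASSES].
#' @export
generate_soils <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  k <- cfg$n_soil_patches
  stopifnot(k >= 1)
  with_seed(cfg$seed + .seed_offsets[["soils"]], {
    sr <- stats::runif(k, 0.5, nr + 0.5)
    sc <- stats::runif(k, 0.5, nc + 0.5)
    cls <- if (k >= 9) c(SOIL_CLASSES, sample(SOIL_CLASSES, k - 9,
                                              replace = TRUE))
           else sample(SOIL_CLASSES, k)
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    nearest <- matrix(0L, nr, nc)
    best <- matrix(Inf, nr, nc)
    for (i in seq_len(k)) {
      d <- (rows - sr[i])^2 + (cols - sc[i])^2
      upd <- d < best
      nearest[upd] <- i
      best[upd] <- d[upd]
    }
    out <- matrix(cls[nearest], nr, nc)
    stopifnot(all(out %in% SOIL_CLASSES))
    raster_grid(out, cell_size = cfg$cell_size)
  })
}

#' Place synthetic archaeological sites
#'
#' Sites are scattered uniformly over the interior of the grid (keeping a
#' margin so a catchment window fits) and assigned to a region by the
#' Danube-like north-south divide at the grid's midline: west =
#' Transdanubia, east = Alfold. Each site receives a period (EN/MN/LN)
#' and a period-consistent cultural label for its region.
#'
#' @param cfg a [synthetic_config()].
#' @param margin_cells cells kept free along each edge (catchment windows
#'   must not cross the boundary).
#' @return data.frame: `site_id`, `x`, `y`, `row`, `col`, `region`,
#'   `period`, `culture`.
#' @export
generate_sites <- function(cfg, margin_cells = 3L) {
  stopifnot(inherits(cfg, "synthetic_config"), cfg$n_sites >= 1)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  if (nr - 2 * margin_cells < 1 || nc - 2 * margin_cells < 1)
    stop("grid too small for the requested site margin")
  cultures <- list(
    Alfold = c(EN = "Koros", MN = "ALBK", LN = "Tisza"),
    Transdanubia = c(EN = "Starcevo", MN = "TLBK", LN = "Lengyel")
  )
  with_seed(cfg$seed + .seed_offsets[["sites"]], {
    row <- sample((margin_cells + 1):(nr - margin_cells), cfg$n_sites,
                  replace = TRUE)
    col <- sample((margin_cells + 1):(nc - margin_cells), cfg$n_sites,
                  replace = TRUE)
    region <- ifelse(col > nc / 2, "Alfold", "Transdanubia")
    period <- sample(c("EN", "MN", "LN"), cfg$n_sites, replace = TRUE)
    g <- raster_grid(matrix(0, nr, nc), cell_size = cfg$cell_size)
    ctr <- lapply(seq_len(cfg$n_sites),
                  function(i) cell_centre(g, row[i], col[i]))
    data.frame(
      site_id = sprintf("S%03d", seq_len(cfg$n_sites)),
      x = vapply(ctr, `[[`, numeric(1), "x"),
      y = vapply(ctr, `[[`, numeric(1), "y"),
      row = row, col = col, region = region, period = period,
      culture = mapply(function(r, p) cultures[[r]][[p]], region, period,
                       USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic bone-collagen sample table
#'
#' Emulates a deposited collagen measurement table. Per site, fauna values
#' are drawn Normal(baseline + group effect, noise sd); human values are
#' drawn around the realised fauna site mean plus the configured trophic
#' offset. A configured fraction of rows receives failing preservation
#' fields (atomic C/N pushed outside 2.9-3.6) and a fraction of humans is
#' flagged as infants with a +2 permil nursing enrichment in
#' \eqn{\delta^{15}}N. The generating truth (per-site fauna means, offsets,
#' QC-fail ids) is returned in a sidecar, never in the table itself.
#'
#' @param cfg a [synthetic_config()].
#' @param sites data.frame as returned by [generate_sites()]; an empty
#'   site table yields an empty sample table.
#' @return List with `samples` (data.frame in the sample-table schema, see
#'   [read_sample_table()]) and `truth` (list of generating parameters).
#' @export
generate_isotope_dataset <- function(cfg, sites = generate_sites(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (nrow(sites) == 0) {
    return(list(samples = empty_sample_table(),
                truth = list(config = cfg, site_fauna_means = NULL,
                             qc_fail_ids = character(0))))
  }
  taxa <- c("Bos taurus", "Sus domesticus", "ovicaprid", "Cervus elaphus")
  categ <- c("herbivore", "omnivore", "herbivore", "herbivore")
  with_seed(cfg$seed + .seed_offsets[["isotopes"]], {
    rows <- list()
    fauna_means <- list()
    n <- cfg$samples_per_site
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      eff <- cfg$group_effects[[paste(s$region, s$period, sep = "|")]] %||%
        c(0, 0)
      mu13 <- cfg$fauna_baseline_d13C + eff[1]
      mu15 <- cfg$fauna_baseline_d15N + eff[2]
      f13 <- mu13 + stats::rnorm(n, sd = cfg$noise_sd_d13C)
      f15 <- mu15 + stats::rnorm(n, sd = cfg$noise_sd_d15N)
      ti <- sample.int(length(taxa), n, replace = TRUE)
      h13 <- mean(f13) + cfg$trophic_offset_d13C +
        stats::rnorm(n, sd = cfg$noise_sd_d13C)
      h15 <- mean(f15) + cfg$trophic_offset_d15N +
        stats::rnorm(n, sd = cfg$noise_sd_d15N)
      infant <- stats::runif(n) < cfg$frac_infant
      h15 <- h15 + 2 * infant
      fauna_means[[s$site_id]] <- c(d13C = mean(f13), d15N = mean(f15))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s-F%02d", s$site_id, seq_len(n)),
        site_id = s$site_id, lab_id = sprintf("L%04d", seq_len(n)),
        taxon = taxa[ti], category = categ[ti],
        period = s$period, culture = s$culture, region = s$region,
        bone_element = "long bone",
        d13C = f13, d15N = f15,
        collagen_yield = stats::runif(n, 2, 12),
        pct_C = stats::runif(n, 35, 45), pct_N = stats::runif(n, 12, 16),
        CN_atomic = stats::runif(n, 3.0, 3.5),
        is_infant = FALSE, source = "new", stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s-H%02d", s$site_id, seq_len(n)),
        site_id = s$site_id, lab_id = sprintf("L%04d", n + seq_len(n)),
        taxon = "Homo sapiens", category = "human",
        period = s$period, culture = s$culture, region = s$region,
        bone_element = "rib",
        d13C = h13, d15N = h15,
        collagen_yield = stats::runif(n, 2, 12),
        pct_C = stats::runif(n, 35, 45), pct_N = stats::runif(n, 12, 16),
        CN_atomic = stats::runif(n, 3.0, 3.5),
        is_infant = infant, source = "new", stringsAsFactors = FALSE
      )
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    # preservation failures: push atomic C/N outside the accepted window
    fail <- stats::runif(nrow(samples)) < cfg$frac_qc_fail
    samples$CN_atomic[fail] <- sample(c(2.5, 3.9), sum(fail),
                                      replace = TRUE)
    list(samples = samples,
         truth = list(
           config = cfg,
           site_fauna_means = fauna_means,
           trophic_offset = c(d13C = cfg$trophic_offset_d13C,
                              d15N = cfg$trophic_offset_d15N),
           qc_fail_ids = samples$sample_id[fail]
         ))
  })
}

empty_sample_table <- function() {
  data.frame(
    sample_id = character(0), site_id = character(0), lab_id = character(0),
    taxon = character(0), category = character(0), period = character(0),
    culture = character(0), region = character(0),
    bone_element = character(0), d13C = numeric(0), d15N = numeric(0),
    collagen_yield = numeric(0), pct_C = numeric(0), pct_N = numeric(0),
    CN_atomic = numeric(0), is_infant = logical(0), source = character(0),
    stringsAsFactors = FALSE
  )
}
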