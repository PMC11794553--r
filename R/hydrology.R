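# 8-neighbour scheme shared by the hydrological operators.
# Offsets are (row, col) with row 1 = north; angles are map angles of the
# direction towards the neighbour (0 = east, counter-clockwise, radians).
.nbr_dr <- c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L)
.nbr_dc <- c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L)
.nbr_dist <- sqrt(.nbr_dr^2 + .nbr_dc^2)
.nbr_angle <- atan2(-.nbr_dr, .nbr_dc)

neighbour_index <- function(idx, nr, nc) {
  # idx is a single column-major cell index; returns up to 8 neighbour
  # indices (NA where off-grid), aligned with the offset tables above
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  rr <- r + .nbr_dr
  cc <- c + .nbr_dc
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  out <- rep(NA_integer_, 8L)
  out[ok] <- (cc[ok] - 1L) * nr + rr[ok]
  out
}

#' Remove depressions from a DEM (priority-flood)
#'
#' Fills every closed depression so that each cell gains a non-ascending
#' (strictly descending when `epsilon > 0`) 8-neighbour path to the grid
#' boundary, the precondition for continuous downslope water accumulation.
#' Implemented as a priority-flood sweep from the boundary inwards: cells
#' are visited in order of increasing filled elevation and raised to at
#' least their spill level plus `epsilon`. Cells not inside depressions
#' are returned unchanged; the operation is idempotent. A cell exactly
#' level with its spill neighbour is treated as part of a flat and
#' receives the epsilon nudge, so surfaces with exact neighbour ties may
#' gain tiny gradients even outside closed depressions.
#'
#' @param dem a [raster_grid()] DEM; `NA` cells are treated as off-grid
#'   (their neighbours become boundary cells).
#' @param epsilon small elevation increment (m) imposed along filled
#'   areas so flats drain deterministically; default 1e-4.
#' @return A [raster_grid()] with `values >= dem$values` everywhere.
#' @examples
#' bowl <- raster_grid(matrix(c(5,5,5, 5,1,5, 5,5,5), 3, 3))
#' fill_sinks(bowl)$values[2, 2] >= 5
#' @export
fill_sinks <- function(dem, epsilon = 1e-4) {
  stopifnot(is_raster(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  if (all(is.na(z))) stop("cannot fill an all-nodata DEM")
  filled <- as.numeric(z)
  closed <- is.na(filled)
  prio <- rep(Inf, n)

  idx_mat <- matrix(seq_len(n), nr, nc)
  boundary <- c(idx_mat[1, ], idx_mat[nr, ], idx_mat[, 1], idx_mat[, nc])
  # cells adjacent to nodata drain off-grid too
  if (any(closed)) {
    for (i in which(closed)) {
      nb <- neighbour_index(i, nr, nc)
      boundary <- c(boundary, nb[!is.na(nb)])
    }
  }
  boundary <- unique(boundary[!closed[boundary]])
  prio[boundary] <- filled[boundary]

  while (any(is.finite(prio))) {
    cur <- which.min(prio)
    prio[cur] <- Inf
    if (closed[cur]) next
    closed[cur] <- TRUE
    nb <- neighbour_index(cur, nr, nc)
    for (k in seq_len(8L)) {
      j <- nb[k]
      if (is.na(j) || closed[j]) next
      spill <- filled[cur] + epsilon
      if (filled[j] < spill) filled[j] <- spill
      if (filled[j] < prio[j]) prio[j] <- filled[j]
    }
  }
  out <- matrix(filled, nr, nc)
  out[is.na(z)] <- NA
  raster_like(dem, out)
}

#' Weighted single-direction flow accumulation
#'
#' Routes each cell's weight (for instance its monthly precipitation) to
#' exactly one downslope 8-neighbour and accumulates contributions top
#' down (cells processed in order of decreasing elevation). `D8` sends
#' flow to the steepest descent neighbour (drop divided by centre
#' distance, diagonals penalised by sqrt(2)); `Rho8` draws, under a fixed
#' seed, one of the two neighbour directions bracketing the local aspect
#' with probability proportional to angular proximity, falling back to
#' steepest descent where the drawn neighbour is not lower. Boundary
#' cells with no lower in-grid neighbour drain off-grid.
#'
#' @param dem sink-free [raster_grid()] (see [fill_sinks()]).
#' @param weights non-negative [raster_grid()] of per-cell input weight;
#'   `NULL` means unit weight per cell.
#' @param algorithm `"d8"` (deterministic, default) or `"rho8"`.
#' @param seed integer seed for the Rho8 draws.
#' @return A `flow_field`: list with `receiver` (column-major index of the
#'   downslope neighbour, 0 = off-grid), `acc` ([raster_grid()] of
#'   accumulated weight), `dem`, `weights`, `algorithm`, `seed`.
#' @examples
#' dem <- raster_grid(matrix(5:1, 1, 5))
#' flow_accumulation(dem)$acc$values
#' @export
flow_accumulation <- function(dem, weights = NULL,
                              algorithm = c("d8", "rho8"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(is_raster(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  if (is.null(weights))
    weights <- raster_like(dem, matrix(1, nr, nc))
  stopifnot(same_geometry(dem, weights))
  w <- weights$values
  if (any(w < 0, na.rm = TRUE)) stop("weights must be non-negative")

  zv <- as.numeric(z)
  receiver <- rep(0L, n)
  is_boundary <- function(i) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    r == 1L || r == nr || c == 1L || c == nc
  }
  aspect <- if (algorithm == "rho8") aspect_angles(z) else NULL
  draws <- if (algorithm == "rho8")
    with_seed(seed, stats::runif(n)) else NULL

  for (i in seq_len(n)) {
    if (is.na(zv[i])) { receiver[i] <- NA_integer_; next }
    nb <- neighbour_index(i, nr, nc)
    drop <- (zv[i] - zv[nb]) / .nbr_dist
    drop[is.na(nb) | is.na(zv[nb])] <- NA
    lower <- !is.na(drop) & drop > 0
    if (!any(lower)) {
      if (is_boundary(i) || any(is.na(nb)) || any(is.na(zv[nb]))) {
        receiver[i] <- 0L   # drains off-grid
      } else {
        stop("unresolved flat or pit at cell ", i,
             "; run fill_sinks() with epsilon > 0 first")
      }
      next
    }
    steepest <- nb[which.max(drop)]
    if (algorithm == "d8") {
      receiver[i] <- steepest
    } else {
      receiver[i] <- rho8_pick(aspect[i], nb, lower, draws[i], steepest)
    }
  }

  ord <- order(zv, decreasing = TRUE, na.last = NA)
  acc <- ifelse(is.na(zv), NA_real_, as.numeric(w))
  for (i in ord) {
    r <- receiver[i]
    if (!is.na(r) && r > 0L) acc[r] <- acc[r] + acc[i]
  }
  structure(list(receiver = receiver,
                 acc = raster_like(dem, matrix(acc, nr, nc)),
                 dem = dem, weights = weights,
                 algorithm = algorithm, seed = seed),
            class = "flow_field")
}

# Downslope aspect (map angle, 0 = east, ccw) from central differences
# with edge replication; NA where the surface is locally flat.
aspect_angles <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  east <- z[, pmin(seq_len(nc) + 1, nc)]
  west <- z[, pmax(seq_len(nc) - 1, 1)]
  north <- z[pmax(seq_len(nr) - 1, 1), ]
  south <- z[pmin(seq_len(nr) + 1, nr), ]
  dzdx <- (east - west) / 2
  dzdy <- (north - south) / 2   # y increases northwards
  ang <- atan2(-dzdy, -dzdx)
  ang[dzdx == 0 & dzdy == 0] <- NA
  as.numeric(ang)
}

# Rho8 draw: the two neighbour directions bracketing the aspect split the
# 45-degree sector; u decides between them in proportion to proximity.
rho8_pick <- function(theta, nb, lower, u, fallback) {
  if (is.na(theta)) return(fallback)
  diffs <- (( .nbr_angle - theta + pi) %% (2 * pi)) - pi
  ordk <- order(abs(diffs))
  k1 <- ordk[1]; k2 <- ordk[2]
  p2 <- abs(diffs[k1]) / (abs(diffs[k1]) + abs(diffs[k2]) + 1e-12)
  pick <- if (u < p2) k2 else k1
  if (!is.na(nb[pick]) && lower[pick]) return(nb[pick])
  alt <- if (pick == k1) k2 else k1
  if (!is.na(nb[alt]) && lower[alt]) return(nb[alt])
  fallback
}

#' Extract the stream network and its main stem
#'
#' Thresholds the accumulation grid into a stream set, keeps its largest
#' 8-connected component, and traces the maximum-accumulation path (the
#' main stem): from the component's highest-accumulation cell downstream
#' to the component edge, and upstream along the largest donor at each
#' junction.
#'
#' @param flow a `flow_field` from [flow_accumulation()].
#' @param threshold minimum accumulated weight for stream membership.
#' @return List of three logical [raster_grid()]s: `stream` (all cells at
#'   or above threshold), `component` (largest connected stream body),
#'   `stem` (main stem cells).
#' @export
extract_main_stem <- function(flow, threshold) {
  stopifnot(inherits(flow, "flow_field"))
  acc <- flow$acc$values
  nr <- nrow(acc); nc <- ncol(acc)
  stream <- !is.na(acc) & acc >= threshold
  if (!any(stream))
    stop("threshold ", threshold, " exceeds the maximum accumulation (",
         max(acc, na.rm = TRUE), "): empty stream set")
  # label 8-connected components by BFS
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(stream & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- neighbour_index(i, nr, nc)
      nb <- nb[!is.na(nb)]
      nb <- nb[stream[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)

  stem <- matrix(FALSE, nr, nc)
  i <- which(comp)[which.max(acc[comp])]
  # downstream to the component edge
  j <- i
  while (!is.na(j) && j > 0L && comp[j]) {
    stem[j] <- TRUE
    j <- flow$receiver[j]
  }
  # upstream along the largest donor chain
  donors <- split(seq_along(flow$receiver),
                  factor(flow$receiver, levels = seq_along(flow$receiver)))
  j <- i
  repeat {
    d <- donors[[j]]
    d <- d[comp[d]]
    if (!length(d)) break
    j <- d[which.max(acc[d])]
    if (stem[j]) break
    stem[j] <- TRUE
  }
  list(stream = raster_like(flow$acc, stream),
       component = raster_like(flow$acc, comp),
       stem = raster_like(flow$acc, stem))
}

#' Delineate the upslope watershed of a pour point
#'
#' Returns the mask of every cell whose flow path passes through the pour
#' point (the pour point included), by walking the donor graph upstream.
#'
#' @param flow a `flow_field` from [flow_accumulation()].
#' @param pour_point integer vector `(row, col)` of the outlet cell.
#' @return A logical [raster_grid()] watershed mask.
#' @export
delineate_watershed <- function(flow, pour_point) {
  stopifnot(inherits(flow, "flow_field"), length(pour_point) == 2)
  acc <- flow$acc$values
  nr <- nrow(acc); nc <- ncol(acc)
  r <- pour_point[1]; c <- pour_point[2]
  if (r < 1 || r > nr || c < 1 || c > nc)
    stop("pour point lies outside the grid")
  start <- (c - 1L) * nr + r
  if (is.na(acc[start])) stop("pour point falls on a nodata cell")
  mask <- matrix(FALSE, nr, nc)
  mask[start] <- TRUE
  donors <- split(seq_along(flow$receiver),
                  factor(flow$receiver, levels = seq_along(flow$receiver)))
  queue <- start
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    d <- donors[[i]]
    d <- d[!mask[d]]
    mask[d] <- TRUE
    queue <- c(queue, d)
  }
  raster_like(flow$acc, mask)
}
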