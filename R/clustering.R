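#' Extract the environmental feature vector of a site catchment
#'
#' Reads every raster in a fixed square window centred on the site's
#' cell (side `ceiling(2 * radius / cell) + 1` cells), masks cells whose
#' centre lies farther than `radius` from the site cell's centre, and
#' concatenates the surviving cell values raster by raster in row-major
#' order. Categorical soil rasters (values in [SOIL_CLASSES]) are one-hot
#' expanded per cell by default, avoiding a false ordinal reading of the
#' class codes; `soil_encoding = "raw"` keeps the numeric ids.
#'
#' @param site one-row data.frame with `site_id`, `x`, `y` (projected m).
#' @param rasters named or unnamed list of co-registered
#'   [raster_grid()]s (e.g. 12 monthly wCON grids plus a soil grid).
#' @param radius catchment radius in metres (default 3000).
#' @param soil_encoding `"onehot"` or `"raw"`.
#' @param edge `"error"` (default) refuses windows crossing the raster
#'   boundary; `"zero"` pads them with zeros.
#' @return List of class `catchment_features`: `site_id`, `vector`,
#'   `window_shape`, `mask`.
#' @export
extract_catchment <- function(site, rasters, radius = 3000,
                              soil_encoding = c("onehot", "raw"),
                              edge = c("error", "zero")) {
  soil_encoding <- match.arg(soil_encoding)
  edge <- match.arg(edge)
  stopifnot(nrow(site) == 1, length(rasters) >= 1)
  g0 <- rasters[[1]]
  for (g in rasters) if (!same_geometry(g0, g))
    stop("rasters are not co-registered")
  cs <- g0$cell_size
  half <- ceiling(radius / cs)
  ctr <- cell_at(g0, site$x, site$y)
  nr <- nrow(g0$values); nc <- ncol(g0$values)
  rows <- (ctr$row - half):(ctr$row + half)
  cols <- (ctr$col - half):(ctr$col + half)
  off_grid <- rows < 1 | rows > nr
  off_gridc <- cols < 1 | cols > nc
  if ((any(off_grid) || any(off_gridc)) && edge == "error")
    stop("catchment window of site ", site$site_id,
         " crosses the raster boundary; use edge = \"zero\" to pad")
  # distance mask on cell centres
  dr <- (rows - ctr$row) * cs
  dc <- (cols - ctr$col) * cs
  mask <- outer(dr, dc, function(a, b) sqrt(a^2 + b^2)) <= radius
  window_vals <- function(g, fill = 0) {
    m <- matrix(fill, length(rows), length(cols))
    rok <- which(!off_grid); cok <- which(!off_gridc)
    m[rok, cok] <- g$values[rows[rok], cols[cok]]
    m
  }
  vec <- numeric(0)
  for (g in rasters) {
    w <- window_vals(g)
    cells <- t(w)[t(mask)]   # row-major order within the window
    if (soil_encoding == "onehot" && all(g$values %in% SOIL_CLASSES)) {
      oh <- vapply(SOIL_CLASSES, function(cl) as.numeric(cells == cl),
                   numeric(length(cells)))
      vec <- c(vec, as.numeric(t(oh)))
    } else {
      vec <- c(vec, as.numeric(cells))
    }
  }
  structure(list(site_id = site$site_id, vector = vec,
                 window_shape = c(length(rows), length(cols)),
                 mask = mask),
            class = "catchment_features")
}

#' Site-by-feature matrix from catchment extractions
#'
#' @param sites data.frame of sites (`site_id`, `x`, `y`).
#' @param rasters list of co-registered [raster_grid()]s.
#' @inheritParams extract_catchment
#' @return Numeric matrix with one row per site (rownames = site ids).
#' @export
build_feature_matrix <- function(sites, rasters, radius = 3000,
                                 soil_encoding = "onehot",
                                 edge = "error") {
  feats <- lapply(seq_len(nrow(sites)), function(i)
    extract_catchment(sites[i, , drop = FALSE], rasters, radius,
                      soil_encoding, edge))
  lens <- vapply(feats, function(f) length(f$vector), integer(1))
  stopifnot(length(unique(lens)) == 1)
  m <- do.call(rbind, lapply(feats, `[[`, "vector"))
  rownames(m) <- sites$site_id
  m
}

#' Reduce a feature matrix by PCA at a variance threshold
#'
#' Centres the matrix, drops zero-variance features, and keeps the
#' smallest number of leading principal components whose cumulative
#' explained variance reaches `variance_kept` (default 99%).
#'
#' @param x sites-by-features numeric matrix (at least 2 rows).
#' @param variance_kept cumulative explained-variance target in (0, 1].
#' @return List: `scores` (sites x components), `n_components`,
#'   `explained` (cumulative variance fractions), `rotation`.
#' @export
pca_reduce <- function(x, variance_kept = 0.99) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2) stop("PCA needs at least 2 sites")
  stopifnot(variance_kept > 0, variance_kept <= 1)
  keep <- apply(x, 2, stats::var) > 0
  if (!any(keep)) stop("all features have zero variance")
  p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                     scale. = FALSE)
  cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
  k <- which(cum >= variance_kept)[1]
  list(scores = p$x[, seq_len(k), drop = FALSE], n_components = k,
       explained = cum[seq_len(k)], rotation = p$rotation)
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x),
                            byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[i + 1], ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of site feature vectors
#'
#' Best-of-restarts K-means with k-means++ seeding (each restart draws
#' fresh seeds and is refined by [stats::kmeans()]); the partition with
#' the lowest within-cluster sum of squares wins. Deterministic under a
#' fixed seed. Per-site silhouette widths are attached when `k >= 2`.
#'
#' @param x numeric matrix (sites x features or PCA scores).
#' @param k number of clusters (at most `nrow(x)`).
#' @param n_restarts independent k-means++ restarts (default 25).
#' @param seed RNG seed.
#' @return List of class `cluster_result`: `assignments` (named integer
#'   vector), `k`, `inertia`, `silhouette_per_site`, `centers`, `seed`.
#' @export
kmeans_cluster <- function(x, k, n_restarts = 25, seed = 1L) {
  stopifnot(is.matrix(x))
  if (k > nrow(x)) stop("k = ", k, " exceeds the number of sites (",
                        nrow(x), ")")
  if (k == nrow(x)) {
    assignments <- seq_len(nrow(x))
    names(assignments) <- rownames(x)
    return(structure(list(assignments = assignments, k = k, inertia = 0,
                          silhouette_per_site = rep(0, nrow(x)),
                          centers = x, seed = seed),
                     class = "cluster_result"))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      ctr <- kmeanspp_centers(x, k)
      ctr <- ctr + stats::rnorm(length(ctr), sd = 1e-9)  # avoid dup centres
      # duplicated points can empty a cluster under Hartigan-Wong;
      # fall back to MacQueen, then skip the restart
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = ctr, iter.max = 100)),
        error = function(e) tryCatch(
          suppressWarnings(stats::kmeans(x, centers = ctr, iter.max = 100,
                                         algorithm = "MacQueen")),
          error = function(e) NULL))
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
  })
  if (is.null(best))
    stop("k-means failed for every restart; k = ", k,
         " likely exceeds the number of distinct points")
  sil <- rep(NA_real_, nrow(x))
  if (k >= 2 && k < nrow(x)) {
    sw <- cluster::silhouette(best$cluster, stats::dist(x))
    sil <- sw[, "sil_width"]
  } else if (k == nrow(x)) sil <- rep(0, nrow(x))
  assignments <- best$cluster
  names(assignments) <- rownames(x)
  structure(list(assignments = assignments, k = k,
                 inertia = best$tot.withinss,
                 silhouette_per_site = sil, centers = best$centers,
                 seed = seed),
            class = "cluster_result")
}

#' Choose the number of clusters by gap statistic and silhouette
#'
#' Computes, for k = 1..`k_max`, the gap statistic against `B` uniform
#' reference data sets (with the firstSEmax decision rule) and, for
#' k = 2..`k_max`, the mean silhouette width, and returns both curves
#' with a recommendation per method.
#'
#' @param x numeric matrix (sites x features or PCA scores).
#' @param k_max largest k examined; must be below `nrow(x)`.
#' @param method `"gap"`, `"silhouette"`, or `"both"` (default).
#' @param B reference replicates for the gap statistic (default 50).
#' @param seed RNG seed.
#' @param n_restarts k-means restarts per k.
#' @return List: `gap_k`, `gap_curve` (k, gap, SE), `silhouette_k`,
#'   `silhouette_curve` (k, mean width), `recommended_k`.
#' @export
select_k <- function(x, k_max = 30, method = c("both", "gap",
                                               "silhouette"),
                     B = 50, seed = 1L, n_restarts = 10) {
  method <- match.arg(method)
  stopifnot(is.matrix(x))
  if (k_max >= nrow(x))
    stop("k_max must be smaller than the number of sites")
  if (k_max < 2) {
    warning("k_max < 2: returning the trivial single cluster")
    return(list(gap_k = 1L, gap_curve = NULL, silhouette_k = 1L,
                silhouette_curve = NULL, recommended_k = 1L))
  }
  kmfun <- function(x, k) {
    list(cluster = kmeans_cluster(x, k, n_restarts = n_restarts,
                                  seed = seed + k)$assignments)
  }
  out <- list(gap_k = NA_integer_, gap_curve = NULL,
              silhouette_k = NA_integer_, silhouette_curve = NULL)
  if (method %in% c("both", "gap")) {
    gap <- with_seed(seed, cluster::clusGap(x, FUNcluster = kmfun,
                                            K.max = k_max, B = B,
                                            verbose = FALSE))
    tab <- gap$Tab
    out$gap_k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                                method = "firstSEmax")
    out$gap_curve <- data.frame(k = seq_len(k_max), gap = tab[, "gap"],
                                se = tab[, "SE.sim"])
  }
  if (method %in% c("both", "silhouette")) {
    widths <- vapply(2:k_max, function(k) {
      mean(kmeans_cluster(x, k, n_restarts = n_restarts,
                          seed = seed + k)$silhouette_per_site)
    }, numeric(1))
    out$silhouette_k <- (2:k_max)[which.max(widths)]
    out$silhouette_curve <- data.frame(k = 2:k_max,
                                       mean_silhouette = widths)
  }
  out$recommended_k <- switch(method,
    gap = out$gap_k,
    silhouette = out$silhouette_k,
    both = out$silhouette_k)
  out
}

#' Contingency tables of cluster membership
#'
#' Crosses the cluster assignment with region, period and culture so the
#' dependence of the environmental typology on those factors can be
#' tested (see [crosstab_test()]).
#'
#' @param result a `cluster_result` from [kmeans_cluster()].
#' @param sites data.frame carrying `site_id` and any of `region`,
#'   `period`, `culture`.
#' @return Named list of `table` objects (one per available factor).
#' @export
cluster_composition <- function(result, sites) {
  stopifnot(inherits(result, "cluster_result"))
  idx <- match(sites$site_id, names(result$assignments))
  if (anyNA(idx)) stop("assignments missing for sites: ",
                       paste(sites$site_id[is.na(idx)], collapse = ", "))
  cl <- result$assignments[idx]
  out <- list()
  for (f in c("region", "period", "culture")) {
    if (f %in% names(sites))
      out[[f]] <- table(cluster = cl, sites[[f]], dnn = c("cluster", f))
  }
  out
}
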