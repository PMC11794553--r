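#' Gridded raster surface
#'
#' Minimal single-band raster container used throughout the package: a
#' numeric (or categorical integer) matrix with a square-cell geotransform
#' in a projected metric coordinate system. Row 1 is the northernmost row;
#' column 1 the westernmost column. `NA` cells are nodata and are excluded
#' from all statistics.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cell_size cell edge length in metres; must be positive.
#' @param crs_label free-text label of the projected CRS; the package never
#'   reprojects, it only records the label.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), cell_size = 150)
#' dim(g$values)
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cell_size = 150,
                        crs_label = "local_metric") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(cell_size > 0, nrow(values) >= 1, ncol(values) >= 1)
  structure(
    list(values = values, xll = xll, yll = yll, cell_size = cell_size,
         crs_label = crs_label),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, cell %gm, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  } else cat("  all nodata\n")
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster <- function(x) inherits(x, "raster_grid")

#' Replace the value matrix of a raster, keeping its geotransform
#' @param grid a [raster_grid()].
#' @param values replacement matrix with identical dimensions.
#' @return A `raster_grid`.
#' @export
raster_like <- function(grid, values) {
  stopifnot(is_raster(grid), all(dim(values) == dim(grid$values)))
  raster_grid(values, grid$xll, grid$yll, grid$cell_size, grid$crs_label)
}

same_geometry <- function(a, b) {
  is_raster(a) && is_raster(b) && all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

#' Cell centre coordinates
#'
#' @param grid a [raster_grid()].
#' @param row,col cell indices (row 1 = north).
#' @return List with `x` and `y` of the cell centre in map units.
#' @export
cell_centre <- function(grid, row, col) {
  nr <- nrow(grid$values)
  list(x = grid$xll + (col - 0.5) * grid$cell_size,
       y = grid$yll + (nr - row + 0.5) * grid$cell_size)
}

#' Row/column of the cell containing a point
#' @param grid a [raster_grid()].
#' @param x,y projected coordinates (m).
#' @return List with `row` and `col`, or an error if outside the extent.
#' @export
cell_at <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  col <- floor((x - grid$xll) / cs) + 1
  row <- nr - floor((y - grid$yll) / cs)
  if (col < 1 || col > nc || row < 1 || row > nr)
    stop("point (", x, ", ", y, ") lies outside the raster extent")
  list(row = row, col = col)
}

#' Min-max rescale a raster to [0, 1]
#'
#' Affine rescaling of the non-nodata cells so that the minimum maps to 0
#' and the maximum to 1. A constant grid maps to all zeros (downstream
#' quartile logic requires finite values). Nodata is preserved.
#'
#' @param grid a [raster_grid()].
#' @return A `raster_grid` with values in `[0, 1]`.
#' @examples
#' minmax_rescale(raster_grid(matrix(c(0, 5, 10, NA), 2, 2)))$values
#' @export
minmax_rescale <- function(grid) {
  stopifnot(is_raster(grid))
  v <- grid$values
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot rescale an all-nodata raster")
  rng <- range(v[ok])
  if (rng[1] == rng[2]) {
    v[ok] <- 0
  } else {
    v[ok] <- (v[ok] - rng[1]) / (rng[2] - rng[1])
  }
  raster_like(grid, v)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param path file path.
#' @return `read_ascii_grid` returns a [raster_grid()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing field: ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_grid(m,
              xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
              cell_size = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param grid a [raster_grid()] to write.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(is_raster(grid))
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
    paste("cellsize", grid$cell_size), paste("NODATA_value", nodata)
  ), con)
  apply(v, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
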