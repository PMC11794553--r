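#' Quartile classification of a raster
#'
#' Classifies every non-nodata cell into four ordinal classes using the
#' grid's own 25/50/75% quantiles as thresholds: class 1 below the 25th
#' percentile up to class 4 above the 75th. Ties are broken by
#' right-closed intervals — a cell's class is one plus the number of
#' thresholds strictly below its value — so a constant grid collapses to
#' class 1 with a warning.
#'
#' @param grid a [raster_grid()].
#' @param probs quantile probabilities delimiting the classes.
#' @param type quantile algorithm (see [stats::quantile()]).
#' @return List: `classes` (integer [raster_grid()], 1..4) and
#'   `thresholds` (the quantile triple).
#' @examples
#' quantile_classes(raster_grid(matrix(1:16, 4, 4)))$classes$values
#' @export
quantile_classes <- function(grid, probs = c(0.25, 0.5, 0.75), type = 7) {
  stopifnot(is_raster(grid))
  v <- grid$values
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot classify an all-nodata raster")
  thr <- stats::quantile(v[ok], probs, type = type, names = FALSE)
  if (length(unique(v[ok])) < length(probs) + 1)
    warning("fewer distinct values than classes; ",
            "ties collapse classes (constant grids map to class 1)")
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  cls[ok] <- 1L + vapply(v[ok], function(x) sum(thr < x), integer(1))
  list(classes = raster_like(grid, cls), thresholds = thr)
}

#' Default conditional-model rule table (P class x T class)
#'
#' 4 x 4 ordinal lookup encoding the climatic semantics of the
#' conditional model: dry classes under high temperature with low
#' precipitation, humid classes under high precipitation with low
#' temperature, moderate classes in between. The default is
#' `clamp(P_class - T_class + 2, 1, 4)`, non-decreasing along
#' precipitation and non-increasing along temperature. A published or
#' bespoke table can be dropped in wherever a `rule` argument is
#' accepted.
#'
#' @return Integer matrix with rows = P class 1..4, cols = T class 1..4.
#' @export
default_con_rule <- function() {
  outer(1:4, 1:4, function(p, t) pmin(pmax(p - t + 2L, 1L), 4L))
}

#' Default flow-weighting rule table (QA x QC)
#'
#' 4 x 4 lookup applied on the accumulation quartile (QA) and the
#' conditional-model quartile (QC): top-quartile accumulation raises the
#' index one class (enhanced water availability along high-order flow
#' paths), bottom-quartile lowers it one class, the middle quartiles
#' leave it unchanged. Clamped to 1..4.
#'
#' @return Integer matrix with rows = QA 1..4, cols = QC 1..4.
#' @export
default_wcon_rule <- function() {
  outer(1:4, 1:4, function(qa, qc)
    pmin(pmax(qc + (qa == 4L) - (qa == 1L), 1L), 4L))
}

check_rule_monotone <- function(rule, decreasing_cols = FALSE,
                                allow_custom = FALSE) {
  stopifnot(is.matrix(rule), all(dim(rule) == c(4, 4)))
  ok_rows <- all(apply(rule, 2, function(x) all(diff(x) >= 0)))
  col_diffs <- apply(rule, 1, diff)
  ok_cols <- if (decreasing_cols) all(col_diffs <= 0)
             else all(col_diffs >= 0)
  if (!(ok_rows && ok_cols) && !allow_custom)
    stop("rule table violates the expected ordinal monotonicity; ",
         "pass allow_custom = TRUE to use it anyway")
  invisible(rule)
}

#' Monthly conditional climate model (CON)
#'
#' Classifies one month's precipitation and temperature grids into
#' quartile classes and combines them through a 4 x 4 rule table:
#' `CON = rule[P_class, T_class]`. Low classes mark drought-vulnerable
#' cells (hot and dry), high classes humid cells (wet and cool).
#'
#' @param climate a [monthly_climate()] (rescaling to `[0, 1]` is applied
#'   internally; classes are rank-based and unaffected by it).
#' @param month month number 1..12.
#' @param rule 4 x 4 integer lookup; see [default_con_rule()].
#' @param allow_custom skip the monotonicity check on `rule`.
#' @return List: `con` (integer [raster_grid()]), `p_thresholds`,
#'   `t_thresholds`.
#' @export
monthly_con <- function(climate, month, rule = default_con_rule(),
                        allow_custom = FALSE) {
  stopifnot(inherits(climate, "monthly_climate"),
            month %in% 1:12)
  check_rule_monotone(rule, decreasing_cols = TRUE,
                      allow_custom = allow_custom)
  pq <- quantile_classes(minmax_rescale(climate$p[[month]]))
  tq <- quantile_classes(minmax_rescale(climate$t[[month]]))
  pc <- pq$classes$values; tc <- tq$classes$values
  con <- matrix(NA_integer_, nrow(pc), ncol(pc))
  ok <- !is.na(pc) & !is.na(tc)
  con[ok] <- rule[cbind(pc[ok], tc[ok])]
  list(con = raster_like(pq$classes, con),
       p_thresholds = pq$thresholds, t_thresholds = tq$thresholds)
}

#' Flow-weighted conditional model (wCON)
#'
#' Refines a monthly CON grid by the rescaled flow accumulation:
#' quartiles of the accumulation (QA) and of the CON grid (QC) index a
#' 4 x 4 rule table, so cells on major flow paths are shifted towards
#' wetter classes and hydrologically starved cells towards drier ones.
#'
#' @param con integer CON [raster_grid()] (one month).
#' @param acc_rescaled min-max rescaled accumulation [raster_grid()] on
#'   the same geometry.
#' @param rule 4 x 4 integer lookup; see [default_wcon_rule()].
#' @param allow_custom skip the monotonicity check on `rule`.
#' @return List: `wcon` (integer [raster_grid()]), `qa` and `qc`
#'   (threshold triples).
#' @export
weighted_con <- function(con, acc_rescaled, rule = default_wcon_rule(),
                         allow_custom = FALSE) {
  stopifnot(is_raster(con), is_raster(acc_rescaled))
  if (!same_geometry(con, acc_rescaled))
    stop("CON and accumulation grids differ in geometry")
  check_rule_monotone(rule, decreasing_cols = FALSE,
                      allow_custom = allow_custom)
  qa <- suppressWarnings(quantile_classes(acc_rescaled))
  qc <- suppressWarnings(quantile_classes(con))
  qav <- qa$classes$values; qcv <- qc$classes$values
  w <- matrix(NA_integer_, nrow(qav), ncol(qav))
  ok <- !is.na(qav) & !is.na(qcv)
  w[ok] <- rule[cbind(qav[ok], qcv[ok])]
  list(wcon = raster_like(con, w), qa = qa$thresholds,
       qc = qc$thresholds)
}

#' Build the full monthly drought index
#'
#' Runs the conditional model for all twelve months and weights each by
#' the flow-accumulation quartiles, returning the complete drought/
#' wetness index with every threshold used. Accumulation quartiles (QA)
#' are computed once from the flow field; CON quartiles (QC) per month.
#'
#' @param climate a [monthly_climate()].
#' @param flow a `flow_field` from [flow_accumulation()] on the same
#'   grid (typically precipitation-weighted).
#' @param con_rule,wcon_rule 4 x 4 lookup tables.
#' @param allow_custom skip monotonicity checks on the rules.
#' @return A `drought_index`: lists `con` and `wcon` of 12 integer
#'   [raster_grid()]s, per-month `p_thresholds`/`t_thresholds`/`qc`, the
#'   common `qa`, both rules, and provenance (`algorithm`, `seed`).
#' @export
build_drought_index <- function(climate, flow,
                                con_rule = default_con_rule(),
                                wcon_rule = default_wcon_rule(),
                                allow_custom = FALSE) {
  stopifnot(inherits(climate, "monthly_climate"),
            inherits(flow, "flow_field"))
  if (!same_geometry(climate$p[[1]], flow$acc))
    stop("climate and flow grids differ in geometry")
  accr <- minmax_rescale(flow$acc)
  con <- vector("list", 12); wcon <- vector("list", 12)
  pth <- vector("list", 12); tth <- vector("list", 12)
  qcth <- vector("list", 12); qath <- NULL
  for (m in 1:12) {
    cm <- monthly_con(climate, m, con_rule, allow_custom)
    wm <- weighted_con(cm$con, accr, wcon_rule, allow_custom)
    con[[m]] <- cm$con; wcon[[m]] <- wm$wcon
    pth[[m]] <- cm$p_thresholds; tth[[m]] <- cm$t_thresholds
    qcth[[m]] <- wm$qc
    qath <- wm$qa
  }
  structure(list(con = con, wcon = wcon, p_thresholds = pth,
                 t_thresholds = tth, qc = qcth, qa = qath,
                 con_rule = con_rule, wcon_rule = wcon_rule,
                 algorithm = flow$algorithm, seed = flow$seed),
            class = "drought_index")
}

#' @export
print.drought_index <- function(x, ...) {
  cat(sprintf(
    "<drought_index> 12 monthly CON + wCON grids (%d x %d), %s routing\n",
    nrow(x$con[[1]]$values), ncol(x$con[[1]]$values), x$algorithm))
  invisible(x)
}
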