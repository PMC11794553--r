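#' Five-number summary of isotope values
#'
#' Minimum, quartiles and maximum of a set of permil values, optionally
#' dropping individuals flagged as infants (whose \eqn{\delta^{15}}N may
#' carry a nursing enrichment). Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7, the R default under which
#' published collagen summaries are usually computed); the convention is
#' configurable.
#'
#' @param values numeric vector (permil).
#' @param is_infant optional logical vector, same length, used when
#'   `exclude_infants` is set.
#' @param exclude_infants drop values where `is_infant` is `TRUE`.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return A one-row data.frame: `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @examples
#' summarize_values(c(1, 2, 3, 4, 5))
#' @export
summarize_values <- function(values, is_infant = NULL,
                             exclude_infants = FALSE, type = 7) {
  if (exclude_infants) {
    if (is.null(is_infant) || length(is_infant) != length(values))
      stop("exclude_infants requires an is_infant vector matching values")
    values <- values[!is_infant]
  }
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values left to summarize")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = type,
                       names = FALSE)
  data.frame(n = length(values), min = q[1], q1 = q[2], median = q[3],
             q3 = q[4], max = q[5])
}

#' Site-level human-fauna isotope offsets
#'
#' For every site-and-period combination with at least `min_n` humans and
#' at least `min_n` fauna from the baseline pool, the offset is the mean
#' human value minus the mean fauna value, for both isotopes. The fauna
#' pool excludes carnivores and (by default) fish, whose trophic position
#' would contaminate the herbivore/omnivore baseline. Combinations
#' failing the rule yield no record.
#'
#' @param samples sample table (QC-filtered upstream).
#' @param min_n minimum humans and minimum fauna per site-period (default
#'   2 — small, but it widens site coverage).
#' @param include_fish admit the `fish` category into the baseline pool.
#' @param exclude_infants drop flagged infants from the human pool.
#' @return data.frame of offset records: `site_id`, `period`, `culture`,
#'   `n_human`, `n_fauna`, `offset_d13C`, `offset_d15N`.
#' @examples
#' d <- generate_isotope_dataset(synthetic_config(seed = 1, n_sites = 5))
#' compute_offsets(d$samples)
#' @export
compute_offsets <- function(samples, min_n = 2, include_fish = FALSE,
                            exclude_infants = FALSE) {
  check_sample_schema(samples)
  pool <- c("herbivore", "omnivore", if (include_fish) "fish")
  if (exclude_infants)
    samples <- samples[!(samples$category == "human" &
                           samples$is_infant %in% TRUE), , drop = FALSE]
  key <- interaction(samples$site_id, samples$period, drop = TRUE)
  recs <- lapply(split(samples, key), function(g) {
    hum <- g[g$category == "human", , drop = FALSE]
    fau <- g[g$category %in% pool, , drop = FALSE]
    if (nrow(hum) < min_n || nrow(fau) < min_n) return(NULL)
    data.frame(
      site_id = g$site_id[1], period = g$period[1],
      culture = g$culture[1],
      n_human = nrow(hum), n_fauna = nrow(fau),
      offset_d13C = mean(hum$d13C) - mean(fau$d13C),
      offset_d15N = mean(hum$d15N) - mean(fau$d15N),
      stringsAsFactors = FALSE
    )
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs))
    return(data.frame(site_id = character(0), period = character(0),
                      culture = character(0), n_human = integer(0),
                      n_fauna = integer(0), offset_d13C = numeric(0),
                      offset_d15N = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[order(out$site_id, out$period), , drop = FALSE]
}

#' Parametric and rank-based one-way group tests
#'
#' Runs a one-way ANOVA and a Kruskal-Wallis test of an isotope value
#' against a grouping factor, reporting both so that the parametric
#' result can be read against its distribution-free counterpart.
#'
#' @param samples sample table (or any data.frame holding the columns).
#' @param value response column, `"d13C"` or `"d15N"`.
#' @param grouping grouping column, e.g. `"period"`, `"region"`,
#'   `"culture"`, `"cluster"`.
#' @return A list of class `group_test_result`: `grouping`, `value`,
#'   `anova_F`, `p_anova`, `kw_H`, `p_kw`, `group_ns`.
#' @examples
#' d <- generate_isotope_dataset(synthetic_config(seed = 1, n_sites = 6))
#' group_tests(d$samples, "d15N", "region")
#' @export
group_tests <- function(samples, value = c("d13C", "d15N"), grouping) {
  value <- match.arg(value)
  if (!grouping %in% names(samples))
    stop("grouping column not found: ", grouping)
  v <- samples[[value]]
  g <- factor(samples[[grouping]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2)
    stop("group_tests needs at least 2 non-empty groups, got ",
         nlevels(g))
  a <- stats::anova(stats::aov(v ~ g))
  kw <- stats::kruskal.test(v, g)
  structure(list(
    grouping = grouping, value = value,
    anova_F = unname(a[["F value"]][1]),
    p_anova = unname(a[["Pr(>F)"]][1]),
    kw_H = unname(kw$statistic), p_kw = kw$p.value,
    group_ns = table(g)
  ), class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Group test of %s by %s (%d groups)\n", x$value, x$grouping,
              length(x$group_ns)))
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g\n", x$anova_F,
              x$p_anova))
  cat(sprintf("  Kruskal-Wallis: H = %.3f, p = %.4g\n", x$kw_H, x$p_kw))
  invisible(x)
}

#' Test independence of two site-level factors
#'
#' Chi-square test of independence on a contingency table (for instance
#' environmental cluster against major region). When any expected count
#' falls below 5 and the table is 2 x 2, Fisher's exact test is used
#' instead. A table with an all-zero row or column margin is degenerate
#' and rejected.
#'
#' @param tab a contingency table / matrix of counts, or the output of
#'   `table()`.
#' @return List: `method` ("chisq" or "fisher"), `statistic` (NA for
#'   Fisher), `p_value`, `expected` (chi-square only), `table`.
#' @examples
#' crosstab_test(matrix(c(10, 0, 0, 10), 2, 2))$p_value
#' @export
crosstab_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2))
    stop("crosstab_test needs at least 2 levels of each factor")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table: a row or column margin is zero")
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(cs$expected < 5) && all(dim(tab) == c(2, 2))) {
    f <- stats::fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p_value = f$p.value,
         expected = cs$expected, table = tab)
  } else {
    list(method = "chisq", statistic = unname(cs$statistic),
         p_value = cs$p.value, expected = cs$expected, table = tab)
  }
}
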