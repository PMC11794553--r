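#' Collagen preservation quality thresholds
#'
#' Screening windows used to reject diagenetically altered collagen.
#' Defaults are the standard preservation windows used in palaeodietary
#' work: atomic C/N within 2.9-3.6, collagen yield at least 1% of bone
#' mass, at least 13% carbon and 4.8% nitrogen in the extract. All are
#' configurable; rows from the literature that lack preservation fields
#' pass those checks vacuously (their publications applied their own
#' screening) but still face the explicit exclusion list and, when
#' `require_period` is set, the chronological criterion.
#'
#' @param cn_min,cn_max accepted atomic C/N window.
#' @param yield_min minimum collagen yield (% of bone mass).
#' @param pctC_min,pctN_min minimum elemental percentages.
#' @param exclusion_ids sample ids excluded a priori (e.g. a known
#'   isotopic outlier kept out of all summaries).
#' @param require_period drop samples without a period assignment.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cn_min = 2.9, cn_max = 3.6, yield_min = 1,
                          pctC_min = 13, pctN_min = 4.8,
                          exclusion_ids = character(0),
                          require_period = TRUE) {
  stopifnot(cn_min < cn_max, yield_min >= 0, pctC_min >= 0, pctN_min >= 0)
  structure(list(cn_min = cn_min, cn_max = cn_max, yield_min = yield_min,
                 pctC_min = pctC_min, pctN_min = pctN_min,
                 exclusion_ids = exclusion_ids,
                 require_period = require_period),
            class = "qc_thresholds")
}

.qc_required_cols <- c("sample_id", "site_id", "taxon", "category",
                       "period", "culture", "region", "d13C", "d15N",
                       "collagen_yield", "pct_C", "pct_N", "CN_atomic",
                       "is_infant", "source")

check_sample_schema <- function(samples) {
  missing <- setdiff(.qc_required_cols, names(samples))
  if (length(missing))
    stop("sample table is missing required columns: ",
         paste(missing, collapse = ", "))
  invisible(samples)
}

#' Partition a sample table into kept and rejected rows
#'
#' Applies the preservation windows, the explicit exclusion list and the
#' chronological criterion. Every input row lands in exactly one of the
#' two outputs; each rejected row carries one or more semicolon-joined
#' reason codes from `cn_out_of_range`, `low_yield`, `low_pctC`,
#' `low_pctN`, `explicit_exclusion`, `no_chronology`. A missing (NA)
#' preservation field never triggers its check, so literature rows with
#' empty QC columns are judged only on exclusions and chronology.
#'
#' @param samples sample table (see [read_sample_table()] for the schema).
#' @param thresholds a [qc_thresholds()].
#' @return List with `kept` and `rejected` data.frames; `rejected` gains a
#'   `qc_reasons` column.
#' @examples
#' d <- generate_isotope_dataset(synthetic_config(seed = 1, n_sites = 3))
#' qc <- apply_quality_filter(d$samples, qc_thresholds())
#' nrow(qc$kept) + nrow(qc$rejected) == nrow(d$samples)
#' @export
apply_quality_filter <- function(samples, thresholds = qc_thresholds()) {
  check_sample_schema(samples)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- nrow(samples)
  reasons <- vector("list", n)
  add <- function(idx, code) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  fails <- function(x, bad) !is.na(x) & bad
  add(fails(samples$CN_atomic,
            samples$CN_atomic < thresholds$cn_min |
              samples$CN_atomic > thresholds$cn_max), "cn_out_of_range")
  add(fails(samples$collagen_yield,
            samples$collagen_yield < thresholds$yield_min), "low_yield")
  add(fails(samples$pct_C, samples$pct_C < thresholds$pctC_min),
      "low_pctC")
  add(fails(samples$pct_N, samples$pct_N < thresholds$pctN_min),
      "low_pctN")
  add(samples$sample_id %in% thresholds$exclusion_ids,
      "explicit_exclusion")
  if (isTRUE(thresholds$require_period))
    add(is.na(samples$period) | samples$period %in% c("", "NA"),
        "no_chronology")
  bad <- vapply(reasons, function(r) length(r) > 0, logical(1))
  rejected <- samples[bad, , drop = FALSE]
  if (nrow(rejected))
    rejected$qc_reasons <- vapply(reasons[bad], paste, character(1),
                                  collapse = ";")
  else rejected$qc_reasons <- character(0)
  list(kept = samples[!bad, , drop = FALSE], rejected = rejected)
}

#' Flag isotopically suspect diets without excluding samples
#'
#' Adds two advisory flags to the table: `c4_suspect` for
#' \eqn{\delta^{13}}C above -18.00 permil (possible C4 plant input,
#' unexpected for the Neolithic and worth a direct radiocarbon date) and
#' `forest_freshwater_suspect` for \eqn{\delta^{13}}C below -22.00 permil
#' (canopy or freshwater-influenced resources). Flags never remove rows.
#'
#' @param samples sample table with a `d13C` column.
#' @param c4_above,forest_below flag thresholds (permil VPDB).
#' @return The table with the two logical columns appended.
#' @export
flag_dietary_outliers <- function(samples, c4_above = -18.0,
                                  forest_below = -22.0) {
  if (!"d13C" %in% names(samples)) stop("samples must carry a d13C column")
  samples$c4_suspect <- !is.na(samples$d13C) & samples$d13C > c4_above
  samples$forest_freshwater_suspect <-
    !is.na(samples$d13C) & samples$d13C < forest_below
  samples
}

#' Flag per-taxon robust outliers (advisory, off the default QC path)
#'
#' Marks values outside median +/- `k` times the interquartile range
#' within each taxon, separately for both isotopes. Intended to surface
#' candidates for the explicit exclusion list, not to drop rows.
#'
#' @param samples sample table.
#' @param k IQR multiplier (default 4, deliberately permissive).
#' @return The table with a logical `robust_outlier` column appended.
#' @export
flag_robust_outliers <- function(samples, k = 4) {
  check_sample_schema(samples)
  out <- rep(FALSE, nrow(samples))
  for (tx in unique(samples$taxon)) {
    idx <- samples$taxon == tx
    for (col in c("d13C", "d15N")) {
      v <- samples[[col]][idx]
      if (sum(!is.na(v)) < 4) next
      md <- stats::median(v, na.rm = TRUE)
      iqr <- stats::IQR(v, na.rm = TRUE)
      out[idx] <- out[idx] | (!is.na(v) & abs(v - md) > k * iqr)
    }
  }
  samples$robust_outlier <- out
  samples
}
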