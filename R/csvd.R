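#' WMH volume normalized by intracranial volume
#'
#' White-matter-hyperintensity lesion load is normalized by total
#' intracranial volume (TIV) so that the classification threshold is a
#' unitless ratio. Inputs may be tagged in millilitres or litres; both are
#' converted to a common unit before dividing.
#'
#' @param wmh_volume WMH lesion volume(s).
#' @param tiv Total intracranial volume(s), > 0.
#' @param wmh_unit,tiv_unit Unit tags, `"ml"` or `"l"`.
#' @return The unitless ratio `wmh_volume / tiv`.
#' @examples
#' wmh_ratio(0.91, 1300)          # 7e-04
#' wmh_ratio(0.91, 1.3, tiv_unit = "l")
#' @export
wmh_ratio <- function(wmh_volume, tiv, wmh_unit = "ml", tiv_unit = "ml") {
  to_ml <- function(x, unit, what) {
    switch(unit,
           ml = x,
           l = x * 1000,
           stop("unknown ", what, " unit: ", unit))
  }
  wmh <- to_ml(wmh_volume, wmh_unit, "wmh")
  tiv <- to_ml(tiv, tiv_unit, "tiv")
  if (any(tiv <= 0)) stop("tiv must be > 0")
  if (any(wmh < 0)) stop("wmh_volume must be >= 0")
  wmh / tiv
}

#' Classify cerebral small vessel disease from MRI markers
#'
#' Implements the marker rule: a subject is CSVD when the WMH/TIV ratio is
#' at or above the cohort's empirical percentile (default the median) AND
#' at least one lacune or cerebral microbleed is present. The percentile is
#' computed over the full input cohort with the median-unbiased quantile
#' convention (`type = 8`), and the `>=` comparison is applied as stated by
#' the rule.
#'
#' @param markers Data frame with columns `subject_id`, `wmh_volume` (ml),
#'   `tiv` (ml by default; see `tiv_unit`), `lacune_count`, `cmb_count`.
#' @param percentile Percentile of the ratio distribution used as the WMH
#'   threshold, in (0, 100); default 50.
#' @param tiv_unit Unit tag for the `tiv` column (`"ml"` or `"l"`).
#' @return A list with `flags` (data frame: subject_id, wmh_ratio, csvd),
#'   `threshold` (the ratio threshold used), `percentile`, and `rule`
#'   (provenance string).
#' @examples
#' mk <- data.frame(subject_id = letters[1:6],
#'                  wmh_volume = 1:6, tiv = 1e4,
#'                  lacune_count = c(1, 0, 0, 1, 0, 0),
#'                  cmb_count = 0)
#' classify_csvd(mk)$flags$csvd   # only subject "d"
#' @export
classify_csvd <- function(markers, percentile = 50, tiv_unit = "ml") {
  need <- c("subject_id", "wmh_volume", "tiv", "lacune_count", "cmb_count")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0) {
    stop("marker table missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(markers) < 2) stop("need >= 2 subjects to set a cohort threshold")
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)")
  }
  counts <- c(markers$lacune_count, markers$cmb_count)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("lesion counts must be non-negative integers")
  }
  ratio <- wmh_ratio(markers$wmh_volume, markers$tiv, tiv_unit = tiv_unit)
  threshold <- stats::quantile(ratio, percentile / 100, type = 8,
                               names = FALSE)
  lesions <- markers$lacune_count >= 1 | markers$cmb_count >= 1
  flags <- data.frame(
    subject_id = markers$subject_id,
    wmh_ratio = ratio,
    csvd = ratio >= threshold & lesions,
    stringsAsFactors = FALSE
  )
  list(
    flags = flags,
    threshold = threshold,
    percentile = percentile,
    rule = paste0("wmh_ratio >= p", percentile,
                  " (type-8 quantile) AND (lacune_count >= 1 OR cmb_count >= 1)")
  )
}

#' Marker subgroup composition of a classified CSVD group
#'
#' Tallies lacune-positive, CMB-positive and both-positive subjects within
#' the CSVD group, with percentages of the group size. By construction the
#' inclusion-exclusion identity
#' `n_lacune + n_cmb - n_both = n_group` holds whenever every CSVD subject
#' has at least one lesion type (which the rule guarantees).
#'
#' @param markers Marker data frame (see [classify_csvd()]).
#' @param flags The `flags` data frame returned by [classify_csvd()].
#' @return Data frame with counts and percentages for lacunes, CMBs, both.
#' @export
csvd_subgroup_summary <- function(markers, flags) {
  stopifnot(identical(markers$subject_id, flags$subject_id))
  grp <- markers[flags$csvd, ]
  n <- nrow(grp)
  n_lac <- sum(grp$lacune_count >= 1)
  n_cmb <- sum(grp$cmb_count >= 1)
  n_both <- sum(grp$lacune_count >= 1 & grp$cmb_count >= 1)
  data.frame(
    marker = c("lacunes", "cmb", "both"),
    n = c(n_lac, n_cmb, n_both),
    pct = if (n > 0) 100 * c(n_lac, n_cmb, n_both) / n else rep(NA_real_, 3),
    group_size = n
  )
}
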