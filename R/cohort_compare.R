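NOMINAL_DAYS <- c(30, 90, 180, 270, 365)
NOMINAL_MONTHS <- c(1, 3, 6, 9, 12)

#' Map a sampling day to the nearest nominal month
#'
#' Sampling clusters around months 1, 3, 6, 9 and 12 post-transplant
#' (nominal days 30, 90, 180, 270, 365). A day maps to the nearest
#' nominal day within a +/- `tolerance` window; equidistant ties are
#' broken to the earlier month; days outside every window are unmapped
#' (`NA`).
#'
#' @param day sampling day(s) post-transplant.
#' @param tolerance half-width of the mapping window in days
#'   (default 45).
#' @return Nominal month (1, 3, 6, 9, 12) or `NA` per day.
#' @examples
#' map_to_nominal_month(c(30, 200, 135, 500))
#' @export
map_to_nominal_month <- function(day, tolerance = 45) {
  vapply(day, function(d) {
    dist <- abs(d - NOMINAL_DAYS)
    j <- which.min(dist) # ties broken to the earlier month
    if (dist[j] <= tolerance) NOMINAL_MONTHS[j] else NA_real_
  }, 0)
}

#' Mann-Whitney U comparison of two count samples
#'
#' Two-sided Mann-Whitney U test of subset counts between two cohorts:
#' exact enumeration when the combined sample size is at most 12 and the
#' data are tie-free, normal approximation (with tie correction, no
#' continuity correction) otherwise.
#'
#' @param counts_a,counts_b numeric samples (non-empty).
#' @return List: `median_a`, `median_b`, `U` (statistic of the first
#'   sample), `p_value`.
#' @examples
#' median_compare(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
median_compare <- function(counts_a, counts_b) {
  if (length(counts_a) == 0 || length(counts_b) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(counts_a, counts_b)) > 0
  exact <- (length(counts_a) + length(counts_b)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(counts_a, counts_b, exact = exact,
                       correct = FALSE))
  list(median_a = stats::median(counts_a),
       median_b = stats::median(counts_b),
       U = unname(wt$statistic), p_value = wt$p.value)
}

#' Cross-cohort comparison of median counts at nominal timepoints
#'
#' The conventional analysis arm: for every subset and nominal month,
#' absolute counts of the two cohorts are compared by the Mann-Whitney U
#' test. Each patient contributes at most one sample per nominal month
#' (the day closest to the nominal day wins).
#'
#' @param measurements long-format measurements (see
#'   [read_measurements()]).
#' @param cohort_a,cohort_b the two cohort labels compared.
#' @param subsets subset identifiers to summarise (default: all present).
#' @param tolerance mapping window, see [map_to_nominal_month()].
#' @return Data frame with one row per (month, subset): cohort sample
#'   sizes, medians, `U` and `p_value`.
#' @export
cohort_timepoint_summary <- function(measurements, cohort_a, cohort_b,
                                     subsets = NULL, tolerance = 45) {
  subsets <- subsets %||% sort(unique(measurements$subset))
  m <- measurements[measurements$cohort %in% c(cohort_a, cohort_b) &
                    measurements$subset %in% subsets, , drop = FALSE]
  m$count <- absolute_counts(m$fraction, m$alc)
  m$month <- map_to_nominal_month(m$day, tolerance)
  m <- m[!is.na(m$month), , drop = FALSE]
  # closest day wins within (patient, subset, month)
  nominal <- NOMINAL_DAYS[match(m$month, NOMINAL_MONTHS)]
  m <- m[order(abs(m$day - nominal)), ]
  m <- m[!duplicated(m[c("patient_id", "subset", "month")]), ]
  out <- list()
  for (mo in NOMINAL_MONTHS) {
    for (s in subsets) {
      xa <- m$count[m$month == mo & m$subset == s & m$cohort == cohort_a]
      xb <- m$count[m$month == mo & m$subset == s & m$cohort == cohort_b]
      if (length(xa) == 0 || length(xb) == 0) next
      cmp <- median_compare(xa, xb)
      out[[length(out) + 1L]] <- data.frame(
        nominal_month = mo, subset = s,
        n_a = length(xa), n_b = length(xb),
        median_a = cmp$median_a, median_b = cmp$median_b,
        U = cmp$U, p_value = cmp$p_value)
    }
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  attr(res, "cohorts") <- c(a = cohort_a, b = cohort_b)
  res
}
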