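#' Absolute subset count from fraction and lymphocyte count
#'
#' Flow cytometry reports each T cell subset as a fraction of the
#' lymphocyte gate; the absolute count is that fraction times the
#' absolute lymphocyte count (ALC) measured on the same sampling date.
#'
#' @param fraction subset fraction of lymphocytes, in `[0, 1]`.
#' @param alc absolute lymphocyte count in cells/uL, >= 0.
#' @return Absolute subset count in cells/uL.
#' @examples
#' absolute_counts(0.2, 1500) # 300 cells/uL
#' @export
absolute_counts <- function(fraction, alc) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("fraction must lie in [0, 1]")
  if (any(alc < 0, na.rm = TRUE)) stop("alc must be >= 0")
  fraction * alc
}

#' Eligibility filter for clustering analysis
#'
#' Keeps patients with (1) at least `min_samples` distinct sampling days
#' within the first `horizon_days` post-transplant and (2) a first sample
#' no later than day `first_by_day`. Both bounds are inclusive. Excluded
#' patients are logged with every rule they violate.
#'
#' @param measurements long-format measurement data frame with at least
#'   `patient_id` and `day` columns (see [read_measurements()]).
#' @param min_samples minimum number of distinct sampling days (default 3).
#' @param first_by_day latest admissible day of the first sample
#'   (default 45).
#' @param horizon_days horizon within which samples are counted
#'   (default 365).
#' @return A list with `eligible` (the measurement rows of retained
#'   patients) and `exclusions` (data frame `patient_id`, `rule` with
#'   values `too_few_samples` and/or `first_sample_late`).
#' @export
filter_eligible <- function(measurements, min_samples = 3,
                            first_by_day = 45, horizon_days = 365) {
  if (nrow(measurements) == 0) {
    warning("no measurements supplied; nothing to filter")
    return(list(eligible = measurements,
                exclusions = data.frame(patient_id = character(),
                                        rule = character())))
  }
  within <- measurements[measurements$day <= horizon_days, , drop = FALSE]
  n_days <- tapply(within$day, within$patient_id,
                   function(d) length(unique(d)))
  first_day <- tapply(measurements$day, measurements$patient_id, min)
  ids <- unique(measurements$patient_id)
  n_days <- ifelse(is.na(n_days[ids]), 0L, n_days[ids])
  first_day <- first_day[ids]
  fail1 <- n_days < min_samples
  fail2 <- first_day > first_by_day
  rule <- character(length(ids))
  rule[fail1] <- "too_few_samples"
  rule[fail2] <- ifelse(fail1[fail2], "too_few_samples;first_sample_late",
                        "first_sample_late")
  keep <- ids[!(fail1 | fail2)]
  list(
    eligible = measurements[measurements$patient_id %in% keep, ,
                            drop = FALSE],
    exclusions = data.frame(patient_id = ids[fail1 | fail2],
                            rule = rule[fail1 | fail2],
                            row.names = NULL))
}

# Build one patient's multivariate series (counts matrix, 4 x n_days) from
# long-format measurements; duplicate same-day measurements are averaged.
patient_series <- function(rows, panel, cohort = NULL) {
  counts <- absolute_counts(rows$fraction, rows$alc)
  days <- sort(unique(rows$day))
  mat <- matrix(NA_real_, nrow = length(panel), ncol = length(days),
                dimnames = list(unclass(panel), days))
  for (s in seq_along(panel)) {
    sel <- rows$subset == panel[s]
    if (!any(sel)) next
    agg <- tapply(counts[sel], rows$day[sel], mean)
    mat[s, match(as.integer(names(agg)), days)] <- agg
  }
  structure(list(patient_id = rows$patient_id[1],
                 cohort = cohort %||% rows$cohort[1],
                 days = days, counts = mat, panel = panel),
            class = "patient_series")
}

#' Linear interpolation onto a regular day grid
#'
#' Interpolates each subset's series linearly between observed values onto
#' the common weekly grid (`seq(0, horizon, grid_step)`), clipped to the
#' patient's observed support: no values are produced before the first or
#' after the last observed day (no extrapolation). Observed days that fall
#' on grid points reproduce their values exactly.
#'
#' @param series a `patient_series` (internal long-to-matrix form) with at
#'   least two observed days per subset.
#' @param grid_step grid resolution in days (default 7).
#' @param horizon last grid day (default 365).
#' @return A `regular_series`: list with `patient_id`, `grid` (days),
#'   `values` (4 x length(grid) matrix) and `support`.
#' @export
interpolate_linear <- function(series, grid_step = 7, horizon = 365) {
  interp_series(series, grid_step, horizon, smoothing = 0)
}

#' Smoothed interpolation onto a regular day grid
#'
#' Monotone-segment-preserving smoothing: a blend of linear interpolation
#' and a monotone (Fritsch-Carlson) cubic Hermite interpolant with clamped
#' overshoot, controlled by `smoothing` in `[0, 1]`. At `smoothing = 0`
#' the result equals [interpolate_linear()]; at 1 it is fully cubic.
#' Observed days always reproduce their values.
#'
#' @inheritParams interpolate_linear
#' @param smoothing blend weight in `[0, 1]` (default 1).
#' @return A `regular_series`, as [interpolate_linear()].
#' @export
interpolate_smooth <- function(series, grid_step = 7, horizon = 365,
                               smoothing = 1) {
  stopifnot(smoothing >= 0, smoothing <= 1)
  if (length(series$days) < 3)
    stop("smoothed interpolation needs at least three observed days")
  interp_series(series, grid_step, horizon, smoothing)
}

interp_series <- function(series, grid_step, horizon, smoothing) {
  days <- series$days
  if (length(days) < 2)
    stop("patient ", series$patient_id,
         " has a single observation; exclude upstream")
  if (anyNA(series$counts))
    stop("patient ", series$patient_id, " is missing subset measurements")
  full_grid <- seq(0, horizon, by = grid_step)
  grid <- full_grid[full_grid >= min(days) & full_grid <= max(days)]
  if (length(grid) == 0) grid <- min(days) # degenerate narrow support
  vals <- matrix(0, nrow = nrow(series$counts), ncol = length(grid),
                 dimnames = list(rownames(series$counts), grid))
  for (s in seq_len(nrow(series$counts))) {
    y <- series$counts[s, ]
    lin <- stats::approx(days, y, xout = grid)$y
    if (smoothing > 0) {
      mono <- stats::splinefun(days, y, method = "monoH.FC")(grid)
      vals[s, ] <- (1 - smoothing) * lin + smoothing * mono
    } else vals[s, ] <- lin
  }
  structure(list(patient_id = series$patient_id, cohort = series$cohort,
                 grid = grid, values = vals,
                 support = c(min(days), max(days))),
            class = "regular_series")
}

#' Assemble the multivariate series set for clustering
#'
#' Runs the long-format measurements of (already filtered) patients
#' through count conversion and interpolation for one panel, producing the
#' ordered collection of regular multivariate series consumed by the DTW
#' stage. Patients missing any panel subset, or with fewer than two
#' (three, for smoothed interpolation) observed days, are excluded with a
#' logged reason. Per-series grid support may differ; DTW handles the
#' variable lengths.
#'
#' @param measurements long-format measurements of eligible patients.
#' @param panel a [subset_panel()].
#' @param interpolation `"linear"` or `"smooth"`.
#' @param grid_step,horizon grid definition, see [interpolate_linear()].
#' @param smoothing blend weight for `"smooth"`, see
#'   [interpolate_smooth()].
#' @return A `series_set`: list of `regular_series` with attributes
#'   `ids`, `panel`, and `excluded` (data frame of exclusions).
#' @export
assemble_model_matrix <- function(measurements, panel,
                                  interpolation = c("linear", "smooth"),
                                  grid_step = 7, horizon = 365,
                                  smoothing = 1) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(panel, "subset_panel"))
  ids <- unique(measurements$patient_id)
  out <- vector("list", length(ids))
  excluded <- list()
  kept <- character()
  for (i in seq_along(ids)) {
    rows <- measurements[measurements$patient_id == ids[i] &
                         measurements$subset %in% unclass(panel), ,
                         drop = FALSE]
    missing <- setdiff(unclass(panel), unique(rows$subset))
    if (length(missing) > 0) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        patient_id = ids[i],
        reason = paste0("missing_subset:", paste(missing, collapse = ",")))
      next
    }
    ser <- patient_series(rows, panel)
    min_days <- if (interpolation == "smooth") 3L else 2L
    if (length(ser$days) < min_days || anyNA(ser$counts)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        patient_id = ids[i], reason = "insufficient_observations")
      next
    }
    out[[i]] <- if (interpolation == "linear")
      interpolate_linear(ser, grid_step, horizon)
    else interpolate_smooth(ser, grid_step, horizon, smoothing)
    kept <- c(kept, ids[i])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  structure(out, ids = kept, panel = panel,
            excluded = if (length(excluded)) do.call(rbind, excluded)
                       else data.frame(patient_id = character(),
                                       reason = character()),
            class = "series_set")
}

#' @export
print.series_set <- function(x, ...) {
  lens <- vapply(x, function(s) length(s$grid), 1L)
  cat("Series set: ", length(x), " patients, panel '",
      panel_name(attr(x, "panel")), "', grid lengths ",
      min(lens), "-", max(lens), "\n", sep = "")
  invisible(x)
}
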