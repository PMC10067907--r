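MEASUREMENT_COLS <- c("patient_id", "cohort", "day", "subset",
                      "fraction", "alc")

#' Read and validate a long-format measurements CSV
#'
#' Expected columns: `patient_id`, `cohort`, `day` (integer days
#' post-transplant), `subset`, `fraction` (of lymphocytes, in `[0, 1]`)
#' and `alc` (absolute lymphocyte count, cells/uL). Row-level problems
#' are collected and reported together with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated measurements data frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MEASUREMENT_COLS, names(m))
  if (length(missing) > 0)
    stop("measurements file lacks column(s): ",
         paste(missing, collapse = ", "))
  line <- seq_len(nrow(m)) + 1L # header is line 1
  bad <- character()
  chk <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond))
      bad <<- c(bad, paste0(what, " at line(s) ",
                            paste(line[which(cond | is.na(cond))],
                                  collapse = ", ")))
  }
  chk(!is.finite(m$fraction) | m$fraction < 0 | m$fraction > 1,
      "fraction outside [0, 1]")
  chk(!is.finite(m$alc) | m$alc < 0, "negative or non-numeric alc")
  chk(!is.finite(m$day) | m$day < 0, "negative or non-numeric day")
  if (length(bad) > 0)
    stop("invalid measurement rows:\n  ", paste(bad, collapse = "\n  "))
  dup <- duplicated(m[c("patient_id", "day", "subset")])
  if (any(dup))
    stop("duplicate (patient_id, day, subset) at line(s) ",
         paste(line[dup], collapse = ", "))
  m$day <- as.integer(m$day)
  m
}

#' Write a measurements CSV
#' @param measurements data frame as returned by [generate_cohort()].
#' @param path output path.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements[MEASUREMENT_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an outcomes CSV
#'
#' Required columns: `patient_id`, `time_days` (> 0), `event`
#' (`censored`, `relapse` or `nrm`); optional `os_time_days`,
#' `os_event`.
#'
#' @param path CSV file path.
#' @return Validated outcomes data frame.
#' @export
read_outcomes <- function(path) {
  oc <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "time_days", "event")
  missing <- setdiff(req, names(oc))
  if (length(missing) > 0)
    stop("outcomes file lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(oc$time_days <= 0)) stop("time_days must be positive")
  check_event_types(oc$event)
  if (anyDuplicated(oc$patient_id))
    stop("duplicate patient_id in outcomes file")
  oc
}

#' Write an outcomes CSV
#' @param outcomes outcomes data frame.
#' @param path output path.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Round-trip a distance matrix to CSV
#'
#' @param dm symmetric distance matrix with ids as dimnames.
#' @param path CSV path; the id order is kept in a header row and a
#'   leading id column.
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return `read_distance_matrix()` returns the matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  dm <- as.matrix(df[, -1, drop = FALSE])
  rownames(dm) <- df$id
  storage.mode(dm) <- "double"
  validate_distance_matrix(dm)
  dm
}

#' Read a pipeline configuration from YAML
#'
#' Fields: `measurements` and `outcomes` (CSV paths), `panel`,
#' `interpolation`, `out_dir`, `seed`, plus optional filter
#' (`min_samples`, `first_by_day`, `horizon_days`), grid overrides
#' (`k`, `window_frac`, `normalization`, `centroid_method`), and
#' selection (`min_cluster_frac`, `max_sil_variance`) settings.
#'
#' @param path YAML file path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("measurements", "out_dir")
  missing <- setdiff(req, names(cfg))
  if (length(missing) > 0)
    stop("pipeline config lacks field(s): ",
         paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}
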