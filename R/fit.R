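#' Fit reconstitution trajectory clusters
#'
#' The central fitting function of the package: applies the eligibility
#' filters, converts fractions to absolute counts, interpolates each
#' eligible patient's four-subset series onto the weekly grid, runs the
#' DTW clustering configuration search with subsampling robustness,
#' selects the working configuration (silhouette, balance and
#' robustness rules), and — when outcomes are supplied — links the
#' resulting patient clusters to overall survival and to relapse/NRM as
#' competing risks.
#'
#' @param measurements long-format measurements data frame (see
#'   [read_measurements()]).
#' @param outcomes optional outcomes data frame (see [read_outcomes()]).
#' @param panel a [subset_panel()] (default: the GVHD-associated panel).
#' @param interpolation `"linear"` or `"smooth"`.
#' @param grid a [configuration_grid()]; defaults to the full
#'   36-configuration reference grid for `panel`.
#' @param seed master seed for the search.
#' @param min_samples,first_by_day,horizon_days eligibility filter, see
#'   [filter_eligible()].
#' @param grid_step interpolation grid resolution in days.
#' @param local_norm DTW local norm (`"L1"` or `"L2"`).
#' @param n_rep,subsample_frac robustness settings, see
#'   [resample_stability()].
#' @param min_cluster_frac,max_sil_variance selection rules, see
#'   [select_configuration()].
#' @return An object of class `trecon_fit` with components `labels`
#'   (selected cluster per patient), `selected` (configuration, result
#'   and stability), `search` (the ranked configuration table), `set`
#'   (the interpolated series), `exclusions`, and `outcome_report`
#'   (when outcomes were given). Methods: `print`, `summary`, `plot`,
#'   `predict`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(generator_config(
#'   n_per_cohort = c(SIM = 40), seed = 7))
#' fit <- trajectory_clusters(cohort$measurements, cohort$outcomes,
#'                            grid = configuration_grid(k = 2:3))
#' fit
#' }
#' @export
trajectory_clusters <- function(measurements, outcomes = NULL,
                                panel = subset_panel("gvhd_associated"),
                                interpolation = c("linear", "smooth"),
                                grid = NULL, seed = 1,
                                min_samples = 3, first_by_day = 45,
                                horizon_days = 365, grid_step = 7,
                                local_norm = "L1", n_rep = 10,
                                subsample_frac = 0.8,
                                min_cluster_frac = 0.10,
                                max_sil_variance = 0.01) {
  interpolation <- match.arg(interpolation)
  cl <- match.call()
  flt <- filter_eligible(measurements, min_samples, first_by_day,
                         horizon_days)
  if (nrow(flt$eligible) == 0)
    stop("no patient passed the eligibility filter (",
         nrow(flt$exclusions), " excluded)")
  set <- assemble_model_matrix(flt$eligible, panel, interpolation,
                               grid_step, horizon_days)
  exclusions <- rbind(
    flt$exclusions,
    stats::setNames(attr(set, "excluded"), c("patient_id", "rule")))
  grid <- grid %||% configuration_grid(panel)
  search <- run_configuration_search(set, grid, seed = seed,
                                     n_rep = n_rep,
                                     subsample_frac = subsample_frac,
                                     local_norm = local_norm)
  selected <- select_configuration(search, min_cluster_frac,
                                   max_sil_variance)
  outcome_report <- if (!is.null(outcomes))
    associate_clusters_outcomes(selected$result, outcomes) else NULL
  structure(list(call = cl, panel = panel, interpolation = interpolation,
                 set = set, exclusions = exclusions,
                 search = search, selected = selected,
                 labels = selected$result$labels,
                 outcome_report = outcome_report, seed = seed,
                 local_norm = local_norm),
            class = "trecon_fit")
}

#' @export
print.trecon_fit <- function(x, ...) {
  cfg <- x$selected$config
  cat("Trajectory clustering fit ('", panel_name(x$panel),
      "' panel, ", x$interpolation, " interpolation)\n", sep = "")
  cat("  patients clustered: ", length(x$labels), " (",
      nrow(x$exclusions), " excluded)\n", sep = "")
  cat("  selected configuration: ", cfg$config_id, " (",
      cfg$centroid_method, ", k = ", cfg$k, ", window ",
      cfg$window_frac, ", ", cfg$normalization, ")\n", sep = "")
  cat("  silhouette: ", format(x$selected$result$sil_overall,
                               digits = 3),
      " (resampling variance ",
      format(x$selected$stability$sil_variance, digits = 2), ")\n",
      sep = "")
  cat("  cluster sizes:",
      paste(x$selected$result$cluster_sizes, collapse = " / "), "\n")
  if (!is.null(x$outcome_report)) print(x$outcome_report)
  invisible(x)
}

#' @export
summary.trecon_fit <- function(object, n_top = 10, ...) {
  cat("Configuration ranking (top ", n_top, " of ",
      nrow(object$search$summary), "):\n", sep = "")
  print(utils::head(object$search$summary, n_top), digits = 3)
  cat("\nSelected: ", object$selected$config$config_id, "\n", sep = "")
  print(object$selected$result)
  invisible(object$search$summary)
}

#' Predict cluster membership for new patient series
#'
#' Assigns each new series to the cluster of its nearest prototype under
#' the selected configuration's DTW distance: the nearest medoid series
#' for a PAM fit, the nearest DBA centroid (squared-cost alignment) for
#' a DBA fit.
#'
#' @param object a `trecon_fit`.
#' @param newdata a `series_set` or list of series matrices (4 channels,
#'   same panel order as the fit).
#' @param ... unused.
#' @return Named integer vector of predicted cluster labels.
#' @export
predict.trecon_fit <- function(object, newdata, ...) {
  cfg <- object$selected$config
  params <- config_params(cfg, object$local_norm)
  res <- object$selected$result
  new_mats <- lapply(newdata, as_series_matrix)
  if (params$normalization == "zscore_per_subset") {
    ref <- lapply(object$set, as_series_matrix)
    all_vals <- do.call(cbind, ref)
    mu <- rowMeans(all_vals); sdv <- apply(all_vals, 1, stats::sd)
    sdv[sdv == 0] <- 1
    new_mats <- lapply(new_mats, function(m) (m - mu) / sdv)
  }
  protos <- if (res$method == "PAM") {
    prepare_set_matrices(object$set, params)[res$medoid_index]
  } else res$centroids
  norm <- if (res$method == "PAM") norm_code(params$local_norm) else 0L
  cd <- .cpp_cross_dist(new_mats, protos, norm, params$window_frac)
  labels <- apply(cd, 1, which.min)
  names(labels) <- attr(newdata, "ids") %||%
    vapply(seq_along(newdata), function(i) {
      s <- newdata[[i]]
      if (is.list(s) && !is.null(s$patient_id)) s$patient_id
      else as.character(i)
    }, "")
  labels
}

#' Plot a trajectory clustering fit
#'
#' Draws, per subset, the interpolated patient trajectories coloured by
#' cluster with the selected prototypes overlaid; if outcomes were
#' supplied, adds the per-cluster overall survival curves.
#'
#' @param x a `trecon_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trecon_fit <- function(x, ...) {
  panel <- unclass(x$panel)
  res <- x$selected$result
  n_panels <- length(panel) + as.integer(!is.null(x$outcome_report))
  old <- graphics::par(mfrow = c(ceiling(n_panels / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- res$labels
  for (s in seq_along(panel)) {
    xs <- lapply(x$set, function(r) r$grid)
    ys <- lapply(x$set, function(r) r$values[s, ])
    xlim <- range(unlist(xs)); ylim <- range(unlist(ys))
    graphics::plot(NA, xlim = xlim, ylim = ylim,
                   xlab = "day post-HCT", ylab = "cells/uL",
                   main = panel[s], ...)
    for (i in seq_along(x$set))
      graphics::lines(xs[[i]], ys[[i]],
                      col = grDevices::adjustcolor(cols[i] + 1, 0.35))
    if (res$method == "DBA") {
      for (c in seq_along(res$centroids)) {
        cen <- res$centroids[[c]]
        graphics::lines(seq(0, by = 7, length.out = ncol(cen)),
                        cen[s, ], col = c + 1, lwd = 3)
      }
    } else {
      for (c in seq_len(res$k)) {
        med <- x$set[[res$medoid_index[c]]]
        graphics::lines(med$grid, med$values[s, ], col = c + 1, lwd = 3)
      }
    }
  }
  if (!is.null(x$outcome_report)) {
    rep <- x$outcome_report
    graphics::plot(NA, xlim = c(0, 365), ylim = c(0, 1),
                   xlab = "days post-HCT", ylab = "overall survival",
                   main = "OS by cluster")
    for (g in seq_along(rep$os$curves)) {
      cv <- rep$os$curves[[g]]
      graphics::lines(stats::stepfun(cv$times, c(1, cv$surv)),
                      col = g + 1, do.points = FALSE)
    }
  }
  invisible(x)
}
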