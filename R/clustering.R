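#' k-partitional clustering with DBA prototypes
#'
#' Alternates assignment of each series to its nearest DBA centroid
#' (squared-cost DTW alignment, matching the DBA objective) with
#' recomputation of each centroid by [dba_centroid()], until the labels
#' reach a fixpoint or `max_iter` passes. An emptied cluster is re-seeded
#' with the series farthest from every centroid (logged as a warning).
#'
#' @param set `series_set` or list of series matrices.
#' @param k number of clusters, `1 <= k < n`.
#' @param params a [dtw_params()]; the window and normalization apply,
#'   alignment cost is the squared-Euclidean DBA formulation.
#' @param seed integer seed for the random initial centroid draw.
#' @param max_iter cap on assignment/update passes.
#' @param dba_iter DBA refinement passes per centroid update; centroids
#'   are warm-started from their previous value, so a few passes per
#'   update suffice (default 5).
#' @param dm optional precomputed DTW distance matrix over `set`, used
#'   only to attach silhouette values to the result.
#' @return A `cluster_result` with `labels`, `centroids` (list of DBA
#'   prototype matrices) and `objective` (sum of squared-cost alignment
#'   distances to assigned centroids).
#' @export
dba_partitional_cluster <- function(set, k, params = dtw_params(),
                                    seed = 1, max_iter = 20, dm = NULL,
                                    dba_iter = 5) {
  mats <- prepare_set_matrices(set, params)
  n <- length(mats)
  if (k >= n) stop("k must be smaller than the number of series")
  ids <- attr(set, "ids") %||% as.character(seq_len(n))
  if (k == 1) {
    cen <- dba_centroid(mats, params)
    labels <- rep(1L, n); names(labels) <- ids
    return(structure(list(method = "DBA", k = 1L, labels = labels,
                          centroids = list(cen),
                          objective = attr(cen, "objective"),
                          cluster_sizes = n, sil_points = NULL,
                          sil_overall = NA_real_),
                     class = "cluster_result"))
  }
  set.seed(seed)
  centroids <- mats[sample.int(n, k)]
  labels <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    cd <- .cpp_cross_dist(mats, centroids, 0L, params$window_frac)
    new_labels <- apply(cd, 1, which.min)
    for (c in seq_len(k)) { # re-seed emptied clusters
      if (!any(new_labels == c)) {
        far <- which.max(apply(cd, 1, min))
        new_labels[far] <- c
        warning("cluster ", c, " emptied; re-seeded with farthest series")
      }
    }
    if (all(new_labels == labels)) break
    labels <- new_labels
    centroids <- lapply(seq_len(k), function(c)
      dba_centroid(mats[labels == c], params, init = centroids[[c]],
                   max_iter = dba_iter))
  }
  cd <- .cpp_cross_dist(mats, centroids, 0L, params$window_frac)
  objective <- sum(cd[cbind(seq_len(n), labels)])
  names(labels) <- ids
  sil <- if (!is.null(dm)) silhouette_score(dm, labels) else
    list(sil_points = NULL, sil_overall = NA_real_)
  structure(list(method = "DBA", k = as.integer(k), labels = labels,
                 centroids = centroids, objective = objective,
                 cluster_sizes = tabulate(labels, k),
                 sil_points = sil$sil_points,
                 sil_overall = sil$sil_overall),
            class = "cluster_result")
}

#' The clustering configuration grid
#'
#' The reference grid crosses centroid method (PAM, DBA), cluster count
#' `k`, Sakoe-Chiba window fraction, and normalization into 36 distinct
#' configurations, identified as `"<model>_<index>"` where the model
#' digit encodes the subset panel (1 = GVHD-associated, 2 = broad
#' spectrum, c = custom). Every axis can be overridden.
#'
#' @param panel optional [subset_panel()], used only for the id prefix.
#' @param centroid_method,k,window_frac,normalization grid axes.
#' @return Data frame of class `cluster_grid` with one row per
#'   configuration (`config_id`, `centroid_method`, `k`, `window_frac`,
#'   `normalization`).
#' @examples
#' nrow(configuration_grid()) # 36
#' @export
configuration_grid <- function(panel = NULL,
                               centroid_method = c("PAM", "DBA"),
                               k = 2:4,
                               window_frac = c(0.05, 0.10, 0.20),
                               normalization = c("raw",
                                                 "zscore_per_subset")) {
  g <- expand.grid(centroid_method = centroid_method, k = k,
                   window_frac = window_frac,
                   normalization = normalization,
                   stringsAsFactors = FALSE)
  model <- if (is.null(panel)) "1" else panel_model_index(panel)
  g <- cbind(config_id = paste0(model, "_", seq_len(nrow(g))), g,
             stringsAsFactors = FALSE)
  class(g) <- c("cluster_grid", "data.frame")
  g
}

config_params <- function(config, local_norm = "L1") {
  dtw_params(window_frac = config$window_frac, local_norm = local_norm,
             normalization = config$normalization)
}

run_one_config <- function(mats_raw, dm, config, seed, local_norm) {
  params <- config_params(config, local_norm)
  if (config$centroid_method == "PAM") {
    pam_cluster(dm, config$k)
  } else {
    dba_partitional_cluster(mats_raw, config$k, params, seed = seed,
                            dm = dm)
  }
}

#' Subsampling robustness of one configuration
#'
#' Re-clusters `n_rep` random subsamples (drawn without replacement) of
#' the series set under one configuration and records the silhouette of
#' each replicate; the variance across replicates is the robustness
#' readout used to screen configurations.
#'
#' @param set `series_set` (needed for DBA configurations; may be `NULL`
#'   for PAM when `dm` is given).
#' @param config one row of [configuration_grid()].
#' @param n_rep number of replicates (default 10).
#' @param subsample_frac fraction of patients per replicate (default
#'   0.8); `floor(subsample_frac * n)` must exceed `k`.
#' @param seed integer seed; the replicate draw sequence is reproducible.
#' @param local_norm DTW local norm shared across the grid.
#' @param dm optional precomputed distance matrix over the full set.
#' @return List of class `stability_result`: `config_id`,
#'   `sil_replicates`, `sil_mean`, `sil_variance`, `seed`.
#' @export
resample_stability <- function(set, config, n_rep = 10,
                               subsample_frac = 0.8, seed = 1,
                               local_norm = "L1", dm = NULL) {
  params <- config_params(config, local_norm)
  if (is.null(dm)) dm <- pairwise_distances(set, params)
  n <- nrow(dm)
  m <- floor(subsample_frac * n)
  if (m <= config$k) stop("subsample too small for k = ", config$k)
  mats <- if (config$centroid_method == "DBA")
    lapply(set, as_series_matrix) else NULL
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_rep)
  sil <- vapply(seq_len(n_rep), function(r) {
    set.seed(sub_seeds[r])
    idx <- sort(sample.int(n, m))
    sub_dm <- dm[idx, idx]
    res <- if (config$centroid_method == "PAM") {
      pam_cluster(sub_dm, config$k)
    } else {
      sub_set <- structure(mats[idx], ids = dm_ids(dm)[idx])
      dba_partitional_cluster(sub_set, config$k, params,
                              seed = sub_seeds[r], dm = sub_dm)
    }
    res$sil_overall
  }, 0)
  structure(list(config_id = config$config_id, sil_replicates = sil,
                 sil_mean = mean(sil),
                 sil_variance = stats::var(sil), seed = seed),
            class = "stability_result")
}

#' Run the full configuration search
#'
#' Clusters the series set under every configuration of the grid,
#' evaluates each by the silhouette coefficient on the full data, probes
#' its robustness by subsampling ([resample_stability()]), and ranks the
#' configurations by silhouette (descending). Distance matrices are
#' shared across configurations with identical distance settings. A
#' failing configuration is logged and skipped, never aborts the search.
#'
#' @param set `series_set` from [assemble_model_matrix()].
#' @param grid a [configuration_grid()].
#' @param seed master seed; per-configuration seeds are derived from it.
#' @param n_rep,subsample_frac robustness settings, see
#'   [resample_stability()].
#' @param local_norm DTW local norm shared across the grid
#'   (default `"L1"` on raw counts).
#' @return List of class `config_search`: `summary` (ranked data frame),
#'   `results` (per config: `config`, `result`, `stability`), `n`.
#' @export
run_configuration_search <- function(set, grid = configuration_grid(),
                                     seed = 1, n_rep = 10,
                                     subsample_frac = 0.8,
                                     local_norm = "L1") {
  n <- length(set)
  if (n < 2 * max(grid$k)) stop("too few series for the configured k")
  set.seed(seed)
  config_seeds <- sample.int(.Machine$integer.max, nrow(grid))

  dm_cache <- list()
  get_dm <- function(config) {
    key <- paste(config$window_frac, config$normalization, sep = "|")
    if (is.null(dm_cache[[key]]))
      dm_cache[[key]] <<- pairwise_distances(
        set, config_params(config, local_norm))
    dm_cache[[key]]
  }

  results <- list()
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    config <- grid[i, ]
    entry <- tryCatch({
      dm <- get_dm(config)
      res <- run_one_config(set, dm, config, config_seeds[i], local_norm)
      stab <- resample_stability(set, config, n_rep, subsample_frac,
                                 seed = config_seeds[i],
                                 local_norm = local_norm, dm = dm)
      list(config = config, result = res, stability = stab)
    }, error = function(e) {
      warning("configuration ", config$config_id, " skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(entry)) next
    results[[config$config_id]] <- entry
    rows[[config$config_id]] <- data.frame(
      config_id = config$config_id,
      centroid_method = config$centroid_method, k = config$k,
      window_frac = config$window_frac,
      normalization = config$normalization,
      sil = entry$result$sil_overall,
      sil_resample_mean = entry$stability$sil_mean,
      sil_resample_var = entry$stability$sil_variance,
      min_cluster_size = min(entry$result$cluster_sizes))
  }
  if (length(rows) == 0) stop("every configuration failed")
  summary <- do.call(rbind, rows)
  summary <- summary[order(-summary$sil), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, results = results, n = n,
                 seed = seed), class = "config_search")
}

#' @export
print.config_search <- function(x, ...) {
  cat("Configuration search over", nrow(x$summary),
      "configurations,", x$n, "patients\n")
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' Select the working configuration
#'
#' Picks the highest-silhouette configuration whose smallest cluster
#' holds at least `min_cluster_frac` of the patients (the balance rule)
#' and whose subsampling silhouette variance does not exceed
#' `max_sil_variance` (the robustness rule). If no configuration
#' qualifies, the top-silhouette configuration is returned with a
#' warning.
#'
#' @param search a `config_search` from [run_configuration_search()].
#' @param min_cluster_frac minimum size of the smallest cluster as a
#'   fraction of `n` (default 0.10).
#' @param max_sil_variance maximum silhouette variance under resampling
#'   (default 0.01).
#' @return The selected entry: list with `config`, `result`,
#'   `stability`.
#' @export
select_configuration <- function(search, min_cluster_frac = 0.10,
                                 max_sil_variance = 0.01) {
  stopifnot(inherits(search, "config_search"))
  s <- search$summary
  if (nrow(s) == 0) stop("empty configuration ranking")
  ok <- s$min_cluster_size >= min_cluster_frac * search$n &
    s$sil_resample_var <= max_sil_variance
  pick <- if (any(ok)) s$config_id[which(ok)[1]] else {
    warning("no configuration met the balance/robustness rules; ",
            "falling back to the best silhouette")
    s$config_id[1]
  }
  search$results[[pick]]
}
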