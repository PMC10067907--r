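validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  invisible(dm)
}

dm_ids <- function(dm) rownames(dm) %||% as.character(seq_len(nrow(dm)))

#' Partition around medoids on a precomputed distance matrix
#'
#' Classic deterministic PAM: the BUILD phase greedily accumulates the
#' `k` medoids that most reduce the total distance of every point to its
#' nearest medoid, then the SWAP phase exchanges a medoid for a
#' non-medoid whenever that lowers the objective, until no improving swap
#' exists. Medoids are always data members ("most representative
#' samples"). Ties are broken by the lowest patient index, so the result
#' is deterministic; `seed` is accepted for interface uniformity only.
#'
#' @param dm symmetric distance matrix with zero diagonal (patient ids as
#'   dimnames).
#' @param k number of clusters, `1 <= k < n`.
#' @param seed unused (PAM here has no random component).
#' @param max_iter cap on SWAP passes.
#' @return A `cluster_result`: labels (named by patient id), medoid ids,
#'   total within-cluster distance to medoids (`objective`), cluster
#'   sizes, and — for `k >= 2` — silhouette values.
#' @export
pam_cluster <- function(dm, k, seed = NULL, max_iter = 100) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (k >= n) stop("k must be smaller than the number of patients")
  if (k < 1) stop("k must be >= 1")
  if (k > 1 && all(dm == 0))
    warning("all distances are zero; clusters are arbitrary")

  # BUILD: greedy accumulation (ties to lowest index via which.min)
  medoids <- which.min(colSums(dm))
  dnear <- dm[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gains <- vapply(cand, function(c) sum(pmin(dnear, dm[, c])), 0)
    best <- cand[which.min(gains)]
    medoids <- c(medoids, best)
    dnear <- pmin(dnear, dm[, best])
  }

  # SWAP: best-improvement passes until a local optimum
  objective <- sum(dnear)
  for (pass in seq_len(max_iter)) {
    nearest <- apply(dm[, medoids, drop = FALSE], 1, which.min)
    ord <- apply(dm[, medoids, drop = FALSE], 1, function(r)
      sort(r, partial = seq_len(min(2, k)))[seq_len(min(2, k))])
    d1 <- dm[cbind(seq_len(n), medoids[nearest])]
    d2 <- if (k > 1) ord[2, ] else rep(Inf, n)
    best_delta <- 0; best_swap <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      own <- nearest == mi
      for (h in nonmed) {
        dh <- dm[, h]
        new_cost <- sum(ifelse(own, pmin(d2, dh), pmin(d1, dh)))
        delta <- new_cost - objective
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    objective <- objective + best_delta
  }

  medoids <- sort(medoids)
  labels <- apply(dm[, medoids, drop = FALSE], 1, which.min)
  objective <- sum(dm[cbind(seq_len(n), medoids[labels])])
  ids <- dm_ids(dm)
  names(labels) <- ids
  sil <- if (k >= 2 && length(unique(labels)) >= 2)
    silhouette_score(dm, labels)
  else list(sil_points = NULL, sil_overall = NA_real_)
  structure(list(method = "PAM", k = k, labels = labels,
                 medoid_ids = ids[medoids], medoid_index = medoids,
                 objective = objective,
                 cluster_sizes = tabulate(labels, k),
                 sil_points = sil$sil_points,
                 sil_overall = sil$sil_overall),
            class = "cluster_result")
}

#' Silhouette coefficient of a clustering
#'
#' For each point, `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)`
#' is the mean distance to its own cluster (excluding itself) and `b(i)`
#' the smallest mean distance to any other cluster. Members of singleton
#' clusters get `s(i) = 0`, as does the degenerate 0/0 case. The overall
#' coefficient is the mean of `s(i)`, ranging from -1 to +1 with the
#' optimum at +1.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param labels integer cluster label per point (at least two non-empty
#'   clusters).
#' @return List with `sil_points` (per-point `s(i)`, named like `dm`) and
#'   `sil_overall` (their mean).
#' @export
silhouette_score <- function(dm, labels) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette is undefined for a single cluster")
  sizes <- tabulate(labels, k)
  sums <- rowsum(dm, labels) # k x n: distance sums to each cluster
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    a[i] <- if (sizes[own] > 1) sums[own, i] / (sizes[own] - 1) else NA
    b[i] <- min(sums[-own, i] / sizes[-own])
  }
  s <- ifelse(is.na(a) | pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  names(s) <- dm_ids(dm)
  list(sil_points = s, sil_overall = mean(s))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(x$method, " clustering, k = ", x$k, "\n", sep = "")
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = " / "), "\n")
  if (!is.na(x$sil_overall))
    cat("  silhouette:", format(x$sil_overall, digits = 3), "\n")
  invisible(x)
}
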