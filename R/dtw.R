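#' DTW distance parameters
#'
#' @param window_frac Sakoe-Chiba band half-width as a fraction of the
#'   longer series length, in `(0, 1]`, or `NULL` for an unconstrained
#'   alignment. The band is slanted along the main diagonal and floored
#'   at one cell so an alignment path always exists.
#' @param local_norm norm of the 4-vector pointwise difference: `"L1"`
#'   or `"L2"`.
#' @param normalization `"raw"` (absolute counts, untransformed) or
#'   `"zscore_per_subset"` (each subset standardised with statistics
#'   pooled over the series set before distances are computed).
#' @return A list of class `dtw_params`.
#' @export
dtw_params <- function(window_frac = 0.1, local_norm = c("L1", "L2"),
                       normalization = c("raw", "zscore_per_subset")) {
  local_norm <- match.arg(local_norm)
  normalization <- match.arg(normalization)
  if (!is.null(window_frac)) {
    stopifnot(is.numeric(window_frac), length(window_frac) == 1L,
              window_frac > 0, window_frac <= 1)
  }
  structure(list(window_frac = window_frac %||% -1,
                 local_norm = local_norm,
                 normalization = normalization), class = "dtw_params")
}

norm_code <- function(local_norm) if (local_norm == "L1") 1L else 2L

as_series_matrix <- function(x) {
  if (inherits(x, "regular_series")) return(x$values)
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), nrow = 1) # univariate vector
}

#' Dynamic time warping distance between two multivariate series
#'
#' Classic cumulative DTW: `D(i,j) = c(i,j) + min(D(i-1,j), D(i,j-1),
#' D(i-1,j-1))` with `D(1,1) = c(1,1)`, where the local cost `c` is the
#' L1 or L2 norm of the pointwise difference across channels, and cells
#' outside the (slanted) Sakoe-Chiba band are inadmissible. The
#' symmetric three-way step pattern carries no step weights and the
#' returned value `D(n,m)` is not path-length normalised.
#'
#' @param x,y series: `d x n` matrices (rows = subsets), numeric vectors
#'   (univariate), or `regular_series` objects. `x` and `y` must share
#'   the channel count.
#' @param params a [dtw_params()].
#' @return Non-negative alignment cost; 0 for identical series.
#' @examples
#' dtw_distance(c(1, 3, 4), c(1, 2, 4), dtw_params(window_frac = NULL))
#' @export
dtw_distance <- function(x, y, params = dtw_params()) {
  x <- as_series_matrix(x); y <- as_series_matrix(y)
  if (ncol(x) < 1 || ncol(y) < 1) stop("empty series")
  .cpp_dtw(x, y, norm_code(params$local_norm), params$window_frac)
}

# pooled per-subset z-scoring across a list of matrices
zscore_set <- function(mats) {
  d <- nrow(mats[[1]])
  all_vals <- do.call(cbind, mats)
  mu <- rowMeans(all_vals)
  sdv <- apply(all_vals, 1, stats::sd)
  sdv[sdv == 0] <- 1
  lapply(mats, function(m) (m - mu) / sdv)
}

prepare_set_matrices <- function(set, params) {
  mats <- lapply(set, as_series_matrix)
  if (params$normalization == "zscore_per_subset") mats <- zscore_set(mats)
  mats
}

#' Pairwise DTW distance matrix over a series set
#'
#' @param set a `series_set` (see [assemble_model_matrix()]) or a list of
#'   series matrices.
#' @param params a [dtw_params()]; with `normalization =
#'   "zscore_per_subset"`, per-subset statistics are pooled over the set
#'   before distances are computed.
#' @return Symmetric non-negative matrix with zero diagonal and patient
#'   ids as dimnames.
#' @export
pairwise_distances <- function(set, params = dtw_params()) {
  if (length(set) < 2) stop("need at least two series")
  mats <- prepare_set_matrices(set, params)
  d <- .cpp_pairwise(mats, norm_code(params$local_norm),
                     params$window_frac)
  ids <- attr(set, "ids") %||%
    vapply(seq_along(set), function(i) {
      s <- set[[i]]
      if (is.list(s) && !is.null(s$patient_id)) s$patient_id
      else as.character(i)
    }, "")
  dimnames(d) <- list(ids, ids)
  d
}

#' DTW barycenter averaging (DBA) prototype of a set of series
#'
#' Iteratively refines a prototype series: every member is aligned to the
#' current barycenter by DTW and each barycenter point is replaced by the
#' mean of all member points aligned to it. Alignment uses the squared-
#' Euclidean local cost of the classic DBA formulation, under which the
#' alignment objective (sum over members of the squared-cost alignment
#' distance) is non-increasing across iterations. Iteration stops when
#' the objective decreases by less than `tol` or after `max_iter` passes.
#'
#' @param members list of series (matrices or `regular_series`) to
#'   average; the barycenter keeps the length of the initial member.
#' @param params a [dtw_params()]; only the window applies (DBA alignment
#'   cost is squared Euclidean).
#' @param init initial barycenter: a member index, a series matrix (used
#'   to warm-start from a previous prototype), or `NULL` for the medoid
#'   under squared-cost DTW (ties to the lowest index).
#' @param max_iter,tol stopping rule.
#' @return The barycenter matrix, with attributes `objective` (final
#'   alignment objective) and `objective_trace` (per-iteration values).
#' @export
dba_centroid <- function(members, params = dtw_params(), init = NULL,
                         max_iter = 15, tol = 1e-6) {
  if (length(members) == 0) stop("empty member list")
  mats <- lapply(members, as_series_matrix)
  if (length(mats) == 1) {
    return(structure(mats[[1]], objective = 0,
                     objective_trace = numeric()))
  }
  bary <- if (is.matrix(init)) init
  else if (!is.null(init)) mats[[init]]
  else {
    dsq <- .cpp_pairwise(mats, 0L, params$window_frac)
    mats[[which.min(rowSums(dsq))]] # ties: lowest index via which.min
  }
  trace <- numeric()
  obj_prev <- Inf
  updated <- FALSE
  for (it in seq_len(max_iter)) {
    step <- .cpp_dba_step(mats, bary, params$window_frac)
    trace <- c(trace, step$objective)
    if (obj_prev - step$objective < tol) { updated <- FALSE; break }
    obj_prev <- step$objective
    bary <- step$barycenter
    updated <- TRUE
  }
  if (updated) { # max_iter exhausted: score the final barycenter
    final <- .cpp_dba_step(mats, bary, params$window_frac)
    trace <- c(trace, final$objective)
  }
  structure(bary, objective = utils::tail(trace, 1),
            objective_trace = trace)
}
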