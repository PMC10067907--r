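# Independent oracles used to verify the package's core algorithms.
# These deliberately use naive formulations (explicit path enumeration,
# exhaustive search, double loops) rather than the implementations they
# check.

# --- exhaustive DTW ---------------------------------------------------

# all monotone warping paths from (1,1) to (n,m), as matrices of linear
# indices into an n x m cost matrix; memoised per (n, m)
.path_cache <- new.env(parent = emptyenv())
enum_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(list(matrix(c(1, 1), 1)))
    out <- list()
    if (i > 1) for (p in rec(i - 1, j))
      out[[length(out) + 1]] <- rbind(p, c(i, j))
    if (j > 1) for (p in rec(i, j - 1))
      out[[length(out) + 1]] <- rbind(p, c(i, j))
    if (i > 1 && j > 1) for (p in rec(i - 1, j - 1))
      out[[length(out) + 1]] <- rbind(p, c(i, j))
    out
  }
  paths <- lapply(rec(n, m), function(p) (p[, 2] - 1) * n + p[, 1])
  .path_cache[[key]] <- paths
  paths
}

# minimum path cost by explicit enumeration (unconstrained alignment)
enum_dtw <- function(x, y, local_norm = "L1") {
  x <- if (is.matrix(x)) x else matrix(x, 1)
  y <- if (is.matrix(y)) y else matrix(y, 1)
  n <- ncol(x); m <- ncol(y)
  C <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d <- x[, i] - y[, j]
    C[i, j] <- if (local_norm == "L1") sum(abs(d)) else sqrt(sum(d^2))
  }
  min(vapply(enum_paths(n, m), function(p) sum(C[p]), 0))
}

# --- exhaustive PAM ---------------------------------------------------

pam_brute <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf
  sets <- utils::combn(n, k)
  for (c in seq_len(ncol(sets))) {
    medoids <- sets[, c]
    obj <- sum(apply(dm[, medoids, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# --- double-loop silhouette ------------------------------------------

sil_oracle <- function(dm, labels) {
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dm[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dm[i, labels == cl]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# --- pair-counting adjusted Rand -------------------------------------

ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# --- small fixtures ---------------------------------------------------

# random multivariate series list (d channels, lengths in len_range)
random_series_set <- function(n, d = 4, len_range = c(5, 12)) {
  lapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    matrix(stats::runif(d * len, 0, 10), nrow = d)
  })
}

# random symmetric distance matrix with zero diagonal
random_dm <- function(n) {
  m <- matrix(stats::runif(n * n, 0.1, 5), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# block-structured distance matrix: two groups, small within-group and
# large between-group distances
blob_dm <- function(n1, n2, within = 1, between = 10) {
  n <- n1 + n2
  d <- matrix(between, n, n)
  d[seq_len(n1), seq_len(n1)] <- within
  d[n1 + seq_len(n2), n1 + seq_len(n2)] <- within
  diag(d) <- 0
  dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
  d
}

# long-format measurements for hand-built patients: days list per patient
make_measurements <- function(days_by_patient,
                              subsets = c("s1", "s2", "s3", "s4"),
                              cohort = "A") {
  rows <- list()
  for (pid in names(days_by_patient)) {
    days <- days_by_patient[[pid]]
    for (s in subsets) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, cohort = cohort, day = days, subset = s,
        fraction = 0.1, alc = 1000)
    }
  }
  do.call(rbind, rows)
}

no_window <- function() dtw_params(window_frac = NULL)
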