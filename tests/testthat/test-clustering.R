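test_that("PAM swap phase reaches a true local optimum", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    dm <- random_dm(n)
    res <- pam_cluster(dm, k)
    brute <- pam_brute(dm, k)
    # never better than the exhaustive optimum (objective is computed
    # correctly) ...
    expect_gte(res$objective, brute - 1e-10)
    # ... and no single medoid/non-medoid exchange improves it (the
    # swap neighbourhood is fully explored)
    med <- res$medoid_index
    for (mi in seq_along(med)) for (h in setdiff(seq_len(n), med)) {
      cand <- med; cand[mi] <- h
      obj <- sum(apply(dm[, cand, drop = FALSE], 1, min))
      expect_gte(obj, res$objective - 1e-10)
    }
  }
})

test_that("PAM finds the exhaustive optimum on cluster-structured data", {
  set.seed(12)
  for (rep in 1:15) {
    # distances from points with genuine group structure
    centers <- matrix(runif(6, 0, 20), 3)
    pts <- centers[sample(1:3, 8, replace = TRUE), ] +
      matrix(rnorm(16, sd = 0.5), 8)
    dm <- as.matrix(dist(pts))
    k <- sample(2:3, 1)
    expect_equal(pam_cluster(dm, k)$objective, pam_brute(dm, k),
                 tolerance = 1e-10)
  }
})

test_that("PAM recovers separated blobs and the k = 1 medoid", {
  dm <- blob_dm(6, 4)
  res <- pam_cluster(dm, 2)
  expect_equal(length(unique(res$labels[1:6])), 1)
  expect_equal(length(unique(res$labels[7:10])), 1)
  expect_false(res$labels[1] == res$labels[7])
  expect_equal(sort(res$cluster_sizes), c(4, 6))
  # k = 1: medoid minimises the summed distance
  dm2 <- random_dm(7)
  r1 <- pam_cluster(dm2, 1)
  expect_equal(r1$medoid_index, unname(which.min(colSums(dm2))))
  expect_error(pam_cluster(dm2, 7), "smaller")
  expect_warning(pam_cluster(matrix(0, 4, 4), 2), "zero")
})

test_that("silhouette matches the worked example and the oracle", {
  # two pairs: within-cluster distance 1, between 10 -> s = 0.9 for all
  dm <- blob_dm(2, 2, within = 1, between = 10)
  sil <- silhouette_score(dm, c(1, 1, 2, 2))
  expect_equal(unname(sil$sil_points), rep(0.9, 4))
  expect_equal(sil$sil_overall, 0.9)
  # degenerate all-zero distances: 0/0 guarded to 0
  sil0 <- silhouette_score(matrix(0, 4, 4), c(1, 1, 2, 2))
  expect_equal(unname(sil0$sil_points), rep(0, 4))
  # random matrices against the double-loop oracle; bounds; invariance
  set.seed(22)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    dm <- random_dm(n)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    sil <- silhouette_score(dm, labels)
    expect_equal(unname(sil$sil_points), sil_oracle(dm, labels))
    expect_true(all(abs(sil$sil_points) <= 1))
    perm <- c(3, 1, 2)[labels]
    expect_equal(silhouette_score(dm, perm)$sil_overall,
                 sil$sil_overall)
  }
  expect_error(silhouette_score(random_dm(4), rep(1, 4)), "single")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(33)
  dm <- random_dm(10)
  labels <- sample(1:2, 10, replace = TRUE)
  ours <- silhouette_score(dm, labels)
  ref <- cluster::silhouette(labels, dmatrix = dm)
  expect_equal(unname(ours$sil_points), unname(ref[, "sil_width"]))
})

test_that("the reference grid crosses its axes into 36 configurations", {
  g <- configuration_grid()
  expect_equal(nrow(g), 36)
  expect_equal(anyDuplicated(g$config_id), 0)
  expect_equal(nrow(configuration_grid(k = 2)), 12)
  expect_equal(nrow(configuration_grid(centroid_method = "PAM")), 18)
  expect_equal(nrow(configuration_grid(window_frac = 0.1)), 12)
  # the model digit encodes the panel
  g2 <- configuration_grid(subset_panel("broad_spectrum"))
  expect_true(all(startsWith(g2$config_id, "2_")))
})

test_that("DBA partitional clustering handles consistency cases", {
  set.seed(44)
  mats <- random_series_set(6, d = 2, c(5, 8))
  params <- dtw_params(0.2)
  # k = 1 equals the plain DBA centroid of the full set
  r1 <- dba_partitional_cluster(mats, 1, params, seed = 1)
  expect_equal(unclass(r1$centroids[[1]])[, ],
               unclass(dba_centroid(mats, params))[, ],
               ignore_attr = TRUE)
  # duplicated set at k = n_distinct reaches zero objective
  dup <- c(mats[1:3], mats[1:3])
  rdup <- suppressWarnings(dba_partitional_cluster(dup, 3, params,
                                                   seed = 7))
  expect_lt(rdup$objective, 1e-9)
  expect_error(dba_partitional_cluster(mats, 6, params), "smaller")
})

test_that("DBA partitional clustering recovers strong separation", {
  set.seed(55)
  lowv <- lapply(1:8, function(i) matrix(runif(4 * 6, 0, 1), 4))
  high <- lapply(1:7, function(i) matrix(runif(4 * 6, 50, 51), 4))
  set <- c(lowv, high)
  truth <- rep(1:2, c(8, 7))
  res <- dba_partitional_cluster(set, 2, dtw_params(0.2), seed = 3)
  expect_equal(adjusted_rand(res$labels, setNames(truth,
                                                  names(res$labels))), 1)
})

test_that("resampling stability is deterministic and flat when separated", {
  set.seed(66)
  lowv <- lapply(1:10, function(i) matrix(runif(4 * 6, 0, 1), 4))
  high <- lapply(1:10, function(i) matrix(runif(4 * 6, 50, 51), 4))
  set <- structure(c(lowv, high), ids = sprintf("p%02d", 1:20))
  cfg <- configuration_grid()[1, ] # PAM, k = 2
  s1 <- resample_stability(set, cfg, seed = 9)
  s2 <- resample_stability(set, cfg, seed = 9)
  expect_identical(s1$sil_replicates, s2$sil_replicates)
  expect_length(s1$sil_replicates, 10)
  expect_lt(s1$sil_variance, 1e-3)
  expect_error(resample_stability(set, cfg, subsample_frac = 0.1),
               "too small")
})

test_that("configuration search ranks by silhouette and is reproducible", {
  set.seed(77)
  lowv <- lapply(1:10, function(i)
    matrix(rep(runif(4, 0, 1), 6) + runif(24, 0, 0.3), 4))
  high <- lapply(1:10, function(i)
    matrix(rep(runif(4, 8, 10), 6) + runif(24, 0, 0.3), 4))
  set <- structure(c(lowv, high), ids = sprintf("p%02d", 1:20))
  grid <- configuration_grid(k = 2:3, window_frac = 0.1)
  s1 <- run_configuration_search(set, grid, seed = 5)
  expect_true(all(diff(s1$summary$sil) <= 0))
  expect_equal(s1$summary$k[1], 2) # true structure has two clusters
  s2 <- run_configuration_search(set, grid, seed = 5)
  expect_identical(s1$summary, s2$summary)
  one <- run_configuration_search(set, grid[1, , drop = FALSE], seed = 5)
  expect_equal(nrow(one$summary), 1)
})

test_that("configuration selection enforces balance and robustness", {
  mk_entry <- function(id, sil, var, min_size) {
    list(config = data.frame(config_id = id, centroid_method = "PAM",
                             k = 2, window_frac = 0.1,
                             normalization = "raw"),
         result = list(sil_overall = sil,
                       cluster_sizes = c(min_size, 100 - min_size)),
         stability = list(sil_variance = var))
  }
  summary <- data.frame(
    config_id = c("1_1", "1_2", "1_3"),
    sil = c(0.9, 0.8, 0.7),
    sil_resample_var = c(0.001, 0.5, 0.002),
    min_cluster_size = c(1, 40, 30))
  search <- structure(list(
    summary = summary, n = 100,
    results = list("1_1" = mk_entry("1_1", 0.9, 0.001, 1),
                   "1_2" = mk_entry("1_2", 0.8, 0.5, 40),
                   "1_3" = mk_entry("1_3", 0.7, 0.002, 30))),
    class = "config_search")
  # top config has a 1-patient cluster, second fails robustness
  sel <- select_configuration(search)
  expect_equal(sel$config$config_id, "1_3")
  # nothing qualifies: fall back to the top silhouette with a warning
  expect_warning(
    sel2 <- select_configuration(search, min_cluster_frac = 0.45),
    "falling back")
  expect_equal(sel2$config$config_id, "1_1")
})
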