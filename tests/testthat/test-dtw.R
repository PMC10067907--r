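test_that("DTW distance matches hand-checked and enumerated alignments", {
  # identity and symmetry
  x <- matrix(runif(20), 4)
  expect_equal(dtw_distance(x, x), 0)
  y <- matrix(runif(28), 4)
  expect_equal(dtw_distance(x, y), dtw_distance(y, x))
  # the classic univariate example: one warp absorbs the difference
  expect_equal(dtw_distance(c(1, 3, 4), c(1, 2, 4), no_window()), 1)
  expect_equal(enum_dtw(c(1, 3, 4), c(1, 2, 4)), 1)
  expect_error(dtw_distance(matrix(0, 4, 0), y), "empty")
})

test_that("DTW equals exhaustive path enumeration on short series", {
  set.seed(101)
  for (rep in 1:60) {
    d <- sample(c(1, 4), 1)
    x <- matrix(runif(d * sample(1:6, 1), 0, 5), nrow = d)
    y <- matrix(runif(d * sample(1:6, 1), 0, 5), nrow = d)
    norm <- sample(c("L1", "L2"), 1)
    expect_equal(
      dtw_distance(x, y, dtw_params(window_frac = NULL,
                                    local_norm = norm)),
      enum_dtw(x, y, norm), tolerance = 1e-12)
  }
})

test_that("widening the Sakoe-Chiba band never increases the distance", {
  set.seed(202)
  for (rep in 1:20) {
    x <- matrix(runif(4 * 15, 0, 5), nrow = 4)
    y <- matrix(runif(4 * 18, 0, 5), nrow = 4)
    d <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(w)
      dtw_distance(x, y, dtw_params(window_frac = w)), 0)
    expect_true(all(diff(d) <= 1e-12))
    # the full-width band equals the unconstrained alignment
    expect_equal(d[5], dtw_distance(x, y, no_window()))
  }
})

test_that("banded alignment stays feasible for very unequal lengths", {
  x <- matrix(runif(2), 1)
  y <- matrix(runif(40), 1)
  expect_true(is.finite(dtw_distance(x, y, dtw_params(0.05))))
  expect_true(is.finite(dtw_distance(y, x, dtw_params(0.05))))
  expect_true(is.finite(dtw_distance(x[, 1, drop = FALSE], y,
                                     dtw_params(0.05))))
})

test_that("pairwise distance matrix is consistent with single calls", {
  set.seed(303)
  mats <- random_series_set(5)
  params <- dtw_params(0.2)
  dm <- pairwise_distances(mats, params)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dm[i, j], dtw_distance(mats[[i]], mats[[j]], params))
  # identical series at zero distance
  twin <- list(mats[[1]], mats[[1]])
  expect_equal(unname(pairwise_distances(twin, params)),
               matrix(0, 2, 2))
  expect_error(pairwise_distances(mats[1], params), "two series")
})

test_that("DBA handles the degenerate prototypes exactly", {
  one <- matrix(1:8, nrow = 4)
  expect_equal(unclass(dba_centroid(list(one)))[, ], one[, ])
  same <- list(one, one, one)
  cen <- dba_centroid(same)
  expect_equal(cen[, ], one[, ], ignore_attr = TRUE)
  expect_equal(attr(cen, "objective"), 0)
  # two constant univariate members average to the constant midpoint
  a <- matrix(2, 1, 3); b <- matrix(4, 1, 3)
  cen2 <- dba_centroid(list(a, b))
  expect_equal(cen2[, ], rep(3, 3), ignore_attr = TRUE)
  # ... and 3 is the best constant prototype by grid search
  sq_cost <- function(m, proto) trecon:::.cpp_dtw(m, proto, 0L, -1)
  obj_const <- vapply(seq(2, 4, 0.1), function(v) {
    proto <- matrix(v, 1, 3)
    sq_cost(a, proto) + sq_cost(b, proto)
  }, 0)
  expect_lte(attr(cen2, "objective"), min(obj_const) + 1e-12)
  expect_error(dba_centroid(list()), "empty")
})

test_that("DBA objective is non-increasing across iterations", {
  set.seed(404)
  for (rep in 1:10) {
    members <- random_series_set(sample(3:8, 1), d = 4, c(4, 10))
    cen <- dba_centroid(members, dtw_params(0.2), max_iter = 15)
    trace <- attr(cen, "objective_trace")
    expect_true(all(diff(trace) <= 1e-9))
  }
})
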