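test_that("fractions convert to absolute counts and are range-checked", {
  expect_equal(absolute_counts(0, 1500), 0)
  expect_equal(absolute_counts(1, 1500), 1500)
  expect_equal(absolute_counts(0.2, 1500), 300)
  expect_error(absolute_counts(1.2, 1500), "\\[0, 1\\]")
  expect_error(absolute_counts(0.5, -10), "alc")
})

test_that("eligibility filter applies both rules and logs the violation", {
  m <- make_measurements(list(
    few    = c(30, 90),        # rule 1: fewer than three samples
    late   = c(50, 90, 180),   # rule 2: first sample after day 45
    ok     = c(30, 90, 180),
    both   = c(60, 200),       # violates both rules
    edge   = c(45, 100, 365),  # inclusive bounds: day 45 and 365 count
    beyond = c(30, 40, 400)))  # third sample outside the horizon
  flt <- filter_eligible(m)
  kept <- sort(unique(flt$eligible$patient_id))
  expect_identical(kept, c("edge", "ok"))
  rules <- setNames(flt$exclusions$rule, flt$exclusions$patient_id)
  expect_identical(rules[["few"]], "too_few_samples")
  expect_identical(rules[["late"]], "first_sample_late")
  expect_identical(rules[["both"]], "too_few_samples;first_sample_late")
  expect_identical(rules[["beyond"]], "too_few_samples")
})

test_that("eligibility filter is idempotent and warns on empty input", {
  m <- make_measurements(list(ok = c(30, 90, 180), few = c(30, 90)))
  once <- filter_eligible(m)
  twice <- filter_eligible(once$eligible)
  expect_identical(sort(unique(twice$eligible$patient_id)),
                   sort(unique(once$eligible$patient_id)))
  expect_equal(nrow(twice$exclusions), 0)
  expect_warning(filter_eligible(m[0, ]), "nothing to filter")
})

make_series <- function(days, values) {
  structure(list(patient_id = "p", cohort = "A", days = days,
                 counts = matrix(values, nrow = 1,
                                 dimnames = list("s1", days))),
            class = "patient_series")
}

test_that("linear interpolation reproduces knots and interior points", {
  ser <- make_series(c(30, 90), c(100, 200))
  reg <- interpolate_linear(ser, grid_step = 5)
  expect_equal(unname(reg$values[1, reg$grid == 60]), 150) # midpoint
  expect_equal(unname(reg$values[1, reg$grid == 30]), 100) # knot
  # support-clipped: no extrapolation beyond observed days
  expect_true(all(reg$grid >= 30 & reg$grid <= 90))

  ser3 <- make_series(c(30, 90, 180), c(100, 200, 50))
  reg3 <- interpolate_linear(ser3, grid_step = 5)
  expect_equal(unname(reg3$values[1, reg3$grid == 135]),
               200 + (50 - 200) * 45 / 90) # 125
  # linearity: every grid value within its bracketing observations
  for (g in seq_along(reg3$grid)) {
    d <- reg3$grid[g]
    lo <- max(ser3$days[ser3$days <= d]); hi <- min(ser3$days[ser3$days >= d])
    vals <- ser3$counts[1, as.character(unique(c(lo, hi)))]
    expect_gte(reg3$values[1, g], min(vals) - 1e-12)
    expect_lte(reg3$values[1, g], max(vals) + 1e-12)
  }
  expect_error(interpolate_linear(make_series(30, 100)), "single")
})

test_that("smoothed interpolation preserves knots and clamps overshoot", {
  ser <- make_series(c(30, 90, 180), c(100, 200, 50))
  sm <- interpolate_smooth(ser, grid_step = 5)
  # knots reproduced exactly at full smoothing
  expect_equal(unname(sm$values[1, sm$grid %in% c(30, 90, 180)]),
               c(100, 200, 50))
  # smoothing -> 0 converges to the linear interpolant
  lin <- interpolate_linear(ser, grid_step = 5)
  sm0 <- interpolate_smooth(ser, grid_step = 5, smoothing = 0)
  expect_equal(sm0$values, lin$values)
  # clamped overshoot: values stay within bracketing observations
  for (g in seq_along(sm$grid)) {
    d <- sm$grid[g]
    lo <- max(ser$days[ser$days <= d]); hi <- min(ser$days[ser$days >= d])
    vals <- ser$counts[1, as.character(unique(c(lo, hi)))]
    expect_gte(sm$values[1, g], min(vals) - 1e-9)
    expect_lte(sm$values[1, g], max(vals) + 1e-9)
  }
  # constant series stays constant
  cst <- interpolate_smooth(make_series(c(30, 90, 180), c(70, 70, 70)),
                            grid_step = 7)
  expect_true(all(cst$values == 70))
})

test_that("series assembly collects eligible four-subset patients", {
  m <- make_measurements(list(a = c(30, 90, 180), b = c(30, 60, 120),
                              c = c(14, 90, 300)))
  panel <- subset_panel("custom", c("s1", "s2", "s3", "s4"))
  set <- assemble_model_matrix(m, panel)
  expect_s3_class(set, "series_set")
  expect_length(set, 3)
  expect_true(all(vapply(set, function(s) nrow(s$values), 0L) == 4))

  # a patient missing one panel subset is excluded with a logged reason
  m2 <- m[!(m$patient_id == "b" & m$subset == "s4"), ]
  set2 <- assemble_model_matrix(m2, panel)
  expect_length(set2, 2)
  excl <- attr(set2, "excluded")
  expect_identical(excl$patient_id, "b")
  expect_match(excl$reason, "missing_subset:s4")
})

test_that("dropout-free generator output assembles completely", {
  cfg <- generator_config(n_per_cohort = c(A = 12), dropout_prob = 0,
                          hazards = cbind(relapse = c(0, 0),
                                          nrm = c(0, 0)),
                          jitter_sd = 0, seed = 31)
  sim <- generate_cohort(cfg)
  flt <- filter_eligible(sim$measurements)
  set <- assemble_model_matrix(flt$eligible,
                               subset_panel("gvhd_associated"))
  expect_length(set, 12)
})

test_that("interpolation is exact on noise-free logistic trajectories", {
  # dense noise-free sampling: linear interpolation error is tiny
  cfg <- generator_config(
    n_per_cohort = c(A = 3), noise_cv = 0, jitter_sd = 0,
    dropout_prob = 0, hazards = cbind(relapse = c(0, 0), nrm = c(0, 0)),
    sampling_days = seq(14, 365, by = 7), seed = 8)
  sim <- generate_cohort(cfg)
  set <- assemble_model_matrix(sim$measurements,
                               subset_panel("gvhd_associated"))
  truth <- sim$truth
  for (s in set) {
    cl <- truth$true_cluster[truth$patient_id == s$patient_id]
    pars <- cfg$subset_params[cfg$subset_params$cluster == cl, ]
    for (sub in seq_len(4)) {
      p <- pars[pars$subset == rownames(s$values)[sub], ]
      mu <- trajectory_mean(s$grid, p$asymptote, p$rate, p$midpoint)
      expect_equal(unname(s$values[sub, ]), mu, tolerance = 1e-3)
    }
  }
})
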