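test_that("Kaplan-Meier estimate matches hand products and the ECDF", {
  # all censored: survival stays at 1
  km0 <- km_estimate(c(10, 20, 30), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_equal(curve_at(km0, 365), 1)
  # no censoring: complement of the empirical CDF
  tt <- c(5, 10, 15, 20)
  km1 <- km_estimate(tt, rep(1, 4))
  expect_equal(curve_at(km1, c(4, 5, 12, 20)), c(1, 0.75, 0.5, 0))
  # mixed: times 1+, 2, 3+, 4 -> S = 2/3 after t=2, 0 after t=4
  km2 <- km_estimate(1:4, c(0, 1, 0, 1))
  expect_equal(curve_at(km2, 2), 2 / 3)
  expect_equal(curve_at(km2, 3.5), 2 / 3)
  expect_equal(curve_at(km2, 4), 0)
  expect_error(km_estimate(c(-1, 3), c(1, 1)), "positive")
})

test_that("log-rank test vanishes on duplicated groups", {
  tt <- c(5, 8, 12, 20, 33, 40)
  ev <- c(1, 0, 1, 1, 0, 1)
  res <- logrank_test(c(tt, tt), c(ev, ev), rep(1:2, each = 6))
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$df, 1)
  expect_gt(res$p_value, 0.99)
  expect_error(logrank_test(tt, ev, rep(1, 6)), "two non-empty groups")
})

test_that("asymptotic and permutation log-rank p agree within MC error", {
  set.seed(71)
  n <- 100
  g <- rep(1:2, each = n / 2)
  tt <- ceiling(rexp(n, ifelse(g == 1, 1 / 150, 1 / 220)))
  ev <- as.integer(tt < 365); tt <- pmin(tt, 365)
  asym <- logrank_test(tt, ev, g)
  perm <- logrank_test(tt, ev, g, p_method = "permutation",
                       n_perm = 2000, seed = 14)
  mc_se <- sqrt(perm$p_value * (1 - perm$p_value) / 2000)
  expect_lt(abs(asym$p_value - perm$p_value), 3 * mc_se + 0.01)
})

test_that("Aalen-Johansen estimates conserve probability exactly", {
  set.seed(81)
  n <- 120
  tt <- ceiling(rexp(n, 1 / 180))
  type <- ifelse(tt >= 365, "censored",
                 sample(c("relapse", "nrm"), n, replace = TRUE))
  tt <- pmin(tt, 365)
  cif <- cif_estimate(tt, type)
  total <- cif$relapse$est + cif$nrm$est + cif$overall_surv$surv
  expect_equal(total, rep(1, length(total)), tolerance = 1e-12)
  # both CIFs are monotone non-decreasing step functions from 0
  expect_true(all(diff(cif$relapse$est) >= -1e-12))
  expect_true(all(diff(cif$nrm$est) >= -1e-12))
  expect_error(cif_estimate(tt, replace(type, 1, "unknown")), "unknown")
})

test_that("single-cause incidence reduces to one minus Kaplan-Meier", {
  tt <- c(3, 5, 8, 8, 12, 20, 30)
  ev <- c(1, 0, 1, 1, 0, 1, 0)
  cif <- cif_estimate(tt, ifelse(ev == 1, "relapse", "censored"))
  km <- km_estimate(tt, ev)
  probe <- c(2, 5, 8, 15, 30)
  expect_equal(curve_at(cif$relapse, probe), 1 - curve_at(km, probe))
  expect_true(all(cif$nrm$est == 0))
})

test_that("Aalen-Johansen matches cmprsk::cuminc point estimates", {
  set.seed(91)
  n <- 80
  tt <- ceiling(rexp(n, 1 / 150))
  type <- ifelse(tt >= 300, "censored",
                 sample(c("relapse", "nrm"), n, replace = TRUE,
                        prob = c(0.6, 0.4)))
  tt <- pmin(tt, 300)
  cif <- cif_estimate(tt, type)
  code <- match(type, c("censored", "relapse", "nrm")) - 1L
  ref <- cmprsk::cuminc(tt, code, cencode = 0)
  probe <- c(50, 100, 200, 299)
  ref_rel <- cmprsk::timepoints(ref, probe)$est["1 1", ]
  expect_equal(unname(curve_at(cif$relapse, probe)), unname(ref_rel),
               tolerance = 1e-10)
})

test_that("CIF on competing exponentials matches the closed form", {
  set.seed(1001)
  n <- 5000
  l_rel <- 2e-3; l_nrm <- 1e-3; l_tot <- l_rel + l_nrm
  t_rel <- rexp(n, l_rel); t_nrm <- rexp(n, l_nrm)
  tt <- pmin(t_rel, t_nrm, 365)
  type <- ifelse(tt >= 365, "censored",
                 ifelse(t_rel <= t_nrm, "relapse", "nrm"))
  cif <- cif_estimate(tt, type)
  for (t0 in c(90, 180, 300)) {
    f_true <- l_rel / l_tot * (1 - exp(-l_tot * t0))
    mc_se <- sqrt(f_true * (1 - f_true) / n)
    expect_lt(abs(curve_at(cif$relapse, t0) - f_true), 3 * mc_se)
  }
})

test_that("Gray's test vanishes on duplicated groups and checks causes", {
  tt <- c(30, 60, 90, 150, 250, 365)
  type <- c("relapse", "nrm", "censored", "relapse", "nrm", "censored")
  res <- gray_test(c(tt, tt), c(type, type), rep(1:2, each = 6),
                   cause = "relapse")
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.99)
  expect_error(
    gray_test(tt, rep("censored", 6), rep(1:2, each = 3), "relapse"),
    "absent")
})

test_that("asymptotic and permutation Gray p agree within MC error", {
  set.seed(111)
  n <- 100
  g <- rep(1:2, each = n / 2)
  t_rel <- rexp(n, ifelse(g == 1, 1.2e-3, 2.5e-3))
  t_nrm <- rexp(n, 1e-3)
  tt <- ceiling(pmin(t_rel, t_nrm, 365))
  type <- ifelse(pmin(t_rel, t_nrm) >= 365, "censored",
                 ifelse(t_rel <= t_nrm, "relapse", "nrm"))
  asym <- gray_test(tt, type, g, "relapse")
  perm <- gray_test(tt, type, g, "relapse", p_method = "permutation",
                    n_perm = 2000, seed = 15)
  mc_se <- sqrt(perm$p_value * (1 - perm$p_value) / 2000)
  expect_lt(abs(asym$p_value - perm$p_value), 3 * mc_se + 0.01)
})

test_that("cluster-outcome association assembles all three analyses", {
  set.seed(121)
  cohort <- generate_cohort(generator_config(n_per_cohort = c(A = 60),
                                             seed = 17))
  labels <- setNames(cohort$truth$true_cluster,
                     cohort$truth$patient_id)
  rep <- associate_clusters_outcomes(labels, cohort$outcomes)
  expect_s3_class(rep, "outcome_report")
  expect_named(rep$os$curves, c("1", "2"))
  expect_equal(rep$os$test$df, 1)
  expect_true(!is.null(rep$relapse$test))
  expect_true(all(vapply(rep$relapse$curves, inherits, TRUE,
                         "cif_curve")))
  # missing outcome records: warn, then proceed on complete cases
  oc_partial <- cohort$outcomes[-(1:3), ]
  expect_warning(rep2 <- associate_clusters_outcomes(labels, oc_partial),
                 "complete cases")
  expect_equal(rep2$n, 57)
  expect_length(rep2$missing_ids, 3)
  # a single cluster cannot be compared
  one <- labels; one[] <- 1L
  expect_error(associate_clusters_outcomes(one, cohort$outcomes),
               "two clusters")
})
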