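#' Expected subset count along a logistic recovery curve
#'
#' Immune reconstitution after transplant is emulated as logistic recovery
#' towards a plateau: the expected absolute count at day `t` is
#' `A / (1 + exp(-r * (t - m)))`, where `A` is the asymptotic count
#' (cells/uL), `r` the recovery rate (per day) and `m` the midpoint day at
#' which half the plateau is reached.
#'
#' @param t_days day(s) post-transplant, non-negative.
#' @param asymptote plateau count `A` in cells/uL, non-negative.
#' @param rate recovery rate `r` per day.
#' @param midpoint midpoint day `m`.
#' @return Expected count(s) in cells/uL, same length as `t_days`.
#' @examples
#' trajectory_mean(60, asymptote = 400, rate = 0.05, midpoint = 60) # A/2
#' @export
trajectory_mean <- function(t_days, asymptote, rate, midpoint) {
  if (any(t_days < 0)) stop("t_days must be non-negative")
  if (any(asymptote < 0)) stop("asymptote must be non-negative")
  asymptote / (1 + exp(-rate * (t_days - midpoint)))
}

#' Default logistic recovery parameters per latent cluster
#'
#' Two latent reconstitution phenotypes are emulated: cluster 1 recovers
#' slowly to low plateaus, cluster 2 recovers faster to plateaus about
#' 3-4x higher, mirroring the level-and-shape separation seen between
#' reconstitution clusters in transplant cohorts.
#'
#' @param panel which panel's subsets to parameterise: a [subset_panel()]
#'   name or `"both"` for the union of both predefined panels.
#' @return A data frame with columns `cluster`, `subset`, `asymptote`
#'   (cells/uL), `rate` (per day) and `midpoint` (days).
#' @export
default_subset_params <- function(panel = c("gvhd_associated",
                                            "broad_spectrum", "both")) {
  panel <- match.arg(panel)
  gvhd <- data.frame(
    subset = c("treg", "activated_t", "tcr_ab", "tcr_gd"),
    a1 = c(25, 120, 400, 30), a2 = c(80, 420, 1400, 100))
  broad <- data.frame(
    subset = c("cd4_helper", "cd4_naive", "cd8_cytotoxic", "cd8_memory"),
    a1 = c(150, 40, 250, 180), a2 = c(500, 140, 900, 650))
  tab <- switch(panel, gvhd_associated = gvhd, broad_spectrum = broad,
                both = rbind(gvhd, broad))
  rbind(
    data.frame(cluster = 1L, subset = tab$subset, asymptote = tab$a1,
               rate = 0.02, midpoint = 120),
    data.frame(cluster = 2L, subset = tab$subset, asymptote = tab$a2,
               rate = 0.035, midpoint = 75))
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic-data generator:
#' cohort sizes, latent cluster mixture, per-cluster logistic recovery
#' parameters, measurement noise, the sparse visit schedule, dropout,
#' cause-specific outcome hazards, and the administrative censoring
#' horizon.
#'
#' @param n_per_cohort named integer vector: patients per cohort label.
#' @param cluster_proportions probability vector over latent clusters;
#'   must sum to 1.
#' @param subset_params data frame with columns `cluster`, `subset`,
#'   `asymptote`, `rate`, `midpoint`; see [default_subset_params()].
#' @param noise_cv lognormal coefficient of variation of multiplicative
#'   measurement noise, >= 0.
#' @param sampling_days nominal visit days post-transplant.
#' @param jitter_sd standard deviation (days) of Gaussian jitter around
#'   nominal visit days; jittered days are truncated to
#'   `[14, censor_day]` and duplicate days are re-drawn.
#' @param dropout_prob per-visit missingness probability in `[0, 1)`.
#' @param hazards matrix (clusters x 2, columns `relapse`, `nrm`) of
#'   cause-specific exponential rates per day.
#' @param post_relapse_hazard per-cluster exponential death rate per day
#'   after relapse (0 = relapse non-fatal for overall survival).
#' @param censor_day administrative censoring horizon in days.
#' @param cmv_prevalence per-cluster probability of CMV R+ serostatus.
#' @param background_alc median non-panel lymphocyte count (cells/uL)
#'   added when composing the absolute lymphocyte count.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_per_cohort = c(MUD_ATG = 150),
                             cluster_proportions = c(0.65, 0.35),
                             subset_params = default_subset_params(),
                             noise_cv = 0.25,
                             sampling_days = c(30, 90, 180, 270, 365),
                             jitter_sd = 10,
                             dropout_prob = 0.1,
                             hazards = default_hazards(),
                             post_relapse_hazard = c(0, 0),
                             censor_day = 365,
                             cmv_prevalence = c(0.4, 0.75),
                             background_alc = 600,
                             seed = 1L) {
  k <- length(cluster_proportions)
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must sum to 1")
  if (any(cluster_proportions < 0)) stop("cluster_proportions must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (any(n_per_cohort < 1)) stop("n_per_cohort must be positive")
  if (is.null(names(n_per_cohort)))
    names(n_per_cohort) <- paste0("cohort", seq_along(n_per_cohort))
  req <- c("cluster", "subset", "asymptote", "rate", "midpoint")
  if (!all(req %in% names(subset_params)))
    stop("subset_params must have columns ", paste(req, collapse = ", "))
  if (any(subset_params$asymptote < 0)) stop("asymptotes must be >= 0")
  if (!setequal(unique(subset_params$cluster), seq_len(k)))
    stop("subset_params must parameterise clusters 1..", k)
  hazards <- as.matrix(hazards)
  if (nrow(hazards) != k || !all(c("relapse", "nrm") %in% colnames(hazards)))
    stop("hazards must be a clusters x {relapse, nrm} matrix")
  if (any(hazards < 0)) stop("hazards must be >= 0")
  if (length(post_relapse_hazard) != k || any(post_relapse_hazard < 0))
    stop("post_relapse_hazard must be a non-negative rate per cluster")
  if (length(cmv_prevalence) != k ||
      any(cmv_prevalence < 0 | cmv_prevalence > 1))
    stop("cmv_prevalence must be a probability per cluster")
  if (censor_day <= max(14, min(sampling_days)))
    stop("censor_day too small for the sampling schedule")
  structure(list(
    n_per_cohort = n_per_cohort,
    cluster_proportions = cluster_proportions,
    subset_params = subset_params,
    noise_cv = noise_cv,
    sampling_days = sort(sampling_days),
    jitter_sd = jitter_sd,
    dropout_prob = dropout_prob,
    hazards = hazards,
    post_relapse_hazard = post_relapse_hazard,
    censor_day = censor_day,
    cmv_prevalence = cmv_prevalence,
    background_alc = background_alc,
    seed = as.integer(seed)), class = "generator_config")
}

#' Default cause-specific outcome hazards
#'
#' Cluster 1 (poor reconstitution) carries roughly 25%/year relapse and
#' 23%/year non-relapse mortality; cluster 2 (robust reconstitution)
#' roughly 7%/year and 2%/year, echoing the survival separation between
#' reconstitution phenotypes.
#'
#' @return clusters x 2 matrix of exponential rates per day.
#' @export
default_hazards <- function() {
  cbind(relapse = c(8e-4, 2e-4), nrm = c(7e-4, 6e-5))
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cohort with known latent structure
#'
#' Draws, for each patient, a latent reconstitution cluster, a jittered
#' sparse visit schedule with per-visit dropout, noisy absolute subset
#' counts along the cluster's logistic recovery curves, and a competing-
#' risks outcome (independent exponential relapse and NRM times, first
#' event wins, administrative censoring at the horizon). Measurements are
#' emitted in the long format consumed by the pipeline (fractions of the
#' absolute lymphocyte count), and visits after death are dropped, as in
#' real longitudinal monitoring.
#'
#' @param config a [generator_config()].
#' @return A list with components
#'   \describe{
#'     \item{measurements}{long data frame: `patient_id`, `cohort`,
#'       `day`, `subset`, `fraction`, `alc`.}
#'     \item{outcomes}{data frame: `patient_id`, `time_days`, `event`
#'       (censored/relapse/nrm), `os_time_days`, `os_event`.}
#'     \item{truth}{latent ground truth: `patient_id`, `true_cluster`,
#'       `cohort`, `cmv_status`.}
#'   }
#' @examples
#' cfg <- generator_config(n_per_cohort = c(TEST = 8), seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort$measurements)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  subsets <- unique(config$subset_params$subset)
  n_total <- sum(config$n_per_cohort)
  ids <- sprintf("P%04d", seq_len(n_total))
  cohorts <- rep(names(config$n_per_cohort), config$n_per_cohort)

  meas <- vector("list", n_total)
  out <- vector("list", n_total)
  truth <- vector("list", n_total)

  for (p in seq_len(n_total)) {
    cl <- sample.int(length(config$cluster_proportions), 1L,
                     prob = config$cluster_proportions)
    cmv <- if (stats::runif(1) < config$cmv_prevalence[cl]) "R+" else "R-"

    # outcome: competing exponentials, first event wins
    haz <- config$hazards[cl, ]
    t_rel <- if (haz["relapse"] > 0) stats::rexp(1, haz["relapse"]) else Inf
    t_nrm <- if (haz["nrm"] > 0) stats::rexp(1, haz["nrm"]) else Inf
    t_evt <- min(t_rel, t_nrm, config$censor_day)
    event <- if (t_evt >= config$censor_day) "censored"
             else if (t_rel <= t_nrm) "relapse" else "nrm"
    time_days <- ceiling(min(t_evt, config$censor_day))

    # overall survival: NRM is death; relapse may be followed by death
    os_time <- config$censor_day; os_event <- 0L
    if (event == "nrm") {
      os_time <- time_days; os_event <- 1L
    } else if (event == "relapse" && config$post_relapse_hazard[cl] > 0) {
      t_death <- t_rel + stats::rexp(1, config$post_relapse_hazard[cl])
      if (t_death < config$censor_day) {
        os_time <- ceiling(t_death); os_event <- 1L
      }
    }

    # jittered visit schedule, truncated, duplicates re-drawn
    days <- round(config$sampling_days +
                  stats::rnorm(length(config$sampling_days),
                               sd = config$jitter_sd))
    days <- pmin(pmax(days, 14), config$censor_day)
    for (tries in 1:20) {
      dup <- duplicated(days)
      if (!any(dup)) break
      days[dup] <- pmin(pmax(round(config$sampling_days[dup] +
        stats::rnorm(sum(dup), sd = config$jitter_sd)), 14),
        config$censor_day)
    }
    days <- sort(unique(days))
    if (config$dropout_prob > 0)
      days <- days[stats::runif(length(days)) >= config$dropout_prob]
    if (os_event == 1L) days <- days[days <= os_time]

    if (length(days) > 0) {
      pars <- config$subset_params[config$subset_params$cluster == cl, ]
      pars <- pars[match(subsets, pars$subset), ]
      counts <- sapply(seq_along(subsets), function(s) {
        mu <- trajectory_mean(days, pars$asymptote[s], pars$rate[s],
                              pars$midpoint[s])
        mu * rlnorm_cv(length(days), config$noise_cv)
      })
      counts <- matrix(counts, nrow = length(days))
      background <- config$background_alc *
        rlnorm_cv(length(days), max(config$noise_cv, 0.2))
      alc <- rowSums(counts) + background
      meas[[p]] <- data.frame(
        patient_id = ids[p], cohort = cohorts[p],
        day = rep(days, times = length(subsets)),
        subset = rep(subsets, each = length(days)),
        fraction = as.vector(counts) / rep(alc, times = length(subsets)),
        alc = rep(alc, times = length(subsets)))
    }
    out[[p]] <- data.frame(patient_id = ids[p], time_days = time_days,
                           event = event, os_time_days = os_time,
                           os_event = os_event)
    truth[[p]] <- data.frame(patient_id = ids[p], true_cluster = cl,
                             cohort = cohorts[p], cmv_status = cmv)
  }
  list(measurements = do.call(rbind, meas[!vapply(meas, is.null, TRUE)]),
       outcomes = do.call(rbind, out),
       truth = do.call(rbind, truth))
}
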