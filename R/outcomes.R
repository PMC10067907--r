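EVENT_LEVELS <- c("censored", "relapse", "nrm")

check_event_types <- function(event_types) {
  if (!all(event_types %in% EVENT_LEVELS))
    stop("unknown event code(s): ",
         paste(setdiff(unique(event_types), EVENT_LEVELS), collapse = ", "))
  factor(event_types, levels = EVENT_LEVELS)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function,
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`.
#'
#' @param times positive follow-up times in days.
#' @param event_indicators 1/TRUE = event (death), 0/FALSE = censored.
#' @return A `survival_curve`: list with `times` (distinct event/censor
#'   times), `surv` (the step function values), `n_risk`, `n_event`.
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' @export
km_estimate <- function(times, event_indicators) {
  if (any(times <= 0)) stop("times must be positive")
  fit <- survival::survfit(
    survival::Surv(times, as.integer(event_indicators)) ~ 1)
  structure(list(times = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "survival_curve")
}

#' Evaluate a survival curve (or CIF) step function at given times
#'
#' @param curve a `survival_curve` or one cause of a `cif_estimate`.
#' @param t times at which to evaluate.
#' @return Right-continuous step-function values; `S(0) = 1` (or
#'   `F(0) = 0` for a CIF) before the first event.
#' @export
curve_at <- function(curve, t) {
  start <- if (inherits(curve, "cif_curve")) 0 else 1
  vals <- c(start, curve$surv %||% curve$est)
  idx <- findInterval(t, curve$times) + 1L
  vals[idx]
}

#' Log-rank test for equality of survival across groups
#'
#' Standard observed-minus-expected chi-square statistic over the pooled
#' event times, with `df = groups - 1`. The permutation mode re-computes
#' the statistic under random group-label shuffles and reports the
#' Monte-Carlo p-value `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param times positive follow-up times.
#' @param events 1 = event, 0 = censored.
#' @param groups group label per subject (>= 2 non-empty groups).
#' @param p_method `"asymptotic"` (chi-square reference) or
#'   `"permutation"`.
#' @param n_perm number of permutations.
#' @param seed seed for the permutation draw.
#' @return List: `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(times, events, groups,
                         p_method = c("asymptotic", "permutation"),
                         n_perm = 5000, seed = 1) {
  p_method <- match.arg(p_method)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two non-empty groups")
  groups <- droplevels(groups)
  stat_fun <- function(g) {
    fit <- survival::survdiff(
      survival::Surv(times, as.integer(events)) ~ g)
    unname(fit$chisq)
  }
  stat <- stat_fun(groups)
  df <- nlevels(groups) - 1
  if (p_method == "asymptotic") {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm),
                   function(i) stat_fun(sample(groups)), 0)
    p <- (1 + sum(perm >= stat - 1e-12)) / (1 + n_perm)
  }
  list(statistic = stat, df = df, p_value = p, method = p_method)
}

#' Aalen-Johansen cumulative incidence of competing events
#'
#' Nonparametric cause-specific cumulative incidence,
#' `F_k(t) = sum over t_i <= t of S(t_i-) d_ki / n_i`, with `S` the
#' all-cause Kaplan-Meier estimator, for relapse and non-relapse
#' mortality treated as competing events. At every event time
#' `F_relapse + F_nrm + S = 1` (conservation).
#'
#' @param times positive follow-up times.
#' @param event_types `"censored"`, `"relapse"` or `"nrm"` per subject.
#' @return A `cif_estimate`: list with one `cif_curve` per cause
#'   (`times`, `est`) and `overall_surv`, the all-cause
#'   `survival_curve`.
#' @export
cif_estimate <- function(times, event_types) {
  if (any(times <= 0)) stop("times must be positive")
  status <- check_event_types(event_types)
  if (all(status == "censored")) { # degenerate: no events at all
    tu <- sort(unique(times))
    zero <- function(cause) structure(
      list(cause = cause, times = tu, est = rep(0, length(tu))),
      class = "cif_curve")
    n_risk <- vapply(tu, function(t) sum(times >= t), 0)
    return(structure(list(
      relapse = zero("relapse"), nrm = zero("nrm"),
      overall_surv = structure(list(times = tu,
                                    surv = rep(1, length(tu)),
                                    n_risk = n_risk,
                                    n_event = rep(0, length(tu))),
                               class = "survival_curve")),
      class = "cif_estimate"))
  }
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  states <- fit$states
  cifs <- lapply(EVENT_LEVELS[-1], function(cause) {
    j <- match(cause, states)
    est <- if (is.na(j)) rep(0, length(fit$time)) else fit$pstate[, j]
    structure(list(cause = cause, times = fit$time, est = est),
              class = "cif_curve")
  })
  names(cifs) <- EVENT_LEVELS[-1]
  s0 <- match("(s0)", states)
  overall <- structure(list(times = fit$time, surv = fit$pstate[, s0],
                            n_risk = fit$n.risk[, 1],
                            n_event = rowSums(fit$n.event[, -s0,
                                                          drop = FALSE])),
                       class = "survival_curve")
  structure(list(relapse = cifs$relapse, nrm = cifs$nrm,
                 overall_surv = overall), class = "cif_estimate")
}

gray_stat <- function(times, status_code, groups, cause_code) {
  fit <- cmprsk::cuminc(ftime = times, fstatus = status_code,
                        group = groups, cencode = 0)
  tests <- fit$Tests
  row <- match(cause_code, rownames(tests))
  c(stat = tests[row, "stat"], pv = tests[row, "pv"],
    df = tests[row, "df"])
}

#' Gray's test for equality of cumulative incidence functions
#'
#' K-sample test of the cause-specific subdistribution hazards (rho = 0
#' weighting), comparing the cumulative incidence of one cause across
#' groups in the presence of the competing cause. The permutation mode
#' shuffles group labels and reports a Monte-Carlo p-value.
#'
#' @param times positive follow-up times.
#' @param event_types `"censored"`, `"relapse"` or `"nrm"`.
#' @param groups group label per subject.
#' @param cause the cause compared, `"relapse"` or `"nrm"`.
#' @param p_method `"asymptotic"` or `"permutation"`.
#' @param n_perm,seed permutation settings.
#' @return List: `statistic`, `df`, `p_value`, `method`, `cause`.
#' @export
gray_test <- function(times, event_types, groups,
                      cause = c("relapse", "nrm"),
                      p_method = c("asymptotic", "permutation"),
                      n_perm = 5000, seed = 1) {
  cause <- match.arg(cause)
  p_method <- match.arg(p_method)
  status <- check_event_types(event_types)
  if (!any(status == cause)) stop("cause '", cause,
                                  "' absent from the data")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least two non-empty groups")
  status_code <- as.integer(status) - 1L # 0 censored, 1 relapse, 2 nrm
  cause_code <- match(cause, EVENT_LEVELS) - 1L
  obs <- gray_stat(times, status_code, groups, cause_code)
  df <- nlevels(groups) - 1
  if (p_method == "asymptotic") {
    p <- unname(obs["pv"])
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i)
      gray_stat(times, status_code, sample(groups), cause_code)["stat"], 0)
    p <- (1 + sum(perm >= obs["stat"] - 1e-12)) / (1 + n_perm)
  }
  list(statistic = unname(obs["stat"]), df = df, p_value = p,
       method = p_method, cause = cause)
}

#' Link patient clusters to clinical outcomes
#'
#' For a cluster assignment, compares overall survival across clusters
#' (per-cluster Kaplan-Meier plus log-rank test) and the cumulative
#' incidence of relapse and of non-relapse mortality (per-cluster
#' Aalen-Johansen estimates plus Gray's test, each cause treating the
#' other as competing). Patients without an outcome record are listed
#' and the analysis proceeds on the complete cases with a warning.
#'
#' @param result a `cluster_result`, or a named cluster label vector.
#' @param outcomes outcome data frame with `patient_id`, `time_days`,
#'   `event` and optionally `os_time_days`, `os_event` (without them,
#'   death is taken as the NRM event).
#' @param p_method passed to [logrank_test()] and [gray_test()].
#' @param n_perm,seed permutation settings.
#' @return List of class `outcome_report`: `os` (curves + log-rank),
#'   `relapse` and `nrm` (curves + Gray's test), `missing_ids`, `n`.
#' @export
associate_clusters_outcomes <- function(result, outcomes,
                                        p_method = "asymptotic",
                                        n_perm = 5000, seed = 1) {
  labels <- if (inherits(result, "cluster_result")) result$labels
            else result
  if (is.null(names(labels))) stop("cluster labels must be named")
  idx <- match(names(labels), outcomes$patient_id)
  missing_ids <- names(labels)[is.na(idx)]
  if (length(missing_ids) > 0)
    warning(length(missing_ids),
            " clustered patient(s) lack outcome records; ",
            "proceeding on complete cases")
  keep <- !is.na(idx)
  labels <- labels[keep]
  oc <- outcomes[idx[keep], ]
  if (length(unique(labels)) < 2)
    stop("outcome comparison needs at least two clusters")

  if (!("os_time_days" %in% names(oc))) {
    oc$os_time_days <- oc$time_days
    oc$os_event <- as.integer(oc$event == "nrm")
  }
  cl <- factor(labels)
  os_curves <- lapply(split(seq_len(nrow(oc)), cl), function(i)
    km_estimate(oc$os_time_days[i], oc$os_event[i]))
  os_test <- logrank_test(oc$os_time_days, oc$os_event, cl,
                          p_method = p_method, n_perm = n_perm,
                          seed = seed)
  cif_curves <- lapply(split(seq_len(nrow(oc)), cl), function(i)
    cif_estimate(oc$time_days[i], oc$event[i]))
  cmp <- lapply(c(relapse = "relapse", nrm = "nrm"), function(cause) {
    test <- if (any(oc$event == cause))
      gray_test(oc$time_days, oc$event, cl, cause = cause,
                p_method = p_method, n_perm = n_perm, seed = seed)
    else NULL
    list(curves = lapply(cif_curves, function(x) x[[cause]]),
         test = test)
  })
  structure(list(os = list(curves = os_curves, test = os_test),
                 relapse = cmp$relapse, nrm = cmp$nrm,
                 missing_ids = missing_ids, n = nrow(oc),
                 cluster_sizes = table(cl)),
            class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("Cluster-outcome association (n = ", x$n, ")\n", sep = "")
  fmt_p <- function(t) if (is.null(t)) "NA (cause absent)" else
    format.pval(t$p_value, digits = 3)
  cat("  OS log-rank p:      ", fmt_p(x$os$test), "\n")
  cat("  Gray's test relapse:", fmt_p(x$relapse$test), "\n")
  cat("  Gray's test NRM:    ", fmt_p(x$nrm$test), "\n")
  for (g in names(x$os$curves)) {
    s1y <- curve_at(x$os$curves[[g]], 365)
    cat("  cluster ", g, ": 1-year OS ",
        sprintf("%.1f%%", 100 * s1y), "\n", sep = "")
  }
  invisible(x)
}
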