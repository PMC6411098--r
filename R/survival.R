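#' Median-split score stratification
#'
#' Patients at or below the median score are labelled `low`, those strictly
#' above `high`. Ties at the median go to `low`; the split depends only on
#' score ranks, so any monotone transform of the scores yields the same
#' labels.
#'
#' @param scores numeric scores (names preserved).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (!length(obs) || length(unique(obs)) < 2)
    stop("all scores identical: median split undefined")
  m <- stats::median(obs)
  out <- factor(ifelse(scores <= m, "low", "high"), levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival curve for one group, plus the estimate at a queried horizon and
#' risk-set counts at regular landmarks (defaults mirror a risk table every
#' 2.5 years with a 5-year survival readout, for times in days).
#'
#' @param times follow-up times (days, >= 0).
#' @param events event indicators, 1 = death observed, 0 = censored.
#' @param horizon time at which the survival probability is reported.
#' @param landmarks times at which the number at risk is reported.
#' @return list with `time`, `surv` (the step function evaluated at each
#'   distinct observed time), `surv_at_horizon`, `n_risk_at_landmarks` and
#'   the underlying `survival::survfit` object (`fit`).
#' @export
km_estimate <- function(times, events, horizon = 5 * 365.25,
                        landmarks = seq(0, 10 * 365.25, by = 2.5 * 365.25)) {
  if (any(times < 0, na.rm = TRUE)) stop("negative survival time")
  if (length(times) != length(events)) stop("times and events must align")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  sf <- summary(fit, times = sort(unique(times)), extend = TRUE)
  at_h <- summary(fit, times = horizon, extend = TRUE)$surv
  at_l <- summary(fit, times = landmarks, extend = TRUE)$n.risk
  list(time = sf$time, surv = sf$surv,
       surv_at_horizon = at_h,
       n_risk_at_landmarks = stats::setNames(at_l, landmarks),
       fit = fit)
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time, observed minus expected
#' events in group 1 under hypergeometric margins; the statistic is the
#' squared standardized O - E sum, chi-square with 1 degree of freedom.
#'
#' @param times follow-up times.
#' @param events event indicators (1 = event).
#' @param groups two-level grouping.
#' @return list with `chisq`, `p`, `observed` and `expected` per group.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2)
    stop("`groups` must contain exactly two non-empty groups")
  if (sum(events) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, rho = 0)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Pan-cohort survival scan
#'
#' Per cohort: drop patients with missing survival, keep cohorts with
#' strictly more than `min_samples` remaining, median-split the score, run
#' the log-rank test and record 5-year survival per arm; BH across cohorts.
#'
#' @param scores named score vector (names = patient/sample ids).
#' @param survival_data data.frame with columns `time` and `event`, rownames
#'   = patient ids.
#' @param cohorts named cohort labels per patient.
#' @param min_samples cohorts with `n <= min_samples` patients (with
#'   survival) are excluded.
#' @param horizon horizon for the per-arm survival rate (default 5 years in
#'   days).
#' @return data.frame with `cohort`, `chisq`, `p`, `q`, `n`,
#'   `surv_low`, `surv_high`, `worse_arm`.
#' @export
survival_scan <- function(scores, survival_data, cohorts, min_samples = 40,
                          horizon = 5 * 365.25) {
  ids <- Reduce(intersect, list(names(scores), rownames(survival_data),
                                names(cohorts)))
  ok <- ids[!is.na(survival_data[ids, "time"]) &
              !is.na(survival_data[ids, "event"]) & !is.na(scores[ids])]
  rows <- list()
  for (co in unique(cohorts[ok])) {
    cid <- ok[cohorts[ok] == co]
    if (length(cid) <= min_samples) next
    grp <- median_split(scores[cid])
    tm <- survival_data[cid, "time"]; ev <- survival_data[cid, "event"]
    lr <- logrank_test(tm, ev, grp)
    s_low <- km_estimate(tm[grp == "low"], ev[grp == "low"],
                         horizon = horizon)$surv_at_horizon
    s_high <- km_estimate(tm[grp == "high"], ev[grp == "high"],
                          horizon = horizon)$surv_at_horizon
    rows[[co]] <- data.frame(cohort = co, chisq = lr$chisq, p = lr$p,
                             n = length(cid), surv_low = s_low,
                             surv_high = s_high,
                             worse_arm = if (s_high <= s_low) "high" else "low")
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(cohort = character(), chisq = numeric(), p = numeric(),
                      q = numeric(), n = integer(), surv_low = numeric(),
                      surv_high = numeric(), worse_arm = character()))
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  res[, c("cohort", "chisq", "p", "q", "n", "surv_low", "surv_high",
          "worse_arm")]
}
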