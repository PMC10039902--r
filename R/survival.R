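#' Kaplan-Meier product-limit estimate for one group
#'
#' `S(t)` is the product over event times up to `t` of `(1 - d_i / n_i)`;
#' censored subjects at an event time remain at risk for that event
#' (standard convention). Confidence intervals use the log transform,
#' clipped to \[0, 1\]; the standard error is Greenwood's.
#'
#' @param time positive follow-up times (months).
#' @param event 1 = event, 0 = censored.
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se`, `lower`, `upper` (one row per distinct
#'   observed time, right-continuous).
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("no records")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log", conf.int = 0.95)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv,
             se = fit$surv * fit$std.err,     # Greenwood SE on the S scale
             lower = pmax(ifelse(is.na(fit$lower), fit$surv, fit$lower), 0),
             upper = pmin(ifelse(is.na(fit$upper), fit$surv, fit$upper), 1))
}

#' Median survival time of a group
#'
#' Smallest observed time at which the Kaplan-Meier estimate drops to 0.5
#' or below; NA while the curve stays above 0.5.
#'
#' @inheritParams kmEstimate
#' @return numeric median survival (same units as `time`) or NA.
#' @export
medianSurvival <- function(time, event) {
  km <- kmEstimate(time, event)
  drop <- which(km$surv <= 0.5)
  if (!length(drop)) NA_real_ else km$time[drop[1]]
}

#' Log-rank comparison of survival across groups
#'
#' Standard log-rank statistic over pooled event times with
#' `df = groups - 1`. When no events are observed at all, the comparison is
#' undefined and the test returns p = 1 with `no_events = TRUE`.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group group labels (>= 2 groups).
#' @return list: `statistic`, `df`, `p`, `no_events`.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(time <= 0)) stop("times must be positive")
  if (sum(event) == 0) {
    warning("no events observed; log-rank undefined")
    return(list(statistic = 0, df = nlevels(group) - 1L, p = 1,
                no_events = TRUE))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       no_events = FALSE)
}
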