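#' Adjusted estimate container
#'
#' Wraps an adjusted count or ratio together with a validity status. The
#' inverse adjustment can produce out-of-range values when the supplied
#' sensitivity/specificity are inconsistent with the observed data (for
#' example a negative count when specificity is underestimated); such values
#' are flagged, never clamped, because they are a diagnostic that the
#' accuracy estimates are invalid for these data.
#'
#' Status is one of `"ok"`, `"below_zero"` (value < 0) or `"above_n"`
#' (value exceeds the applicable upper bound). `display` carries the
#' presentation value: counts are truncated toward zero, ratios rounded to
#' 2 decimals; the full-precision `value` is always retained.
#'
#' @param value Full-precision adjusted value.
#' @param bound Upper bound for an `ok` status (population size for counts),
#'   or `NULL` for ratios.
#' @param interval Optional numeric `c(lower, upper)` uncertainty interval.
#' @param type `"count"` or `"ratio"`, controls display rounding.
#' @return An object of class `adjusted_estimate`.
#' @keywords internal
adjusted_estimate <- function(value, bound = NULL, interval = NULL,
                              type = c("count", "ratio")) {
  type <- match.arg(type)
  # relative tolerance so exact-boundary round trips (T = 0 or T = N) are
  # not flagged for floating-point noise
  tol <- 1e-8 * max(1, if (is.null(bound)) abs(value) else abs(bound))
  status <- if (value < -tol) {
    "below_zero"
  } else if (!is.null(bound) && value > bound + tol) {
    "above_n"
  } else {
    "ok"
  }
  display <- switch(type, count = trunc(value), ratio = round(value, 2))
  structure(list(value = value, status = status, display = display,
                 interval = interval, bound = bound, type = type),
            class = "adjusted_estimate")
}

#' @export
print.adjusted_estimate <- function(x, ...) {
  lbl <- switch(x$type, count = "Adjusted count", ratio = "Adjusted ratio")
  cat(sprintf("%s: %s (full precision %.6g)\n", lbl,
              format(x$display, big.mark = ","), x$value))
  if (x$status != "ok") {
    cat(sprintf("  status: %s -- accuracy estimates look invalid for these data\n",
                x$status))
  }
  if (!is.null(x$interval)) {
    cat(sprintf("  interval: [%.6g, %.6g]\n", x$interval[1], x$interval[2]))
  }
  invisible(x)
}

#' Estimate the true number of events from an observed count
#'
#' Inverts the forward misclassification model. Given O events observed by a
#' linkage with sensitivity SE and specificity SP in a cohort of size N, the
#' estimated true count is
#' \deqn{\hat{T} = \frac{O - (1 - SP)\,N}{SE + SP - 1},}
#' i.e. the observed count minus the expected false positives, rescaled by
#' the identifiability denominator. This is the count analogue of the
#' Rogan-Gladen prevalence adjustment.
#'
#' Requires SE + SP > 1. Values outside \eqn{[0, N]} are returned unclamped
#' with a non-`"ok"` status (see [adjusted_estimate]).
#'
#' @param obs An [observed_cohort()].
#' @param acc A [linkage_accuracy()] with `sensitivity + specificity > 1`.
#' @return An `adjusted_estimate` of type count; `$value` is the
#'   full-precision estimate, `$display` its integer truncation.
#' @examples
#' # NSW prisoner cohort: 5,137 observed deaths among 85,203 inmates
#' adjust_events(observed_cohort(85203, 5137), linkage_accuracy(0.884, 0.997))
#' @export
adjust_events <- function(obs, acc) {
  stopifnot(inherits(obs, "observed_cohort"), inherits(acc, "linkage_accuracy"))
  assert_identifiable(acc)
  t_hat <- (obs$observed_events - (1 - acc$specificity) * obs$n) /
    (acc$sensitivity + acc$specificity - 1)
  adjusted_estimate(t_hat, bound = obs$n, type = "count")
}

#' Adjusted standardised mortality ratio
#'
#' The SMR is O / E where E is the expected number of events under
#' comparator-population rates. Only the numerator is affected by linkage
#' misclassification, so only the numerator is adjusted:
#' adjusted SMR = \eqn{\hat{T} / E}. E (and person-time) are never adjusted.
#'
#' @param outcome A [standardized_outcome()].
#' @param acc A [linkage_accuracy()].
#' @return A list of class `adjusted_smr` with elements `unadjusted` (O/E),
#'   `adjusted` (an `adjusted_estimate` ratio), `adjusted_events` (the
#'   `adjusted_estimate` count) and `expected_events`.
#' @examples
#' out <- standardized_outcome(observed_cohort(85203, 5137), 1323)
#' adjust_smr(out, linkage_accuracy(0.884, 0.997)) # SMR 3.9 -> 4.2
#' @export
adjust_smr <- function(outcome, acc) {
  stopifnot(inherits(outcome, "standardized_outcome"))
  events <- adjust_events(outcome$cohort, acc)
  unadj <- outcome$cohort$observed_events / outcome$expected_events
  adj <- adjusted_estimate(events$value / outcome$expected_events,
                           type = "ratio")
  adj$status <- events$status  # validity travels with the adjusted count
  structure(list(unadjusted = unadj, adjusted = adj,
                 adjusted_events = events,
                 expected_events = outcome$expected_events),
            class = "adjusted_smr")
}

#' @export
print.adjusted_smr <- function(x, ...) {
  cat(sprintf("SMR: unadjusted %.1f, adjusted %.1f", round(x$unadjusted, 1),
              round(x$adjusted$value, 1)))
  if (x$adjusted$status != "ok") cat(sprintf("  [status: %s]", x$adjusted$status))
  cat("\n")
  cat(sprintf("  adjusted events: %s (full precision %.6g)\n",
              format(x$adjusted_events$display, big.mark = ","),
              x$adjusted_events$value))
  invisible(x)
}

#' Adjusted relative risk across two exposure strata
#'
#' The unadjusted RR is the crude rate ratio
#' \eqn{(O_E/N_E) / (O_{NE}/N_{NE})}; the adjusted RR replaces each
#' observed count by its inverse-adjusted estimate
#' (\eqn{(\hat{T}_E/N_E) / (\hat{T}_{NE}/N_{NE})}). By default the same
#' accuracy applies to both strata (non-differential linkage error);
#' per-stratum accuracy is an explicit opt-in via `acc_non_exposed`.
#'
#' @param exposed,non_exposed [observed_cohort()] objects.
#' @param acc A [linkage_accuracy()] applied to the exposed stratum (and to
#'   both strata when `acc_non_exposed` is omitted).
#' @param acc_non_exposed Optional [linkage_accuracy()] for the non-exposed
#'   stratum, for differential-error what-if analyses.
#' @return A list of class `adjusted_rr` with elements `unadjusted`,
#'   `adjusted` (an `adjusted_estimate` ratio), and the per-stratum
#'   `adjusted_events_exposed` / `adjusted_events_non_exposed`. A warning is
#'   issued when either adjusted count has non-`"ok"` status.
#' @examples
#' # male prisoners, death by psychiatric-admission history
#' adjust_rr(observed_cohort(3919, 467), observed_cohort(72444, 4247),
#'           linkage_accuracy(0.884, 0.997)) # RR 2.03 -> 2.09
#' @export
adjust_rr <- function(exposed, non_exposed, acc, acc_non_exposed = NULL) {
  stopifnot(inherits(exposed, "observed_cohort"),
            inherits(non_exposed, "observed_cohort"))
  if (is.null(acc_non_exposed)) acc_non_exposed <- acc
  t_e <- adjust_events(exposed, acc)
  t_ne <- adjust_events(non_exposed, acc_non_exposed)
  if (t_ne$value <= 0) {
    stop("adjusted non-exposed events are ", signif(t_ne$value, 6),
         " (<= 0): adjusted RR undefined; check the accuracy estimates",
         call. = FALSE)
  }
  if (non_exposed$observed_events <= 0) {
    stop("observed non-exposed events are 0: unadjusted RR undefined",
         call. = FALSE)
  }
  if (t_e$status != "ok" || t_ne$status != "ok") {
    warning("out-of-range adjusted stratum count (status ", t_e$status, " / ",
            t_ne$status, "); the accuracy estimates look invalid for these data",
            call. = FALSE)
  }
  unadj <- (exposed$observed_events / exposed$n) /
    (non_exposed$observed_events / non_exposed$n)
  adj <- adjusted_estimate((t_e$value / exposed$n) / (t_ne$value / non_exposed$n),
                           type = "ratio")
  if (t_e$status != "ok") adj$status <- t_e$status
  structure(list(unadjusted = unadj, adjusted = adj,
                 adjusted_events_exposed = t_e,
                 adjusted_events_non_exposed = t_ne),
            class = "adjusted_rr")
}

#' @export
print.adjusted_rr <- function(x, ...) {
  cat(sprintf("Relative risk: unadjusted %.2f, adjusted %.2f",
              round(x$unadjusted, 2), x$adjusted$display))
  if (x$adjusted$status != "ok") cat(sprintf("  [status: %s]", x$adjusted$status))
  cat("\n")
  invisible(x)
}

#' Propagate validation-table uncertainty into an adjusted estimate
#'
#' The point adjustment treats sensitivity and specificity as known; this
#' parametric bootstrap propagates their estimation uncertainty from the
#' validation 2x2 table. Per replicate, TP* ~ Binomial(TP+FN, SE-hat) and
#' TN* ~ Binomial(TN+FP, SP-hat) are drawn, accuracy re-estimated, and the
#' adjustment recomputed; the interval is the percentile interval of the
#' replicate values. Replicates with SE* + SP* <= 1 are non-identifiable and
#' dropped (an error is raised if more than half are). The point estimate is
#' unchanged from [adjust_events()] / [adjust_rr()].
#'
#' Outcome-count sampling noise is *not* resampled: the interval reflects
#' accuracy uncertainty only, which dominates when the study cohort is large
#' relative to the validation sub-study.
#'
#' @param obs An [observed_cohort()] (interval on the adjusted count), or a
#'   list of two observed cohorts `list(exposed =, non_exposed =)` (interval
#'   on the adjusted RR, same resampled accuracy in both strata).
#' @param table The [validation_table()] the accuracy was estimated from.
#' @param replicates Number of bootstrap replicates (>= 100; default 10000).
#' @param seed Integer seed; required for reproducibility.
#' @param level Interval level (default 0.95).
#' @return An `adjusted_estimate` with `$interval`, plus attributes
#'   `replicates_used` and `replicates_dropped`.
#' @examples
#' tab <- validation_table(275, 23, 36, 7535)
#' propagate_accuracy_uncertainty(observed_cohort(85203, 5137), tab,
#'                                replicates = 1000, seed = 7)
#' @export
propagate_accuracy_uncertainty <- function(obs, table, replicates = 10000,
                                           seed = NULL, level = 0.95) {
  stopifnot(inherits(table, "validation_table"))
  if (replicates < 100) stop("need at least 100 replicates", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  acc <- estimate_accuracy(table)
  assert_identifiable(acc)

  strata <- if (inherits(obs, "observed_cohort")) {
    NULL
  } else if (is.list(obs) && inherits(obs$exposed, "observed_cohort") &&
             inherits(obs$non_exposed, "observed_cohort")) {
    obs
  } else {
    stop("obs must be an observed_cohort or list(exposed =, non_exposed =)",
         call. = FALSE)
  }

  if (!is.null(seed)) set.seed(seed)
  m_ev <- table$tp + table$fn
  m_ne <- table$tn + table$fp
  se_star <- stats::rbinom(replicates, m_ev, acc$sensitivity) / m_ev
  sp_star <- stats::rbinom(replicates, m_ne, acc$specificity) / m_ne
  keep <- se_star + sp_star > 1
  dropped <- sum(!keep)
  if (dropped > replicates / 2) {
    stop("more than 50% of bootstrap replicates were non-identifiable ",
         "(SE* + SP* <= 1): the validation table is too weak to propagate",
         call. = FALSE)
  }
  se_star <- se_star[keep]
  sp_star <- sp_star[keep]
  denom <- se_star + sp_star - 1

  inv <- function(o, n) (o - (1 - sp_star) * n) / denom
  if (is.null(strata)) {
    draws <- inv(obs$observed_events, obs$n)
    point <- adjust_events(obs, acc)
  } else {
    t_e <- inv(strata$exposed$observed_events, strata$exposed$n)
    t_ne <- inv(strata$non_exposed$observed_events, strata$non_exposed$n)
    ok <- t_ne > 0
    draws <- (t_e[ok] / strata$exposed$n) / (t_ne[ok] / strata$non_exposed$n)
    dropped <- dropped + sum(!ok)
    point <- adjust_rr(strata$exposed, strata$non_exposed, acc)$adjusted
    point <- adjusted_estimate(point$value, type = "ratio")
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE))
  out <- adjusted_estimate(point$value, bound = point$bound,
                           interval = ci, type = point$type)
  attr(out, "replicates_used") <- length(draws)
  attr(out, "replicates_dropped") <- dropped
  attr(out, "level") <- level
  out
}
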