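#' Cohort containers
#'
#' A *true cohort* holds the population size N and the actual (true) number
#' of events T; an *observed cohort* holds N and the number of events O
#' detected by record linkage. True event counts may be non-integer, so that
#' expected-value arithmetic (e.g. incidence times N) flows through the
#' forward model without rounding.
#'
#' @param n Population size (> 0).
#' @param true_events Actual number of events, in \eqn{[0, n]}; real-valued
#'   allowed.
#' @return An object of class `true_cohort` or `observed_cohort`.
#' @examples
#' true_cohort(5000, 500)
#' observed_cohort(85203, 5137)
#' @export
true_cohort <- function(n, true_events) {
  check_cohort(n, true_events, "true_events")
  structure(list(n = as.numeric(n), true_events = as.numeric(true_events)),
            class = "true_cohort")
}

#' @rdname true_cohort
#' @param observed_events Number of events detected by linkage, in
#'   \eqn{[0, n]}.
#' @export
observed_cohort <- function(n, observed_events) {
  check_cohort(n, observed_events, "observed_events")
  structure(list(n = as.numeric(n), observed_events = as.numeric(observed_events)),
            class = "observed_cohort")
}

check_cohort <- function(n, events, label) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("n must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(events) || length(events) != 1L || !is.finite(events)) {
    stop(label, " must be a single finite number", call. = FALSE)
  }
  if (events < 0 || events > n) {
    stop(label, " = ", events, " must lie in [0, n] with n = ", n,
         call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.true_cohort <- function(x, ...) {
  cat(sprintf("True cohort: n = %g, true events = %g (incidence %.4g)\n",
              x$n, x$true_events, x$true_events / x$n))
  invisible(x)
}

#' @export
print.observed_cohort <- function(x, ...) {
  cat(sprintf("Observed cohort: n = %g, observed events = %g (rate %.4g)\n",
              x$n, x$observed_events, x$observed_events / x$n))
  invisible(x)
}

#' Exposure scenario: exposed and non-exposed true cohorts
#'
#' Defines the truth underlying a two-group comparison: an exposed cohort
#' (size N_E, true events T_E) and a non-exposed cohort (N_NE, T_NE). The
#' true relative risk is the ratio of true incidences; the non-exposed
#' cohort must have at least one true event for it to be defined.
#'
#' @param exposed,non_exposed [true_cohort()] objects.
#' @return An object of class `exposure_scenario`.
#' @seealso [scenario_from_incidence()] for the common
#'   sizes-plus-incidences parameterisation.
#' @examples
#' exposure_scenario(true_cohort(5000, 500), true_cohort(5000, 250))
#' @export
exposure_scenario <- function(exposed, non_exposed) {
  stopifnot(inherits(exposed, "true_cohort"),
            inherits(non_exposed, "true_cohort"))
  if (non_exposed$true_events <= 0) {
    stop("non-exposed cohort must have true_events > 0 so the true RR is defined",
         call. = FALSE)
  }
  structure(list(exposed = exposed, non_exposed = non_exposed),
            class = "exposure_scenario")
}

#' @rdname exposure_scenario
#' @param n_exposed,n_non_exposed Cohort sizes.
#' @param incidence_exposed,incidence_non_exposed True incidences in
#'   \eqn{[0, 1]}; true event counts are incidence times size, kept
#'   real-valued.
#' @export
scenario_from_incidence <- function(n_exposed, n_non_exposed,
                                    incidence_exposed, incidence_non_exposed) {
  exposure_scenario(
    true_cohort(n_exposed, incidence_exposed * n_exposed),
    true_cohort(n_non_exposed, incidence_non_exposed * n_non_exposed))
}

#' True relative risk of an exposure scenario
#'
#' @param scenario An [exposure_scenario()].
#' @return The ratio of true incidences,
#'   \eqn{(T_E/N_E) / (T_{NE}/N_{NE})}.
#' @examples
#' true_rr(scenario_from_incidence(5000, 5000, 0.10, 0.05)) # 2
#' @export
true_rr <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  (scenario$exposed$true_events / scenario$exposed$n) /
    (scenario$non_exposed$true_events / scenario$non_exposed$n)
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat("Exposure scenario\n")
  cat(sprintf("  exposed:     n = %g, true events = %g (incidence %.4g)\n",
              x$exposed$n, x$exposed$true_events,
              x$exposed$true_events / x$exposed$n))
  cat(sprintf("  non-exposed: n = %g, true events = %g (incidence %.4g)\n",
              x$non_exposed$n, x$non_exposed$true_events,
              x$non_exposed$true_events / x$non_exposed$n))
  cat(sprintf("  true RR = %.4g\n", true_rr(x)))
  invisible(x)
}

#' Standardised outcome: observed cohort plus expected events
#'
#' Pairs an observed cohort with the number of events E expected under the
#' rates of a comparator population, the denominator of a standardised
#' mortality/morbidity ratio (SMR = O / E).
#'
#' @param cohort An [observed_cohort()].
#' @param expected_events Expected number of events E (> 0) from the
#'   comparator population; never adjusted by this package.
#' @return An object of class `standardized_outcome`.
#' @examples
#' standardized_outcome(observed_cohort(85203, 5137), 1323)
#' @export
standardized_outcome <- function(cohort, expected_events) {
  stopifnot(inherits(cohort, "observed_cohort"))
  if (!is.numeric(expected_events) || length(expected_events) != 1L ||
      !is.finite(expected_events) || expected_events <= 0) {
    stop("expected_events must be a single positive number", call. = FALSE)
  }
  structure(list(cohort = cohort, expected_events = as.numeric(expected_events)),
            class = "standardized_outcome")
}

#' @export
print.standardized_outcome <- function(x, ...) {
  cat(sprintf("Standardised outcome: O = %g, N = %g, E = %g (SMR %.2f)\n",
              x$cohort$observed_events, x$cohort$n, x$expected_events,
              x$cohort$observed_events / x$expected_events))
  invisible(x)
}
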