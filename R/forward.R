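#' Forward misclassification model: expected observed events
#'
#' Under non-differential linkage error, each of the T true events is
#' detected with probability SE and each of the N - T non-events is falsely
#' linked with probability 1 - SP, so the expected observed count is
#' \deqn{O = SE \cdot T + (1 - SP)(N - T).}
#' The value is kept real-valued; rounding is a reporting concern.
#'
#' @param cohort A [true_cohort()].
#' @param acc A [linkage_accuracy()].
#' @return Expected observed event count, a real number in \eqn{[0, N]}.
#' @examples
#' forward_observed_events(true_cohort(5000, 500),
#'                         linkage_accuracy(0.90, 0.95)) # 675
#' @export
forward_observed_events <- function(cohort, acc) {
  stopifnot(inherits(cohort, "true_cohort"), inherits(acc, "linkage_accuracy"))
  acc$sensitivity * cohort$true_events +
    (1 - acc$specificity) * (cohort$n - cohort$true_events)
}

#' Observed incidence under linkage misclassification
#'
#' The unit-normalised forward model: a true incidence p is observed as
#' \eqn{SE \cdot p + (1 - SP)(1 - p)}. Vectorised over `true_incidence`.
#'
#' @param true_incidence True incidence(s) in \eqn{[0, 1]}.
#' @param acc A [linkage_accuracy()].
#' @return Observed incidence(s), same length as `true_incidence`.
#' @examples
#' observed_incidence(0.10, linkage_accuracy(0.90, 0.95)) # 0.135
#' @export
observed_incidence <- function(true_incidence, acc) {
  stopifnot(inherits(acc, "linkage_accuracy"))
  if (any(!is.finite(true_incidence)) ||
      any(true_incidence < 0) || any(true_incidence > 1)) {
    stop("true_incidence must lie in [0, 1]", call. = FALSE)
  }
  acc$sensitivity * true_incidence +
    (1 - acc$specificity) * (1 - true_incidence)
}

#' Observed relative risk under linkage misclassification
#'
#' Applies the forward model per exposure stratum and forms the rate ratio
#' of observed incidences,
#' \eqn{(O_E/N_E) / (O_{NE}/N_{NE})}. With SE + SP > 1 and true RR above 1
#' the observed RR is attenuated toward the null; with perfect specificity
#' it equals the true RR exactly, whatever the sensitivity.
#'
#' @param scenario An [exposure_scenario()].
#' @param acc A [linkage_accuracy()].
#' @return Observed relative risk (> 0).
#' @examples
#' sc <- scenario_from_incidence(5000, 5000, 0.10, 0.05) # true RR 2
#' forward_observed_rr(sc, linkage_accuracy(0.90, 0.95)) # 1.459 ("1.46")
#' @export
forward_observed_rr <- function(scenario, acc) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  o_e <- forward_observed_events(scenario$exposed, acc)
  o_ne <- forward_observed_events(scenario$non_exposed, acc)
  if (o_ne <= 0) {
    stop("degenerate scenario: expected observed events in the non-exposed ",
         "stratum are 0; observed RR undefined", call. = FALSE)
  }
  (o_e / scenario$exposed$n) / (o_ne / scenario$non_exposed$n)
}
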