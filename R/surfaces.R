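#' Default sensitivity/specificity axis for bias surfaces
#'
#' 0.90 to 1.00 in steps of 0.01, with the extra points 0.995 and 0.999 so
#' that every accuracy value commonly quoted for high-quality linkages is on
#' the grid. Fully overridable.
#'
#' @return Sorted numeric vector of proportions.
#' @export
default_accuracy_axis <- function() {
  # round() keeps axis values exactly comparable to literals like 0.99
  sort(unique(round(c(seq(0.90, 1.00, by = 0.01), 0.995, 0.999), 3)))
}

check_axis <- function(axis, label) {
  if (length(axis) == 0 || any(!is.finite(axis)) ||
      any(axis <= 0) || any(axis > 1)) {
    stop(label, " must be a non-empty vector of proportions in (0, 1]",
         call. = FALSE)
  }
  sort(unique(axis))
}

surface_grid <- function(se_axis, sp_axis, value, value_name, scenario) {
  grid <- expand.grid(sensitivity = se_axis, specificity = sp_axis,
                      KEEP.OUT.ATTRS = FALSE)
  grid[[value_name]] <- value
  structure(grid, scenario = scenario,
            class = c("surface_grid", "data.frame"))
}

#' Observed-incidence bias surface
#'
#' Evaluates the forward model over a sensitivity-by-specificity grid for a
#' fixed true incidence, in long format (one row per SE/SP pair). These
#' surfaces make visible that observed incidence is far more distorted by
#' imperfect specificity than by imperfect sensitivity when the true
#' incidence is low: false positives accrue from the large event-free
#' majority.
#'
#' @param true_incidence True incidence in \eqn{[0, 1]}.
#' @param se_axis,sp_axis Grid axes, proportions in (0, 1]; defaults
#'   [default_accuracy_axis()].
#' @return A `surface_grid` data frame with columns `sensitivity`,
#'   `specificity`, `observed_incidence`.
#' @examples
#' head(incidence_surface(0.05))
#' @export
incidence_surface <- function(true_incidence,
                              se_axis = default_accuracy_axis(),
                              sp_axis = default_accuracy_axis()) {
  if (length(true_incidence) != 1L || !is.finite(true_incidence) ||
      true_incidence < 0 || true_incidence > 1) {
    stop("true_incidence must be a single value in [0, 1]", call. = FALSE)
  }
  se_axis <- check_axis(se_axis, "se_axis")
  sp_axis <- check_axis(sp_axis, "sp_axis")
  grid <- expand.grid(sensitivity = se_axis, specificity = sp_axis,
                      KEEP.OUT.ATTRS = FALSE)
  value <- grid$sensitivity * true_incidence +
    (1 - grid$specificity) * (1 - true_incidence)
  surface_grid(se_axis, sp_axis, value, "observed_incidence",
               scenario = list(true_incidence = true_incidence))
}

#' Observed-relative-risk bias surface
#'
#' Evaluates [forward_observed_rr()] for every SE/SP pair on the grid. For
#' any scenario with true RR > 1 and SE + SP > 1, every cell lies between 1
#' and the true RR (attenuation toward the null); the SP = 1 column
#' reproduces the true RR exactly.
#'
#' @param scenario An [exposure_scenario()].
#' @inheritParams incidence_surface
#' @return A `surface_grid` data frame with columns `sensitivity`,
#'   `specificity`, `observed_rr`.
#' @examples
#' sc <- scenario_from_incidence(5000, 5000, 0.10, 0.02) # true RR 5
#' head(rr_surface(sc))
#' @export
rr_surface <- function(scenario,
                       se_axis = default_accuracy_axis(),
                       sp_axis = default_accuracy_axis()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  se_axis <- check_axis(se_axis, "se_axis")
  sp_axis <- check_axis(sp_axis, "sp_axis")
  grid <- expand.grid(sensitivity = se_axis, specificity = sp_axis,
                      KEEP.OUT.ATTRS = FALSE)
  p_e <- scenario$exposed$true_events / scenario$exposed$n
  p_ne <- scenario$non_exposed$true_events / scenario$non_exposed$n
  obs_e <- grid$sensitivity * p_e + (1 - grid$specificity) * (1 - p_e)
  obs_ne <- grid$sensitivity * p_ne + (1 - grid$specificity) * (1 - p_ne)
  if (any(obs_ne <= 0)) {
    stop("degenerate scenario: observed non-exposed incidence is 0 for some ",
         "grid cells; observed RR undefined", call. = FALSE)
  }
  surface_grid(se_axis, sp_axis, obs_e / obs_ne, "observed_rr",
               scenario = scenario)
}

#' Percent attenuation between two relative risks
#'
#' Summarises how much an estimate drops between two accuracy settings:
#' \eqn{100 (RR_{high} - RR_{low}) / RR_{high}}, reported to 1 decimal.
#'
#' @param rr_high Reference (larger) RR, > 0.
#' @param rr_low Comparison RR.
#' @return Percent decrease, rounded to 1 decimal place.
#' @examples
#' attenuation_percent(4.81, 3.65) # 24.1
#' attenuation_percent(1.98, 1.83) # 7.6
#' @export
attenuation_percent <- function(rr_high, rr_low) {
  if (any(rr_high <= 0)) stop("rr_high must be > 0", call. = FALSE)
  round(100 * (rr_high - rr_low) / rr_high, 1)
}
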