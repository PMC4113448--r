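# Shared fixtures: the NSW prisoner linkage study and the standard
# worked scenarios (all counts as printed in the study tables).

prisoner_table <- function() validation_table(tp = 275, fp = 23, fn = 36, tn = 7535)
prisoner_accuracy <- function() linkage_accuracy(0.884, 0.997)
prisoner_cohort <- function() observed_cohort(85203, 5137)
prisoner_psych <- function() observed_cohort(3919, 467)
prisoner_no_psych <- function() observed_cohort(72444, 4247)

# population of 10,000 split evenly, true incidence 10% vs 5% (true RR 2)
worked_scenario <- function() scenario_from_incidence(5000, 5000, 0.10, 0.05)

# grid of valid identifiable accuracy pairs used by the property tests
accuracy_grid <- function() {
  grid <- expand.grid(se = c(0.55, 0.7, 0.85, 0.95, 0.99, 1.0),
                      sp = c(0.55, 0.7, 0.9, 0.99, 0.999, 1.0))
  grid[grid$se + grid$sp > 1, ]
}

write_counts_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
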