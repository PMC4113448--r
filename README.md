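# linkadjust

Tools for assessing and correcting the outcome-misclassification bias that
imperfect record linkage introduces into cohort studies.

When outcomes (deaths, cancers, admissions) are ascertained by
probabilistically linking a cohort to a registry, the linkage behaves like a
diagnostic test with sensitivity *SE* and specificity *SP*: some true events
are missed, some event-free subjects are falsely linked to an event. The
package is for epidemiologists and data-linkage units who want to quantify —
and, as a sensitivity analysis, correct — what those errors do to event
counts, incidence, standardised mortality ratios (SMR) and relative risks
(RR).

## The model

With `N` subjects of whom `T` truly have the event, non-differential linkage
error observes in expectation

```
O = SE · T + (1 − SP) · (N − T)
```

Inverting gives the adjusted (estimated true) count, the count analogue of
the Rogan–Gladen estimator, valid when SE + SP > 1:

```
T̂ = (O − (1 − SP) · N) / (SE + SP − 1)
```

Adjusted measures follow by substitution: adjusted SMR = T̂ / E (only the
numerator is adjusted; expected events E and person-time are untouched) and
adjusted RR = (T̂_E/N_E) / (T̂_NE/N_NE). Two structural consequences, both
enforced as property tests: non-differential error attenuates the RR toward
the null (observed RR lies between 1 and the true RR), and with SP = 1 the
observed RR equals the true RR exactly, whatever the sensitivity —
specificity is what protects ratio estimates, especially at low incidence.

The package provides the forward model (`forward_observed_events()`,
`observed_incidence()`, `forward_observed_rr()`), the inverse adjustment
(`adjust_events()`, `adjust_smr()`, `adjust_rr()`), accuracy estimation from
a gold-standard validation 2×2 table with exact confidence intervals
(`estimate_accuracy()`, `accuracy_ci()`), SE × SP bias surfaces
(`incidence_surface()`, `rr_surface()`, `attenuation_percent()`), a
Monte-Carlo oracle (`simulate_observed()`, `empirical_bias_report()`), a
parametric bootstrap propagating accuracy uncertainty
(`propagate_accuracy_uncertainty()`), and a command-line front end
(`inst/cli/linkadjust.R`).

## Worked example: a prisoner mortality linkage study

A cohort of 85,203 inmates was linked to a national death index; 5,137
deaths were observed against 1,323 expected. A validation sub-study of
7,869 subjects with known vital status gauges the linkage:

```r
library(linkadjust)

tab <- validation_table(tp = 275, fp = 23, fn = 36, tn = 7535)
tab
#> Validation 2x2 table (rows: linked, cols: true event)
#>       true event
#> linked yes   no
#>    yes 275   23
#>    no   36 7535
#>   sensitivity = 275/311 = 0.8842
#>   specificity = 7535/7558 = 0.9970
```

Adjusting the cohort's mortality with the reported accuracy (0.884, 0.997):

```r
acc <- linkage_accuracy(0.884, 0.997)   # or "88.4%", "99.7%"

adjust_smr(standardized_outcome(observed_cohort(85203, 5137), 1323), acc)
#> SMR: unadjusted 3.9, adjusted 4.2
#>   adjusted events: 5,540 (full precision 5540.74)

adjust_rr(observed_cohort(3919, 467), observed_cohort(72444, 4247), acc)
#> Relative risk: unadjusted 2.03, adjusted 2.09
```

The missed deaths outnumber the false-positive links, so both the SMR and
the psychiatric-admission RR were biased toward the null: the adjustment
moves them from 3.9 to 4.2 and from 2.03 to 2.09. A bootstrap over the
validation table shows how much the adjusted count depends on the accuracy
estimates themselves (here using the full-precision fractions 275/311 and
7535/7558, which give 5,535 rather than 5,540):

```r
propagate_accuracy_uncertainty(observed_cohort(85203, 5137), tab,
                               replicates = 10000, seed = 1)
#> Adjusted count: 5,535 (full precision 5535.3)
#>   interval: [5303.07, 5797.22]
```

Out-of-range adjusted values (negative counts, counts above N) are returned
unclamped with a `below_zero`/`above_n` status: they signal that the
supplied SE/SP are invalid for the data.

## Command line

```sh
Rscript inst/cli/linkadjust.R forward \
  --n-exposed=5000 --n-non-exposed=5000 \
  --incidence-exposed=0.10 --incidence-non-exposed=0.05 \
  --sensitivity=0.90 --specificity=0.95
#> {
#>   "observed_events_exposed": 675,
#>   "observed_events_non_exposed": 462.5,
#>   "observed_rr": 1.45945945945946,
#>   "true_rr": 2
#> }
```

Subcommands: `forward`, `adjust`, `validate`, `surface`, `simulate`; shared
flags `--sensitivity --specificity --validation-table --out --format --seed`.

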