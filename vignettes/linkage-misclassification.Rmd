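---
title: "Quantifying and correcting outcome misclassification from imperfect record linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting outcome misclassification from imperfect record linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkadjust)
```

## The problem

Cohort studies increasingly determine outcomes — deaths, cancers, hospital
admissions — by probabilistically linking the cohort to administrative
registries. No linkage is perfect: some true events are missed (false
negatives) and some event-free subjects are spuriously linked to an event
(false positives). Viewed as a diagnostic test for the outcome, the linkage
has a *sensitivity* SE (probability a true event is detected) and a
*specificity* SP (probability a non-event is left alone), and outcome
misclassification at those rates biases every downstream estimate: event
counts, incidence, standardised mortality ratios (SMR) and relative risks
(RR).

`linkadjust` implements the closed-form machinery for this problem: a
forward model predicting what a study will observe given the truth and the
linkage accuracy, the inverse adjustment recovering the estimated truth from
what was observed, accuracy estimation from a gold-standard validation 2×2
table, bias surfaces over SE × SP grids, a Monte-Carlo simulation oracle,
and a parametric bootstrap for the uncertainty the point adjustment ignores.

## The forward model

In a cohort of `N` subjects of whom `T` truly have the event, non-differential
linkage error observes, in expectation,

$$O = SE \cdot T + (1 - SP)(N - T),$$

the true events thinned by sensitivity plus false positives accrued from the
event-free remainder. On the incidence scale, a true incidence $p$ is
observed as $SE\,p + (1 - SP)(1 - p)$. Two structural facts follow directly
and are enforced as package invariants (and property tests):

* **Attenuation toward the null.** For two exposure strata with true RR
  $\ge 1$ and an informative linkage ($SE + SP > 1$), the observed rate
  ratio always lies between 1 and the true RR.
* **Perfect specificity is exact.** When $SP = 1$ the false-positive term
  vanishes and the sensitivity cancels from the rate ratio, so the observed
  RR equals the true RR *exactly*, whatever the sensitivity. Specificity,
  not sensitivity, is what protects ratio estimates — especially at low
  incidence, where the $(1-SP)(1-p)$ term dominates $SE\,p$.

```{r forward}
sc <- scenario_from_incidence(5000, 5000, 0.10, 0.05)  # true RR 2
acc <- linkage_accuracy(0.90, 0.95)
forward_observed_events(sc$exposed, acc)
forward_observed_rr(sc, acc)     # attenuated from 2 to ~1.46
forward_observed_rr(sc, linkage_accuracy(0.50, 1.0))  # SP = 1: exactly 2
```

Expected counts are kept real-valued throughout; chained computations would
otherwise accumulate rounding error, and integer presentation is purely a
reporting concern.

## The inverse adjustment

Real studies face the reverse question: `O` was observed, what was `T`?
Solving the forward equation gives

$$\hat{T} = \frac{O - (1 - SP)\,N}{SE + SP - 1},$$

the observed count minus the expected false positives, rescaled by the
informativeness of the linkage. This is the count analogue of the
Rogan–Gladen prevalence estimator. It requires $SE + SP > 1$
(identifiability: the denominator must be positive), checked at adjustment
time rather than at construction, because the forward model is well defined
without it.

Adjusted measures of effect follow by substitution: the adjusted SMR is
$\hat{T}/E$ (the expected count `E` comes from comparator-population rates
and is *not* affected by linkage error, so only the numerator is adjusted),
and the adjusted RR is the rate ratio of per-stratum adjusted counts.
Person-time denominators are likewise never adjusted; for uncommon events
the person-years at risk are only minimally distorted, and modelling that
distortion is out of scope here.

```{r inverse}
tab <- validation_table(tp = 275, fp = 23, fn = 36, tn = 7535)
estimate_accuracy(tab)

acc <- linkage_accuracy(0.884, 0.997)
adjust_smr(standardized_outcome(observed_cohort(85203, 5137), 1323), acc)
adjust_rr(observed_cohort(3919, 467), observed_cohort(72444, 4247), acc)
```

If the supplied SE/SP are inconsistent with the data — specificity
underestimated, say — the formula can produce a negative count or one
exceeding `N`. These are returned **unclamped** with a `below_zero` /
`above_n` status rather than silently truncated: an out-of-range adjustment
is a diagnostic that the accuracy estimates are invalid for these data, and
hiding it would defeat the method's purpose as a bias check. A relative
tolerance of $10^{-8}$ at the boundaries prevents floating-point noise from
flagging exact round trips ($T = 0$ or $T = N$).

Two reporting conventions are deliberate. Adjusted counts are *truncated*
toward zero for display (5540.74 → 5,540), with the full-precision value
always retained alongside. And when reproducing published numbers computed
from rounded accuracy values (0.884/0.997 rather than 275/311 and
7535/7558), the user chooses the precision by what they pass in; the package
never re-rounds inputs. The full-precision fractions give 5,535 rather than
5,540 for the prisoner cohort — a visible illustration of how sensitive the
adjustment is to the third decimal of specificity.

## Estimating accuracy from a validation table

Sensitivity and specificity are estimated from a sub-study with
gold-standard outcome status as the margin proportions TP/(TP+FN) and
TN/(TN+FP). Confidence intervals default to Clopper–Pearson exact binomial
intervals: validation sub-studies typically have small event margins
(a few hundred), where the exact interval's guaranteed nominal coverage is
worth its extra width; Wilson score intervals are available via
`method = "wilson"` for users who prefer shorter intervals. Verification
bias — non-random selection into the gold-standard sub-study — is not
modelled.

## Bias surfaces

`incidence_surface()` and `rr_surface()` tabulate the forward model over an
SE × SP grid in long format (one row per accuracy pair), ready for any
plotting tool. The default axis runs 0.90–1.00 in steps of 0.01 plus the
extra points 0.995 and 0.999, covering the accuracy range of realistic
high-quality linkages; it is a presentation choice, fully overridable. Axis
values are rounded to 3 decimals so grid lookups against literals like
`0.99` behave. `attenuation_percent()` summarises the drop between two
cells as a percent decrease to 1 decimal, applied to the values it is given
(so quoting rounded 2-dp RRs reproduces percent drops computed from rounded
values). Pixel-faithful reproduction of any published figure is a non-goal.

For the headline comparison: with exposed incidence 10% versus non-exposed
2% (true RR 5), holding SE at 0.99 and dropping SP from 0.999 to 0.99 moves
the observed RR from 4.81 to 3.65 — a 24.1% drop from a 0.9-point change in
specificity. The non-exposed incidence of 2% in that scenario is this
package's choice: it is the value that reproduces both quoted cells, though
it is not stated alongside them.

## The simulation oracle

`simulate_observed()` mechanises the generative reading of the 2×2 table:
each of `T` true events is detected with probability SE and each of `N − T`
non-events is falsely linked with probability 1 − SP, independently across
subjects — so observed counts are sums of two binomials. Every closed form
in the package is tested against this simulator: the forward expectation at
3 Monte-Carlo standard errors, the unbiasedness of the inverse adjustment
(a linear function of `O`, hence exactly unbiased under the binomial
model), and pooled TP/FP/FN/TN convergence to the configured accuracy.

Two design choices:

* Counts are drawn as two binomials rather than per-record Bernoulli loops,
  for speed; a `per_record` mode is retained for generating record-level
  validation-table fixtures.
* A master seed spawns one substream seed per replicate, so replicate *k*
  of a 10,000-replicate run is bit-identical to replicate *k* of a
  40-replicate run with the same master seed. Reproducibility of individual
  replicates in isolation is worth the negligible cost of re-seeding.

The simulator emulates *non-differential, independent* linkage error only.
It does not model the linkage algorithm itself (blocking, match weights,
clerical review), correlated errors within families or facilities, or
error rates that depend on exposure status. Passing tests therefore
validate the algebra under the stated error model, not the behaviour of
any real linkage engine; differential error can be explored through the
explicit per-stratum accuracy arguments, but the defaults assume it away,
as the adjustment formula does.

## Propagating accuracy uncertainty

The point adjustment treats SE and SP as known constants, yet they are
themselves estimates from a finite validation table.
`propagate_accuracy_uncertainty()` wraps the adjustment in a parametric
bootstrap: per replicate, TP\* ~ Binomial(TP+FN, $\widehat{SE}$) and
TN\* ~ Binomial(TN+FP, $\widehat{SP}$) are redrawn, accuracy re-estimated
and the adjustment recomputed; the percentile interval of the replicate
values (default 95%) is attached to the unchanged point estimate.
Replicates that land non-identifiable (SE\* + SP\* ≤ 1) are dropped and
counted, and the function refuses to report if more than half are — an
interval built on the identifiable half of a mostly non-identifiable
bootstrap would be misleading.

The interval deliberately propagates accuracy uncertainty only, not the
binomial noise of the observed count itself. That is the right trade-off
when the study cohort is much larger than the validation sub-study — the
regime this method targets — and the coverage test in the suite is designed
in exactly that regime: 800 simulated studies of N = 200,000 at 10% true
incidence (SE 0.90, SP 0.99) with a validation margin of 300 events and
3,000 non-events, where accuracy uncertainty contributes about 98% of the
variance of $\hat{T}$ and the percentile interval attains close to nominal
95% coverage. In the opposite regime (small cohort, huge validation study)
the interval will undercover, because the dominant noise source is the one
it does not model.

## Numerical and scale choices

* Test-suite problem sizes (10,000 Monte-Carlo replicates for oracle
  agreement, 800 × 2,000 for bootstrap coverage, 2,000 replicates for
  interval fixtures) keep every stochastic check at ≥ 3-standard-error
  resolution while the whole suite runs in seconds; they are stated here as
  the package's own verification scale.
* Accuracy inputs accept percent strings (`"88.4%"`) or proportions; bare
  numerics above 1 are rejected with a hint rather than guessed at.
* True incidences of exactly 0 or 1 are allowed in the forward model; only
  the inverse carries identifiability constraints.
* The two-strata CLI adjustment and `adjust_rr()` report the *crude* rate
  ratio $(O_E/N_E)/(O_{NE}/N_{NE})$, not a ratio of per-stratum SMRs — the
  two differ whenever the strata have different age structures, and the
  crude ratio is what the adjustment formula inverts.

## Known limitations

The adjustment is exact algebra on an approximate premise: errors must be
non-differential and independent across subjects, accuracy estimates must
transport from the validation sub-study to the full cohort, and person-time
is untouched. Regression-style corrections that use linkage weights
directly (useful when no gold-standard subsample exists) are a different
method family and are out of scope. Unadjusted results should remain the
primary presentation, with these adjustments reported as a quantitative
sensitivity analysis of the linkage.
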