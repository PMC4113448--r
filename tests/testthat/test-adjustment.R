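# Inverse adjustment: recovering true counts, adjusted SMR and adjusted RR.

test_that("adjustment is the exact algebraic inverse of the forward model", {
  grid <- accuracy_grid()
  set.seed(11)
  for (i in seq_len(nrow(grid))) {
    acc <- linkage_accuracy(grid$se[i], grid$sp[i])
    for (t in c(0, 1, runif(3, 0, 5000), 5000)) {
      o <- forward_observed_events(true_cohort(5000, t), acc)
      est <- adjust_events(observed_cohort(5000, o), acc)
      expect_equal(est$value, t, tolerance = 1e-10)
      expect_identical(est$status, "ok")
    }
  }
})

test_that("prisoner deaths adjust from 5,137 to 5,540 (truncated)", {
  est <- adjust_events(prisoner_cohort(), prisoner_accuracy())
  expect_equal(est$value, (5137 - 0.003 * 85203) / 0.881)
  expect_equal(est$display, 5540)
  expect_identical(est$status, "ok")
})

test_that("out-of-range adjusted counts are flagged, never clamped", {
  # observing zero events despite imperfect specificity implies T < 0
  est <- adjust_events(observed_cohort(1000, 0), linkage_accuracy(0.9, 0.99))
  expect_equal(est$value, (0 - 0.01 * 1000) / 0.89)
  expect_identical(est$status, "below_zero")
  # observing everything implies T > N under imperfect sensitivity
  est2 <- adjust_events(observed_cohort(1000, 1000), linkage_accuracy(0.8, 1.0))
  expect_gt(est2$value, 1000)
  expect_identical(est2$status, "above_n")
})

test_that("non-identifiable accuracy is refused by name", {
  expect_error(adjust_events(observed_cohort(100, 10),
                             linkage_accuracy(0.5, 0.5)),
               "non-identifiable")
  expect_false(is_identifiable(linkage_accuracy(0.5, 0.5)))
  expect_true(is_identifiable(linkage_accuracy(0.884, 0.997)))
})

test_that("SMR adjustment rescales only the numerator", {
  out <- standardized_outcome(prisoner_cohort(), 1323)
  smr <- adjust_smr(out, prisoner_accuracy())
  expect_equal(round(smr$unadjusted, 1), 3.9)
  expect_equal(round(smr$adjusted$value, 1), 4.2)
  # ratio of SMRs equals ratio of counts: E is untouched
  expect_equal(smr$adjusted$value / smr$unadjusted,
               smr$adjusted_events$value / 5137)
  # perfect linkage leaves the SMR unchanged; null SMR stays null
  perfect <- linkage_accuracy(1, 1)
  smr_p <- adjust_smr(out, perfect)
  expect_equal(smr_p$adjusted$value, smr_p$unadjusted)
  smr_null <- adjust_smr(standardized_outcome(observed_cohort(1e6, 50), 50),
                         perfect)
  expect_equal(smr_null$unadjusted, 1)
  expect_equal(smr_null$adjusted$value, 1)
})

test_that("RR adjustment reproduces the psychiatric-admission comparison", {
  rr <- adjust_rr(prisoner_psych(), prisoner_no_psych(), prisoner_accuracy())
  expect_equal(round(rr$unadjusted, 2), 2.03)
  expect_equal(round(rr$adjusted$value, 2), 2.09)
  expect_identical(rr$adjusted$status, "ok")
})

test_that("RR adjustment round-trips a forward-generated scenario to the true RR", {
  grid <- accuracy_grid()
  scenarios <- list(worked_scenario(),
                    scenario_from_incidence(2000, 8000, 0.02, 0.005))
  for (sc in scenarios) {
    for (i in seq_len(nrow(grid))) {
      acc <- linkage_accuracy(grid$se[i], grid$sp[i])
      exp_obs <- observed_cohort(sc$exposed$n,
                                 forward_observed_events(sc$exposed, acc))
      ne_obs <- observed_cohort(sc$non_exposed$n,
                                forward_observed_events(sc$non_exposed, acc))
      rr <- adjust_rr(exp_obs, ne_obs, acc)
      expect_equal(rr$adjusted$value, true_rr(sc), tolerance = 1e-10)
    }
  }
  # perfect linkage: adjusted equals unadjusted
  rr_p <- adjust_rr(prisoner_psych(), prisoner_no_psych(),
                    linkage_accuracy(1, 1))
  expect_equal(rr_p$adjusted$value, rr_p$unadjusted)
})

test_that("adjustment moves an attenuated RR away from the null", {
  grid <- accuracy_grid()
  imperfect <- grid[grid$sp < 1, ]
  for (i in seq_len(nrow(imperfect))) {
    acc <- linkage_accuracy(imperfect$se[i], imperfect$sp[i])
    exp_obs <- observed_cohort(5000,
                               forward_observed_events(worked_scenario()$exposed, acc))
    ne_obs <- observed_cohort(5000,
                              forward_observed_events(worked_scenario()$non_exposed, acc))
    rr <- adjust_rr(exp_obs, ne_obs, acc)
    expect_gt(rr$unadjusted, 1)
    expect_gt(rr$adjusted$value, rr$unadjusted)
  }
})

test_that("differential accuracy can be supplied per stratum", {
  acc_e <- linkage_accuracy(0.9, 0.99)
  acc_ne <- linkage_accuracy(0.95, 0.995)
  exp_obs <- observed_cohort(5000,
                             forward_observed_events(true_cohort(5000, 500), acc_e))
  ne_obs <- observed_cohort(5000,
                            forward_observed_events(true_cohort(5000, 250), acc_ne))
  rr <- adjust_rr(exp_obs, ne_obs, acc_e, acc_non_exposed = acc_ne)
  expect_equal(rr$adjusted$value, 2, tolerance = 1e-10)
  # using the exposed accuracy for both strata would not recover the truth
  rr_wrong <- adjust_rr(exp_obs, ne_obs, acc_e)
  expect_false(isTRUE(all.equal(rr_wrong$adjusted$value, 2)))
})

test_that("bootstrap interval brackets the point estimate and is reproducible", {
  tab <- prisoner_table()
  est <- propagate_accuracy_uncertainty(prisoner_cohort(), tab,
                                        replicates = 2000, seed = 7)
  expect_lte(est$interval[1], est$value)
  expect_gte(est$interval[2], est$value)
  # the rounded-accuracy point estimate also lies inside
  expect_lte(est$interval[1], 5540.74)
  expect_gte(est$interval[2], 5540.74)
  est2 <- propagate_accuracy_uncertainty(prisoner_cohort(), tab,
                                         replicates = 2000, seed = 7)
  expect_identical(est$interval, est2$interval)
  est3 <- propagate_accuracy_uncertainty(prisoner_cohort(), tab,
                                         replicates = 2000, seed = 8)
  expect_false(identical(est$interval, est3$interval))
})

test_that("a perfectly accurate validation table yields a zero-width interval", {
  tab <- validation_table(tp = 10, fp = 0, fn = 0, tn = 10)
  est <- propagate_accuracy_uncertainty(observed_cohort(1000, 100), tab,
                                        replicates = 500, seed = 3)
  expect_equal(est$interval[1], est$value)
  expect_equal(est$interval[2], est$value)
})

test_that("bootstrap intervals extend to two-stratum adjusted RRs", {
  strata <- list(exposed = prisoner_psych(), non_exposed = prisoner_no_psych())
  est <- propagate_accuracy_uncertainty(strata, prisoner_table(),
                                        replicates = 2000, seed = 21)
  point <- adjust_rr(prisoner_psych(), prisoner_no_psych(),
                     estimate_accuracy(prisoner_table()))
  expect_equal(est$value, point$adjusted$value)
  expect_lte(est$interval[1], est$value)
  expect_gte(est$interval[2], est$value)
})

test_that("a weak validation table fails the bootstrap loudly", {
  # point estimates non-identifiable: refused before any resampling
  weak <- validation_table(tp = 3, fp = 7, fn = 7, tn = 3)
  expect_error(propagate_accuracy_uncertainty(observed_cohort(100, 10), weak,
                                              replicates = 200, seed = 1),
               "non-identifiable")
  expect_error(propagate_accuracy_uncertainty(observed_cohort(100, 10),
                                              prisoner_table(),
                                              replicates = 10, seed = 1),
               "at least 100")
})
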