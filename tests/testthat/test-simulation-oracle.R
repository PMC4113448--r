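# Monte-Carlo generator: the independent check on every closed form.

test_that("degenerate accuracies simulate deterministically", {
  # no true events + perfect specificity: nothing is ever observed
  cfg0 <- simulation_config(true_cohort(2000, 0), linkage_accuracy(0.7, 1.0),
                            replicates = 50, seed = 5)
  expect_true(all(simulate_observed(cfg0)$observed_events == 0))
  # perfect linkage observes exactly T every time
  cfg1 <- simulation_config(true_cohort(2000, 321), linkage_accuracy(1, 1),
                            replicates = 50, seed = 5)
  expect_true(all(simulate_observed(cfg1)$observed_events == 321))
})

test_that("empirical mean observed count agrees with the closed form at 3 SEs", {
  acc <- linkage_accuracy(0.90, 0.95)
  cohort <- true_cohort(5000, 500)
  reps <- 10000
  cfg <- simulation_config(cohort, acc, replicates = reps, seed = 202)
  sims <- simulate_observed(cfg)
  analytic <- forward_observed_events(cohort, acc) # 675
  # analytic MC standard error of the mean from the two binomial components
  var_o <- 500 * 0.90 * 0.10 + 4500 * 0.05 * 0.95
  se_mean <- sqrt(var_o / reps)
  expect_lt(abs(mean(sims$observed_events) - analytic), 3 * se_mean)
})

test_that("fixed seed gives bit-identical streams; replicates reproduce in isolation", {
  cfg <- simulation_config(worked_scenario(), linkage_accuracy(0.9, 0.95),
                           replicates = 40, seed = 99)
  s1 <- simulate_observed(cfg)
  s2 <- simulate_observed(cfg)
  expect_identical(s1, s2)
  # the first k replicates are unchanged when more replicates are requested:
  # replicate-level substreams derive from the master seed
  cfg_longer <- simulation_config(worked_scenario(), linkage_accuracy(0.9, 0.95),
                                  replicates = 80, seed = 99)
  s3 <- simulate_observed(cfg_longer)
  expect_equal(as.data.frame(s3[s3$replicate <= 40, ]), as.data.frame(s1),
               ignore_attr = TRUE)
})

test_that("pooled simulated tables recover the configured accuracy", {
  acc <- linkage_accuracy(0.85, 0.98)
  cfg <- simulation_config(true_cohort(2000, 400), acc,
                           replicates = 4000, seed = 31)
  sims <- simulate_observed(cfg)
  se_hat <- sum(sims$tp) / sum(sims$tp + sims$fn)
  sp_hat <- sum(sims$tn) / sum(sims$tn + sims$fp)
  n_ev <- sum(sims$tp + sims$fn)
  n_ne <- sum(sims$tn + sims$fp)
  expect_lt(abs(se_hat - 0.85), 3 * sqrt(0.85 * 0.15 / n_ev))
  expect_lt(abs(sp_hat - 0.98), 3 * sqrt(0.98 * 0.02 / n_ne))
  # cells are a valid partition of each cohort
  expect_true(all(sims$tp + sims$fp + sims$fn + sims$tn == sims$n))
  expect_true(all(sims$tp + sims$fn == sims$true_events))
})

test_that("per-record mode draws valid tables and honours perfect accuracy", {
  cfg <- simulation_config(true_cohort(200, 40), linkage_accuracy(0.8, 0.9),
                           replicates = 30, seed = 12, per_record = TRUE)
  sims <- simulate_observed(cfg)
  expect_true(all(sims$tp <= 40 & sims$fn <= 40))
  expect_true(all(sims$tp + sims$fp + sims$fn + sims$tn == 200))
  cfg_perfect <- simulation_config(true_cohort(200, 40), linkage_accuracy(1, 1),
                                   replicates = 10, seed = 12, per_record = TRUE)
  expect_true(all(simulate_observed(cfg_perfect)$observed_events == 40))
})

test_that("bias report ties simulation to the analytic RR and the inverse adjustment", {
  acc <- linkage_accuracy(0.90, 0.95)
  cfg <- simulation_config(worked_scenario(), acc, replicates = 4000, seed = 77)
  rep <- empirical_bias_report(cfg)
  expect_equal(rep$rr$true_rr, 2)
  expect_equal(rep$rr$analytic_observed_rr, 675 / 462.5)
  # a ratio of independent counts carries a small positive finite-sample
  # (Jensen) bias of about RR * CV(O_ne)^2; allow for it analytically
  var_ne <- 250 * 0.9 * 0.1 + 4750 * 0.05 * 0.95
  jensen <- rep$rr$analytic_observed_rr * var_ne / 462.5^2
  expect_lt(abs(rep$rr$empirical_mean_observed_rr - rep$rr$analytic_observed_rr),
            3 * rep$rr$mc_se_observed_rr + jensen)
  # per-replicate inverse adjustment recovers the truth on average
  for (i in seq_len(nrow(rep$strata))) {
    se_adj <- rep$strata$mc_se_observed[i] / (0.90 + 0.95 - 1)
    expect_lt(abs(rep$strata$mean_recovery_error[i]), 3 * se_adj)
  }
  expect_identical(rep$rr$degenerate_replicates, 0L)
})

test_that("simulation configs validate their inputs", {
  expect_error(simulation_config(true_cohort(10, 5), linkage_accuracy(0.9, 0.9),
                                 replicates = 0, seed = 1),
               "positive integer")
  expect_error(simulation_config(list(), linkage_accuracy(0.9, 0.9),
                                 replicates = 10, seed = 1),
               "true_cohort")
  expect_error(simulation_config(true_cohort(10, 5), linkage_accuracy(0.9, 0.9),
                                 replicates = 10, seed = 1,
                                 accuracy_non_exposed = linkage_accuracy(0.9, 0.9)),
               "exposure scenario")
})
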