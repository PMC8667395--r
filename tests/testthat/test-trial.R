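test_that("dose decisions follow the inclusive boundary comparisons", {
  d <- design_bin02()
  expect_equal(decide(data.frame(dose = 1, n = 3, sum_y = 0), d)$decision,
               "escalate")
  expect_equal(decide(data.frame(dose = 1, n = 3, sum_y = 1), d)$decision,
               "deescalate")
  expect_equal(decide(data.frame(dose = 1, n = 5, sum_y = 1), d)$decision,
               "retain")
  # quasi-binary: one grade-2 event in three patients escalates
  dq <- design_ets()
  out <- decide(data.frame(dose = 1, n = 3, sum_y = 0.5), dq)
  expect_equal(out$mu_hat, 0.5 / 3)
  expect_equal(out$decision, "escalate")
  expect_lt(out$lambda_e, 0.47)
  expect_gt(out$lambda_d, 0.47)
  expect_error(decide(data.frame(dose = 1, n = 0, sum_y = 0), d),
               "no patients")
})

test_that("beta-binomial overdose posteriors match hand-derived CDFs", {
  d <- design_bin02()
  p <- overdose_posterior(
    data.frame(dose = 1:3, n = 3, sum_y = c(3, 2, 0)), d)$p_overdose
  expect_equal(p[1], 1 - 0.2^4, tolerance = 1e-12)          # Beta(4,1)
  expect_equal(p[2], 1 - (4 * 0.2^3 - 3 * 0.2^4), tolerance = 1e-12) # Beta(3,2)
  expect_equal(p[3], 1 - (1 - 0.8^4), tolerance = 1e-12)    # Beta(1,4)
  # quasi-binary fractional counts exceeding n imply certain overdose
  dq <- design_ets()
  pq <- overdose_posterior(data.frame(dose = 1, n = 3, sum_y = 4.5 + 1.5),
                           dq)$p_overdose
  expect_equal(pq, 1)
  # normal endpoint needs two observations
  dn <- design_cont()
  pn <- overdose_posterior(
    data.frame(dose = 1, n = 1, sum_y = 0.9, sum_y2 = 0.81), dn)$p_overdose
  expect_equal(pn, 0)
})

test_that("elimination removes the dose and all above it, permanently", {
  d <- design_bin02()
  st <- eliminate_check(data.frame(dose = 1:3, n = c(3, 3, 0),
                                   sum_y = c(0, 3, 0)),
                        d, dose = 2, admissible = rep(TRUE, 3))
  expect_equal(st$admissible, c(TRUE, FALSE, FALSE))
  expect_false(st$terminated)
  # fewer than elim_min_n patients: the rule does not apply
  st2 <- eliminate_check(data.frame(dose = 1, n = 2, sum_y = 2), d,
                         dose = 1, admissible = rep(TRUE, 3))
  expect_true(all(st2$admissible))
  # eliminating dose 1 terminates
  st3 <- eliminate_check(data.frame(dose = 1, n = 3, sum_y = 3), d,
                         dose = 1, admissible = rep(TRUE, 3))
  expect_true(st3$terminated)
})

test_that("dose transitions respect edges and admissibility", {
  adm <- rep(TRUE, 3)
  expect_equal(apply_decision("escalate", 3, adm)$dose, 3)
  expect_equal(apply_decision("deescalate", 1, adm)$dose, 1)
  expect_equal(apply_decision("retain", 2, adm)$dose, 2)
  expect_equal(apply_decision("escalate", 2, c(TRUE, TRUE, FALSE))$dose, 2)
  expect_equal(apply_decision("escalate", 2, c(TRUE, FALSE, FALSE))$dose, 1)
  out <- apply_decision("deescalate", 1, c(FALSE, FALSE, FALSE))
  expect_true(out$terminated)
})

test_that("a harmless scenario escalates monotonically to the top dose", {
  sc <- scenario_binary(rep(0, 5), true_mtd = 5)
  d <- gboins_design(tox_binary(), target = 0.2, n_max = 30, n_doses = 5,
                     preset = "tab-binary-0.2")
  tr <- run_trial(sc, d, seed = 1)
  expect_false(tr$terminated)
  expect_equal(tr$history$dose, c(1, 2, 3, 4, 5, 5, 5, 5, 5, 5))
  expect_true(all(tr$history$decision == "escalate"))
  expect_true(all(tr$admissible))
  expect_equal(sum(tr$dose_data$n), 30)
})

test_that("a uniformly lethal dose 1 terminates the trial without an MTD", {
  sc <- scenario_binary(c(1, 1, 1), true_mtd = 1)
  d <- gboins_design(tox_binary(), target = 0.2, n_max = 30, n_doses = 3,
                     preset = "tab-binary-0.2")
  tr <- run_trial(sc, d, seed = 2)
  expect_true(tr$terminated)
  expect_equal(tr$reason, "all_doses_eliminated")
  expect_true(is.na(tr$mtd))
  expect_true(is.na(glance(tr)$mtd))
})

test_that("trials are reproducible and conserve patients", {
  sc <- builtin_scenarios("binary-0.2", 1)
  d <- gboins_design(tox_binary(), target = 0.2, n_max = 30, n_doses = 5,
                     preset = "sim-binary-0.2")
  t1 <- run_trial(sc, d, seed = 99)
  t2 <- run_trial(sc, d, seed = 99)
  expect_identical(t1$dose_data, t2$dose_data)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$mtd, t2$mtd)
  if (!t1$terminated) {
    expect_equal(sum(t1$dose_data$n), t1$n_cohorts * d$cohort_size)
  }
})

test_that("decisions are long-term memory coherent (exhaustive tallies)", {
  for (des in c("gboin", "gboins")) {
    d <- gboins_design(tox_binary(), target = 0.2, n_max = 30,
                       design = des, preset = "tab-binary-0.2")
    for (n in 1:12) {
      for (y in 0:n) {
        mu <- y / n
        dec <- decide(data.frame(dose = 1, n = n, sum_y = y), d)$decision
        if (mu > 0.2) expect_false(dec == "escalate")
        if (mu < 0.2) expect_false(dec == "deescalate")
      }
    }
  }
})

test_that("continuous decisions never escalate above / de-escalate below target", {
  d <- design_cont(0.25, n_max = 100)
  set.seed(5)
  for (i in 1:500) {
    n <- sample(1:40, 1)
    y <- rnorm(n, runif(1, 0, 0.5), 0.2)
    dec <- decide(data.frame(dose = 1, n = n, sum_y = sum(y),
                             sum_y2 = sum(y^2)), d)$decision
    mu <- mean(y)
    if (mu > 0.25) expect_false(dec == "escalate")
    if (mu < 0.25) expect_false(dec == "deescalate")
  }
})
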