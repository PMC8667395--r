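test_that("fixed binomial boundaries equal the interval-design log ratios", {
  b <- gboin_boundaries(tox_binary(), 0.2)
  expect_equal(b$lambda_e, 0.1572423, tolerance = 1e-6)
  expect_equal(b$lambda_d, 0.2384624, tolerance = 1e-6)
  expect_equal(b$regime, "fixed_gboin")
  # generic eta/A route vs directly coded log-ratio formulas, random triples
  set.seed(7)
  for (i in 1:20) {
    phi0 <- runif(1, 0.1, 0.4)
    phi1 <- phi0 * runif(1, 0.3, 0.9)
    phi2 <- phi0 * runif(1, 1.1, 1.9)
    got <- gboin_boundaries(tox_binary(), phi0, phi1, phi2)
    want <- boin_oracle(phi0, phi1, phi2)
    expect_equal(c(got$lambda_e, got$lambda_d), want, tolerance = 1e-12)
  }
})

test_that("fixed normal boundaries are the hypothesis midpoints", {
  b <- gboin_boundaries(tox_normal(), 0.2, 0.12, 0.28)
  expect_equal(b$lambda_e, 0.16)
  expect_equal(b$lambda_d, 0.24)
  expect_error(gboin_boundaries(tox_binary(), 0.2, 0.2, 0.28), "phi1")
})

test_that("threshold schedule grows as exp(c * n^eps)", {
  expect_equal(gamma_schedule(log(1.1), 0.5, 9), 1.1^3)
  expect_equal(gamma_schedule(log(1.05), 0.5, 16), 1.05^4)
  expect_equal(gamma_schedule(log(1.2) / 3, 0.5, 9), 1.2)
  g <- gamma_schedule(log(1.1), 0.5, 1:50)
  expect_true(all(diff(g) > 0))
  expect_error(gamma_schedule(-1, 0.5, 9), "positive")
  expect_error(gamma_schedule(log(1.1), 1.5, 9), "\\(0, 1\\)")
})

test_that("schedule constants are checked against their bounds", {
  # c1 < c2 violated only
  expect_warning(
    msgs <- validate_schedule(0.2, log(1.05), log(1.05) / 3, n = 9),
    "c1.*not smaller"
  )
  expect_length(msgs, 1)
  # all constraints satisfied
  expect_no_warning(
    msgs2 <- validate_schedule(0.2, log(1.05) / 3, log(1.05), n = 9)
  )
  expect_length(msgs2, 0)
  expect_warning(validate_schedule(0.2, 0, log(1.05), n = 9),
                 "c1 must be positive")
})

test_that("the UMPBT objective matches its closed normal form", {
  fam <- tox_normal()
  for (mu in c(0.05, 0.15, 0.25, 0.4)) {
    for (n in c(3, 9, 27)) {
      got <- g_gamma(fam, mu, 0.2, n, gamma = 1.4, sigma = 0.3)
      want <- (0.3^2 * log(1.4)) / (n * (mu - 0.2)) + (mu + 0.2) / 2
      expect_equal(got / n, want, tolerance = 1e-12)
    }
  }
  # binomial form written out explicitly
  got <- g_gamma(tox_binary(), 0.1, 0.2, 9, gamma = 1.157625)
  want <- (log(1.157625) - 9 * (log(0.9) - log(0.8))) /
    (qlogis(0.1) - qlogis(0.2))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(g_gamma(tox_binary(), 0.2, 0.2, 9, gamma = 1.1), "differ")
  # with gamma = 1 and n = 1 the objective reduces to the fixed-boundary form
  expect_equal(g_gamma(tox_binary(), 0.1, 0.2, 1, gamma = 1),
               boin_oracle(0.2, 0.1, 0.3)[1], tolerance = 1e-12)
})

test_that("normal hypothesis points follow the closed form", {
  expect_equal(optimal_phi1(tox_normal(), 0.2, 9, 1.331, sigma = 0.22),
               0.2 - 0.22 * sqrt(2 * log(1.331) / 9), tolerance = 1e-12)
  expect_equal(optimal_phi1(tox_normal(), 0.2, 9, 1.331, sigma = 0.22),
               0.14453, tolerance = 1e-4)
  expect_equal(optimal_phi2(tox_normal(), 0.2, 9, 1.1, sigma = 0.22),
               0.23202, tolerance = 1e-4)
  expect_equal(optimal_phi1(tox_normal(), 0.2, 9, 1, sigma = 0.22), 0.2)
  expect_equal(optimal_phi2(tox_normal(), 0.2, 9, 1, sigma = 0.22), 0.2)
})

test_that("binomial hypothesis points agree with a fine grid scan", {
  fam <- tox_binary()
  for (cfg in list(list(t = 0.2, n = 9, g = 1.05^3),
                   list(t = 0.47, n = 9, g = 1.2^3),
                   list(t = 0.3, n = 15, g = 1.1^2))) {
    p1 <- optimal_phi1(fam, cfg$t, cfg$n, cfg$g)
    p2 <- optimal_phi2(fam, cfg$t, cfg$n, cfg$g)
    grid1 <- seq(1e-6, cfg$t - 1e-6, by = 1e-5)
    v1 <- g_gamma(fam, grid1, cfg$t, cfg$n, cfg$g)
    expect_equal(p1, grid1[which.max(v1)], tolerance = 1e-4)
    grid2 <- seq(cfg$t + 1e-6, 1 - 1e-6, by = 1e-5)
    v2 <- g_gamma(fam, grid2, cfg$t, cfg$n, cfg$g)
    expect_equal(p2, grid2[which.min(v2)], tolerance = 1e-4)
    expect_lt(p1, cfg$t)
    expect_gt(p2, cfg$t)
  }
})

test_that("shrinkage boundaries use the lead-in then close on the target", {
  d <- design_cont(0.2, n_max = 30, cohort_size = 3)
  b3 <- shrinkage_boundaries(d, 3)
  expect_equal(b3$regime, "fixed_gboin")
  expect_equal(round(c(b3$lambda_e, b3$lambda_d), 2), c(0.16, 0.24))
  b9 <- shrinkage_boundaries(d, 9)
  expect_equal(b9$regime, "shrinkage")
  # hypothesis points straddle the target and both boundaries stay ordered
  tab <- boundary_table(d, 7:200)
  expect_true(all(tab$lambda_e < 0.2 & 0.2 < tab$lambda_d))
  expect_true(all(diff(tab$lambda_e) >= -1e-12))
  expect_true(all(diff(tab$lambda_d) <= 1e-12))
})

test_that("normal fixed boundaries ignore sigma; shrinkage offsets scale with it", {
  d <- design_cont(0.2)
  for (s in c(0.05, 0.22, 1, 3)) {
    b <- shrinkage_boundaries(d, 3, sigma = s)
    expect_equal(c(b$lambda_e, b$lambda_d), c(0.16, 0.24))
  }
  offs <- vapply(c(0.1, 0.2, 0.4, 0.8), function(s) {
    b <- shrinkage_boundaries(d, 12, sigma = s)
    0.2 - b$lambda_e
  }, numeric(1))
  expect_equal(offs / offs[1], c(1, 2, 4, 8), tolerance = 1e-9)
})

test_that("boundary tables reproduce the reference rows", {
  d02 <- design_bin02()
  tab <- boundary_table(d02, seq(3, 30, 3))
  expect_equal(tab$lambda_e_2dp,
               c(0.16, 0.16, 0.16, 0.17, 0.17, 0.17, 0.17, 0.17, 0.17, 0.17))
  d03 <- gboins_design(tox_binary(), target = 0.3, n_max = 30,
                       preset = "tab-binary-0.3")
  tab3 <- boundary_table(d03, seq(3, 30, 3))
  expect_equal(tab3$lambda_d_2dp,
               c(0.36, 0.36, 0.33, 0.33, 0.33, 0.33, 0.33, 0.33, 0.33, 0.32))
  # a lead-in covering the whole grid freezes the fixed pair
  dfix <- gboins_design(tox_binary(), target = 0.2, n_max = 30,
                        preset = "tab-binary-0.2", n_lead = 30)
  tf <- boundary_table(dfix, seq(3, 30, 3))
  expect_true(all(tf$regime == "fixed_gboin"))
  expect_equal(unique(tf$lambda_e), tf$lambda_e[1])
  expect_error(boundary_table(d02, numeric(0)), "non-empty")
})

test_that("incorrect-decision probability is an exact enumeration", {
  fam <- tox_binary()
  # n = 1 by hand: mu_hat in {0, 1}
  a <- decision_error_rate(fam, 0.157, 0.238, 0.2, 0.12, 0.28, n = 1)
  # H0: both outcomes are wrong (0 escalates, 1 de-escalates) -> prob 1
  # H1: y = 1 (prob 0.12) fails to escalate
  # H2: y = 0 (prob 0.72) fails to de-escalate
  by_hand <- (1 + 0.12 + 0.72) / 3
  expect_equal(a, by_hand, tolerance = 1e-12)
  # degenerate boundaries always retain: wrong under H1 and H2 only
  a2 <- decision_error_rate(fam, -10, 10, 0.2, 0.12, 0.28, n = 12)
  expect_equal(a2, 2 / 3, tolerance = 1e-12)
  # normal closed form sanity: wider separation -> smaller error
  lo <- decision_error_rate(tox_normal(), 0.16, 0.24, 0.2, 0.12, 0.28,
                            n = 12, sigma = 0.22)
  hi <- decision_error_rate(tox_normal(), 0.16, 0.24, 0.2, 0.18, 0.22,
                            n = 12, sigma = 0.22)
  expect_lt(lo, hi)
})
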