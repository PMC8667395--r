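test_that("packaged scenario sets have the documented shapes", {
  b2 <- builtin_scenarios("binary-0.2")
  expect_length(b2, 16)
  expect_true(all(vapply(b2, nrow, integer(1)) == 5))
  expect_equal(b2[[1]]$p_dlt, c(0.20, 0.25, 0.35, 0.45, 0.50))
  expect_equal(attr(b2[[1]], "true_mtd"), 1L)
  b3 <- builtin_scenarios("binary-0.3")
  expect_length(b3, 16)
  bss <- builtin_scenarios("binary-samplesize")
  expect_length(bss, 4)
  ets <- builtin_scenarios("ets")
  expect_length(ets, 10)
  cont <- builtin_scenarios("continuous")
  expect_length(cont, 10)
  expect_error(builtin_scenarios("ets", 11), "unknown scenario")
})

test_that("binary scenario toxicities are monotone in dose", {
  for (set in c("binary-0.2", "binary-0.3", "binary-samplesize")) {
    for (sc in builtin_scenarios(set)) {
      expect_true(all(diff(sc$p_dlt) >= 0))
    }
  }
})

test_that("grade profiles are simplex-valid and give the published mean scores", {
  ets <- builtin_scenarios("ets")
  for (sc in ets) {
    probs <- as.matrix(sc[, c("p_grade01", "p_grade2", "p_grade3",
                              "p_grade4")])
    expect_equal(unname(rowSums(probs)), rep(1, 6), tolerance = 1e-9)
    expect_true(all(probs >= 0))
  }
  # expected scores against independently computed dot products
  expect_equal(true_mean_score(ets[[1]], 4)$true_mean, 0.475)  # ~0.48
  expect_equal(true_mean_score(ets[[5]], 6)$true_mean, 0.325)  # ~0.32
  expect_equal(true_mean_score(ets[[9]])$true_mean[2], 0.45)
  expect_equal(true_mean_score(ets[[7]])$true_mean,
               c(0.19, 0.45, 0.57, 0.73, 0.90, 1.17), tolerance = 1e-9)
})

test_that("continuous scenarios carry the dose-indexed normal laws", {
  sc7 <- builtin_scenarios("continuous", 7)
  expect_equal(sc7$mean, 0.05 + 0.05 * (1:6))
  expect_equal(sc7$sd, 0.05 * (1:6))
  expect_equal(sc7$mean[3], 0.20)
  expect_equal(sc7$sd[3], 0.15)
  expect_equal(attr(sc7, "true_mtd"), 3L)
  expect_equal(attr(sc7, "target"), 0.20)
  expect_equal(attr(sc7, "n_max"), 100L)
  sc1 <- builtin_scenarios("continuous", 1)
  expect_equal(attr(sc1, "n_max"), 15L)
})

test_that("outcome sampling honours degenerate and stochastic laws", {
  set.seed(3)
  expect_equal(sample_outcome(scenario_binary(c(0, 0), 1), 1, 20), rep(0, 20))
  sure_grade4 <- scenario_quasibinary(
    matrix(c(0, 0, 0, 1), 1, 4), true_mtd = 1)
  expect_equal(sample_outcome(sure_grade4, 1, 10), rep(1.5, 10))
  sn <- scenario_normal(0.2, 0.15, 1)
  y <- sample_outcome(sn, 1, 1e5)
  expect_lt(abs(mean(y) - 0.2), 3 * 0.15 / sqrt(1e5))
  expect_error(sample_outcome(sn, 2), "invalid dose")
})

test_that("profile repair closes small transcription gaps only", {
  # completing the non-toxic category
  sc <- scenario_quasibinary(matrix(c(0.57, 0.19, 0.12, 0.12), 1), 1)
  expect_equal(sum(sc[1, -1]), 1)
  sc2 <- scenario_quasibinary(matrix(c(0.56, 0.19, 0.12, 0.12), 1), 1)
  expect_equal(unlist(sc2[1, -1], use.names = FALSE),
               c(0.57, 0.19, 0.12, 0.12))
  expect_error(scenario_quasibinary(matrix(c(0.2, 0.2, 0.2, 0.2), 1), 1),
               "sums to")
})
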