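test_that("design configurations round-trip through YAML exactly", {
  set.seed(17)
  designs <- list(
    design_bin02(),
    design_ets(),
    design_cont(0.25),
    gboins_design(tox_normal(sigma_policy = "sample"), target = 0.3,
                  n_max = 60, n_doses = 6, cohort_size = 1,
                  c1 = log(1.1) / 3, c2 = log(1.1), t_scale = "sem")
  )
  for (i in 1:20) {
    tgt <- runif(1, 0.1, 0.4)
    designs <- c(designs, list(gboins_design(
      tox_binary(), target = tgt, n_max = 3 * sample(5:15, 1),
      design = sample(c("gboin", "gboins"), 1),
      phi1 = tgt * runif(1, 0.4, 0.8), phi2 = tgt * runif(1, 1.2, 1.8),
      c1 = runif(1, 0.01, 0.2), c2 = runif(1, 0.01, 0.2),
      n_lead = sample(0:9, 1)
    )))
  }
  for (d in designs) {
    f <- tempfile(fileext = ".yaml")
    write_design_config(d, f)
    expect_identical(read_design_config(f), d)
    unlink(f)
  }
})

test_that("config validation names the offending field", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("family: binary", "target: 0.3", "n_max: 30",
               "c1: 0.03", "c2: 0.01", "frobnicate: 1"), f)
  expect_error(read_design_config(f), "frobnicate")
  writeLines(c("family: binary", "target: 1.3", "n_max: 30",
               "c1: 0.03", "c2: 0.01"), f)
  expect_error(read_design_config(f), "target")
  writeLines(c("family: binary", "target: 0.3"), f)
  expect_error(read_design_config(f), "n_max")
  unlink(f)
  expect_error(read_design_config("no/such/file.yaml"), "no such file")
})

test_that("reference boundary tables regenerate and round-trip to CSV", {
  f <- tempfile(fileext = ".csv")
  tab <- report_boundary_tables(f)
  expect_equal(nrow(tab), 40)
  expect_equal(unique(tab$endpoint), c("bernoulli", "continuous"))
  reread <- tibble::as_tibble(utils::read.csv(f))
  expect_equal(reread$lambda_e_2dp, tab$lambda_e_2dp)
  expect_equal(reread$lambda_e, tab$lambda_e, tolerance = 1e-12)
  unlink(f)
})

test_that("OC reports carry identical numbers in CSV and JSON", {
  sc <- builtin_scenarios("ets", 5)
  oc <- operating_characteristics(sc, design_ets(), n_reps = 50, seed = 2)
  base <- tempfile()
  rep_tab <- report_oc(list(gBOINS = oc), paste0(base, ".csv"))
  expect_equal(nrow(rep_tab), 2)
  expect_equal(rep_tab$metric, c("selection_pct", "avg_n_treated"))
  csv <- utils::read.csv(paste0(base, ".csv"))
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  for (col in paste0("d", 1:6)) {
    expect_equal(csv[[col]], js[[col]], tolerance = 1e-12)
    expect_equal(csv[[col]], rep_tab[[col]], tolerance = 1e-12)
  }
  unlink(paste0(base, c(".csv", ".json")))
})
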