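#' Operating characteristics by replicated simulation
#'
#' Repeats [run_trial()] `n_reps` times (each replicate on its own RNG
#' substream spawned from `seed`, so results are independent of execution
#' order) and summarises the design's behaviour under the scenario:
#'
#' * **PCS** — percentage of replicates selecting the true MTD;
#' * **average patients at the MTD**;
#' * **overdosing risk** — percentage of replicates in which strictly more
#'   than 60% (and 80%) of treated patients received doses above the MTD;
#' * **underdosing risk** — percentage with strictly more than 80% treated
#'   below the MTD;
#' * per-dose selection percentages and average allocation, plus the
#'   percentage of replicates selecting no dose (early termination).
#'
#' @inheritParams run_trial
#' @param n_reps Number of replicated trials.
#' @param seed Integer master seed.
#' @return An object of class `gboins_oc`; see [tidy.gboins_oc()] and
#'   [glance.gboins_oc()].
#' @examples
#' sc <- builtin_scenarios("ets", 9)
#' d <- gboins_design(tox_quasibinary(), target = 0.47, n_max = 30,
#'                    n_doses = 6, preset = "sim-quasibinary")
#' oc <- operating_characteristics(sc, d, n_reps = 50, seed = 1)
#' glance(oc)
#' @export
operating_characteristics <- function(scenario, design, n_reps = 1000,
                                      seed = 1) {
  check_scenario_design(scenario, design)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  J <- nrow(scenario)
  mtd <- attr(scenario, "true_mtd")
  bl <- boundary_matrix(design)
  reps <- with_substreams(seed, n_reps, function(r) {
    res <- trial_core(scenario, design, bl = bl)
    list(sel = res$mtd, n = res$dose_data$n)
  })
  sel <- vapply(reps, function(r) {
    if (is.na(r$sel)) 0L else r$sel
  }, integer(1))
  alloc <- t(vapply(reps, function(r) r$n, numeric(J)))
  treated <- rowSums(alloc)
  above <- if (mtd < J) rowSums(alloc[, (mtd + 1):J, drop = FALSE]) else {
    rep(0, n_reps)
  }
  below <- if (mtd > 1) rowSums(alloc[, 1:(mtd - 1), drop = FALSE]) else {
    rep(0, n_reps)
  }
  per_dose <- tibble::tibble(
    dose = seq_len(J),
    true_mean = true_mean_score(scenario)$true_mean,
    selection_pct = 100 * vapply(seq_len(J), function(j) {
      mean(sel == j)
    }, numeric(1)),
    n_avg = colMeans(alloc),
    is_mtd = seq_len(J) == mtd
  )
  structure(list(
    per_dose = per_dose,
    pcs = 100 * mean(sel == mtd),
    avg_n_at_mtd = mean(alloc[, mtd]),
    overdose_risk_60 = 100 * mean(above / treated > 0.6),
    overdose_risk_80 = 100 * mean(above / treated > 0.8),
    underdose_risk_80 = 100 * mean(below / treated > 0.8),
    pct_no_selection = 100 * mean(sel == 0L),
    n_reps = n_reps, seed = seed,
    true_mtd = mtd, scenario = scenario, design = design
  ), class = "gboins_oc")
}

#' Per-dose operating characteristics
#'
#' @param x A `gboins_oc` from [operating_characteristics()].
#' @param ... Unused.
#' @return A tibble with per-dose true mean, selection percentage and average
#'   allocation.
#' @method tidy gboins_oc
#' @export
tidy.gboins_oc <- function(x, ...) {
  x$per_dose
}

#' One-row operating-characteristics summary
#'
#' @inheritParams tidy.gboins_oc
#' @return A tibble with `pcs`, `avg_n_at_mtd`, the overdosing/underdosing
#'   risks, `pct_no_selection` and `n_reps`.
#' @method glance gboins_oc
#' @export
glance.gboins_oc <- function(x, ...) {
  tibble::tibble(
    pcs = x$pcs,
    avg_n_at_mtd = x$avg_n_at_mtd,
    overdose_risk_60 = x$overdose_risk_60,
    overdose_risk_80 = x$overdose_risk_80,
    underdose_risk_80 = x$underdose_risk_80,
    pct_no_selection = x$pct_no_selection,
    n_reps = x$n_reps
  )
}

#' @export
print.gboins_oc <- function(x, ...) {
  cat("<gboins_oc> ", toupper(x$design$design), ", ", x$n_reps,
      " replicates, true MTD at dose ", x$true_mtd, "\n", sep = "")
  cat(sprintf(
    "  PCS %.1f%%, %.1f patients at MTD, overdose risk (60/80) %.1f/%.1f%%, underdose risk (80) %.1f%%\n",
    x$pcs, x$avg_n_at_mtd, x$overdose_risk_60, x$overdose_risk_80,
    x$underdose_risk_80))
  print(x$per_dose)
  invisible(x)
}
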