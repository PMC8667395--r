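#' Dose-transition decision at the current dose
#'
#' Compares the observed mean toxicity at the current dose with the active
#' boundary pair — fixed for a gBOIN design, sample-size-dependent
#' ([shrinkage_boundaries()]) for gBOINS — using the inclusive conventions:
#' escalate iff \eqn{\hat\mu_j \le \lambda_e}, de-escalate iff
#' \eqn{\hat\mu_j \ge \lambda_d}, otherwise retain.
#'
#' @param dose_data A data frame of per-dose tallies with columns `dose`,
#'   `n`, `sum_y` (and `sum_y2` for the normal family). `sum_y` is in raw
#'   score units (DLT count, summed ETS, or summed continuous scores).
#' @param design A [gboins_design()].
#' @param dose The current dose level; may be omitted when `dose_data` has a
#'   single row.
#' @return A one-row tibble: `dose`, `n`, `mu_hat`, `lambda_e`, `lambda_d`,
#'   `regime`, `decision` (`"escalate"`, `"retain"` or `"deescalate"`).
#' @examples
#' d <- gboins_design(tox_binary(), target = 0.2, n_max = 30,
#'                    preset = "tab-binary-0.2")
#' decide(data.frame(dose = 1, n = 3, sum_y = 0), d)
#' @export
decide <- function(dose_data, design, dose = NULL) {
  stopifnot(inherits(design, "gboins_design"))
  dose_data <- tibble::as_tibble(dose_data)
  if (is.null(dose)) {
    if (nrow(dose_data) != 1) {
      stop("`dose` must be given when `dose_data` has several rows",
           call. = FALSE)
    }
    dose <- dose_data$dose[1]
  }
  row <- which(dose_data$dose == dose)
  if (!length(row)) stop("no row for dose ", dose, call. = FALSE)
  n <- dose_data$n[row]
  if (n < 1) stop("no patients observed at dose ", dose, call. = FALSE)
  mu <- dose_data$sum_y[row] / n
  sigma <- NULL
  if (design$family$kind == "normal") {
    sy2 <- if ("sum_y2" %in% names(dose_data)) dose_data$sum_y2[row] else NULL
    sigma <- resolve_sigma(design, n, dose_data$sum_y[row], sy2)
  }
  b <- shrinkage_boundaries(design, n, sigma = sigma)
  decision <- if (mu <= b$lambda_e) {
    "escalate"
  } else if (mu >= b$lambda_d) {
    "deescalate"
  } else {
    "retain"
  }
  tibble::tibble(dose = dose, n = n, mu_hat = mu,
                 lambda_e = b$lambda_e, lambda_d = b$lambda_d,
                 regime = b$regime, decision = decision)
}

# SD entering the adaptive boundary offsets, per the family's policy
resolve_sigma <- function(design, n, sum_y, sum_y2) {
  fam <- design$family
  if (fam$kind != "normal") return(NULL)
  plugin <- design_sigma(design)
  if (fam$sigma_policy == "plugin") return(plugin)
  if (is.null(sum_y2) || n < 2) return(plugin)
  ss <- max(sum_y2 - sum_y^2 / n, 0) # = sum (y - mu)^2
  if (fam$sigma_policy == "sample") {
    s <- sqrt(ss / n)
    if (s == 0) plugin else s
  } else { # posterior_mean of sigma^2 under the inverse-gamma prior
    sqrt((2 * fam$prior_rate + ss) / (n + fam$prior_shape))
  }
}

#' Overdose-control posterior probability
#'
#' \eqn{P(\mu_j > \phi_0 \mid D_j)} at each dose, the quantity driving the
#' elimination rule. (Quasi-)binomial endpoints use a beta-binomial model
#' with a uniform beta(1, 1) prior, quasi-binary tallies entering as
#' fractional pseudo-counts on the normalised score scale. Normal endpoints
#' use the \eqn{t_{n_j-1}} posterior of \eqn{\mu_j} centred at
#' \eqn{\hat\mu_j}; its scale convention is governed by the design's
#' `t_scale` (the divisor-\eqn{n} \eqn{\hat\sigma} by default). Doses with
#' too few patients to evaluate the posterior (none for binary; fewer than 2
#' for normal) report 0.
#'
#' @inheritParams decide
#' @return The input tibble with an added `p_overdose` column.
#' @examples
#' d <- gboins_design(tox_binary(), target = 0.2, n_max = 30,
#'                    preset = "tab-binary-0.2")
#' overdose_posterior(data.frame(dose = 1, n = 3, sum_y = 3), d)
#' @export
overdose_posterior <- function(dose_data, design) {
  dose_data <- tibble::as_tibble(dose_data)
  fam <- design$family
  smax <- score_scale(fam)
  p <- vapply(seq_len(nrow(dose_data)), function(i) {
    n <- dose_data$n[i]
    if (is_binomial_kind(fam)) {
      if (n < 1) return(0)
      sy <- dose_data$sum_y[i] / smax
      shape1 <- 1 + sy
      shape2 <- 1 + n - sy
      if (shape2 <= 0) return(1) # mean score beyond the scale: overly toxic
      1 - stats::pbeta(design$target / smax, shape1, shape2)
    } else {
      if (n < 2) return(0)
      mu <- dose_data$sum_y[i] / n
      sy2 <- if ("sum_y2" %in% names(dose_data)) dose_data$sum_y2[i] else {
        stop("the normal family needs a `sum_y2` column", call. = FALSE)
      }
      s <- sqrt(max(sy2 / n - mu^2, 0))
      if (s == 0) return(as.numeric(mu > design$target))
      scale <- if (design$t_scale == "sigma_hat") s else s / sqrt(n)
      1 - stats::pt((design$target - mu) / scale, df = n - 1)
    }
  }, numeric(1))
  dplyr::mutate(dose_data, p_overdose = p)
}

#' Apply the overdose-control elimination rule
#'
#' Evaluates the rule at the current dose: when
#' \eqn{P(\mu_j > \phi_0 \mid D_j)} exceeds the design's threshold and at
#' least `elim_min_n` patients have been treated there, the dose and all
#' higher doses become inadmissible; the trial terminates when the lowest
#' dose is eliminated. Elimination is permanent.
#'
#' @inheritParams decide
#' @param dose Dose at which to evaluate the rule.
#' @param admissible Logical vector, one entry per dose.
#' @return A list with updated `admissible` and a `terminated` flag.
#' @export
eliminate_check <- function(dose_data, design, dose, admissible) {
  row <- which(dose_data$dose == dose)
  J <- length(admissible)
  terminated <- FALSE
  if (length(row) && dose_data$n[row] >= design$elim_min_n) {
    post <- overdose_posterior(dose_data[row, ], design)$p_overdose
    if (post > design$elim_threshold) {
      admissible[dose:J] <- FALSE
      if (!any(admissible)) terminated <- TRUE
    }
  }
  list(admissible = admissible, terminated = terminated)
}

#' Move to the next dose
#'
#' Edge-handled dose transition: escalation targets the lowest admissible
#' dose above the current one (staying put at the top or when all higher
#' doses are eliminated); de-escalation targets the highest admissible dose
#' below (staying put at the bottom); retain stays. If the current dose
#' itself is inadmissible the trial falls to the highest admissible dose
#' below it, and terminates when none exists.
#'
#' @param decision `"escalate"`, `"retain"` or `"deescalate"`.
#' @param dose Current dose level.
#' @param admissible Logical vector, one entry per dose.
#' @return A list with `dose` (the next dose, `NA` on termination) and
#'   `terminated`.
#' @export
apply_decision <- function(decision, dose, admissible) {
  J <- length(admissible)
  nxt <- dose
  if (decision == "escalate") {
    up <- which(admissible & seq_len(J) > dose)
    if (length(up)) nxt <- min(up)
  } else if (decision == "deescalate") {
    dn <- which(admissible & seq_len(J) < dose)
    if (length(dn)) nxt <- max(dn)
  }
  if (!admissible[nxt]) {
    dn <- which(admissible & seq_len(J) <= nxt)
    if (!length(dn)) return(list(dose = NA_integer_, terminated = TRUE))
    nxt <- max(dn)
  }
  list(dose = nxt, terminated = FALSE)
}

# Pre-tabulated decision boundaries on the internal decision scale
# (normalised for (quasi-)binomial, raw for plug-in normal); NULL when the
# boundaries are data-dependent (sample / posterior-mean sigma policies).
boundary_matrix <- function(design) {
  fam <- design$family
  if (fam$kind == "normal" && fam$sigma_policy != "plugin") return(NULL)
  smax <- score_scale(fam)
  ns <- seq_len(design$n_max)
  tab <- boundary_table(design, ns)
  cbind(le = tab$lambda_e / smax, ld = tab$lambda_d / smax)
}

# normal-family shrinkage pair for a data-dependent sigma (raw scale)
normal_pair <- function(design, n, sigma) {
  if (design$design == "gboin" || n <= design$n_lead) {
    c((design$target + design$phi1) / 2, (design$target + design$phi2) / 2)
  } else {
    g1 <- exp(design$c1 * n^design$eps1)
    g2 <- exp(design$c2 * n^design$eps2)
    c(design$target - (sigma / 2) * sqrt(2 * log(g1) / n),
      design$target + (sigma / 2) * sqrt(2 * log(g2) / n))
  }
}

# sequential trial on the internal decision scale; assumes RNG already seeded
trial_core <- function(scenario, design, bl = NULL, record = FALSE) {
  fam <- design$family
  smax <- score_scale(fam)
  J <- nrow(scenario)
  p0 <- design$target / smax
  normal <- fam$kind == "normal"
  if (is.null(bl)) bl <- boundary_matrix(design)
  n <- numeric(J)
  sy <- numeric(J)
  sy2 <- numeric(J)
  adm <- rep(TRUE, J)
  dose <- design$start_dose
  treated <- 0L
  terminated <- FALSE
  reason <- NA_character_
  hist <- if (record) list() else NULL
  cohort <- 0L
  while (treated < design$n_max && !terminated) {
    cohort <- cohort + 1L
    k <- min(design$cohort_size, design$n_max - treated)
    y <- sample_outcome(scenario, dose, k) / smax
    n[dose] <- n[dose] + k
    sy[dose] <- sy[dose] + sum(y)
    sy2[dose] <- sy2[dose] + sum(y^2)
    treated <- treated + k
    nd <- n[dose]
    mu <- sy[dose] / nd
    # overdose-control elimination at the just-updated dose
    eliminated_now <- FALSE
    if (nd >= design$elim_min_n) {
      if (!normal) {
        shape2 <- 1 + nd - sy[dose]
        post <- if (shape2 <= 0) 1 else {
          1 - stats::pbeta(p0, 1 + sy[dose], shape2)
        }
      } else {
        s <- sqrt(max(sy2[dose] / nd - mu^2, 0))
        post <- if (s == 0) as.numeric(mu > p0) else {
          scale <- if (design$t_scale == "sigma_hat") s else s / sqrt(nd)
          1 - stats::pt((p0 - mu) / scale, df = nd - 1)
        }
      }
      if (post > design$elim_threshold) {
        adm[dose:J] <- FALSE
        eliminated_now <- TRUE
        if (!any(adm)) {
          terminated <- TRUE
          reason <- "all_doses_eliminated"
        }
      }
    }
    if (is.null(bl)) {
      sig <- resolve_sigma(design, nd, sy[dose], sy2[dose])
      pair <- normal_pair(design, nd, sig)
    } else {
      pair <- bl[nd, ]
    }
    decision <- if (mu <= pair[1]) {
      "escalate"
    } else if (mu >= pair[2]) {
      "deescalate"
    } else {
      "retain"
    }
    if (record) {
      hist[[cohort]] <- tibble::tibble(
        cohort = cohort, dose = dose, n_at_dose = nd,
        mu_hat = mu * smax,
        lambda_e = pair[1] * smax, lambda_d = pair[2] * smax,
        decision = decision, eliminated = eliminated_now
      )
    }
    if (terminated) break
    mv <- apply_decision(decision, dose, adm)
    if (mv$terminated) {
      terminated <- TRUE
      reason <- "all_doses_eliminated"
      break
    }
    dose <- mv$dose
  }
  dose_data <- tibble::tibble(
    dose = seq_len(J), n = as.integer(n),
    sum_y = sy * smax, sum_y2 = sy2 * smax^2
  )
  mtd <- if (terminated) NA_integer_ else {
    select_mtd(dose_data, design$target, admissible = adm)
  }
  list(dose_data = dose_data, admissible = adm, terminated = terminated,
       reason = reason, mtd = mtd, n_cohorts = cohort,
       history = if (record) dplyr::bind_rows(hist) else NULL)
}

#' Simulate a single dose-finding trial
#'
#' Runs the sequential procedure: cohorts are enrolled starting at the design
#' start dose, outcomes are drawn from the scenario, the overdose-control
#' rule is applied at the treated dose, the escalate/retain/de-escalate
#' decision is made against the active boundaries, and the next cohort is
#' assigned; the trial stops at the patient budget or on termination, after
#' which the MTD is selected by [select_mtd()] (terminated trials select
#' none).
#'
#' @param scenario A [gboins_scenario][scenario_binary].
#' @param design A [gboins_design()].
#' @param seed Optional integer seed; runs are fully reproducible given it.
#' @return An object of class `gboins_trial`: per-dose tallies, admissibility,
#'   cohort history, termination status and the selected MTD. Use
#'   [generics::tidy()] / [generics::glance()] or [ggplot2::autoplot()].
#' @examples
#' sc <- builtin_scenarios("ets", 3)
#' d <- gboins_design(tox_quasibinary(), target = 0.47, n_max = 30,
#'                    n_doses = 6, preset = "sim-quasibinary")
#' run_trial(sc, d, seed = 1)
#' @export
run_trial <- function(scenario, design, seed = NULL) {
  check_scenario_design(scenario, design)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- trial_core(scenario, design, record = TRUE)
  structure(c(res, list(scenario = scenario, design = design, seed = seed)),
            class = "gboins_trial")
}

check_scenario_design <- function(scenario, design) {
  if (!inherits(scenario, "gboins_scenario")) {
    stop("`scenario` must be a gboins_scenario", call. = FALSE)
  }
  if (!is.null(design$n_doses) && design$n_doses != nrow(scenario)) {
    stop("design expects ", design$n_doses, " doses but the scenario has ",
         nrow(scenario), call. = FALSE)
  }
  kind <- attr(scenario, "kind")
  if (kind != design$family$kind) {
    stop("scenario kind (", kind, ") does not match the design family (",
         design$family$kind, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gboins_trial <- function(x, ...) {
  cat("<gboins_trial> ", toupper(x$design$design), ", ",
      sum(x$dose_data$n), " patients in ", x$n_cohorts, " cohorts\n",
      sep = "")
  if (x$terminated) {
    cat("  terminated early (", x$reason, "); no MTD selected\n", sep = "")
  } else {
    cat("  selected MTD: dose ", x$mtd, "\n", sep = "")
  }
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-dose summary of a simulated trial
#'
#' @param x A `gboins_trial`.
#' @param ... Unused.
#' @return A tibble with per-dose `n`, `sum_y`, observed mean `mu_hat`,
#'   isotonic estimate `mu_iso`, admissibility and selection flag.
#' @method tidy gboins_trial
#' @export
tidy.gboins_trial <- function(x, ...) {
  iso <- isotonic_means(x$dose_data)
  dplyr::mutate(
    iso,
    admissible = x$admissible,
    selected = !is.na(x$mtd) & iso$dose == x$mtd
  )
}

#' One-row summary of a simulated trial
#'
#' @inheritParams tidy.gboins_trial
#' @return A tibble with the selected MTD, patients treated, cohort count and
#'   termination status.
#' @method glance gboins_trial
#' @export
glance.gboins_trial <- function(x, ...) {
  tibble::tibble(
    mtd = x$mtd,
    n_treated = sum(x$dose_data$n),
    n_cohorts = x$n_cohorts,
    terminated = x$terminated,
    n_at_mtd = if (is.na(x$mtd)) NA_integer_ else {
      x$dose_data$n[x$dose_data$dose == x$mtd]
    }
  )
}
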