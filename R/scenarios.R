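#' Dose-toxicity scenarios
#'
#' A scenario specifies the true outcome law at every dose level, plus the
#' true maximum tolerated dose (MTD), and is the input to [run_trial()] and
#' [operating_characteristics()].
#'
#' * `scenario_binary()` — per-dose DLT probabilities;
#' * `scenario_quasibinary()` — per-dose probability profiles over the grade
#'   categories (grades 0--1 merged, 2, 3, 4), sampled grades being mapped to
#'   scores by [ets_score()];
#' * `scenario_normal()` — per-dose mean/SD of a Gaussian toxicity score
#'   (draws are not truncated at zero; the benchmark laws are used verbatim).
#'
#' @param p_dlt Numeric vector of DLT probabilities, one per dose.
#' @param grade_probs Matrix (doses x grade categories) of grade
#'   probabilities; rows must sum to 1. Rows whose printed source values
#'   leave the simplex by a small transcription slack are repaired by
#'   completing the first (non-toxic) category, or proportional rescaling if
#'   the toxic mass alone exceeds 1.
#' @param mean,sd Numeric vectors of per-dose normal means and SDs.
#' @param true_mtd Index of the true MTD (the dose whose mean toxicity is
#'   closest to the intended target).
#' @param family Quasi-binary [tox_family][tox_binary] carrying the grade
#'   weights.
#' @return A tibble of class `gboins_scenario` with attributes `kind` and
#'   `true_mtd`.
#' @examples
#' scenario_binary(c(0.05, 0.1, 0.2, 0.3), true_mtd = 3)
#' @export
scenario_binary <- function(p_dlt, true_mtd) {
  if (any(p_dlt < 0 | p_dlt > 1)) {
    stop("DLT probabilities must lie in [0, 1]", call. = FALSE)
  }
  new_scenario(tibble::tibble(dose = seq_along(p_dlt), p_dlt = p_dlt),
               kind = "binomial", true_mtd = true_mtd)
}

#' @rdname scenario_binary
#' @export
scenario_quasibinary <- function(grade_probs, true_mtd,
                                 family = tox_quasibinary()) {
  grade_probs <- as.matrix(grade_probs)
  if (ncol(grade_probs) != length(family$grade_weights)) {
    stop("`grade_probs` needs one column per grade category", call. = FALSE)
  }
  grade_probs <- t(apply(grade_probs, 1, repair_profile))
  tb <- tibble::as_tibble(grade_probs, .name_repair = "minimal")
  names(tb) <- paste0("p_grade", c("01", "2", "3", "4"))[
    seq_len(ncol(grade_probs))]
  tb <- dplyr::bind_cols(tibble::tibble(dose = seq_len(nrow(grade_probs))),
                         tb)
  sc <- new_scenario(tb, kind = "quasi_binomial", true_mtd = true_mtd)
  attr(sc, "family") <- family
  sc
}

#' @rdname scenario_binary
#' @export
scenario_normal <- function(mean, sd, true_mtd) {
  if (length(mean) != length(sd)) {
    stop("`mean` and `sd` must have the same length", call. = FALSE)
  }
  if (any(sd <= 0)) stop("`sd` must be positive", call. = FALSE)
  new_scenario(tibble::tibble(dose = seq_along(mean), mean = mean, sd = sd),
               kind = "normal", true_mtd = true_mtd)
}

new_scenario <- function(tb, kind, true_mtd) {
  if (true_mtd < 1 || true_mtd > nrow(tb)) {
    stop("`true_mtd` must be a valid dose level", call. = FALSE)
  }
  structure(tb, kind = kind, true_mtd = as.integer(true_mtd),
            class = c("gboins_scenario", class(tb)))
}

# close the simplex when a printed profile misses 1 by transcription slack:
# complete the non-toxic category, or rescale if the toxic mass exceeds 1
repair_profile <- function(p) {
  if (any(p < 0)) stop("grade probabilities must be non-negative",
                       call. = FALSE)
  total <- sum(p)
  if (abs(total - 1) <= 1e-9) return(p)
  if (abs(total - 1) > 0.15) {
    stop("grade profile sums to ", format(total), ", not 1", call. = FALSE)
  }
  toxic <- sum(p[-1])
  if (toxic <= 1) {
    p[1] <- 1 - toxic
  } else {
    p <- p / total
  }
  p
}

#' Packaged benchmark scenario sets
#'
#' Returns the benchmark dose-toxicity scenarios shipped with the package,
#' transcribed from the published simulation studies:
#'
#' * `"binary-0.2"`, `"binary-0.3"` — sixteen binary-endpoint scenarios each,
#'   for target DLT rates 0.20 / 0.30, five doses;
#' * `"binary-samplesize"` — four binary scenarios used for sample-size
#'   sweeps (two per target);
#' * `"ets"` — ten quasi-binary scenarios over six doses giving the
#'   probability of each toxicity grade (target ETS 0.47);
#' * `"continuous"` — ten continuous scenarios over six doses with
#'   \eqn{y \sim N(0.05 + 0.05x, (0.05x)^2)}, differing in the target score
#'   (hence MTD position) and recommended sample size.
#'
#' @param set One of the set names above.
#' @param scenario Optional scenario number; if omitted, all scenarios in the
#'   set are returned as a list.
#' @return A `gboins_scenario` (or list of them). Scenarios carry attributes
#'   `true_mtd` and, where the study fixes them, `target` and `n_max`.
#' @examples
#' builtin_scenarios("ets", 9)
#' @export
builtin_scenarios <- function(set = c("binary-0.2", "binary-0.3",
                                      "binary-samplesize", "ets",
                                      "continuous"),
                              scenario = NULL) {
  set <- match.arg(set)
  one <- function(s) {
    if (set == "ets") {
      df <- read_fixture("scenarios_ets.csv")
      df <- df[df$scenario == s, ]
      if (!nrow(df)) stop("unknown scenario ", s, call. = FALSE)
      sc <- scenario_quasibinary(
        as.matrix(df[, c("p_grade01", "p_grade2", "p_grade3", "p_grade4")]),
        true_mtd = which(df$is_mtd == 1)
      )
      attr(sc, "target") <- 0.47
      attr(sc, "n_max") <- 30L
    } else if (set == "continuous") {
      df <- read_fixture("scenarios_continuous.csv")
      df <- df[df$scenario == s, ]
      if (!nrow(df)) stop("unknown scenario ", s, call. = FALSE)
      sc <- scenario_normal(df$mean, df$sd, true_mtd = which(df$is_mtd == 1))
      attr(sc, "target") <- df$target[1]
      attr(sc, "n_max") <- as.integer(df$n_max[1])
    } else {
      df <- read_fixture("scenarios_binary.csv")
      df <- df[df$set == set & df$scenario == s, ]
      if (!nrow(df)) stop("unknown scenario ", s, call. = FALSE)
      sc <- scenario_binary(df$p_dlt, true_mtd = which(df$is_mtd == 1))
      attr(sc, "target") <- df$target[1]
    }
    sc
  }
  if (!is.null(scenario)) return(one(scenario))
  df <- switch(set,
    "ets" = read_fixture("scenarios_ets.csv"),
    "continuous" = read_fixture("scenarios_continuous.csv"),
    read_fixture("scenarios_binary.csv")
  )
  if (!is.null(df$set)) df <- df[df$set == set, ]
  lapply(sort(unique(df$scenario)), one)
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "gboins", mustWork = TRUE)
  utils::read.csv(path)
}

#' True mean toxicity score of a scenario
#'
#' The expected toxicity score at each dose: the DLT probability (binary),
#' the grade-weight dot product (quasi-binary), or the normal mean.
#'
#' @param scenario A [gboins_scenario][scenario_binary].
#' @param dose Optional dose subset.
#' @return A tibble with columns `dose` and `true_mean`.
#' @examples
#' true_mean_score(builtin_scenarios("ets", 1))
#' @export
true_mean_score <- function(scenario, dose = NULL) {
  kind <- attr(scenario, "kind")
  tm <- switch(kind,
    binomial = scenario$p_dlt,
    quasi_binomial = {
      fam <- attr(scenario, "family")
      as.numeric(as.matrix(
        scenario[, grep("^p_grade", names(scenario))]) %*% fam$grade_weights)
    },
    normal = scenario$mean
  )
  out <- tibble::tibble(dose = scenario$dose, true_mean = tm)
  if (!is.null(dose)) out <- out[out$dose %in% dose, ]
  out
}

#' Draw patient outcomes under a scenario
#'
#' Samples toxicity scores for `n` patients treated at one dose, using the
#' session RNG: Bernoulli draws (binary), grade draws mapped through the
#' grade weights (quasi-binary), or Gaussian draws (normal; not truncated).
#'
#' @inheritParams true_mean_score
#' @param dose Dose level.
#' @param n Number of patients.
#' @return Numeric vector of toxicity scores.
#' @export
sample_outcome <- function(scenario, dose, n = 1) {
  row <- which(scenario$dose == dose)
  if (!length(row)) stop("invalid dose ", dose, call. = FALSE)
  kind <- attr(scenario, "kind")
  switch(kind,
    binomial = as.numeric(stats::runif(n) < scenario$p_dlt[row]),
    quasi_binomial = {
      fam <- attr(scenario, "family")
      probs <- as.numeric(scenario[row, grep("^p_grade", names(scenario))])
      idx <- sample.int(length(probs), n, replace = TRUE, prob = probs)
      unname(fam$grade_weights[idx])
    },
    normal = stats::rnorm(n, scenario$mean[row], scenario$sd[row])
  )
}

#' @export
print.gboins_scenario <- function(x, ...) {
  cat("<gboins_scenario> ", attr(x, "kind"), ", true MTD at dose ",
      attr(x, "true_mtd"), "\n", sep = "")
  NextMethod()
}
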