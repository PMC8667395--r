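#' Fixed gBOIN escalation and de-escalation boundaries
#'
#' The gBOIN design compares the observed mean toxicity \eqn{\hat\mu_j} at the
#' current dose against a fixed pair \eqn{(\lambda_e, \lambda_d)} obtained by
#' minimising the probability of an incorrect transition decision under three
#' equally likely point hypotheses \eqn{\mu_j \in \{\phi_1, \phi_0, \phi_2\}}:
#' \deqn{\lambda_e = \frac{A(\phi_1)-A(\phi_0)}{\eta(\phi_1)-\eta(\phi_0)},
#'       \qquad
#'       \lambda_d = \frac{A(\phi_2)-A(\phi_0)}{\eta(\phi_2)-\eta(\phi_0)}.}
#' For the (quasi-)binomial families this reduces to the classical BOIN
#' log-ratio boundaries; for the normal family it reduces to the arithmetic
#' midpoints \eqn{(\phi_0+\phi_k)/2}, independent of \eqn{\sigma}.
#'
#' Quasi-binary targets and hypothesis points are given in raw score units
#' (e.g. a target ETS of 0.47); the boundaries are computed on the normalised
#' quasi-Bernoulli scale and returned in raw score units.
#'
#' @param family A [tox_family][tox_binary].
#' @param target Target mean toxicity \eqn{\phi_0}.
#' @param phi1 Subtherapeutic hypothesis point (default \eqn{0.6\phi_0}).
#' @param phi2 Overly toxic hypothesis point (default \eqn{1.4\phi_0}).
#' @return A one-row tibble with `lambda_e`, `lambda_d` and `regime`
#'   (`"fixed_gboin"`).
#' @examples
#' gboin_boundaries(tox_binary(), target = 0.2)
#' gboin_boundaries(tox_normal(), target = 0.2)
#' @export
gboin_boundaries <- function(family, target, phi1 = 0.6 * target,
                             phi2 = 1.4 * target) {
  stopifnot(inherits(family, "tox_family"))
  if (phi1 == target || phi2 == target) {
    stop("degenerate hypotheses: `phi1` and `phi2` must differ from `target`",
         call. = FALSE)
  }
  if (!(phi1 < target && target < phi2)) {
    stop("need phi1 < target < phi2", call. = FALSE)
  }
  s <- score_scale(family)
  le <- s * lambda_pair(family, target / s, phi1 / s)
  ld <- s * lambda_pair(family, target / s, phi2 / s)
  tibble::tibble(lambda_e = le, lambda_d = ld, regime = "fixed_gboin")
}

# Eq.-3 quotient (A(phi_k) - A(phi_0)) / (eta(phi_k) - eta(phi_0)); sigma
# cancels for the normal family so sigma = 1 is used there.
lambda_pair <- function(family, phi0, phik) {
  t0 <- natural_terms(family, phi0, sigma = 1)
  tk <- natural_terms(family, phik, sigma = 1)
  (tk$A - t0$A) / (tk$eta - t0$eta)
}

#' Bayes-factor threshold schedule
#'
#' The gBOINS shrinkage boundaries use sample-size-dependent Bayes-factor
#' thresholds \eqn{\gamma_k(n) = \exp(c_k n^{\varepsilon_k})}, strictly
#' increasing in \eqn{n}. Larger \eqn{c_k} keeps the corresponding hypothesis
#' point further from the target (slower boundary shrinkage).
#'
#' @param c Positive schedule constant \eqn{c_k}.
#' @param eps Exponent \eqn{\varepsilon_k \in (0, 1)}.
#' @param n Per-dose sample size(s), \eqn{\ge 1}.
#' @return Numeric vector of thresholds.
#' @examples
#' gamma_schedule(log(1.1), 0.5, 9)  # 1.1^3
#' @export
gamma_schedule <- function(c, eps, n) {
  if (c <= 0) stop("`c` must be positive", call. = FALSE)
  if (eps <= 0 || eps >= 1) stop("`eps` must lie in (0, 1)", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  exp(c * n^eps)
}

#' Check the schedule constants against their admissibility bounds
#'
#' The consistency theory for the shrinkage design constrains the schedule
#' constants: \eqn{0 < c_1 < n^{1-\varepsilon_1}\log\{1/(1-\phi_0)\}} and
#' \eqn{c_1 < c_2 < n^{1-\varepsilon_2}\log(1/\phi_0)}. Violations are
#' reported as warnings, never errors: practically useful calibrations
#' (notably the safety-motivated ordering \eqn{c_1 > c_2}, which makes
#' de-escalation decisions easier than escalation decisions) sit outside the
#' asymptotic constraint set.
#'
#' @param target Target mean toxicity \eqn{\phi_0} (probability / normalised
#'   scale).
#' @param c1,c2 Schedule constants.
#' @param eps1,eps2 Schedule exponents.
#' @param n Per-dose sample size at which to evaluate the bounds.
#' @return (Invisibly) a character vector of violated constraints; each is
#'   also emitted as a warning.
#' @export
validate_schedule <- function(target, c1, c2, eps1 = 0.5, eps2 = 0.5, n) {
  msgs <- character()
  if (c1 <= 0) msgs <- c(msgs, "c1 must be positive")
  if (c2 <= 0) msgs <- c(msgs, "c2 must be positive")
  if (c1 > 0 && c1 >= n^(1 - eps1) * log(1 / (1 - target))) {
    msgs <- c(msgs, sprintf(
      "c1 = %.4g exceeds its bound n^(1-eps1) * log(1/(1-target)) = %.4g",
      c1, n^(1 - eps1) * log(1 / (1 - target))))
  }
  if (c1 > 0 && c2 > 0 && c1 >= c2) {
    msgs <- c(msgs, sprintf("c1 = %.4g is not smaller than c2 = %.4g", c1, c2))
  }
  if (c2 > 0 && c2 >= n^(1 - eps2) * log(1 / target)) {
    msgs <- c(msgs, sprintf(
      "c2 = %.4g exceeds its bound n^(1-eps2) * log(1/target) = %.4g",
      c2, n^(1 - eps2) * log(1 / target)))
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}

#' UMPBT objective for the alternative hypothesis point
#'
#' The uniformly most powerful Bayesian test chooses the alternative mean that
#' maximises the probability that the Bayes factor against
#' \eqn{H_0: \mu = \phi_0} exceeds a threshold \eqn{\gamma}. For exponential
#'-family data that probability is monotone in
#' \deqn{g_\gamma(\mu, \phi_0) =
#'   \frac{\log\gamma + n\{A(\mu) - A(\phi_0)\}}{\eta(\mu) - \eta(\phi_0)},}
#' so the subtherapeutic point maximises \eqn{g} over \eqn{\mu < \phi_0} and
#' the overly toxic point minimises it over \eqn{\mu > \phi_0}.
#'
#' Quasi-binary `mu`/`target` are taken in raw score units and normalised
#' internally; the returned objective value is in raw score units.
#'
#' @inheritParams gboin_boundaries
#' @param mu Candidate mean (must differ from `target`).
#' @param n Per-dose sample size.
#' @param gamma Bayes-factor threshold.
#' @param sigma Score SD (normal family).
#' @return Objective value in score units.
#' @export
g_gamma <- function(family, mu, target, n, gamma, sigma = NULL) {
  s <- score_scale(family)
  if (any(mu == target)) {
    stop("`mu` must differ from `target` (zero denominator)", call. = FALSE)
  }
  t0 <- natural_terms(family, target / s, sigma)
  tm <- natural_terms(family, mu / s, sigma)
  s * (log(gamma) + n * (tm$A - t0$A)) / (tm$eta - t0$eta)
}

#' Shrinking hypothesis points
#'
#' `optimal_phi1()` returns the subtherapeutic alternative
#' \eqn{\phi_1^*(n) < \phi_0} and `optimal_phi2()` the overly toxic
#' alternative \eqn{\phi_2^*(n) > \phi_0} of the uniformly most powerful
#' Bayesian test at threshold `gamma`. For the normal family the closed forms
#' \eqn{\phi_0 \mp \sigma\sqrt{2\log\gamma / n}} are used; for the
#' (quasi-)binomial families the objective [g_gamma()] is maximised
#' (minimised) numerically over the open interval between a small floor and
#' the target (the target and an upper ceiling), using golden-section search
#' seeded by a coarse grid scan.
#'
#' @inheritParams g_gamma
#' @return Scalar hypothesis point, in the units of `target`.
#' @examples
#' optimal_phi1(tox_normal(), 0.2, n = 9, gamma = 1.1^3, sigma = 0.22)
#' optimal_phi1(tox_binary(), 0.2, n = 9, gamma = 1.05^3)
#' @export
optimal_phi1 <- function(family, target, n, gamma, sigma = NULL) {
  optimal_phi(family, target, n, gamma, sigma, side = "lower")
}

#' @rdname optimal_phi1
#' @export
optimal_phi2 <- function(family, target, n, gamma, sigma = NULL) {
  optimal_phi(family, target, n, gamma, sigma, side = "upper")
}

optimal_phi <- function(family, target, n, gamma, sigma, side) {
  if (gamma < 1) stop("`gamma` must be >= 1", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  sgn <- if (side == "lower") -1 else 1
  if (family$kind == "normal") {
    if (is.null(sigma) || sigma <= 0) {
      stop("the normal family needs `sigma` > 0", call. = FALSE)
    }
    return(target + sgn * sigma * sqrt(2 * log(gamma) / n))
  }
  s <- score_scale(family)
  t0 <- target / s
  if (gamma == 1) return(target) # thresholdless test collapses onto the null
  floor_mu <- 1e-6
  if (side == "lower") {
    lo <- floor_mu
    hi <- t0 - 1e-6
  } else {
    lo <- t0 + 1e-6
    hi <- 1 - 1e-6
  }
  obj <- function(mu) {
    tt <- natural_terms(family, mu, sigma)
    tn <- natural_terms(family, t0, sigma)
    (log(gamma) + n * (tt$A - tn$A)) / (tt$eta - tn$eta)
  }
  # coarse scan brackets the optimum before golden-section refinement
  grid <- seq(lo, hi, length.out = 1001)
  v <- vapply(grid, obj, numeric(1))
  i <- if (side == "lower") which.max(v) else which.min(v)
  bl <- grid[max(1, i - 1)]
  bu <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, c(bl, bu), maximum = side == "lower",
                         tol = 1e-8)
  res <- if (side == "lower") opt$maximum else opt$minimum
  if (!is.finite(res)) {
    stop("hypothesis-point optimisation failed on (", lo, ", ", hi, ")",
         call. = FALSE)
  }
  s * res
}

#' Adaptive gBOINS boundaries at a given per-dose sample size
#'
#' During the lead-in (per-dose sample size \eqn{n \le N_0}) the fixed gBOIN
#' boundaries are used. Beyond it, the thresholds
#' \eqn{\gamma_k = \exp(c_k n^{\varepsilon_k})} define the shrinking
#' hypothesis points \eqn{\phi_1^*(n)}, \eqn{\phi_2^*(n)}
#' ([optimal_phi1()], [optimal_phi2()]) which replace \eqn{\phi_1},
#' \eqn{\phi_2} in the fixed-boundary formulas, giving a pair that closes in
#' on the target as evidence at the dose accumulates.
#'
#' @param design A [gboins_design()] (used for the target, hypothesis points,
#'   schedule constants, lead-in and sigma policy).
#' @param n Per-dose sample size, \eqn{\ge 1}.
#' @param sigma Optional SD override for the normal family; defaults to the
#'   design's plug-in value.
#' @return A one-row tibble: `n`, `lambda_e`, `lambda_d`, `phi1_star`,
#'   `phi2_star`, `regime`.
#' @export
shrinkage_boundaries <- function(design, n, sigma = NULL) {
  stopifnot(inherits(design, "gboins_design"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  fam <- design$family
  if (design$design == "gboin" || n <= design$n_lead) {
    fixed <- gboin_boundaries(fam, design$target, design$phi1, design$phi2)
    return(tibble::tibble(
      n = n, lambda_e = fixed$lambda_e, lambda_d = fixed$lambda_d,
      phi1_star = design$phi1, phi2_star = design$phi2,
      regime = "fixed_gboin"
    ))
  }
  g1 <- gamma_schedule(design$c1, design$eps1, n)
  g2 <- gamma_schedule(design$c2, design$eps2, n)
  if (fam$kind == "normal" && is.null(sigma)) sigma <- design_sigma(design)
  p1 <- optimal_phi1(fam, design$target, n, g1, sigma)
  p2 <- optimal_phi2(fam, design$target, n, g2, sigma)
  s <- score_scale(fam)
  if (fam$kind == "normal") {
    le <- (design$target + p1) / 2
    ld <- (design$target + p2) / 2
  } else {
    le <- s * lambda_pair(fam, design$target / s, p1 / s)
    ld <- s * lambda_pair(fam, design$target / s, p2 / s)
  }
  tibble::tibble(n = n, lambda_e = le, lambda_d = ld,
                 phi1_star = p1, phi2_star = p2, regime = "shrinkage")
}

#' Decision-boundary table over a grid of sample sizes
#'
#' Tabulates the active escalation/de-escalation boundaries for per-dose
#' sample sizes in `n_grid`, as used to pre-register a trial's decision rules.
#' Display columns round half-up to two decimals (the convention of published
#' boundary tables); the full-precision values drive in-trial decisions.
#'
#' @inheritParams shrinkage_boundaries
#' @param n_grid Ascending vector of per-dose sample sizes.
#' @return A tibble with one row per `n`: full-precision `lambda_e`,
#'   `lambda_d`, rounded `lambda_e_2dp`, `lambda_d_2dp`, and `regime`.
#' @examples
#' d <- gboins_design(tox_binary(), target = 0.3, n_max = 30,
#'                    preset = "tab-binary-0.3")
#' boundary_table(d, n_grid = seq(3, 30, by = 3))
#' @export
boundary_table <- function(design, n_grid = seq_len(design$n_max)) {
  if (length(n_grid) == 0 || is.unsorted(n_grid)) {
    stop("`n_grid` must be non-empty and ascending", call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(n_grid, function(n) {
    shrinkage_boundaries(design, n)
  }))
  dplyr::mutate(
    out,
    lambda_e_2dp = round_half_up(.data$lambda_e, 2),
    lambda_d_2dp = round_half_up(.data$lambda_d, 2)
  )[, c("n", "lambda_e", "lambda_d", "lambda_e_2dp", "lambda_d_2dp",
        "regime")]
}

#' Probability of an incorrect transition decision
#'
#' Evaluates the equally weighted error probability
#' \deqn{\alpha = \tfrac13\{P(\bar R \mid \mu=\phi_0) +
#'   P(\bar E \mid \mu=\phi_1) + P(\bar D \mid \mu=\phi_2)\}}
#' of a candidate boundary pair: failing to retain at the target, failing to
#' escalate at the subtherapeutic mean, failing to de-escalate at the overly
#' toxic mean. Uses exact binomial enumeration for the (quasi-)binomial
#' families and the Gaussian law of the sample mean for the normal family,
#' with the design's inclusive comparison conventions
#' (escalate iff \eqn{\hat\mu \le \lambda_e}, de-escalate iff
#' \eqn{\hat\mu \ge \lambda_d}). The fixed gBOIN boundaries minimise this
#' quantity — a property the test-suite verifies against a grid search.
#'
#' @inheritParams gboin_boundaries
#' @param lambda_e,lambda_d Candidate boundaries.
#' @param n Per-dose sample size.
#' @param sigma Score SD (normal family).
#' @return Scalar error probability.
#' @export
decision_error_rate <- function(family, lambda_e, lambda_d, target,
                                phi1, phi2, n, sigma = NULL) {
  if (lambda_e >= lambda_d) stop("need lambda_e < lambda_d", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (is_binomial_kind(family)) {
    p_wrong <- function(p, wrong) {
      y <- 0:n
      mu <- y / n
      sum(stats::dbinom(y, n, p)[wrong(mu)])
    }
    a0 <- p_wrong(target, function(m) m <= lambda_e | m >= lambda_d)
    a1 <- p_wrong(phi1, function(m) m > lambda_e)
    a2 <- p_wrong(phi2, function(m) m < lambda_d)
  } else {
    if (is.null(sigma) || sigma <= 0) {
      stop("the normal family needs `sigma` > 0", call. = FALSE)
    }
    se <- sigma / sqrt(n)
    a0 <- stats::pnorm(lambda_e, target, se) +
      stats::pnorm(lambda_d, target, se, lower.tail = FALSE)
    a1 <- stats::pnorm(lambda_e, phi1, se, lower.tail = FALSE)
    a2 <- stats::pnorm(lambda_d, phi2, se)
  }
  (a0 + a1 + a2) / 3
}
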