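#' Toxicity endpoint families
#'
#' A phase I toxicity endpoint is modelled as a one-parameter exponential
#' family \eqn{f(y) = h(y)\exp\{\eta(\theta) y - A(\theta)\}} indexed by the
#' mean toxicity value \eqn{\mu}. Three families are supported:
#'
#' * **binary** — the classical dose-limiting toxicity (DLT) indicator,
#'   Bernoulli with \eqn{\eta(\mu) = \mathrm{logit}(\mu)},
#'   \eqn{A(\mu) = -\log(1-\mu)};
#' * **quasi-binary** — an equivalent toxicity score (ETS) that maps each
#'   toxicity grade to a fraction of a DLT and is analysed through the
#'   quasi-Bernoulli likelihood, i.e. the Bernoulli \eqn{\eta}/\eqn{A} forms
#'   applied to the mean score. Because the quasi-Bernoulli likelihood lives
#'   on \eqn{[0,1]} while grade weights may exceed 1 (a grade-4 event counts
#'   as 1.5 DLT by default), all likelihood-based quantities are computed on
#'   the score scale divided by the maximum grade weight and mapped back to
#'   raw score units for reporting;
#' * **normal** — a continuous toxicity burden score (e.g. TTB, TBS, TTP or a
#'   transformed AUC), Gaussian with \eqn{\eta = \mu/\sigma^2},
#'   \eqn{A = \mu^2/(2\sigma^2)}.
#'
#' For the normal family a standard-deviation policy governs how \eqn{\sigma}
#' enters the adaptive boundary offsets:
#' `"plugin"` uses a fixed multiple of the target (default \eqn{1.1\phi_0},
#' which keeps in-trial boundaries equal to pre-tabulated ones), `"sample"`
#' uses the divisor-\eqn{n} sample estimate
#' \eqn{\hat\sigma = \sqrt{\sum (y_i-\hat\mu)^2 / n}} (falling back to the
#' plug-in when \eqn{n < 2} or \eqn{\hat\sigma = 0}), and `"posterior_mean"`
#' uses the posterior mean of \eqn{\sigma^2} under an inverse-gamma prior with
#' user-supplied shape `prior_shape` and rate `prior_rate`.
#'
#' @param grade_weights Named or unnamed numeric vector of scores, in DLT
#'   equivalents, for the grade categories (grades 0--1 merged, then grades
#'   2, 3, 4). Must be non-negative and non-decreasing.
#' @param sigma_policy How the normal-family SD is obtained; see Details.
#' @param plugin_value Plug-in SD in score units. `NULL` (default) means
#'   `1.1 * target`, resolved when a boundary is computed.
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters for
#'   `sigma_policy = "posterior_mean"`.
#'
#' @return An object of class `tox_family`.
#' @examples
#' tox_binary()
#' tox_quasibinary()
#' tox_normal(sigma_policy = "plugin")
#' @export
tox_binary <- function() {
  new_tox_family("binomial")
}

#' @rdname tox_binary
#' @export
tox_quasibinary <- function(grade_weights = c("0/1" = 0, "2" = 0.5,
                                              "3" = 1, "4" = 1.5)) {
  if (any(grade_weights < 0)) {
    stop("`grade_weights` must be non-negative", call. = FALSE)
  }
  if (is.unsorted(grade_weights)) {
    stop("`grade_weights` must be non-decreasing in grade severity",
         call. = FALSE)
  }
  if (max(grade_weights) <= 0) {
    stop("at least one grade weight must be positive", call. = FALSE)
  }
  if (is.null(names(grade_weights))) {
    names(grade_weights) <- c("0/1", "2", "3", "4")[seq_along(grade_weights)]
  }
  new_tox_family("quasi_binomial", grade_weights = grade_weights)
}

#' @rdname tox_binary
#' @export
tox_normal <- function(sigma_policy = c("plugin", "sample", "posterior_mean"),
                       plugin_value = NULL,
                       prior_shape = NULL, prior_rate = NULL) {
  sigma_policy <- match.arg(sigma_policy)
  if (!is.null(plugin_value) && plugin_value <= 0) {
    stop("`plugin_value` must be positive", call. = FALSE)
  }
  if (sigma_policy == "posterior_mean" &&
      (is.null(prior_shape) || is.null(prior_rate))) {
    stop("sigma_policy = \"posterior_mean\" requires `prior_shape` and ",
         "`prior_rate` (no defaults are assumed)", call. = FALSE)
  }
  new_tox_family("normal", sigma_policy = sigma_policy,
                 plugin_value = plugin_value,
                 prior_shape = prior_shape, prior_rate = prior_rate)
}

new_tox_family <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "tox_family")
}

#' @export
print.tox_family <- function(x, ...) {
  label <- switch(x$kind,
    binomial = "binary (DLT indicator)",
    quasi_binomial = "quasi-binary (equivalent toxicity score)",
    normal = "normal (continuous toxicity score)"
  )
  cat("<tox_family> ", label, "\n", sep = "")
  if (x$kind == "quasi_binomial") {
    cat("  grade weights: ",
        paste0(names(x$grade_weights), "=", x$grade_weights, collapse = ", "),
        "\n", sep = "")
  }
  if (x$kind == "normal") {
    cat("  sigma policy: ", x$sigma_policy, "\n", sep = "")
  }
  invisible(x)
}

# score divisor putting quasi-binary data on the [0, 1] quasi-Bernoulli scale
score_scale <- function(family) {
  if (family$kind == "quasi_binomial") max(family$grade_weights) else 1
}

is_binomial_kind <- function(family) {
  family$kind %in% c("binomial", "quasi_binomial")
}

#' Equivalent toxicity score of a grade
#'
#' Maps observed toxicity grades to their score in DLT-equivalent units using
#' the family's grade-weight table. With the default weights, grades 0--1 carry
#' no score, grade 2 counts as 0.5 DLT, grade 3 as 1 DLT and grade 4 as 1.5
#' DLT.
#'
#' @param grade Vector of grades; integers in 0--4 or labels matching the
#'   weight names (`"0/1"`, `"2"`, `"3"`, `"4"`).
#' @param family A quasi-binary [tox_family][tox_binary].
#' @return Numeric vector of scores.
#' @examples
#' ets_score(c(0, 2, 4), tox_quasibinary())
#' @export
ets_score <- function(grade, family = tox_quasibinary()) {
  if (family$kind != "quasi_binomial") {
    stop("`ets_score()` needs a quasi-binary endpoint family", call. = FALSE)
  }
  w <- family$grade_weights
  key <- as.character(grade)
  key[key %in% c("0", "1")] <- "0/1"
  bad <- !(key %in% names(w))
  if (any(bad)) {
    stop("unknown toxicity grade(s): ",
         paste(unique(grade[bad]), collapse = ", "), call. = FALSE)
  }
  unname(w[key])
}

#' Target score implied by a grade profile
#'
#' Computes the mean equivalent toxicity score of a probability profile over
#' the grade categories — the dot product of the profile with the grade
#' weights. Used to turn a clinically elicited target grade profile into the
#' target value \eqn{\phi_0} on the score scale.
#'
#' @param profile Probabilities over the grade categories (grades 0--1 merged,
#'   2, 3, 4); must sum to 1.
#' @inheritParams ets_score
#' @return Scalar target score in DLT equivalents.
#' @examples
#' # 49% grade 0-1, 18% grade 2, 23% grade 3, 10% grade 4
#' target_from_profile(c(0.49, 0.18, 0.23, 0.10))
#' @export
target_from_profile <- function(profile, family = tox_quasibinary()) {
  if (family$kind != "quasi_binomial") {
    stop("`target_from_profile()` needs a quasi-binary endpoint family",
         call. = FALSE)
  }
  w <- family$grade_weights
  if (length(profile) != length(w)) {
    stop("`profile` must have one entry per grade category (",
         length(w), ")", call. = FALSE)
  }
  s <- sum(profile)
  if (abs(s - 1) > 1e-9) {
    stop("`profile` must sum to 1 (got ", format(s, digits = 12), ")",
         call. = FALSE)
  }
  sum(profile * w)
}

#' Natural parameter and log-partition of an endpoint family
#'
#' Returns \eqn{\eta(\mu)} and \eqn{A(\mu)} for the family evaluated at a mean
#' toxicity value: \eqn{(\mathrm{logit}\,\mu,\; -\log(1-\mu))} for the
#' (quasi-)binomial families and \eqn{(\mu/\sigma^2,\; \mu^2/(2\sigma^2))} for
#' the normal family. All interval-design decisions depend only on differences
#' of these two functions, so the carrier \eqn{h(y)} is never evaluated.
#'
#' For the quasi-binomial family `mu` is interpreted on the normalised
#' \eqn{[0,1]} score scale (raw score divided by the maximum grade weight).
#'
#' @param family A [tox_family][tox_binary].
#' @param mu Mean toxicity value(s); in (0, 1) for (quasi-)binomial.
#' @param sigma Score SD (normal family only).
#' @return A list with numeric components `eta` and `A`.
#' @examples
#' natural_terms(tox_binary(), 0.5)
#' natural_terms(tox_normal(), 0.2, sigma = 1)
#' @export
natural_terms <- function(family, mu, sigma = NULL) {
  if (is_binomial_kind(family)) {
    if (any(mu <= 0 | mu >= 1)) {
      stop("`mu` must lie in (0, 1) for the (quasi-)binomial family",
           call. = FALSE)
    }
    list(eta = stats::qlogis(mu), A = -log1p(-mu))
  } else {
    if (is.null(sigma) || any(sigma <= 0)) {
      stop("the normal family needs `sigma` > 0", call. = FALSE)
    }
    list(eta = mu / sigma^2, A = mu^2 / (2 * sigma^2))
  }
}
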