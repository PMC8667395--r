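#' Trial design configuration
#'
#' Bundles every parameter needed to run a gBOIN or gBOINS dose-finding
#' trial: the endpoint family, the target toxicity value, the fixed
#' hypothesis points, the shrinkage schedule, trial-conduct settings and the
#' overdose-control rule.
#'
#' @param family A [tox_family][tox_binary].
#' @param target Target mean toxicity \eqn{\phi_0} (DLT probability, target
#'   ETS, or target continuous score).
#' @param n_max Maximum number of patients.
#' @param design `"gboins"` (adaptive shrinkage boundaries, the default) or
#'   `"gboin"` (fixed boundaries throughout).
#' @param n_doses Number of dose levels under investigation (may be omitted
#'   when the design is only used for boundary tabulation).
#' @param cohort_size Patients per cohort.
#' @param start_dose Starting dose level.
#' @param phi1,phi2 Fixed subtherapeutic / overly toxic hypothesis points.
#'   Defaults \eqn{0.6\phi_0} and \eqn{1.4\phi_0}, the interval-design
#'   convention, which also generate the published lead-in boundary cells.
#' @param c1,c2 Shrinkage schedule constants (see [gamma_schedule()]).
#'   Required for a gBOINS design unless `preset` supplies them.
#' @param eps1,eps2 Schedule exponents; the recommended value is 0.5.
#' @param n_lead Lead-in size \eqn{N_0}: the fixed gBOIN boundaries are used
#'   at a dose until more than `n_lead` patients have been treated there.
#' @param elim_threshold Posterior probability cutoff of the overdose-control
#'   rule (dose eliminated when \eqn{P(\mu_j > \phi_0 \mid D_j)} exceeds it).
#' @param elim_min_n Minimum per-dose sample size before elimination applies.
#' @param t_scale Scale convention of the normal-endpoint overdose posterior:
#'   `"sigma_hat"` (default) takes the posterior of \eqn{\mu_j} as a
#'   \eqn{t_{n-1}} law with scale \eqn{\hat\sigma = \sqrt{\sum(y_i-\hat\mu)^2/n}};
#'   `"sem"` uses the conventional noninformative-posterior scale
#'   \eqn{\hat\sigma/\sqrt{n}}.
#' @param preset Optional name of a packaged schedule-constant preset; see
#'   [design_presets()].
#' @return An object of class `gboins_design`.
#' @examples
#' gboins_design(tox_binary(), target = 0.2, n_max = 30,
#'               preset = "tab-binary-0.2")
#' @export
gboins_design <- function(family, target, n_max,
                          design = c("gboins", "gboin"),
                          n_doses = NULL,
                          cohort_size = 3, start_dose = 1,
                          phi1 = 0.6 * target, phi2 = 1.4 * target,
                          c1 = NULL, c2 = NULL,
                          eps1 = 0.5, eps2 = 0.5, n_lead = 6,
                          elim_threshold = 0.95, elim_min_n = 3,
                          t_scale = c("sigma_hat", "sem"),
                          preset = NULL) {
  stopifnot(inherits(family, "tox_family"))
  design <- match.arg(design)
  t_scale <- match.arg(t_scale)
  if (is_binomial_kind(family)) {
    smax <- score_scale(family)
    if (target <= 0 || target >= smax) {
      stop("`target` must lie in (0, ", smax, ") for this family",
           call. = FALSE)
    }
  } else if (target <= 0) {
    stop("`target` must be positive", call. = FALSE)
  }
  if (!(phi1 < target && target < phi2)) {
    stop("need phi1 < target < phi2", call. = FALSE)
  }
  if (!is.null(preset)) {
    ps <- design_presets()
    if (!preset %in% names(ps)) {
      stop("unknown preset \"", preset, "\"; see design_presets()",
           call. = FALSE)
    }
    if (is.null(c1)) c1 <- ps[[preset]]$c1
    if (is.null(c2)) c2 <- ps[[preset]]$c2
  }
  if (design == "gboins" && (is.null(c1) || is.null(c2))) {
    stop("a gBOINS design needs schedule constants `c1` and `c2` ",
         "(directly or via `preset`)", call. = FALSE)
  }
  if (!is.null(c1) && c1 <= 0) stop("`c1` must be positive", call. = FALSE)
  if (!is.null(c2) && c2 <= 0) stop("`c2` must be positive", call. = FALSE)
  if (!(eps1 < 1 && eps1 >= eps2 && eps2 > 0)) {
    stop("need 1 > eps1 >= eps2 > 0", call. = FALSE)
  }
  if (n_lead < 0 || n_lead != floor(n_lead)) {
    stop("`n_lead` must be a non-negative integer", call. = FALSE)
  }
  if (n_max < 1 || n_max %% cohort_size != 0) {
    stop("`n_max` must be a positive multiple of `cohort_size`",
         call. = FALSE)
  }
  if (!is.null(n_doses)) {
    if (n_doses < 1) stop("`n_doses` must be >= 1", call. = FALSE)
    if (start_dose < 1 || start_dose > n_doses) {
      stop("`start_dose` must be a valid dose level", call. = FALSE)
    }
  }
  if (elim_threshold <= 0.5 || elim_threshold >= 1) {
    stop("`elim_threshold` must lie in (0.5, 1)", call. = FALSE)
  }
  if (elim_min_n < 1) stop("`elim_min_n` must be >= 1", call. = FALSE)
  structure(
    list(family = family, target = as.numeric(target), design = design,
         n_doses = if (!is.null(n_doses)) as.integer(n_doses),
         n_max = as.integer(n_max), cohort_size = as.integer(cohort_size),
         start_dose = as.integer(start_dose),
         phi1 = as.numeric(phi1), phi2 = as.numeric(phi2),
         c1 = if (!is.null(c1)) as.numeric(c1),
         c2 = if (!is.null(c2)) as.numeric(c2),
         eps1 = as.numeric(eps1), eps2 = as.numeric(eps2),
         n_lead = as.integer(n_lead),
         elim_threshold = as.numeric(elim_threshold),
         elim_min_n = as.integer(elim_min_n),
         t_scale = t_scale),
    class = "gboins_design"
  )
}

#' Packaged schedule-constant presets
#'
#' Named \eqn{(c_1, c_2)} pairs. The `tab-*` presets generate the reference
#' decision-boundary tables for binary targets 0.2 / 0.3 and continuous
#' endpoints. The `sim-*` presets are the calibrated defaults for the
#' benchmark simulation studies; each also has a `-body` variant with the
#' constants transposed (\eqn{c_1 < c_2}, the ordering required by the
#' asymptotic consistency constraint, at the price of a de-escalation
#' boundary that shrinks more slowly — see the methods vignette for why the
#' safety ordering \eqn{c_1 > c_2} is the default).
#'
#' @return A named list of lists with components `c1` and `c2`.
#' @export
design_presets <- function() {
  list(
    `tab-binary-0.2`       = list(c1 = log(1.05), c2 = log(1.05) / 3),
    `tab-binary-0.3`       = list(c1 = log(1.1),  c2 = log(1.1) / 3),
    `tab-continuous`       = list(c1 = log(1.1),  c2 = log(1.1) / 3),
    `sim-binary-0.2`       = list(c1 = log(1.05) / 3, c2 = log(1.05) / 3),
    `sim-binary-0.3`       = list(c1 = log(1.1) / 3,  c2 = log(1.1) / 3),
    `sim-quasibinary`      = list(c1 = log(1.2),  c2 = log(1.2) / 3),
    `sim-quasibinary-body` = list(c1 = log(1.2) / 3, c2 = log(1.2)),
    `sim-continuous`       = list(c1 = log(1.1),  c2 = log(1.1) / 3),
    `sim-continuous-body`  = list(c1 = log(1.1) / 3, c2 = log(1.1))
  )
}

# resolve the normal-family plug-in SD (default 1.1 * target)
design_sigma <- function(design) {
  fam <- design$family
  if (fam$kind != "normal") return(NULL)
  if (!is.null(fam$plugin_value)) fam$plugin_value else 1.1 * design$target
}

#' @export
print.gboins_design <- function(x, ...) {
  cat("<gboins_design> ", toupper(x$design), "\n", sep = "")
  cat("  endpoint: ", x$family$kind, ", target ", x$target, "\n", sep = "")
  cat("  hypotheses: phi1 = ", signif(x$phi1, 4), ", phi2 = ",
      signif(x$phi2, 4), "\n", sep = "")
  if (x$design == "gboins") {
    cat("  schedule: c1 = ", signif(x$c1, 4), ", c2 = ", signif(x$c2, 4),
        ", eps = (", x$eps1, ", ", x$eps2, "), lead-in N0 = ", x$n_lead,
        "\n", sep = "")
  }
  cat("  conduct: n_max ", x$n_max, ", cohorts of ", x$cohort_size,
      ", start dose ", x$start_dose, "\n", sep = "")
  cat("  overdose control: posterior > ", x$elim_threshold, " with n >= ",
      x$elim_min_n, "\n", sep = "")
  invisible(x)
}
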