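#' Weighted isotonic regression by pooled adjacent violators
#'
#' Computes the weighted least-squares non-decreasing fit of a sequence of
#' per-dose means: the minimiser of \eqn{\sum_j w_j(\tilde\mu_j - \hat\mu_j)^2}
#' over non-decreasing \eqn{\tilde\mu}. Adjacent violators are pooled into
#' blocks whose fitted value is the weighted mean of their members.
#'
#' @param x Numeric vector of observed means, in dose order.
#' @param w Positive weights (typically the per-dose sample sizes).
#' @return Numeric vector of fitted values, same length as `x`.
#' @examples
#' pava(c(0.3, 0.1), w = c(3, 3))       # pooled to 0.2, 0.2
#' pava(c(0.0, 0.1, 0.3), w = c(3, 3, 3)) # already monotone
#' @export
pava <- function(x, w = rep(1, length(x))) {
  if (length(x) == 0) stop("`x` must be non-empty", call. = FALSE)
  if (length(w) != length(x)) {
    stop("`x` and `w` must have the same length", call. = FALSE)
  }
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  vals <- x
  wts <- w
  sizes <- rep(1L, length(x))
  k <- length(vals)
  i <- 1L
  while (i < k) {
    if (vals[i] > vals[i + 1] + 1e-15) {
      pooled_w <- wts[i] + wts[i + 1]
      vals[i] <- (vals[i] * wts[i] + vals[i + 1] * wts[i + 1]) / pooled_w
      wts[i] <- pooled_w
      sizes[i] <- sizes[i] + sizes[i + 1]
      vals <- vals[-(i + 1)]
      wts <- wts[-(i + 1)]
      sizes <- sizes[-(i + 1)]
      k <- k - 1L
      if (i > 1L) i <- i - 1L # pooling may create an upstream violation
    } else {
      i <- i + 1L
    }
  }
  rep(vals, sizes)
}

#' Isotonic per-dose toxicity estimates
#'
#' Applies [pava()] to the observed per-dose mean toxicity values, weighting
#' by per-dose sample size. Doses without patients are excluded from the fit
#' and returned with `mu_iso = NA`.
#'
#' @param dose_data A data frame with columns `dose`, `n`, `sum_y` (per-dose
#'   tallies as in [run_trial()] output).
#' @return A tibble with columns `dose`, `n`, `mu_hat`, `mu_iso`.
#' @export
isotonic_means <- function(dose_data) {
  dose_data <- tibble::as_tibble(dose_data)
  out <- dplyr::mutate(
    dose_data,
    mu_hat = ifelse(.data$n > 0, .data$sum_y / .data$n, NA_real_),
    mu_iso = NA_real_
  )
  use <- which(out$n > 0)
  if (length(use)) {
    out$mu_iso[use] <- pava(out$mu_hat[use], out$n[use])
  }
  out[, c("dose", "n", "mu_hat", "mu_iso")]
}

#' Select the maximum tolerated dose
#'
#' After the trial, the observed per-dose means are isotonically smoothed
#' ([pava()]) over the admissible doses with data, and the dose whose fitted
#' value is closest to the target is selected. Ties in distance are broken by
#' the published rules: among tied values below the target the highest dose
#' is taken; among tied values above the target the lowest dose. If an
#' equidistant tie straddles the target, the lower dose is preferred
#' (safety); fitted values exactly at the target tie to the lowest such dose.
#'
#' @param dose_data A data frame with columns `dose`, `n`, `sum_y`.
#' @param target Target mean toxicity \eqn{\phi_0} (same scale as `sum_y/n`).
#' @param admissible Optional logical vector (one entry per row of
#'   `dose_data`); non-admissible (eliminated) doses are never selected.
#' @return The selected dose level, or `NA` if no admissible dose has data.
#' @examples
#' d <- data.frame(dose = 1:3, n = c(3, 9, 6), sum_y = c(0, 2, 3))
#' select_mtd(d, target = 0.25)
#' @export
select_mtd <- function(dose_data, target, admissible = NULL) {
  dose_data <- tibble::as_tibble(dose_data)
  if (is.null(admissible)) admissible <- rep(TRUE, nrow(dose_data))
  use <- which(dose_data$n > 0 & admissible)
  if (!length(use)) return(NA_integer_)
  fit <- pava(dose_data$sum_y[use] / dose_data$n[use], dose_data$n[use])
  dist <- abs(fit - target)
  tied <- which(dist <= min(dist) + 1e-10)
  cand_dose <- dose_data$dose[use][tied]
  cand_fit <- fit[tied]
  below <- cand_fit < target - 1e-10
  above <- cand_fit > target + 1e-10
  if (any(below) && !any(above)) {
    cand_dose[max(which(below))]
  } else if (any(above) && !any(below)) {
    cand_dose[min(which(above))]
  } else if (any(below) && any(above)) {
    cand_dose[max(which(below))] # straddling tie: stay on the safe side
  } else {
    cand_dose[1] # fitted exactly at target
  }
}
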