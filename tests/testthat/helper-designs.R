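# shared designs and oracles used across test files

design_bin02 <- function(...) {
  gboins_design(tox_binary(), target = 0.2, n_max = 30,
                preset = "tab-binary-0.2", ...)
}

design_ets <- function(...) {
  gboins_design(tox_quasibinary(), target = 0.47, n_max = 30, n_doses = 6,
                preset = "sim-quasibinary", ...)
}

design_cont <- function(target = 0.2, n_max = 100, cohort_size = 1, ...) {
  gboins_design(tox_normal(), target = target, n_max = n_max, n_doses = 6,
                cohort_size = cohort_size, preset = "sim-continuous", ...)
}

# independent closed-form oracle for weighted isotonic regression:
# fit_j = max_{i<=j} min_{k>=j} weighted mean of x[i:k]
pava_maxmin_oracle <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(j) {
    max(vapply(1:j, function(i) {
      min(vapply(j:n, function(k) {
        sum(x[i:k] * w[i:k]) / sum(w[i:k])
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# BOIN interval boundaries coded directly from the log-ratio formulas,
# independent of the package's generic eta/A route
boin_oracle <- function(phi0, phi1, phi2) {
  le <- log((1 - phi1) / (1 - phi0)) /
    log(phi0 * (1 - phi1) / ((1 - phi0) * phi1))
  ld <- log((1 - phi0) / (1 - phi2)) /
    log(phi2 * (1 - phi0) / ((1 - phi2) * phi0))
  c(le, ld)
}
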