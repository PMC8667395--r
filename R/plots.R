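#' Plot decision boundaries against per-dose sample size
#'
#' Step plot of the escalation and de-escalation boundaries over a grid of
#' per-dose sample sizes, with the target as a reference line — the visual
#' signature of a shrinkage design is both curves closing in on the target.
#'
#' @param design A [gboins_design()].
#' @param n_grid Per-dose sample sizes to tabulate.
#' @return A ggplot object.
#' @export
plot_boundaries <- function(design, n_grid = seq_len(design$n_max)) {
  tab <- boundary_table(design, n_grid)
  long <- tidyr::pivot_longer(
    tab[, c("n", "lambda_e", "lambda_d")],
    cols = c("lambda_e", "lambda_d"),
    names_to = "boundary", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$boundary)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = design$target, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(lambda_e = "#2166ac", lambda_d = "#b2182b"),
      labels = c(lambda_e = "escalation", lambda_d = "de-escalation")
    ) +
    ggplot2::labs(x = "patients at current dose", y = "boundary (score)",
                  colour = NULL,
                  title = sprintf("%s decision boundaries, target %.2f",
                                  toupper(design$design), design$target)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dose-assignment path of a simulated trial
#'
#' @param object A `gboins_trial`.
#' @param ... Unused.
#' @return A ggplot object showing the dose given to each cohort, marking
#'   eliminations.
#' @method autoplot gboins_trial
#' @export
autoplot.gboins_trial <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$cohort, y = .data$dose)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$decision), size = 2) +
    ggplot2::geom_point(
      data = h[h$eliminated, , drop = FALSE],
      colour = "red", shape = 4, size = 4
    ) +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(object$dose_data))) +
    ggplot2::labs(x = "cohort", y = "dose level", shape = "decision",
                  title = if (is.na(object$mtd)) {
                    "trial terminated (no MTD)"
                  } else {
                    sprintf("selected MTD: dose %d", object$mtd)
                  }) +
    ggplot2::theme_minimal()
}

#' Selection and allocation summary plot
#'
#' @param object A `gboins_oc` from [operating_characteristics()].
#' @param ... Unused.
#' @return A ggplot object with per-dose selection percentages and average
#'   patient allocation; the true MTD is highlighted.
#' @method autoplot gboins_oc
#' @export
autoplot.gboins_oc <- function(object, ...) {
  pd <- tidy(object)
  long <- tidyr::pivot_longer(
    pd, cols = c("selection_pct", "n_avg"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, c("selection_pct", "n_avg"),
                        c("selection (%)", "avg. patients"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$dose), y = .data$value,
                                     fill = .data$is_mtd)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#2166ac"),
                               guide = "none") +
    ggplot2::labs(x = "dose level", y = NULL,
                  title = sprintf("%s: PCS %.1f%% (%d replicates)",
                                  toupper(object$design$design), object$pcs,
                                  object$n_reps)) +
    ggplot2::theme_minimal()
}
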