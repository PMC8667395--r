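#' Write and read a design configuration file
#'
#' Serialises a [gboins_design()] to a flat, human-readable YAML file and
#' reads it back. The round trip is exact: reading a written file reproduces
#' an identical design. Unknown keys in a file are errors (protocol-safety
#' posture: a misspelt parameter must not be silently ignored).
#'
#' @param design A [gboins_design()].
#' @param path File path.
#' @return `write_design_config()` returns `path` invisibly;
#'   `read_design_config()` returns a `gboins_design`.
#' @examples
#' d <- gboins_design(tox_binary(), target = 0.3, n_max = 30,
#'                    preset = "tab-binary-0.3")
#' f <- tempfile(fileext = ".yaml")
#' write_design_config(d, f)
#' identical(read_design_config(f), d)
#' @export
write_design_config <- function(design, path) {
  stopifnot(inherits(design, "gboins_design"))
  fam <- design$family
  cfg <- list(
    family = fam$kind,
    target = design$target,
    design = design$design,
    n_doses = design$n_doses,
    n_max = design$n_max,
    cohort_size = design$cohort_size,
    start_dose = design$start_dose,
    phi1 = design$phi1,
    phi2 = design$phi2,
    c1 = design$c1,
    c2 = design$c2,
    eps1 = design$eps1,
    eps2 = design$eps2,
    n_lead = design$n_lead,
    elim_threshold = design$elim_threshold,
    elim_min_n = design$elim_min_n,
    t_scale = design$t_scale
  )
  if (fam$kind == "quasi_binomial") {
    cfg$grade_weights <- as.list(fam$grade_weights)
  }
  if (fam$kind == "normal") {
    cfg$sigma_policy <- fam$sigma_policy
    cfg$sigma_plugin <- fam$plugin_value
    cfg$sigma_prior_shape <- fam$prior_shape
    cfg$sigma_prior_rate <- fam$prior_rate
  }
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  # doubles are written as full-precision strings so the round trip is exact
  fmt <- function(x) {
    if (is.list(x)) lapply(x, fmt)
    else if (is.double(x)) sprintf("%.17g", x)
    else x
  }
  yaml::write_yaml(lapply(cfg, fmt), path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("family", "target", "design", "n_doses", "n_max", "cohort_size",
             "start_dose", "phi1", "phi2", "c1", "c2", "eps1", "eps2",
             "n_lead", "elim_threshold", "elim_min_n", "t_scale",
             "grade_weights", "sigma_policy", "sigma_plugin",
             "sigma_prior_shape", "sigma_prior_rate", "preset")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num_keys <- c("target", "phi1", "phi2", "c1", "c2", "eps1", "eps2",
                "elim_threshold", "sigma_plugin", "sigma_prior_shape",
                "sigma_prior_rate")
  int_keys <- c("n_doses", "n_max", "cohort_size", "start_dose", "n_lead",
                "elim_min_n")
  for (k in intersect(names(cfg), num_keys)) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in intersect(names(cfg), int_keys)) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$grade_weights)) {
    cfg$grade_weights <- lapply(cfg$grade_weights, as.numeric)
  }
  req <- c("family", "target", "n_max")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("configuration is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  family <- switch(cfg$family,
    binomial = , binary = tox_binary(),
    quasi_binomial = , quasibinary = {
      if (is.null(cfg$grade_weights)) tox_quasibinary() else {
        tox_quasibinary(unlist(cfg$grade_weights))
      }
    },
    normal = , continuous = tox_normal(
      sigma_policy = cfg$sigma_policy %||% "plugin",
      plugin_value = cfg$sigma_plugin,
      prior_shape = cfg$sigma_prior_shape,
      prior_rate = cfg$sigma_prior_rate
    ),
    stop("unknown family \"", cfg$family, "\"", call. = FALSE)
  )
  args <- list(
    family = family, target = cfg$target, n_max = cfg$n_max,
    design = cfg$design %||% "gboins",
    n_doses = cfg$n_doses,
    cohort_size = cfg$cohort_size %||% 3,
    start_dose = cfg$start_dose %||% 1,
    c1 = cfg$c1, c2 = cfg$c2,
    eps1 = cfg$eps1 %||% 0.5, eps2 = cfg$eps2 %||% 0.5,
    n_lead = cfg$n_lead %||% 6,
    elim_threshold = cfg$elim_threshold %||% 0.95,
    elim_min_n = cfg$elim_min_n %||% 3,
    t_scale = cfg$t_scale %||% "sigma_hat",
    preset = cfg$preset
  )
  if (!is.null(cfg$phi1)) args$phi1 <- cfg$phi1
  if (!is.null(cfg$phi2)) args$phi2 <- cfg$phi2
  do.call(gboins_design, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference decision-boundary tables
#'
#' Regenerates the four standard boundary blocks — (quasi-)Bernoulli and
#' continuous endpoints at targets 0.2 and 0.3 — over per-dose sample sizes
#' 3, 6, ..., 30, with the tabulation constants (`tab-*` presets),
#' \eqn{\phi_1 = 0.6\phi_0}, \eqn{\phi_2 = 1.4\phi_0}, lead-in
#' \eqn{N_0 = 6}, \eqn{\varepsilon_k = 0.5} and continuous plug-in
#' \eqn{\sigma = 1.1\phi_0}.
#'
#' @param out_path Optional CSV path to write the table to.
#' @return A tibble with columns `endpoint`, `target`, `n`, full-precision
#'   and 2-dp boundary columns, and `regime`.
#' @export
report_boundary_tables <- function(out_path = NULL) {
  n_grid <- seq(3, 30, by = 3)
  blocks <- list(
    list(endpoint = "bernoulli", target = 0.2, family = tox_binary(),
         preset = "tab-binary-0.2"),
    list(endpoint = "bernoulli", target = 0.3, family = tox_binary(),
         preset = "tab-binary-0.3"),
    list(endpoint = "continuous", target = 0.2, family = tox_normal(),
         preset = "tab-continuous"),
    list(endpoint = "continuous", target = 0.3, family = tox_normal(),
         preset = "tab-continuous")
  )
  out <- dplyr::bind_rows(lapply(blocks, function(b) {
    d <- gboins_design(b$family, target = b$target, n_max = 30,
                       preset = b$preset)
    tab <- boundary_table(d, n_grid)
    dplyr::bind_cols(tibble::tibble(endpoint = b$endpoint,
                                    target = b$target)[rep(1, nrow(tab)), ],
                     tab)
  }))
  if (!is.null(out_path)) {
    utils::write.csv(out, out_path, row.names = FALSE)
  }
  out
}

#' Write an operating-characteristics comparison report
#'
#' Formats one or more [operating_characteristics()] results as the standard
#' two-row-per-design blocks (selection percentage, then average patients
#' treated, per dose) and writes matching CSV and JSON files.
#'
#' @param results A named list of `gboins_oc` objects (names label the rows,
#'   e.g. `list(gBOIN = ..., gBOINS = ...)`).
#' @param out_path Output path without extension, or ending in `.csv`;
#'   `.csv` and `.json` files are written. `NULL` writes nothing.
#' @return The report tibble (invisibly when writing).
#' @export
report_oc <- function(results, out_path = NULL) {
  if (!length(results)) stop("`results` must be non-empty", call. = FALSE)
  if (is.null(names(results))) {
    names(results) <- paste0("design", seq_along(results))
  }
  rows <- dplyr::bind_rows(lapply(names(results), function(nm) {
    oc <- results[[nm]]
    pd <- tidy(oc)
    wide <- function(vals, metric) {
      out <- tibble::as_tibble(as.list(stats::setNames(
        round(vals, 2), paste0("d", pd$dose))))
      dplyr::bind_cols(tibble::tibble(design = nm, metric = metric), out)
    }
    dplyr::bind_rows(
      wide(pd$selection_pct, "selection_pct"),
      wide(pd$n_avg, "avg_n_treated")
    )
  }))
  if (!is.null(out_path)) {
    base <- sub("\\.csv$", "", out_path)
    utils::write.csv(rows, paste0(base, ".csv"), row.names = FALSE)
    jsonlite::write_json(rows, paste0(base, ".json"), digits = NA,
                         dataframe = "rows")
    return(invisible(rows))
  }
  rows
}
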