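# Hill-equation fitting of normalized agonist dose-response curves and
# group comparison of fitted EC50 values (wild-type vs mutant).

as_curve_df <- function(curve) {
  if (!all(c("concentration_uM", "current") %in% names(curve))) {
    stop("curve needs columns `concentration_uM` and `current`", call. = FALSE)
  }
  curve
}

#' Normalize a dose-response curve
#'
#' Divides currents by the observed maximum (default) or by the fitted
#' maximal response of a preliminary Hill fit.
#'
#' @param curve data.frame with `concentration_uM` and `current`.
#' @param mode `"observed"` (max current) or `"fitted"` (Hill Imax).
#' @return The curve with `current` rescaled and a `normalized` attribute.
#' @export
normalize_curve <- function(curve, mode = c("observed", "fitted")) {
  mode <- match.arg(mode)
  curve <- as_curve_df(curve)
  if (isTRUE(attr(curve, "normalized"))) return(curve)
  mx <- if (mode == "observed") {
    max(curve$current)
  } else {
    fit_hill(curve, .normalized_check = FALSE)$imax
  }
  if (!is.finite(mx) || mx <= 0) {
    stop("maximum current must be positive to normalize", call. = FALSE)
  }
  curve$current <- curve$current / mx
  attr(curve, "normalized") <- TRUE
  curve
}

#' Fit a Hill function to a dose-response curve
#'
#' Least-squares fit of `I(c) = imax * c^h / (ec50^h + c^h)` on the linear
#' response scale (Levenberg-Marquardt), initialized at `ec50` = geometric
#' mean of the concentrations, `h` = 1, `imax` = maximal response; the
#' Hill coefficient is bounded to (0.2, 5). Non-convergence is flagged on
#' the returned fit, not silently dropped.
#'
#' @param curve data.frame with `concentration_uM` and `current` (>= 4
#'   concentrations).
#' @param .normalized_check internal.
#' @return A `hill_fit`: `ec50` (uM), `hill`, `imax`,
#'   `residual_sum_squares`, `converged`, `n`.
#' @export
fit_hill <- function(curve, .normalized_check = TRUE) {
  curve <- as_curve_df(curve)
  conc <- curve$concentration_uM
  resp <- curve$current
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations to fit", call. = FALSE)
  }
  start <- list(imax = max(resp), ec50 = geometric_mean(unique(conc)), h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ imax * conc^h / (ec50^h + conc^h),
      start = start,
      lower = c(imax = 1e-8, ec50 = 1e-8, h = 0.2),
      upper = c(imax = Inf, ec50 = Inf, h = 5),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_, imax = NA_real_,
                          residual_sum_squares = NA_real_, converged = FALSE,
                          n = length(conc), message = conditionMessage(fit)),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(ec50 = unname(cf["ec50"]), hill = unname(cf["h"]),
                 imax = unname(cf["imax"]),
                 residual_sum_squares = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 n = length(conc)),
            class = "hill_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("hill_fit: NOT CONVERGED\n")
  } else {
    cat(sprintf("hill_fit: EC50 = %.4g uM, h = %.3g, Imax = %.4g (RSS %.3g)\n",
                x$ec50, x$hill, x$imax, x$residual_sum_squares))
  }
  invisible(x)
}

#' Fit Hill functions to every curve of a replicate set
#'
#' @param curves data.frame with `curve_id`, `concentration_uM`, `current`
#'   (as produced by [generate_dose_response()]).
#' @param normalize normalize each curve before fitting (default TRUE).
#' @return list of `hill_fit` objects, one per curve.
#' @export
fit_hill_curves <- function(curves, normalize = TRUE) {
  ids <- unique(curves$curve_id)
  lapply(ids, function(i) {
    cv <- curves[curves$curve_id == i, ]
    if (normalize) cv <- normalize_curve(cv)
    fit_hill(cv)
  })
}

#' Compare EC50 between two groups of Hill fits
#'
#' Two-sample Student's t-test (equal variance) on per-curve EC50 values,
#' with group means, standard errors and percent change. Optionally tests
#' on the log-EC50 scale.
#'
#' @param fits_a,fits_b lists of `hill_fit` objects (>= 2 converged fits
#'   each). Group A is the reference (percent change is B relative to A).
#' @param log_scale run the t-test on log(EC50) (default FALSE: the plain
#'   Student's t on raw EC50).
#' @return A `group_comparison`: `mean_a`, `sem_a`, `n_a`, `mean_b`,
#'   `sem_b`, `n_b`, `percent_change`, `t_statistic`, `p_value`,
#'   `log_scale`.
#' @export
compare_groups <- function(fits_a, fits_b, log_scale = FALSE) {
  ec <- function(fits) {
    v <- vapply(fits, function(f) if (isTRUE(f$converged)) f$ec50 else NA_real_,
                numeric(1))
    v[is.finite(v)]
  }
  a <- ec(fits_a)
  b <- ec(fits_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop(sprintf("need >= 2 converged fits per group (got %d and %d)",
                 length(a), length(b)), call. = FALSE)
  }
  tt <- if (log_scale) {
    stats::t.test(log(b), log(a), var.equal = TRUE)
  } else {
    stats::t.test(b, a, var.equal = TRUE)
  }
  structure(list(
    mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)), n_a = length(a),
    mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)), n_b = length(b),
    percent_change = 100 * (mean(b) - mean(a)) / mean(a),
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    log_scale = log_scale
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison: A %.3g +/- %.2g uM (n=%d) vs B %.3g +/- %.2g uM (n=%d)\n",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("  change %+.1f%%, t = %.3g, p = %.3g%s\n", x$percent_change,
              x$t_statistic, x$p_value,
              if (x$log_scale) " (log scale)" else ""))
  invisible(x)
}

#' Summary table for a dose-response group comparison
#' @param comparison a `group_comparison`.
#' @param labels group labels (length 2).
#' @export
doseresponse_summary <- function(comparison, labels = c("WT", "mutant")) {
  data.frame(
    group = labels,
    n = c(comparison$n_a, comparison$n_b),
    mean_ec50_uM = c(comparison$mean_a, comparison$mean_b),
    sem = c(comparison$sem_a, comparison$sem_b),
    percent_change = c(0, comparison$percent_change),
    t = c(NA, comparison$t_statistic),
    p = c(NA, comparison$p_value)
  )
}
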