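# Binned probability densities of the clamshell coordinate, MSM equilibrium
# reweighting, and percentile-bootstrap comparison of two conditions.
# Resampling is at the whole-trajectory level: frames within a trajectory
# are autocorrelated, so the trajectory is the defensible exchangeable unit.

# Bin edges on a lattice aligned to multiples of `width` covering `range`.
aligned_breaks <- function(range, width) {
  lo <- floor(range[1L] / width) * width
  hi <- ceiling(range[2L] / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi + width / 2, by = width)
}

#' Binned probability density of a scalar ensemble
#'
#' Uniform-width bins (default 0.1 nm) aligned to the bin-width lattice.
#' Optional per-frame weights produce a weighted density. The emitted
#' density integrates to 1.
#'
#' @param values numeric vector (nm), or a `trajectory_ensemble`.
#' @param bin_width bin width, nm.
#' @param breaks optional explicit bin edges (overrides `bin_width` range
#'   alignment).
#' @param weights optional per-frame nonnegative weights.
#' @param weighting label stored on the result (`"raw"` or
#'   `"msm-reweighted"`).
#' @return A `binned_pdf`: `breaks`, `density` (1/nm), `bin_width`,
#'   `weighting`.
#' @export
binned_pdf <- function(values, bin_width = 0.1, breaks = NULL, weights = NULL,
                       weighting = "raw") {
  if (inherits(values, "trajectory_ensemble")) values <- unlist(values$d)
  if (is.null(breaks)) breaks <- aligned_breaks(range(values), bin_width)
  nb <- length(breaks) - 1L
  bi <- findInterval(values, breaks, rightmost.closed = TRUE)
  inside <- bi >= 1L & bi <= nb
  if (!all(inside)) {
    message(sprintf("binned_pdf: %d of %d frames outside the bin range dropped",
                    sum(!inside), length(values)))
  }
  w <- if (is.null(weights)) rep(1, length(values)) else weights
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  mass <- vapply(seq_len(nb), function(b) sum(w[inside & bi == b]), numeric(1))
  widths <- diff(breaks)
  dens <- mass / sum(mass) / widths
  structure(list(breaks = breaks, density = dens, bin_width = widths[1L],
                 weighting = weighting),
            class = "binned_pdf")
}

#' MSM-reweighted probability density of the clamshell coordinate
#'
#' Recovers the equilibrium density from finite trajectories: every frame in
#' discrete state i receives weight `pi_i / n_i` (stationary probability of
#' its state divided by the number of frames observed in it), so each
#' state's total weight equals its equilibrium probability. Frames whose
#' state fell outside the model's active (ergodically trimmed) set are
#' dropped with a logged count.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param dtrajs list of label vectors aligned one-to-one with
#'   `ensemble$d`.
#' @param model an `msmodel`.
#' @param bin_width bin width, nm.
#' @param breaks optional explicit bin edges.
#' @return A `binned_pdf` with weighting `"msm-reweighted"`.
#' @export
reweighted_pdf <- function(ensemble, dtrajs, model, bin_width = 0.1,
                           breaks = NULL) {
  d <- unlist(ensemble$d)
  lab <- unlist(dtrajs)
  if (length(d) != length(lab)) {
    stop("labels do not align one-to-one with ensemble frames", call. = FALSE)
  }
  active <- model$active_set
  pos <- match(lab, active)           # NA for frames in trimmed states
  keep <- !is.na(pos)
  if (!any(keep)) {
    stop("no overlap between the model's active set and the labels",
         call. = FALSE)
  }
  if (any(!keep)) {
    message(sprintf("reweighted_pdf: %d frames in trimmed states dropped",
                    sum(!keep)))
  }
  n_in_state <- tabulate(pos[keep], nbins = length(active))
  w <- model$pi[pos[keep]] / n_in_state[pos[keep]]
  binned_pdf(d[keep], bin_width = bin_width, breaks = breaks, weights = w,
             weighting = "msm-reweighted")
}

# per-trajectory bin counts on a shared grid (rows = trajectories)
traj_bin_counts <- function(d_list, breaks) {
  nb <- length(breaks) - 1L
  t(vapply(d_list, function(v) {
    bi <- findInterval(v, breaks, rightmost.closed = TRUE)
    tabulate(bi[bi >= 1L & bi <= nb], nbins = nb)
  }, numeric(nb)))
}

counts_to_density <- function(counts, widths) {
  counts / sum(counts) / widths
}

#' Percentile-bootstrap comparison of two conformational distributions
#'
#' Estimates the per-bin difference in probability density between two
#' trajectory ensembles (A minus B) and its percentile-bootstrap confidence
#' interval. Each bootstrap replicate redraws whole trajectories with
#' replacement, independently within each ensemble, recomputes both
#' densities and differences them per bin; the CI is the empirical
#' (alpha/2, 1 - alpha/2) quantile band. Bins whose CI excludes 0 are
#' flagged significant (no multiple-testing correction across bins; see the
#' metadata field).
#'
#' @param ensemble_a,ensemble_b `trajectory_ensemble`s (>= 2 trajectories
#'   each).
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed integer seed.
#' @param bin_width bin width, nm.
#' @param breaks optional shared bin edges.
#' @return A `bootstrap_result`: `table` (data.frame bin_lo_nm, bin_hi_nm,
#'   pdf_a, pdf_b, diff, ci_lo, ci_hi, significant), `level`, `n_boot`,
#'   `seed`, `valid` (FALSE when `n_boot < 2` makes the CI degenerate),
#'   `multiple_testing` = "none".
#' @export
pdf_difference_bootstrap <- function(ensemble_a, ensemble_b, n_boot = 1000L,
                                     level = 0.95, seed = 1L,
                                     bin_width = 0.1, breaks = NULL) {
  if (length(ensemble_a$d) < 2L || length(ensemble_b$d) < 2L) {
    stop("both ensembles need at least 2 trajectories", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (is.null(breaks)) {
    breaks <- aligned_breaks(range(unlist(ensemble_a$d), unlist(ensemble_b$d)),
                             bin_width)
  }
  widths <- diff(breaks)
  ca <- traj_bin_counts(ensemble_a$d, breaks)
  cb <- traj_bin_counts(ensemble_b$d, breaks)
  pdf_a <- counts_to_density(colSums(ca), widths)
  pdf_b <- counts_to_density(colSums(cb), widths)
  est <- pdf_a - pdf_b
  na <- nrow(ca); nb_ <- nrow(cb)
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = length(est))
    for (r in seq_len(n_boot)) {
      repeat {
        sa <- colSums(ca[sample.int(na, na, replace = TRUE), , drop = FALSE])
        sb <- colSums(cb[sample.int(nb_, nb_, replace = TRUE), , drop = FALSE])
        if (sum(sa) > 0 && sum(sb) > 0) break
        message("pdf_difference_bootstrap: replicate with zero in-range frames regenerated")
      }
      out[r, ] <- counts_to_density(sa, widths) - counts_to_density(sb, widths)
    }
    out
  })
  alpha <- 1 - level
  ci <- apply(reps, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  valid <- n_boot >= 2L
  if (!valid) {
    warning("n_boot < 2: confidence interval is degenerate; result flagged invalid")
  }
  significant <- valid & (ci[1L, ] > 0 | ci[2L, ] < 0)
  tab <- data.frame(
    bin_lo_nm = breaks[-length(breaks)], bin_hi_nm = breaks[-1L],
    pdf_a = pdf_a, pdf_b = pdf_b, diff = est,
    ci_lo = ci[1L, ], ci_hi = ci[2L, ],
    significant = as.integer(significant)
  )
  structure(list(table = tab, level = level, n_boot = n_boot,
                 seed = as.integer(seed), valid = valid,
                 multiple_testing = "none"),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d bins, level %.2f, n_boot %d%s\n",
              nrow(x$table), x$level, x$n_boot,
              if (x$valid) "" else " [INVALID: degenerate CI]"))
  sig <- x$table[x$table$significant == 1L, ]
  if (nrow(sig) > 0L) {
    cat("significant bins (nm):",
        paste(sprintf("[%.2f,%.2f]", sig$bin_lo_nm, sig$bin_hi_nm),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Analytic binned density of a two-state spec
#'
#' Equilibrium density of the Gaussian-mixture emission integrated over
#' `[lo, hi]`, divided by the bin width.
#' @param spec a [two_state_spec()].
#' @param lo,hi bin edges, nm.
#' @export
analytic_bin_density <- function(spec, lo, hi) {
  pc <- closed_fraction(spec)
  mass_c <- stats::pnorm(hi, spec$mean_closed, spec$sd_closed) -
    stats::pnorm(lo, spec$mean_closed, spec$sd_closed)
  mass_o <- stats::pnorm(hi, spec$mean_open, spec$sd_open) -
    stats::pnorm(lo, spec$mean_open, spec$sd_open)
  (pc * mass_c + (1 - pc) * mass_o) / (hi - lo)
}

#' Empirical coverage of the percentile-bootstrap interval
#'
#' Simulates many independent two-state ensembles with known analytic bin
#' density, computes for each the percentile-bootstrap CI of the requested
#' bin's density (trajectory-level resampling), and reports the fraction of
#' ensembles whose CI covers the analytic truth.
#'
#' @param spec a [two_state_spec()] defining each simulated ensemble.
#' @param n_ensembles number of independent ensembles.
#' @param n_boot bootstrap replicates per ensemble.
#' @param seed integer seed.
#' @param level confidence level.
#' @param bins two-column matrix (or length-2 vector) of bin edges (nm);
#'   default the central closed-basin bin `[mean_closed - bin/2,
#'   mean_closed + bin/2]` with 0.1 nm width.
#' @return data.frame with `bin_lo_nm`, `bin_hi_nm`, `true_density`,
#'   `coverage`.
#' @export
bootstrap_coverage_check <- function(spec, n_ensembles = 500L, n_boot = 200L,
                                     seed = 1L, level = 0.95, bins = NULL) {
  if (is.null(bins)) {
    bins <- matrix(c(spec$mean_closed - 0.05, spec$mean_closed + 0.05),
                   nrow = 1L)
  }
  if (is.null(dim(bins))) bins <- matrix(bins, ncol = 2L, byrow = TRUE)
  truth <- vapply(seq_len(nrow(bins)),
                  function(i) analytic_bin_density(spec, bins[i, 1L], bins[i, 2L]),
                  numeric(1))
  alpha <- 1 - level
  nt <- spec$n_traj
  nf <- spec$n_frames
  covered <- matrix(FALSE, nrow = n_ensembles, ncol = nrow(bins))
  for (e in seq_len(n_ensembles)) {
    sp <- spec
    sp$seed <- child_seed(seed, e)
    ens <- generate_two_state_ensemble(sp)
    # per-trajectory in-bin densities; the ensemble estimate is their mean
    # (all trajectories have equal frame counts)
    for (b in seq_len(nrow(bins))) {
      lo <- bins[b, 1L]; hi <- bins[b, 2L]
      per_traj <- vapply(ens$d, function(v) {
        mean(v >= lo & v < hi) / (hi - lo)
      }, numeric(1))
      ci <- with_seed(child_seed(seed, e) + 500000L, {
        means <- vapply(seq_len(n_boot), function(r) {
          mean(per_traj[sample.int(nt, nt, replace = TRUE)])
        }, numeric(1))
        stats::quantile(means, probs = c(alpha / 2, 1 - alpha / 2),
                        names = FALSE)
      })
      covered[e, b] <- ci[1L] <= truth[b] && truth[b] <= ci[2L]
    }
  }
  data.frame(bin_lo_nm = bins[, 1L], bin_hi_nm = bins[, 2L],
             true_density = truth, coverage = colMeans(covered))
}

#' Write a bootstrap comparison table as TSV
#' @param result a `bootstrap_result`.
#' @param path output file.
#' @export
write_bootstrap_tsv <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
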