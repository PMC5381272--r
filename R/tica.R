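# Time-lagged independent component analysis: linear components maximizing
# autocorrelation at a lag, whose eigenvalues translate into relaxation
# timescales exactly as MSM eigenvalues do.

#' Time-lagged independent component analysis of feature trajectories
#'
#' The feature mean is taken over all frames of all usable trajectories
#' (those with at least `lag_frames + 1` frames). The instantaneous
#' covariance C0 averages the mean-free outer products over all frames; the
#' time-lagged covariance averages over all intra-trajectory pairs at the
#' lag (no cross-trajectory pairs) and is symmetrized. The generalized
#' eigenproblem `Ctau v = lambda C0 v` is solved through a Cholesky
#' factorization of `C0 + eps I`. Timescales are `-lag / log(lambda)` for
#' eigenvalues strictly inside (0, 1); eigenvalues at or below 0 (e.g.
#' perfectly anticorrelated input) are flagged undefined.
#'
#' @param x a `trajectory_ensemble` or list of per-trajectory feature
#'   vectors/matrices (frames in rows).
#' @param lag_frames lag in frames.
#' @param dt frame spacing, ns (taken from the ensemble when available).
#' @param eps ridge added to C0 before factorization (error if C0 is
#'   singular beyond this regularization).
#' @return A `tica_model`: `eigenvalues` (sorted descending),
#'   `timescales_ns`, `defined`, `components` (columns = tICs), `mean`,
#'   `lag_ns`, `c0`, `ctau`.
#' @export
tica_timescales <- function(x, lag_frames, dt = NULL, eps = 1e-10) {
  feats <- ensemble_feature_list(x)
  if (is.null(dt)) {
    dt <- if (inherits(x, "trajectory_ensemble")) x$dt else 0.2
  }
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1L) stop("`lag_frames` must be >= 1", call. = FALSE)
  usable <- vapply(feats, nrow, integer(1)) > lag_frames
  if (!any(usable)) stop("no trajectory longer than the lag", call. = FALSE)
  feats <- feats[usable]
  p <- ncol(feats[[1L]])
  m <- colMeans(do.call(rbind, feats))
  c0 <- matrix(0, p, p); n0 <- 0L
  ct <- matrix(0, p, p); nt <- 0L
  for (f in feats) {
    fc <- sweep(f, 2L, m)
    c0 <- c0 + crossprod(fc)
    n0 <- n0 + nrow(fc)
    L <- nrow(fc)
    head_ <- fc[seq_len(L - lag_frames), , drop = FALSE]
    tail_ <- fc[(lag_frames + 1L):L, , drop = FALSE]
    ct <- ct + crossprod(head_, tail_)
    nt <- nt + nrow(head_)
  }
  c0 <- c0 / n0
  ct <- (ct + t(ct)) / (2 * nt)
  ch <- tryCatch(chol(c0 + diag(eps, p)),
                 error = function(e) stop(
                   sprintf("instantaneous covariance is singular; increase the regularization epsilon (currently %g)", eps),
                   call. = FALSE))
  W <- backsolve(ch, diag(p), transpose = TRUE)     # W = L^-1 with c0 = L'L
  Sm <- W %*% ct %*% t(W)
  Sm <- (Sm + t(Sm)) / 2
  es <- eigen(Sm, symmetric = TRUE)
  lambda <- es$values
  comps <- t(W) %*% es$vectors
  defined <- lambda > 0 & lambda < 1
  ts <- rep(NA_real_, p)
  ts[defined] <- -lag_frames * dt / log(lambda[defined])
  ts[lambda >= 1] <- Inf
  structure(list(eigenvalues = lambda, timescales_ns = ts,
                 defined = defined | lambda >= 1, components = comps,
                 mean = m, lag_ns = lag_frames * dt, c0 = c0, ctau = ct),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: %d components, lag %g ns\n",
              length(x$eigenvalues), x$lag_ns))
  cat("leading eigenvalue:", signif(x$eigenvalues[1L], 6),
      " timescale (ns):", signif(x$timescales_ns[1L], 6), "\n")
  invisible(x)
}
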