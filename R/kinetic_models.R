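# Markov state model machinery: k-means discretization of order-parameter
# trajectories, sliding-window transition counting, ergodic trimming,
# non-reversible and detailed-balance maximum-likelihood transition-matrix
# estimation, and implied timescales.

ensemble_feature_list <- function(x) {
  if (inherits(x, "trajectory_ensemble")) {
    lapply(x$d, function(v) matrix(v, ncol = 1L))
  } else if (is.list(x)) {
    lapply(x, function(v) if (is.matrix(v)) v else matrix(v, ncol = 1L))
  } else {
    stop("expected a trajectory_ensemble or a list of feature vectors/matrices",
         call. = FALSE)
  }
}

# k-means++-style seeding: first centre drawn uniformly, subsequent centres
# drawn with probability proportional to squared distance to the nearest
# chosen centre; ties broken by lowest index.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1L) {
    for (j in 2:k) {
      tot <- sum(d2)
      idx <- if (tot <= 0) {
        which.max(d2)  # all residual distances zero: lowest index via which.max
      } else {
        u <- stats::runif(1L) * tot
        min(which(cumsum(d2) >= u))
      }
      centers[j, ] <- x[idx, ]
      nd2 <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  centers
}

# Nearest-centre assignment for 1-D data via interval search on sorted
# centres (exact, O(n log k)).
assign_nearest_1d <- function(v, centers) {
  ord <- order(centers)
  cs <- centers[ord]
  mids <- (cs[-1L] + cs[-length(cs)]) / 2
  lab <- findInterval(v, mids) + 1L
  ord[lab]
}

assign_nearest <- function(x, centers) {
  if (ncol(x) == 1L) return(assign_nearest_1d(x[, 1L], centers[, 1L]))
  x2 <- rowSums(x^2)
  c2 <- rowSums(centers^2)
  d2 <- outer(x2, c2, "+") - 2 * tcrossprod(x, centers)
  max.col(-d2, ties.method = "first")
}

#' Discretize feature trajectories by k-means clustering
#'
#' Pools all frames, seeds `k` centres with a fixed-seed k-means++ rule and
#' runs Lloyd iterations to convergence (a cluster that empties keeps its
#' centre). Frames are then labelled by their nearest centre (Euclidean).
#' Deterministic for fixed seed and data.
#'
#' @param x a `trajectory_ensemble` or list of per-trajectory feature
#'   vectors/matrices (frames in rows).
#' @param k number of clusters.
#' @param seed integer seed for centre initialization.
#' @param max_iter Lloyd iteration cap.
#' @return list with `model` (class `cluster_model`: `k`, `centers`,
#'   `seed`) and `dtrajs` (list of integer label vectors, 1-based, in frame
#'   order).
#' @export
cluster_features <- function(x, k, seed = 1L, max_iter = 200L) {
  feats <- ensemble_feature_list(x)
  pooled <- do.call(rbind, feats)
  k <- as.integer(k)
  if (nrow(pooled) < k) stop("fewer frames than clusters", call. = FALSE)
  n_distinct <- nrow(unique(pooled))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the number of distinct feature values (%d)",
                 k, n_distinct), call. = FALSE)
  }
  centers <- with_seed(seed, kmeanspp_init(pooled, k))
  if (ncol(pooled) == 1L) {
    # 1-D Lloyd on presorted data: centres partition the sorted values into
    # contiguous segments, whose means come from one cumulative sum
    sv <- sort(pooled[, 1L])
    csum <- c(0, cumsum(sv))
    n <- length(sv)
    cc <- centers[, 1L]
    for (it in seq_len(max_iter)) {
      ord <- order(cc)
      cs <- cc[ord]
      mids <- (cs[-1L] + cs[-k]) / 2
      hi <- c(findInterval(mids, sv), n)     # segment upper bounds
      lo <- c(1L, utils::head(hi, -1L) + 1L) # segment lower bounds
      cnt <- hi - lo + 1L
      means <- ifelse(cnt > 0L, (csum[hi + 1L] - csum[lo]) / cnt, cs)
      new_c <- cc
      new_c[ord] <- means  # empty segment keeps its centre
      shift <- max(abs(new_c - cc))
      cc <- new_c
      if (shift < 1e-12) break
    }
    centers[, 1L] <- cc
  } else {
    km <- stats::kmeans(pooled, centers = centers, iter.max = max_iter,
                        algorithm = "Lloyd")
    centers <- km$centers
  }
  dtrajs <- lapply(feats, function(f) assign_nearest(f, centers))
  model <- structure(list(k = k, centers = centers, seed = as.integer(seed)),
                     class = "cluster_model")
  list(model = model, dtrajs = dtrajs)
}

#' Sliding-window transition counts
#'
#' For each trajectory, counts all pairs (s_t, s_{t+lag}). Trajectories not
#' longer than the lag are skipped with a warning; if all are too short the
#' call errors.
#'
#' @param dtrajs list of integer label vectors (1-based).
#' @param lag_frames lag in frames (>= 1).
#' @param n_states number of states; default `max(labels)`.
#' @param dt frame spacing in ns (stored as `lag_ns = lag_frames * dt`).
#' @return A `count_matrix`: list with `counts` (k x k integer matrix,
#'   from-rows to-columns), `lag_frames`, `lag_ns`, `n_skipped`.
#' @export
count_transitions <- function(dtrajs, lag_frames, n_states = NULL, dt = 0.2) {
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1L) stop("`lag_frames` must be >= 1", call. = FALSE)
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, integer(1)))
  k <- as.integer(n_states)
  usable <- vapply(dtrajs, length, integer(1)) > lag_frames
  if (!any(usable)) {
    stop(sprintf("all %d trajectories are shorter than lag + 1 = %d frames",
                 length(dtrajs), lag_frames + 1L), call. = FALSE)
  }
  if (any(!usable)) {
    warning(sprintf("%d trajectories shorter than the lag were skipped",
                    sum(!usable)))
  }
  counts <- matrix(0L, nrow = k, ncol = k)
  for (s in dtrajs[usable]) {
    L <- length(s)
    from <- s[seq_len(L - lag_frames)]
    to <- s[(lag_frames + 1L):L]
    idx <- (from - 1L) * k + to
    tab <- tabulate(idx, nbins = k * k)
    counts <- counts + matrix(tab, nrow = k, ncol = k, byrow = TRUE)
  }
  structure(list(counts = counts, lag_frames = lag_frames,
                 lag_ns = lag_frames * dt, n_skipped = sum(!usable)),
            class = "count_matrix")
}

#' Largest strongly connected set of a count matrix
#'
#' Restricts the counts to the strongly connected component (of the
#' directed graph of observed transitions) with the largest total count
#' mass. States outside the component, including isolated states, are
#' dropped.
#'
#' @param cm a `count_matrix` (or bare count matrix).
#' @return list with `counts` (trimmed `count_matrix`), `active_set`
#'   (original state indices retained, in ascending order).
#' @export
largest_connected_set <- function(cm) {
  C <- if (inherits(cm, "count_matrix")) cm$counts else cm
  k <- nrow(C)
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  mass <- vapply(seq_len(comp$no), function(ci) {
    members <- which(comp$membership == ci)
    sum(C[members, members, drop = FALSE])
  }, numeric(1))
  best <- which.max(mass)
  active <- sort(which(comp$membership == best))
  trimmed <- C[active, active, drop = FALSE]
  out_cm <- if (inherits(cm, "count_matrix")) {
    structure(list(counts = trimmed, lag_frames = cm$lag_frames,
                   lag_ns = cm$lag_ns, n_skipped = cm$n_skipped),
              class = "count_matrix")
  } else {
    trimmed
  }
  list(counts = out_cm, active_set = active)
}

# Detailed-balance maximum-likelihood estimator: fixed-point iteration on
# the symmetric flux matrix x_ij ~ pi_i T_ij with
#   x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j).
reversible_mle <- function(C, tol = 1e-10, max_iter = 100000L) {
  k <- nrow(C)
  ci <- rowSums(C)
  if (any(ci == 0)) stop("count matrix has an empty row; trim first", call. = FALSE)
  Csym <- C + t(C)
  X <- Csym / sum(C)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    q <- ci / xi
    denom <- outer(q, q, "+")
    Xn <- Csym / denom
    Xn[Csym == 0] <- 0
    rel <- abs(Xn - X) / pmax(X, .Machine$double.xmin)
    rel[Csym == 0] <- 0
    delta <- max(rel)
    X <- Xn
    if (delta < tol) {
      xi <- rowSums(X)
      return(list(T = X / xi, pi = xi / sum(xi), iterations = it,
                  residual = delta))
    }
  }
  stop(sprintf(
    "reversible MLE did not converge in %d iterations (residual %.3e)",
    max_iter, delta), call. = FALSE)
}

stationary_from_eigen <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

msm_eigenvalues <- function(T, pi, reversible) {
  if (reversible) {
    # symmetrize with the stationary weights: real spectrum guaranteed
    s <- sqrt(pi)
    S <- (s %o% (1 / s)) * T
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- Re(eigen(T, only.values = TRUE)$values)
  }
  sort(ev, decreasing = TRUE)
}

#' Estimate a Markov state model from transition counts
#'
#' Counts are first trimmed to their largest strongly connected set. In
#' non-reversible mode the transition matrix is the row-normalized count
#' matrix and the stationary distribution its leading left eigenvector. In
#' reversible mode (default) the detailed-balance maximum-likelihood
#' estimate is found by fixed-point iteration, converged when the maximum
#' relative change falls below `tol`; the stationary distribution follows
#' from the detailed-balance flux weights.
#'
#' @param cm a `count_matrix` (or bare matrix; then supply `lag_ns`).
#' @param reversible enforce detailed balance (default `TRUE`).
#' @param tol convergence tolerance of the fixed-point iteration.
#' @param max_iter iteration cap (error with residual on non-convergence).
#' @param lag_ns lag time in ns (taken from `cm` when available).
#' @return An `msmodel`: list with `T`, `pi`, `eigenvalues` (sorted
#'   descending, leading value 1), `lag_ns`, `active_set`, `reversible`.
#' @export
estimate_transition_matrix <- function(cm, reversible = TRUE, tol = 1e-10,
                                       max_iter = 100000L, lag_ns = NULL) {
  if (inherits(cm, "count_matrix")) {
    if (is.null(lag_ns)) lag_ns <- cm$lag_ns
  } else if (is.null(lag_ns)) {
    stop("`lag_ns` required when passing a bare count matrix", call. = FALSE)
  }
  lcs <- largest_connected_set(cm)
  C <- if (inherits(lcs$counts, "count_matrix")) lcs$counts$counts else lcs$counts
  if (reversible) {
    est <- reversible_mle(C, tol = tol, max_iter = max_iter)
    T <- est$T
    pi <- est$pi
  } else {
    T <- C / rowSums(C)
    pi <- stationary_from_eigen(T)
  }
  stopifnot(max(abs(rowSums(T) - 1)) < 1e-10)
  if (max(abs(pi %*% T - pi)) > 1e-8) {
    stop("stationary distribution check failed (|pi T - pi| > 1e-8)",
         call. = FALSE)
  }
  structure(list(T = T, pi = as.numeric(pi),
                 eigenvalues = msm_eigenvalues(T, as.numeric(pi), reversible),
                 lag_ns = lag_ns, active_set = lcs$active_set,
                 reversible = reversible),
            class = "msmodel")
}

#' @export
print.msmodel <- function(x, ...) {
  its <- implied_timescales(x)
  cat(sprintf("msmodel: %d states, lag %g ns, %s\n", nrow(x$T), x$lag_ns,
              if (x$reversible) "reversible" else "non-reversible"))
  cat("slowest implied timescales (ns):",
      paste(signif(utils::head(its$timescale_ns, 3L), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Implied relaxation timescales of an MSM
#'
#' `t_i = -lag / log(lambda_i)` for eigenvalues strictly inside (0, 1).
#' Eigenvalues equal to 1 beyond the stationary one yield infinite
#' timescales; eigenvalues <= 0 are undefined at this lag and flagged.
#'
#' @param model an `msmodel`.
#' @param n number of timescales to report (default all).
#' @return data.frame with `eigenvalue`, `timescale_ns`, `defined`.
#' @export
implied_timescales <- function(model, n = NULL) {
  ev <- model$eigenvalues[-1L]  # drop the stationary eigenvalue
  if (!is.null(n)) ev <- utils::head(ev, n)
  ts <- rep(NA_real_, length(ev))
  defined <- ev > 0 & ev < 1
  ts[defined] <- -model$lag_ns / log(ev[defined])
  ts[ev >= 1] <- Inf
  data.frame(eigenvalue = ev, timescale_ns = ts,
             defined = defined | ev >= 1)
}

#' Slowest implied timescale, ns
#' @param model an `msmodel`.
#' @export
slowest_timescale <- function(model) {
  its <- implied_timescales(model)
  its$timescale_ns[1L]
}

#' Slowest implied timescale versus lag time
#'
#' Builds one reversible MSM per lag on a shared discretization and
#' tabulates the slowest implied timescale, the standard convergence
#' diagnostic for choosing an MSM lag.
#'
#' @param dtrajs list of integer label vectors.
#' @param lags_ns lag times, ns (each must be a multiple of `dt`).
#' @param dt frame spacing, ns.
#' @param reversible passed to [estimate_transition_matrix()].
#' @return data.frame with `lag_ns`, `timescale_ns`, `n_active`.
#' @export
its_convergence <- function(dtrajs, lags_ns, dt = 0.2, reversible = TRUE) {
  rows <- lapply(lags_ns, function(lag) {
    lf <- as.integer(round(lag / dt))
    cm <- count_transitions(dtrajs, lf, dt = dt)
    m <- estimate_transition_matrix(cm, reversible = reversible)
    data.frame(lag_ns = lag, timescale_ns = slowest_timescale(m),
               n_active = length(m$active_set))
  })
  do.call(rbind, rows)
}

#' Estimator-grid timescale table for two conditions
#'
#' Reproduces the estimator grid used to compare opening/closing
#' timescales with and without glycans: reversible MSMs at each (k, lag)
#' combination plus a tICA row, for two ensembles, with their ratio.
#'
#' @param ensemble_with,ensemble_without `trajectory_ensemble`s for the two
#'   conditions.
#' @param ks cluster counts (default `c(99, 6)`).
#' @param lags_ns MSM lag times in ns (default `c(256, 128)`).
#' @param tica_lag_ns lag for the tICA row (default 256).
#' @param seed clustering seed.
#' @return data.frame: `estimator`, `k`, `lag_ns`, `timescale_us_with`,
#'   `timescale_us_without`, `ratio`.
#' @export
timescale_table <- function(ensemble_with, ensemble_without,
                            ks = c(99L, 6L), lags_ns = c(256, 128),
                            tica_lag_ns = 256, seed = 1L) {
  one_condition <- function(ens) {
    dt <- ens$dt
    res <- list()
    for (k in ks) {
      cl <- cluster_features(ens, k = k, seed = seed)
      for (lag in lags_ns) {
        lf <- as.integer(round(lag / dt))
        cm <- count_transitions(cl$dtrajs, lf, n_states = k, dt = dt)
        m <- estimate_transition_matrix(cm)
        res[[sprintf("MSM_%d_%g", k, lag)]] <- slowest_timescale(m)
      }
    }
    tm <- tica_timescales(ens, lag_frames = as.integer(round(tica_lag_ns / dt)))
    res[["tICA"]] <- tm$timescales_ns[1L]
    res
  }
  # grid: MSM rows in (k major, lag minor) order, then tICA
  a <- one_condition(ensemble_with)
  b <- one_condition(ensemble_without)
  grid <- expand.grid(lag_ns = lags_ns, k = ks)[, c("k", "lag_ns")]
  rows <- data.frame(
    estimator = c(sprintf("MSM, %d clusters, lag %g ns", grid$k, grid$lag_ns),
                  "tICA"),
    k = c(grid$k, NA),
    lag_ns = c(grid$lag_ns, tica_lag_ns),
    timescale_us_with = NA_real_, timescale_us_without = NA_real_
  )
  keys <- c(sprintf("MSM_%d_%g", grid$k, grid$lag_ns), "tICA")
  rows$timescale_us_with <- unlist(a[keys]) / 1000
  rows$timescale_us_without <- unlist(b[keys]) / 1000
  rows$ratio <- rows$timescale_us_with / rows$timescale_us_without
  rows
}
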