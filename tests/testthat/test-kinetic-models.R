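test_that("k-means discretization recovers well-separated generating states", {
  sp <- two_state_spec(rate_close = 0.01, rate_open = 0.01, n_traj = 10L,
                       n_frames = 500L, seed = 3L)
  ens <- generate_two_state_ensemble(sp)
  cl <- cluster_features(ens, k = 2, seed = 5L)
  lab <- unlist(cl$dtrajs)
  truth <- unlist(ens$state)
  # allow the label permutation
  agree <- max(mean(lab == truth), mean((3L - lab) == truth))
  expect_gte(agree, 0.99)
  # determinism: same seed, same centers and labels
  cl2 <- cluster_features(ens, k = 2, seed = 5L)
  expect_identical(cl$model$centers, cl2$model$centers)
  expect_identical(cl$dtrajs, cl2$dtrajs)
  # k = 1 labels everything 0th cluster
  expect_true(all(unlist(cluster_features(ens, k = 1, seed = 1L)$dtrajs) == 1L))
  # k larger than the number of distinct values is rejected
  const <- list(rep(2, 10), rep(c(2, 3), 5))
  expect_error(cluster_features(const, k = 3, seed = 1L), "distinct")
})

test_that("sliding-window transition counts match hand enumeration", {
  # labels 0,0,1,1,0 at lag 1 -> pairs (0,0),(0,1),(1,1),(1,0)
  cm <- count_transitions(list(c(1L, 1L, 2L, 2L, 1L)), 1L, n_states = 2L)
  expect_equal(cm$counts, rbind(c(1L, 1L), c(1L, 1L)), ignore_attr = TRUE)
  # labels 0,1,0,1 at lag 2 -> pairs (0,0),(1,1)
  cm2 <- count_transitions(list(c(1L, 2L, 1L, 2L)), 2L, n_states = 2L)
  expect_equal(cm2$counts, rbind(c(1L, 0L), c(0L, 1L)), ignore_attr = TRUE)
  # constant trajectory of length L at lag 1: L - 1 diagonal counts
  cm3 <- count_transitions(list(rep(1L, 20L)), 1L, n_states = 1L)
  expect_equal(sum(cm3$counts), 19L)
  expect_equal(cm3$lag_ns, 0.2)
  # short trajectories are skipped with a warning; all-short is an error
  expect_warning(count_transitions(list(1:5, 1L), 3L, n_states = 5L), "skipped")
  expect_error(count_transitions(list(1:3), 5L), "shorter")
})

test_that("largest connected set keeps the heaviest strongly connected block", {
  # block-diagonal counts 100 vs 10: the heavy block is retained
  C <- matrix(0L, 4, 4)
  C[1:2, 1:2] <- matrix(c(60L, 20L, 15L, 5L), 2)
  C[3:4, 3:4] <- matrix(c(4L, 2L, 3L, 1L), 2)
  lcs <- largest_connected_set(C)
  expect_equal(lcs$active_set, 1:2)
  expect_equal(lcs$counts, C[1:2, 1:2])
  # fully connected counts keep everything
  full <- matrix(5L, 3, 3)
  expect_equal(largest_connected_set(full)$active_set, 1:3)
  # an isolated state (no in/out counts) is dropped
  iso <- rbind(c(5L, 1L, 0L), c(1L, 5L, 0L), c(0L, 0L, 0L))
  expect_equal(largest_connected_set(iso)$active_set, 1:2)
})

test_that("transition-matrix estimation reproduces analytic stationary solutions", {
  # symmetric counts: row normalization, uniform stationary distribution
  cm <- structure(list(counts = rbind(c(8L, 2L), c(2L, 8L)), lag_frames = 1L,
                       lag_ns = 1, n_skipped = 0L), class = "count_matrix")
  for (rev in c(TRUE, FALSE)) {
    m <- estimate_transition_matrix(cm, reversible = rev)
    expect_equal(m$T, rbind(c(0.8, 0.2), c(0.2, 0.8)), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
  }
  # counts proportional to T = [[.9,.1],[.2,.8]] give pi = (2/3, 1/3)
  cm2 <- structure(list(counts = rbind(c(90L, 10L), c(20L, 80L)),
                        lag_frames = 1L, lag_ns = 1, n_skipped = 0L),
                   class = "count_matrix")
  m2 <- estimate_transition_matrix(cm2, reversible = FALSE)
  expect_equal(m2$pi, c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("reversible estimates satisfy detailed balance and stationarity", {
  withr::local_seed(13)
  for (k in c(3L, 6L)) {
    C <- matrix(rpois(k * k, lambda = 20) + 1L, k, k)
    m <- estimate_transition_matrix(C, reversible = TRUE, lag_ns = 1)
    flux <- m$pi * m$T
    expect_lt(max(abs(flux - t(flux))), 1e-8)
    expect_lt(max(abs(m$pi %*% m$T - m$pi)), 1e-8)
    expect_equal(rowSums(m$T), rep(1, k), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(m$eigenvalues[1], 1, tolerance = 1e-9)
  }
})

test_that("reversible MLE agrees with exhaustive likelihood maximization on small chains", {
  # independent oracle: numerically maximize the reversible log-likelihood
  # over the symmetric flux parametrization with optim
  oracle_reversible <- function(C) {
    k <- nrow(C)
    idx <- which(upper.tri(matrix(0, k, k), diag = TRUE))
    negll <- function(theta) {
      X <- matrix(0, k, k)
      X[idx] <- exp(theta)
      X <- X + t(X) - diag(diag(X))
      T <- X / rowSums(X)
      -sum(C * log(T))
    }
    th0 <- rep(0, length(idx))
    fit <- optim(th0, negll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))
    X <- matrix(0, k, k)
    X[idx] <- exp(fit$par)
    X <- X + t(X) - diag(diag(X))
    X / rowSums(X)
  }
  withr::local_seed(7)
  for (k in 2:4) {
    C <- matrix(rpois(k * k, lambda = 15) + 1L, k, k)
    m <- estimate_transition_matrix(C, reversible = TRUE, lag_ns = 1)
    expect_equal(m$T, oracle_reversible(C), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("implied timescales follow the closed-form eigenvalue relation", {
  # T = [[.9,.1],[.2,.8]]: trace 1.7, det 0.70 -> lambda2 = 0.7
  cm <- structure(list(counts = rbind(c(90L, 10L), c(20L, 80L)),
                       lag_frames = 5L, lag_ns = 1, n_skipped = 0L),
                  class = "count_matrix")
  m <- estimate_transition_matrix(cm, reversible = FALSE)
  its <- implied_timescales(m)
  expect_equal(its$eigenvalue[1], 0.7, tolerance = 1e-12)
  expect_equal(its$timescale_ns[1], -1 / log(0.7), tolerance = 1e-12)
  # identity transition matrix: eigenvalues beyond the stationary one equal
  # 1, so no finite timescale exists and infinity is reported
  ident <- structure(list(eigenvalues = c(1, 1, 1), lag_ns = 256),
                     class = "msmodel")
  expect_true(all(is.infinite(implied_timescales(ident)$timescale_ns)))
  # definition check: lambda = exp(-1) at lag 256 ns gives t = 256 ns
  fake <- structure(list(eigenvalues = c(1, exp(-1)), lag_ns = 256),
                    class = "msmodel")
  expect_equal(implied_timescales(fake)$timescale_ns, 256)
})

test_that("timescales recover the generator's relaxation time at high sampling", {
  # relaxation 50 ns, aggregate sampling 2000x: estimator noise ~ 1-2%
  sp <- fast_spec(seed = 9L, n_traj = 250L)
  ens <- generate_two_state_ensemble(sp)
  cl <- cluster_features(ens, k = 20L, seed = 2L)
  tab <- its_convergence(cl$dtrajs, lags_ns = c(12.8, 25.6), dt = 0.2)
  expect_equal(nrow(tab), 2L)
  for (ts in tab$timescale_ns) {
    expect_lt(abs(ts - relaxation_time(sp)) / relaxation_time(sp), 0.1)
  }
  # Markov property: timescales agree across lags within estimator noise
  expect_lt(abs(tab$timescale_ns[1] - tab$timescale_ns[2]) /
              tab$timescale_ns[2], 0.1)
  # stationary closed population within 2 percentage points: checked on a
  # faster-mixing process (relaxation 10 ns) so each trajectory contributes
  # many independent visits
  sp2 <- two_state_spec(rate_close = 0.065, rate_open = 0.035, n_traj = 250L,
                        n_frames = 2000L, seed = 10L)
  ens2 <- generate_two_state_ensemble(sp2)
  cl2 <- cluster_features(ens2, k = 20L, seed = 2L)
  m <- estimate_transition_matrix(
    count_transitions(cl2$dtrajs, 16L, n_states = 20L, dt = 0.2))
  closed_mass <- sum(m$pi[cl2$model$centers[m$active_set, 1] < 4.2])
  expect_lt(abs(closed_mass - closed_fraction(sp2)), 0.02)
})

test_that("a count matrix with only self-transitions collapses to one active state", {
  cmI <- structure(list(counts = diag(c(50L, 10L, 5L)), lag_frames = 1L,
                        lag_ns = 0.2, n_skipped = 0L), class = "count_matrix")
  m <- estimate_transition_matrix(cmI)
  expect_equal(m$active_set, 1L)
  expect_equal(nrow(implied_timescales(m)), 0L)
})

test_that("tICA eigenvalue on 1-D data equals the lag autocorrelation", {
  withr::local_seed(17)
  xs <- lapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.8), 300)))
  lag <- 3L
  tm <- tica_timescales(xs, lag_frames = lag, dt = 1)
  # independent oracle: mean over all frames, C0 over all frames, lagged
  # covariance over intra-trajectory pairs, symmetrized
  m <- mean(unlist(xs))
  c0 <- mean((unlist(xs) - m)^2)
  num <- 0; np <- 0
  for (x in xs) {
    xc <- x - m
    L <- length(xc)
    num <- num + sum(xc[seq_len(L - lag)] * xc[(lag + 1):L])
    np <- np + L - lag
  }
  expect_equal(tm$eigenvalues[1], (num / np) / c0, tolerance = 1e-10)
})

test_that("tICA flags perfectly anticorrelated input and recovers OU correlation times", {
  # alternating series at lag 1: eigenvalue -1, timescale undefined
  alt <- list(rep(c(1, -1), 100))
  tm <- tica_timescales(alt, lag_frames = 1L, dt = 1)
  expect_equal(tm$eigenvalues[1], -1, tolerance = 1e-9)
  expect_false(tm$defined[1])
  expect_true(is.na(tm$timescales_ns[1]))
  # AR(1) sampling of an Ornstein-Uhlenbeck process with correlation time
  # theta: recovered within 10% at sampling >> theta
  theta <- 5  # ns
  dt <- 0.5
  phi <- exp(-dt / theta)
  withr::local_seed(23)
  xs <- lapply(1:10, function(i) {
    as.numeric(arima.sim(list(ar = phi), 2000)) # 10 x 1000 ns = 2000 theta
  })
  tm2 <- tica_timescales(xs, lag_frames = 10L, dt = dt)
  expect_lt(abs(tm2$timescales_ns[1] - theta) / theta, 0.1)
})

test_that("the estimator-grid table reports unit ratios for identical generators", {
  ens_a <- generate_two_state_ensemble(fast_spec(seed = 31L, n_traj = 60L))
  ens_b <- generate_two_state_ensemble(fast_spec(seed = 32L, n_traj = 60L))
  tab <- timescale_table(ens_a, ens_b, ks = c(12L, 4L), lags_ns = c(12.8, 25.6),
                         tica_lag_ns = 12.8, seed = 2L)
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("estimator", "k", "lag_ns", "timescale_us_with",
                    "timescale_us_without", "ratio") %in% names(tab)))
  # same generating process in both conditions: ratios scatter around 1
  expect_true(all(abs(tab$ratio - 1) < 0.2))
})
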