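test_that("binned pdfs are normalized and align to the bin-width lattice", {
  withr::local_seed(3)
  v <- rnorm(5000, 4.2, 0.3)
  p <- binned_pdf(v, bin_width = 0.1)
  expect_lt(abs(sum(p$density * diff(p$breaks)) - 1), 1e-9)
  expect_true(all(p$density >= 0))
  # edges sit on multiples of the bin width
  expect_equal(p$breaks, round(p$breaks / 0.1) * 0.1, tolerance = 1e-9)
})

test_that("reweighting with uniform stationary weights reproduces the raw pdf", {
  sp <- fast_spec(seed = 5L, n_traj = 20L, n_frames = 1000L)
  ens <- generate_two_state_ensemble(sp)
  # a fake model whose active set covers both states with uniform pi and
  # state occupancies exactly equal: weights constant -> raw pdf
  d <- unlist(ens$d)
  lab <- rep(c(1L, 2L), length.out = length(d))
  dtrajs <- split(lab, rep(seq_along(ens$d), lengths(ens$d)))
  fake <- structure(list(pi = c(0.5, 0.5), active_set = 1:2), class = "msmodel")
  pr <- reweighted_pdf(ens, dtrajs, fake, bin_width = 0.1)
  p0 <- binned_pdf(ens, bin_width = 0.1)
  expect_equal(pr$density, p0$density, tolerance = 1e-12)
  expect_equal(pr$weighting, "msm-reweighted")
})

test_that("MSM reweighting recovers the analytic closed-basin mass", {
  sp <- two_state_spec(rate_close = 0.065, rate_open = 0.035, n_traj = 150L,
                       n_frames = 2000L, seed = 6L)
  ens <- generate_two_state_ensemble(sp)
  cl <- cluster_features(ens, k = 20L, seed = 2L)
  m <- estimate_transition_matrix(
    count_transitions(cl$dtrajs, 16L, n_states = 20L, dt = 0.2))
  p <- reweighted_pdf(ens, cl$dtrajs, m, bin_width = 0.1)
  mids <- (p$breaks[-1] + p$breaks[-length(p$breaks)]) / 2
  closed_mass <- sum(p$density[mids < 4.2] * p$bin_width)
  expect_lt(abs(closed_mass - closed_fraction(sp)), 0.02)
})

test_that("frames in trimmed states are dropped with a logged count", {
  sp <- fast_spec(seed = 5L, n_traj = 4L, n_frames = 100L)
  ens <- generate_two_state_ensemble(sp)
  dtrajs <- lapply(ens$state, function(s) { s[1] <- 3L; s })
  fake <- structure(list(pi = c(0.6, 0.4), active_set = 1:2), class = "msmodel")
  expect_message(reweighted_pdf(ens, dtrajs, fake), "4 frames .* dropped")
  bad <- structure(list(pi = 1, active_set = 9L), class = "msmodel")
  expect_error(suppressMessages(reweighted_pdf(ens, dtrajs, bad)), "no overlap")
})

test_that("the bootstrap comparison is null for identical ensembles and deterministic", {
  sp <- fast_spec(seed = 12L, n_traj = 30L, n_frames = 500L)
  ens <- generate_two_state_ensemble(sp)
  bs <- pdf_difference_bootstrap(ens, ens, n_boot = 200L, seed = 4L)
  expect_true(all(bs$table$significant == 0L))
  expect_true(all(abs(bs$table$diff) < 1e-12))
  bs2 <- pdf_difference_bootstrap(ens, ens, n_boot = 200L, seed = 4L)
  expect_identical(bs$table, bs2$table)
  expect_error(pdf_difference_bootstrap(
    structure(list(d = ens$d[1]), class = "trajectory_ensemble"), ens),
    "2 trajectories")
})

test_that("a known population shift is detected with the forced direction", {
  # closed fraction 0.65 vs 0.50: closed-basin bins significantly enriched,
  # open-basin bins significantly depleted
  sp_a <- two_state_spec(rate_close = 0.013, rate_open = 0.007, n_traj = 100L,
                         n_frames = 1000L, seed = 21L)
  sp_b <- two_state_spec(rate_close = 0.010, rate_open = 0.010, n_traj = 100L,
                         n_frames = 1000L, seed = 22L)
  bs <- pdf_difference_bootstrap(generate_two_state_ensemble(sp_a),
                                 generate_two_state_ensemble(sp_b),
                                 n_boot = 400L, seed = 9L)
  tab <- bs$table
  mid <- (tab$bin_lo_nm + tab$bin_hi_nm) / 2
  closed_core <- tab[abs(mid - 3.7) < 0.15, ]
  open_core <- tab[abs(mid - 4.7) < 0.15, ]
  expect_true(all(closed_core$significant == 1L & closed_core$diff > 0))
  expect_true(all(open_core$significant == 1L & open_core$diff < 0))
})

test_that("swapping the ensembles negates differences and keeps significance", {
  sp_a <- fast_spec(seed = 31L, n_traj = 25L, n_frames = 400L)
  sp_b <- two_state_spec(rate_close = 0.01, rate_open = 0.01, n_traj = 25L,
                         n_frames = 400L, seed = 32L)
  ea <- generate_two_state_ensemble(sp_a)
  eb <- generate_two_state_ensemble(sp_b)
  br <- range(c(unlist(ea$d), unlist(eb$d)))
  breaks <- seq(floor(br[1] * 10) / 10, ceiling(br[2] * 10) / 10 + 0.05, 0.1)
  ab <- pdf_difference_bootstrap(ea, eb, n_boot = 300L, seed = 5L,
                                 breaks = breaks)
  ba <- pdf_difference_bootstrap(eb, ea, n_boot = 300L, seed = 5L,
                                 breaks = breaks)
  expect_equal(ab$table$diff, -ba$table$diff, tolerance = 1e-12)
  # the percentile intervals mirror in distribution (replicate draws are
  # not shared between the two calls), so the significant sets agree up to
  # bootstrap noise on borderline bins
  expect_gte(mean(ab$table$significant == ba$table$significant), 0.9)
  decisive <- abs(ab$table$diff) > (ab$table$ci_hi - ab$table$ci_lo)
  expect_equal(ab$table$significant[decisive], ba$table$significant[decisive])
})

test_that("degenerate single-replicate bootstraps are flagged invalid", {
  sp <- fast_spec(seed = 41L, n_traj = 5L, n_frames = 100L)
  ens <- generate_two_state_ensemble(sp)
  expect_warning(bs <- pdf_difference_bootstrap(ens, ens, n_boot = 1L,
                                                seed = 2L),
                 "degenerate")
  expect_false(bs$valid)
  expect_true(all(bs$table$significant == 0L))
})

test_that("confidence intervals widen as trajectories become scarcer", {
  width_at <- function(n_traj, seed) {
    sp <- fast_spec(seed = seed, n_traj = n_traj, n_frames = 400L)
    ens <- generate_two_state_ensemble(sp)
    bs <- pdf_difference_bootstrap(ens, ens, n_boot = 150L, seed = seed)
    tab <- bs$table
    mid <- (tab$bin_lo_nm + tab$bin_hi_nm) / 2
    mean((tab$ci_hi - tab$ci_lo)[abs(mid - 3.7) < 0.25])
  }
  # averaged over repeats: monotone in expectation
  wide <- mean(vapply(1:4, function(s) width_at(8L, s), numeric(1)))
  narrow <- mean(vapply(1:4, function(s) width_at(60L, s + 100L), numeric(1)))
  expect_gt(wide, narrow)
})

test_that("bootstrap coverage is near nominal and scales with the level", {
  sp <- two_state_spec(rate_close = 0.013, rate_open = 0.007, n_traj = 40L,
                       n_frames = 500L, seed = 1L)
  cov95 <- bootstrap_coverage_check(sp, n_ensembles = 120L, n_boot = 150L,
                                    seed = 3L, level = 0.95)
  expect_gt(cov95$coverage, 0.88)
  expect_lte(cov95$coverage, 1)
  cov50 <- bootstrap_coverage_check(sp, n_ensembles = 120L, n_boot = 150L,
                                    seed = 3L, level = 0.5)
  expect_lt(abs(cov50$coverage - 0.5), 0.15)
  # degenerate zero-variance generator: every CI contains the constant truth
  sp0 <- two_state_spec(rate_close = 1e9, rate_open = 1e-9, sd_closed = 0,
                        sd_open = 0, n_traj = 10L, n_frames = 50L, seed = 2L)
  cov0 <- suppressWarnings(bootstrap_coverage_check(
    sp0, n_ensembles = 20L, n_boot = 50L, seed = 4L,
    bins = c(3.65, 3.75)))
  expect_equal(cov0$coverage, 1)
})
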