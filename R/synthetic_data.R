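# Synthetic-data generators: every input the analysis pipeline consumes can
# be produced here with seeded randomness and known ground truth, so that
# MSM, bootstrap and dose-response estimators can be validated against
# closed-form oracles.

#' Specification of a two-state switching order-parameter ensemble
#'
#' Defines a continuous-time two-state (open/closed) exchange process for a
#' scalar clamshell coordinate `d`, observed every `dt` ns with
#' state-dependent Gaussian emission. The process is sampled exactly (matrix
#' exponential of the two-state generator, not an Euler scheme), so its
#' slowest relaxation time is exactly `1/(rate_close + rate_open)` and its
#' equilibrium closed fraction exactly `rate_close/(rate_close + rate_open)`.
#'
#' Defaults emulate a glycosylated ligand-binding-domain ensemble: closed
#' basin at 3.7 nm, open basin at 4.7 nm (sd 0.15 nm each), closed fraction
#' 0.65, relaxation time 520 ns, 262 trajectories of 2000 frames at 0.2 ns.
#'
#' @param rate_close open-to-closed transition rate, 1/ns.
#' @param rate_open closed-to-open transition rate, 1/ns.
#' @param mean_closed,mean_open basin centres of `d`, nm (`mean_open` must
#'   exceed `mean_closed`).
#' @param sd_closed,sd_open emission standard deviations, nm (>= 0).
#' @param dt frame spacing, ns.
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory.
#' @param seed integer seed.
#' @return An object of class `two_state_spec`.
#' @seealso [generate_two_state_ensemble()], [relaxation_time()],
#'   [closed_fraction()]
#' @export
two_state_spec <- function(rate_close = 0.65 / 520, rate_open = 0.35 / 520,
                           mean_closed = 3.7, mean_open = 4.7,
                           sd_closed = 0.15, sd_open = 0.15,
                           dt = 0.2, n_traj = 262L, n_frames = 2000L,
                           seed = 1L) {
  assert_scalar_number(rate_close, "rate_close", positive = TRUE)
  assert_scalar_number(rate_open, "rate_open", positive = TRUE)
  assert_scalar_number(mean_closed, "mean_closed")
  assert_scalar_number(mean_open, "mean_open")
  assert_scalar_number(sd_closed, "sd_closed", nonneg = TRUE)
  assert_scalar_number(sd_open, "sd_open", nonneg = TRUE)
  assert_scalar_number(dt, "dt", positive = TRUE)
  if (mean_open <= mean_closed) {
    stop("`mean_open` must exceed `mean_closed`", call. = FALSE)
  }
  n_traj <- as.integer(n_traj)
  n_frames <- as.integer(n_frames)
  if (n_traj < 1L || n_frames < 1L) {
    stop("`n_traj` and `n_frames` must be >= 1", call. = FALSE)
  }
  structure(
    list(rate_close = rate_close, rate_open = rate_open,
         mean_closed = mean_closed, mean_open = mean_open,
         sd_closed = sd_closed, sd_open = sd_open,
         dt = dt, n_traj = n_traj, n_frames = n_frames,
         seed = as.integer(seed)),
    class = "two_state_spec"
  )
}

#' Exact slowest relaxation time of a two-state spec, ns
#' @param spec a [two_state_spec()].
#' @export
relaxation_time <- function(spec) 1 / (spec$rate_close + spec$rate_open)

#' Exact equilibrium closed-state fraction of a two-state spec
#' @param spec a [two_state_spec()].
#' @export
closed_fraction <- function(spec) {
  spec$rate_close / (spec$rate_close + spec$rate_open)
}

#' Sample a discrete Markov chain
#'
#' @param transition_matrix row-stochastic square matrix (rows must sum to 1
#'   within 1e-12).
#' @param n_steps chain length (>= 1).
#' @param seed integer seed.
#' @param start starting state (1-based). Default: drawn uniformly.
#' @return Integer vector of 1-based state labels, length `n_steps`.
#' @export
sample_markov_chain <- function(transition_matrix, n_steps, seed, start = NULL) {
  P <- as.matrix(transition_matrix)
  k <- nrow(P)
  if (ncol(P) != k || k < 1L) stop("transition matrix must be square", call. = FALSE)
  if (any(P < 0)) stop("transition matrix has negative entries", call. = FALSE)
  bad <- which(abs(rowSums(P) - 1) > 1e-12)
  if (length(bad) > 0L) {
    stop(sprintf("transition matrix row(s) %s do not sum to 1 (sums: %s)",
                 paste(bad, collapse = ", "),
                 paste(format(rowSums(P)[bad], digits = 15), collapse = ", ")),
         call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  cum <- t(apply(P, 1L, cumsum))
  with_seed(seed, {
    s <- integer(n_steps)
    s[1L] <- if (is.null(start)) sample.int(k, 1L) else as.integer(start)
    if (s[1L] < 1L || s[1L] > k) stop("`start` out of range", call. = FALSE)
    if (n_steps > 1L) {
      u <- stats::runif(n_steps - 1L)
      for (t in 2:n_steps) {
        row <- cum[s[t - 1L], ]
        s[t] <- 1L + sum(u[t - 1L] > row[-k])
      }
    }
    s
  })
}

# Exact frame-to-frame transition probabilities of the sampled two-state
# process: P(stay) follows from the 2x2 generator's matrix exponential.
two_state_step_matrix <- function(spec) {
  q <- spec$rate_close + spec$rate_open
  e <- exp(-q * spec$dt)
  pi_c <- spec$rate_close / q
  pi_o <- 1 - pi_c
  # states: 1 = closed, 2 = open
  rbind(c(pi_c + pi_o * e, pi_o * (1 - e)),
        c(pi_c * (1 - e), pi_o + pi_c * e))
}

#' Generate a two-state switching order-parameter ensemble
#'
#' Simulates `n_traj` trajectories of the scalar clamshell coordinate `d`:
#' hidden open/closed states follow the exactly discretized two-state
#' exchange process, initial states are drawn from the exact equilibrium
#' distribution, and emissions are state-dependent Gaussians.
#'
#' @param spec a [two_state_spec()].
#' @return A `trajectory_ensemble`: list with `d` (list of numeric vectors,
#'   nm), `state` (list of integer vectors; 1 = closed, 2 = open), `dt` (ns)
#'   and `spec`.
#' @export
generate_two_state_ensemble <- function(spec) {
  stopifnot(inherits(spec, "two_state_spec"))
  q <- spec$rate_close + spec$rate_open
  if (spec$dt >= 1 / q) {
    warning(sprintf(
      "frame spacing dt = %g ns is not finer than the relaxation time %g ns; switching dynamics will be under-resolved",
      spec$dt, 1 / q))
  }
  P <- two_state_step_matrix(spec)
  pi_c <- closed_fraction(spec)
  nt <- spec$n_traj
  nf <- spec$n_frames
  with_seed(spec$seed, {
    # state matrix nf x nt, simulated frame-by-frame across all trajectories
    st <- matrix(0L, nrow = nf, ncol = nt)
    st[1L, ] <- ifelse(stats::runif(nt) < pi_c, 1L, 2L)
    if (nf > 1L) {
      p_stay <- c(P[1L, 1L], P[2L, 2L])
      for (t in 2:nf) {
        stay <- stats::runif(nt) < p_stay[st[t - 1L, ]]
        st[t, ] <- ifelse(stay, st[t - 1L, ], 3L - st[t - 1L, ])
      }
    }
    mu <- c(spec$mean_closed, spec$mean_open)
    sd <- c(spec$sd_closed, spec$sd_open)
    noise <- matrix(stats::rnorm(nf * nt), nrow = nf, ncol = nt)
    dmat <- mu[st] + sd[st] * noise
    dim(dmat) <- dim(st)
    structure(
      list(d = lapply(seq_len(nt), function(j) dmat[, j]),
           state = lapply(seq_len(nt), function(j) st[, j]),
           dt = spec$dt, spec = spec),
      class = "trajectory_ensemble"
    )
  })
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d trajectories x %d frames, dt = %g ns\n",
              length(x$d), length(x$d[[1L]]), x$dt))
  invisible(x)
}

#' Write / read a scalar order-parameter ensemble as TSV
#'
#' Columns: `trajectory_id`, `frame_index`, `time_ns`, `d_nm` and, when
#' present, `dgol_nm`.
#'
#' @param ensemble a `trajectory_ensemble` (optionally with a `dgol` field
#'   parallel to `d`).
#' @param path output file.
#' @export
write_series_tsv <- function(ensemble, path) {
  nf <- lengths(ensemble$d)
  df <- data.frame(
    trajectory_id = rep(seq_along(ensemble$d), nf),
    frame_index = unlist(lapply(nf, seq_len)) - 1L,
    time_ns = (unlist(lapply(nf, seq_len)) - 1L) * ensemble$dt,
    d_nm = unlist(ensemble$d)
  )
  if (!is.null(ensemble$dgol)) df$dgol_nm <- unlist(ensemble$dgol)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @param dt frame spacing in ns, used if the file lacks a time column.
#' @export
read_series_tsv <- function(path, dt = 0.2) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  ids <- unique(df$trajectory_id)
  d <- lapply(ids, function(i) df$d_nm[df$trajectory_id == i])
  out <- list(d = d, state = NULL, dt = dt, spec = NULL)
  if ("dgol_nm" %in% names(df)) {
    out$dgol <- lapply(ids, function(i) df$dgol_nm[df$trajectory_id == i])
  }
  if ("time_ns" %in% names(df) && length(d[[1L]]) > 1L) {
    t1 <- df$time_ns[df$trajectory_id == ids[[1L]]]
    out$dt <- t1[2L] - t1[1L]
  }
  structure(out, class = "trajectory_ensemble")
}

#' Specification of a toy two-lobe glycoprotein ensemble
#'
#' Describes a minimal bilobed pseudo-structure used to exercise the
#' geometry operators: two rigid lobes of pseudo C-alpha atoms hinged at the
#' origin, with the hinge angle per frame derived from a two-state `d`
#' series, plus a linear pseudo-glycan chain tethered to lobe S1. In frames
#' whose hidden state is closed, the glycan is swung toward lobe S2 with
#' probability `contact_when_closed` (tip placed 0.35 nm from the nearest
#' S2 atom); in all other frames it points away from S2 so that its minimum
#' heavy-atom distance to S2 exceeds 0.5 nm by construction. Contact is
#' never attempted in a frame with d > 5.2 nm.
#'
#' @param n_lobe_atoms pseudo C-alpha atoms per lobe (>= 3).
#' @param two_state spec of the underlying `d` dynamics (a
#'   [two_state_spec()]); its `n_traj` is forced to 1 per generated file.
#' @param glycan_length number of pseudo-glycan heavy atoms.
#' @param contact_when_closed probability that a closed frame shows a
#'   glycan-to-S2 contact.
#' @param seed integer seed.
#' @export
toy_glycoprotein_spec <- function(n_lobe_atoms = 24L,
                                  two_state = two_state_spec(n_traj = 1L,
                                                             n_frames = 200L),
                                  glycan_length = 11L,
                                  contact_when_closed = 0.8,
                                  seed = 1L) {
  n_lobe_atoms <- as.integer(n_lobe_atoms)
  if (n_lobe_atoms < 3L) stop("`n_lobe_atoms` must be >= 3", call. = FALSE)
  stopifnot(inherits(two_state, "two_state_spec"))
  glycan_length <- as.integer(glycan_length)
  if (glycan_length < 2L) stop("`glycan_length` must be >= 2", call. = FALSE)
  if (contact_when_closed < 0 || contact_when_closed > 1) {
    stop("`contact_when_closed` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_lobe_atoms = n_lobe_atoms, two_state = two_state,
         glycan_length = glycan_length,
         contact_when_closed = contact_when_closed,
         seed = as.integer(seed)),
    class = "toy_glycoprotein_spec"
  )
}

# Marker/selection conventions of the toy structure (author-style residue
# numbering): chain A holds lobe S1 with marker residue 507 and glycan
# tether residue 440; chain B holds lobe S2 with marker residue 701 and the
# opposite-lobe range 710..723; chain G is the pseudo-glycan.
toy_arm_radius_nm <- 3.5

#' Generate a toy two-lobe glycoprotein ensemble
#'
#' Builds per-frame coordinates from a [toy_glycoprotein_spec()] and
#' optionally writes them as a multi-model PDB (coordinates in Angstrom).
#' The interlobe marker distance d (residues 507/701, chain A/B) maps
#' monotonically to the hinge angle; per-frame d is recomputable from the
#' emitted structure.
#'
#' @param spec a [toy_glycoprotein_spec()].
#' @param path optional output PDB path; if `NULL`, no file is written.
#' @param d_override optional numeric vector of target d values (nm), one
#'   per frame, overriding the two-state simulation (hidden state is then
#'   taken as closed iff d < midpoint of the basin means).
#' @param force_contact optional logical vector, one per frame: force or
#'   forbid a glycan contact (subject to the d <= 5.2 nm guard).
#' @return A `structure_trajectory` (see [read_multimodel_pdb()]) with an
#'   extra attribute `d_true` (the generating d series, nm) and
#'   `contact_frame` (logical).
#' @export
generate_toy_glycoprotein_ensemble <- function(spec, path = NULL,
                                               d_override = NULL,
                                               force_contact = NULL) {
  stopifnot(inherits(spec, "toy_glycoprotein_spec"))
  ts <- spec$two_state
  if (is.null(d_override)) {
    ts$n_traj <- 1L
    ens <- generate_two_state_ensemble(ts)
    d <- ens$d[[1L]]
    closed <- ens$state[[1L]] == 1L
  } else {
    d <- as.numeric(d_override)
    closed <- d < (ts$mean_closed + ts$mean_open) / 2
  }
  n_frames <- length(d)
  R <- toy_arm_radius_nm
  if (any(d >= 2 * R) || any(d <= 0)) {
    stop("target d out of the representable range (0, 2 * arm radius)",
         call. = FALSE)
  }
  nl <- spec$n_lobe_atoms
  ng <- spec$glycan_length

  contact <- with_seed(child_seed(spec$seed, 7L), {
    stats::runif(n_frames) < spec$contact_when_closed & closed
  })
  if (!is.null(force_contact)) contact <- as.logical(force_contact)
  # structural guarantee: no contact in open-clamshell frames
  contact <- contact & (d <= 5.2)

  # atom bookkeeping: lobe A then lobe B then glycan
  atoms <- data.frame(
    serial = seq_len(2L * nl + ng),
    atom_name = c(rep("CA", 2L * nl), rep("C1", ng)),
    residue_name = c(rep("ALA", 2L * nl), rep("MAN", ng)),
    chain_id = c(rep("A", nl), rep("B", nl), rep("G", ng)),
    residue_number = c(440L + seq_len(nl) - 1L,   # chain A: 440, 441, ...
                       701L + seq_len(nl) - 1L,   # chain B: 701, 702, ...
                       seq_len(ng)),
    element = c(rep("C", 2L * nl), rep(c("C", "O"), length.out = ng)),
    stringsAsFactors = FALSE
  )
  # markers: chain A residue 507 must exist -> overwrite one lobe-A slot;
  # marker sits at arm radius R (last atom of the arm ray).
  atoms$residue_number[nl] <- 507L
  # lobe A arm: radii spread from 0.5 nm to R; marker at index nl has radius R
  radii <- seq(0.5, R, length.out = nl)

  xyz <- matrix(0, nrow = n_frames, ncol = 3L * nrow(atoms))
  for (f in seq_len(n_frames)) {
    theta <- 2 * asin(d[f] / (2 * R))
    u1 <- c(cos(theta / 2), sin(theta / 2), 0)   # lobe A arm direction
    u2 <- c(cos(theta / 2), -sin(theta / 2), 0)  # lobe B arm direction
    # perpendiculars used to give the lobes a little width
    p1 <- c(-sin(theta / 2), cos(theta / 2), 0)
    p2 <- c(sin(theta / 2), cos(theta / 2), 0)
    a_xyz <- t(vapply(seq_len(nl), function(i) {
      radii[i] * u1 + 0.08 * (i %% 3L) * p1
    }, numeric(3)))
    a_xyz[nl, ] <- R * u1  # marker 507 exactly on the arm ray
    b_xyz <- t(vapply(seq_len(nl), function(i) {
      radii[i] * u2 + 0.08 * (i %% 3L) * p2
    }, numeric(3)))
    b_xyz[1L, ] <- R * u2  # chain B residue 701 marker exactly on the arm ray
    # residues 710..723 need to exist on chain B: they are indices 10..23
    tether <- a_xyz[which(atoms$residue_number[seq_len(nl)] == 440L)[1L], ]
    if (contact[f]) {
      # point the glycan from its tether toward the nearest atom of the
      # opposite-lobe contact range (residues 710-723); tip placed 0.35 nm
      # short of it
      lobe_rows <- which(atoms$residue_number[nl + seq_len(nl)] %in% 710:723)
      dists <- sqrt(rowSums((b_xyz[lobe_rows, , drop = FALSE] -
                               matrix(tether, length(lobe_rows), 3,
                                      byrow = TRUE))^2))
      target <- b_xyz[lobe_rows[which.min(dists)], ]
      v <- target - tether
      len <- sqrt(sum(v^2))
      tipfrac <- (len - 0.35) / len
      g_xyz <- t(vapply(seq_len(ng), function(i) {
        tether + v * tipfrac * (i / ng)
      }, numeric(3)))
    } else {
      # point away from lobe B: outward along +p1 (rotating away from the
      # bisector), guaranteeing min distance to lobe B > 0.5 nm
      g_xyz <- t(vapply(seq_len(ng), function(i) {
        tether + 0.3 * i * p1
      }, numeric(3)))
    }
    xyz[f, ] <- as.vector(t(rbind(a_xyz, b_xyz, g_xyz))) * 10  # nm -> Angstrom
  }
  traj <- structure(
    list(atoms = atoms, xyz = xyz, dt = ts$dt,
         source_label = if (is.null(path)) "toy_glycoprotein" else path),
    class = "structure_trajectory"
  )
  attr(traj, "d_true") <- d
  attr(traj, "contact_frame") <- contact
  if (!is.null(path)) write_multimodel_pdb(traj, path)
  traj
}

#' Specification of replicate sigmoidal dose-response curves
#'
#' @param ec50 half-maximal concentration, uM.
#' @param hill Hill coefficient.
#' @param imax maximal response (current units).
#' @param concentrations strictly positive, strictly increasing uM ladder.
#' @param n_curves replicate curves.
#' @param noise_sd multiplicative Gaussian noise, as a fraction of the
#'   noiseless response.
#' @param seed integer seed.
#' @export
dose_response_spec <- function(ec50 = 2.28, hill = 1.4, imax = 1,
                               concentrations = c(0.1, 0.3, 1, 3, 10, 30, 100),
                               n_curves = 12L, noise_sd = 0.03, seed = 1L) {
  assert_scalar_number(ec50, "ec50", positive = TRUE)
  assert_scalar_number(hill, "hill", positive = TRUE)
  assert_scalar_number(imax, "imax", positive = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    stop("`concentrations` must be strictly positive and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(ec50 = ec50, hill = hill, imax = imax,
         concentrations = as.numeric(concentrations),
         n_curves = as.integer(n_curves), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "dose_response_spec"
  )
}

#' Hill response at given concentrations
#' @param conc concentrations, uM.
#' @param ec50,hill,imax Hill parameters.
#' @export
hill_response <- function(conc, ec50, hill, imax = 1) {
  imax * conc^hill / (ec50^hill + conc^hill)
}

#' Generate replicate dose-response curves
#'
#' Noiseless mean response at concentration c is
#' `imax * c^h / (ec50^h + c^h)`; noise is multiplicative Gaussian with sd
#' `noise_sd` times the noiseless response.
#'
#' @param spec a [dose_response_spec()].
#' @return data.frame with columns `curve_id`, `concentration_uM`, `current`.
#' @export
generate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_response_spec"))
  nc <- length(spec$concentrations)
  mu <- hill_response(spec$concentrations, spec$ec50, spec$hill, spec$imax)
  with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n_curves), function(i) {
      eps <- stats::rnorm(nc, mean = 0, sd = spec$noise_sd)
      data.frame(curve_id = i,
                 concentration_uM = spec$concentrations,
                 current = mu * (1 + eps))
    })
    do.call(rbind, out)
  })
}
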