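# Shared fixtures and independent oracles used across test files.

# fast-relaxing two-state spec: aggregate sampling >> relaxation time, so
# parameter-recovery checks are tight
fast_spec <- function(seed = 1L, n_traj = 50L, n_frames = 2000L) {
  two_state_spec(rate_close = 0.013, rate_open = 0.007,
                 n_traj = n_traj, n_frames = n_frames, seed = seed)
}

# brute-force all-pairs minimum distance (independent of the package path)
brute_min_dist <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      best <- min(best, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    }
  }
  best
}

# brute-force 2-D binning oracle ([lo, hi) bins, last bin closed)
brute_bin2d <- function(d, g, db, gb) {
  nd <- length(db) - 1L; ng <- length(gb) - 1L
  M <- matrix(0L, nd, ng)
  for (f in seq_along(d)) {
    for (i in seq_len(nd)) {
      in_i <- d[f] >= db[i] && (d[f] < db[i + 1L] || (i == nd && d[f] == db[i + 1L]))
      if (!in_i) next
      for (j in seq_len(ng)) {
        in_j <- g[f] >= gb[j] && (g[f] < gb[j + 1L] || (j == ng && g[f] == gb[j + 1L]))
        if (in_j) M[i, j] <- M[i, j] + 1L
      }
    }
  }
  M
}

# minimal synthetic single/multi-model PDB writer used as an independent
# fixture source (not via the package writer)
write_raw_pdb <- function(path, models) {
  lines <- character(0)
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    at <- models[[m]]
    for (i in seq_len(nrow(at))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, at$name[i], at$res[i], at$chain[i], at$resno[i],
        at$x[i], at$y[i], at$z[i], at$elem[i]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

simple_atoms <- function(n = 3L, chain = "A", resno = NULL, elem = "C",
                         name = "CA") {
  data.frame(name = rep(name, n), res = "ALA", chain = chain,
             resno = if (is.null(resno)) seq_len(n) else resno,
             x = seq_len(n) * 1.5, y = rep(2, n), z = rep(3, n),
             elem = rep(elem, n), stringsAsFactors = FALSE)
}
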