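---
title: "Models and methods behind glycoMSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycoMSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMSM)
```

## The scientific problem

Ionotropic glutamate receptors such as the NMDA receptor carry bilobed
extracellular ligand-binding domains (LBDs) that close like a clamshell
around their agonist. N-linked glycans decorate these domains in vivo, and
a glycan tethered near the hinge can reach across and touch the opposite
lobe — but only when the clamshell is closed. If such contacts are
energetically favourable they shift the open/closed equilibrium toward
closed conformations, which at the whole-receptor level shows up as a
left-shifted agonist dose-response curve (a lower EC50). glycoMSM
implements the quantitative machinery needed to interrogate this
hypothesis on conformational ensembles: clamshell order parameters from
structures, Markov state models (MSMs) for equilibrium populations and
relaxation timescales, tICA as an estimator cross-check,
percentile-bootstrap comparison of conformational distributions between
glycosylated and non-glycosylated conditions, glycan-contact geometry, and
Hill-equation EC50 comparison for electrophysiological validation data.

Every stage can be exercised on synthetic data with analytically known
ground truth, which is how the package validates itself.

## Order parameters

Two scalar coordinates summarize each structure frame:

* **d** — the distance between two marker C-alpha atoms, one per lobe
  (residues 507 and 701 in the GluN1 profile, 503 and 701 in GluN2B),
  in nm. Large d = open clamshell. Coordinates are stored in Angstrom (PDB
  native) and converted to nm only at this boundary.
* **d_g-ol** — the minimum heavy-atom distance between a glycan selection
  and a residue range on the opposite lobe (default 710–723), in nm.
  Heavy atom means element other than H or D, with elements inferred from
  atom names when the PDB element column is blank.

A frame "in contact" is defined by d_g-ol below a cutoff, default 0.5 nm.
The cutoff is a declared convention (it matches the empty-region boundary
of the joint (d, d_g-ol) occupancy map, where open-clamshell frames with a
glycan contact never occur) and is exposed as a configuration knob, since
no universal numeric definition of "interacting" exists.

## Markov state models

Trajectories of d are discretized by k-means (k-means++-style seeding from
a fixed seed, Lloyd iterations, ties to the lowest index). For the default
1-D featurization the package runs its own Lloyd iteration on presorted
values: with k = 99 centres on strongly bimodal 1-D data, empty clusters
arise routinely, and this variant simply lets an empty cluster keep its
centre rather than aborting. Multi-dimensional features are passed to
`stats::kmeans`.

Transition counts use a sliding window at lag τ: every pair (s_t, s_t+τ)
within a trajectory contributes; trajectories shorter than the lag are
skipped with a warning, and no pseudocounts are added. Counts are trimmed
to the largest strongly connected component (by total count mass) before
estimation — the standard ergodicity requirement.

Two estimators are provided:

* **non-reversible**: row-normalized counts, stationary distribution from
  the leading left eigenvector;
* **reversible** (default): the detailed-balance maximum-likelihood
  estimate via the classic fixed-point iteration on the symmetric flux
  matrix `x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)`, declared converged
  when the maximum relative change drops below 1e-10 (configurable), with
  π from the flux row sums. On random connected counts the result
  satisfies detailed balance to 1e-8 and matches exhaustive numerical
  likelihood maximization on chains of up to 4 states to 1e-6 (both
  asserted in the test suite).

Implied timescales follow `t_i = -τ / log(λ_i)` for eigenvalues strictly
inside (0, 1); eigenvalues at 1 report an infinite timescale and
eigenvalues at or below 0 are flagged undefined rather than silently
dropped. In reversible mode the spectrum is computed on the
π-symmetrized matrix, guaranteeing real eigenvalues.

**tICA.** The time-lagged independent component analysis uses the mean
over all frames, the instantaneous covariance over all frames, and the
symmetrized lagged covariance over intra-trajectory pairs only; the
generalized eigenproblem is solved through a Cholesky factorization with a
small ridge (default 1e-10) on the instantaneous covariance. For 1-D input
the single eigenvalue is exactly the lag-autocorrelation of the centred
series, which the tests exploit as an oracle.

The estimator grid used for condition comparison — MSM with 99 clusters at
256 ns lag, 99 clusters at 128 ns, 6 clusters at 256 ns, and tICA —
is assembled by `timescale_table()`, which reports the slowest timescale
per condition and their ratio.

## Equilibrium reweighting and the percentile bootstrap

Finite trajectory ensembles over-represent wherever they were started.
`reweighted_pdf()` recovers the equilibrium density of d by giving every
frame in discrete state i the weight π_i / n_i (stationary probability of
its state over the number of frames observed in it), then building a
weighted histogram on a 0.1 nm lattice. The 0.1 nm default bin width was
chosen because the physically meaningful enrichment ranges of d fall on a
0.1 nm lattice; it is configurable.

`pdf_difference_bootstrap()` compares two conditions per bin. The
resampling unit is the **whole trajectory**, drawn with replacement
independently within each ensemble: frames within a trajectory are
strongly autocorrelated, so frame-level resampling would understate the
variance, while trajectory-level resampling is defensible for ensembles of
independently initialized runs. Each replicate differences the two
recomputed densities per bin; the confidence interval is the equal-tail
empirical quantile band (default 95%), and bins whose interval excludes 0
are flagged significant. No multiple-testing correction is applied across
bins; the output metadata says so explicitly. Reweighted densities are
bootstrapped in fixed-weights mode by default (per-frame weights reused
across replicates); re-estimating the MSM inside every replicate is
possible but expensive and changes little when the discretization is
stable.

`bootstrap_coverage_check()` closes the loop: it simulates many ensembles
from a generator whose true bin density is known in closed form and
reports how often the nominal 95% interval covers the truth.

## The synthetic-data generators

The generators define the study conditions; they are not tuning dials.

* **Two-state switching ensembles.** A continuous-time two-state process
  (closed/open) sampled exactly at the frame spacing dt through its 2×2
  propagator — not an Euler approximation — so the slowest relaxation time
  is exactly `1/(rate_close + rate_open)` and the equilibrium closed
  fraction exactly `rate_close/(rate_close + rate_open)`. Emission is
  state-dependent Gaussian. Defaults: closed basin 3.7 nm, open basin
  4.7 nm, sd 0.15 nm (placing the enriched/depleted ranges where they are
  observed for real LBD ensembles), closed fraction 0.65 for the
  glycosylated-like condition, relaxation 520 ns, 262 trajectories × 2000
  frames at 0.2 ns — desk-scale mirrors of the real glycosylated-GluN1
  ensemble. Initial states are drawn from the exact equilibrium
  distribution (the real simulations started from 23 distinct geometries
  that are not individually characterized; the equilibrium draw keeps the
  reweighting and coverage oracles exact). What this emulates is the
  slow open/close exchange observed through a scalar coordinate; what it
  does **not** emulate is multi-state kinetics, non-Gaussian basins, or
  starting-structure bias, so passing recovery tests demonstrates
  estimator correctness, not realism of any force field.
* **Toy two-lobe glycoproteins.** Two rigid pseudo-C-alpha arms hinged at
  the origin, hinge angle chosen per frame so the marker distance d
  reproduces a two-state series exactly (`d = 2R sin(θ/2)`, arm radius
  R = 3.5 nm), plus an 11-atom linear pseudo-glycan tethered to lobe S1.
  In closed frames the glycan swings toward the nearest opposite-lobe
  atom of the 710–723 range (tip 0.35 nm short of it) with a configurable
  probability; otherwise it points away, and contact placement is refused
  outright for any frame with d > 5.2 nm. The joint (d > 5.2 nm,
  d_g-ol < 0.5 nm) block is therefore empty **by construction** — the
  geometry-operator chain must reproduce that exact zero. Only distance
  statistics are consumed downstream, so geometric simplicity is
  preferred over glycan stereochemistry.
* **Dose-response curves.** The Hill function
  `I(c) = Imax c^h / (EC50^h + c^h)` with multiplicative Gaussian noise;
  defaults EC50 2.28 μM, h 1.4, 3% noise, 12 replicate curves over the
  0.1–100 μM half-log ladder used in the validation electrophysiology.

All generators are seed-pure: identical spec plus seed gives bit-identical
output, and the RNG state of the session is restored afterwards.

## Hill fitting and group comparison

Curves are normalized by their observed maximum (fitted-maximum mode is
available), then fit by Levenberg–Marquardt least squares on the linear
response scale, initialized at EC50 = geometric mean of the
concentrations, h = 1, Imax = maximal response, with h bounded to
(0.2, 5) — the Hill coefficient is fitted per curve rather than fixed.
Group comparison uses the equal-variance Student's t-test on per-curve
EC50 values (log-EC50 testing is available as an option), reporting group
means ± SEM and the percent change of the second group relative to the
first. Fitting each replicate and then comparing groups is the default;
fitting a single curve to averaged data is possible by averaging before
fitting.

## Numerical choices and problem sizes

* Reversible-MLE convergence 1e-10 (max relative change), iteration cap
  1e5, error with residual on non-convergence.
* tICA ridge 1e-10; singular covariance raises an error naming the knob.
* k-means ties break to the lowest index; centre shifts below 1e-12 stop
  Lloyd.
* Histogram bins are `[lo, hi)` with the last bin closed; out-of-range
  frames go to reported overflow, never silently vanish.
* The validation experiments run at the following sizes, chosen to mirror
  the real study at desk scale: timescale recovery on 262 (respectively
  247) trajectories × 2000 frames at 0.2 ns with relaxation calibrated to
  0.52 μs (0.21 μs); bootstrap coverage on 500 ensembles of 50 × 1000
  frames with relaxation 50 ns (rates 0.0130/0.0070 per ns), so each
  200-ns trajectory spans about four relaxation times; EC50 recovery on
  12 curves per condition.
* The estimator-consistency experiment (MSM 99/256, 6/256, 99/128, tICA
  agreeing on one slowest timescale) uses emission sd 0.02 nm: the
  consistency property holds for *Markovian* input, and Gaussian emission
  noise makes the observed coordinate a hidden-Markov rather than Markov
  process. A closed-form attenuation analysis shows the tICA
  autocorrelation is damped by the noise-to-basin variance ratio
  (about 9% timescale underestimate at sd 0.15 nm, under 1% at
  sd 0.02 nm), so the near-noiseless emission is the faithful statement
  of that study condition.

## Known limitations

* At the mirrored study scale the aggregate sampling is only about 200
  times the slowest relaxation time, so the slowest-timescale estimator
  carries an intrinsic seed-to-seed standard deviation around 15%, plus a
  small upward bias from the convexity of `-τ/log(λ)`; single-ensemble
  recovery experiments at a 10% tolerance therefore fail for an
  appreciable fraction of seeds. This is a property of the study design
  (the real ensembles have the same sampling depth), not of the
  estimator implementation; tighter checks in the test suite use
  faster-relaxing generators with 1000–2000× sampling.
* The MSM machinery deliberately omits Bayesian error bars, hidden Markov
  models, coarse-graining (PCCA+) and transition-path theory.
* Structure input is multi-model PDB only (no mmCIF, no binary trajectory
  formats); residue numbers are taken verbatim from the file.
* The bootstrap makes no small-sample correction beyond the percentile
  method itself; with very few trajectories the intervals undercover
  (visible in `bootstrap_coverage_check()`).
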