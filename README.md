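# glycoMSM

Markov state models and ensemble statistics for glycan-modulated clamshell
dynamics of receptor ligand-binding domains (LBDs).

## The problem

The extracellular ligand-binding domains of NMDA receptors are bilobed
"clamshells" that close around their agonist, and they carry N-linked
glycans. A glycan tethered near the hinge can reach the opposite lobe, but
only in closed conformations — so favourable glycan–lobe contacts shift
the conformational equilibrium toward the closed (activated) state, which
at the receptor level shows up as a change in the agonist EC50. Testing
this mechanism quantitatively requires a chain of analyses on
conformational ensembles:

* **Order parameters** — the interlobe marker distance *d* (Cα 507–701 in
  GluN1, 503–701 in GluN2B, reported in nm) and *d*<sub>g-ol</sub>, the
  minimum heavy-atom distance between a glycan and the opposite-lobe
  residue range 710–723; joint (d, d_g-ol) occupancy maps; per-residue
  contact profiles at a 0.5 nm cutoff.
* **Kinetics** — k-means discretization of *d*, sliding-window transition
  counts, reversible (detailed-balance maximum-likelihood) and
  non-reversible MSM estimation, implied timescales
  t<sub>i</sub> = −τ/ln λ<sub>i</sub>, and tICA timescales as an
  independent estimator family.
* **Equilibrium statistics** — MSM reweighting of the *d* histogram
  (frame weight π<sub>state</sub>/n<sub>state</sub>) and per-bin
  comparison of two conditions with a trajectory-level percentile
  bootstrap at 95% confidence.
* **Validation electrophysiology** — Hill-function fits
  I(c) = I<sub>max</sub>·c<sup>h</sup>/(EC50<sup>h</sup> + c<sup>h</sup>)
  to replicate dose-response curves and an equal-variance Student's
  t-test on per-curve EC50 between wild-type and mutant groups.

Because real microsecond-scale trajectory ensembles are not shippable, the
package includes first-class synthetic-data generators with exact analytic
ground truth (two-state switching ensembles, toy two-lobe glycoprotein
structures written as multi-model PDB, replicate dose-response curves);
every estimator is validated against these closed forms. See the methods
vignette (`vignettes/glycoMSM-methods.Rmd`) for the models, assumptions
and numerical choices.

## Worked example

Compare a closed-favouring ("glycosylated-like", closed fraction 0.65)
ensemble against a balanced one (0.50), both with a 50 ns relaxation time:

```r
library(glycoMSM)

glyc <- generate_two_state_ensemble(two_state_spec(
  rate_close = 0.013, rate_open = 0.007, n_traj = 60, n_frames = 1000, seed = 1))
bare <- generate_two_state_ensemble(two_state_spec(
  rate_close = 0.010, rate_open = 0.010, n_traj = 60, n_frames = 1000, seed = 2))

timescale_table(glyc, bare, ks = c(20L, 6L), lags_ns = c(12.8, 25.6),
                tica_lag_ns = 12.8, seed = 3)
#>                       estimator  k lag_ns timescale_us_with timescale_us_without ratio
#> 1 MSM, 20 clusters, lag 12.8 ns 20   12.8            0.0540               0.0492  1.10
#> 2 MSM, 20 clusters, lag 25.6 ns 20   25.6            0.0533               0.0491  1.08
#> 3  MSM, 6 clusters, lag 12.8 ns  6   12.8            0.0540               0.0492  1.10
#> 4  MSM, 6 clusters, lag 25.6 ns  6   25.6            0.0532               0.0491  1.08
#> 5                          tICA NA   12.8            0.0391               0.0370  1.06
```

Both MSM variants recover the generator's exact 0.050 μs relaxation time
within estimator noise, and the with/without ratio scatters around 1 —
the two conditions differ in *equilibrium*, not in *rate*. The tICA row
reads low because Gaussian emission noise damps the autocorrelation of the
raw coordinate (quantified in the vignette).

```r
pdf_difference_bootstrap(glyc, bare, n_boot = 500, seed = 4)
#> bootstrap_result: 24 bins, level 0.95, n_boot 500
#> significant bins (nm): [3.10,3.20] [3.30,3.40] [3.40,3.50] [3.50,3.60]
#>   [3.60,3.70] [3.70,3.80] [3.80,3.90] [3.90,4.00] [4.00,4.10] [4.40,4.50]
#>   [4.50,4.60] [4.60,4.70] [4.70,4.80] [4.80,4.90] [4.90,5.00]
```

The closed basin (3.3–4.1 nm) is significantly enriched and the open
basin (4.4–5.0 nm) significantly depleted in the closed-favouring
condition — the distribution-shift signature of a potentiating contact.

```r
wt  <- fit_hill_curves(generate_dose_response(dose_response_spec(ec50 = 2.28, seed = 5)))
mut <- fit_hill_curves(generate_dose_response(dose_response_spec(ec50 = 3.43, seed = 6)))
compare_groups(wt, mut)
#> group_comparison: A 2.31 +/- 0.039 uM (n=12) vs B 3.53 +/- 0.075 uM (n=12)
#>   change +52.3%, t = 14.3, p = 1.29e-12
```

Twelve noisy replicate curves per group recover the generating EC50s
(2.28 and 3.43 μM) and call the ~50% EC50 increase highly significant.

The whole chain — synthetic fixtures, geometry, estimator grid, bootstrap,
dose-response — also runs as one configuration-driven pipeline:

```r
run_pipeline(list(seed = 1), outdir = "glycomsm_out")
# or from the shell:
#   Rscript inst/scripts/glycomsm.R --outdir glycomsm_out --seed 1
```

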