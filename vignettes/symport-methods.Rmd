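---
title: "Models and estimators in symportkit"
author: "symportkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in symportkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symportkit)
```

symportkit bundles the quantitative machinery used to characterize a
proton-coupled symporter of the major facilitator superfamily — a 2 H+ :
1 galactonate transporter studied by solid-supported membrane
electrophysiology (SSME) and molecular simulation. This vignette explains
the models, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices that a user
changing the defaults should know about.

## The eight-state transport cycle

`build_dgot_cycle()` constructs an alternating-access cycle with eight
states: outward-facing apo (1), doubly protonated (2), galactonate-bound
(3), occluded (4), inward-facing loaded (5), first proton released (6),
galactonate released (7), and inward-facing apo (8); step 8 -> 1 is the
reorientation of the empty carrier. Ligand-dependent steps follow mass
action: binding steps are multiplied by the facing concentration raised to
the ligand count (both protons bind in one step of count 2), release steps
acquire concentration-dependent *rebinding* in the backward direction.

**Thermodynamic consistency.** For any solution condition the product of
forward over backward pseudo-first-order rates around the loop must equal
`exp(-dG/RT)` with `dG = 2 dmu_H + dmu_gal` (a generalized Haldane
relation) — otherwise the model would pump at equilibrium.
`apply_solution_conditions()` enforces this exactly by rescaling the
backward rate of the empty-carrier return step, the least experimentally
constrained transition. Because the concentration factors in the loop
product cancel against `exp(-dG/RT)` term-by-term, the constraint reduces
to a condition-independent normalization of the base rates.

**Rate defaults.** The outward substrate step uses the measured induced-fit
parameters (K_D = 15.1 mM; conformational step 70.6 / 23.8 s^-1). The
remaining rates are free parameters; they were fixed once so that (i) the
empty-carrier return (12 s^-1) is the slowest forward rate at reference
conditions, reflecting its rate-limiting role, and (ii) the peak current
versus symmetric pH is bell-shaped with a maximum near pH 7.5: the outer
proton pair titrates near pK 8.3 (alkaline deactivation: no protons, no
gate opening) and the inner release sites near pKa 7.0 (acidic
deactivation: an acidic interior traps the protons by mass action).

**Charge displacement.** Only the net charge per loop (+1: two protons and
one monovalent anion inward) is physically fixed. The split across
transitions is configurable; the default treats ion binding from the
aqueous phases as electroneutral and moves the charge during the
conformational (0.1 + 0.1) and inner release (0.3 + 0.2 + 0.3) steps,
i.e. while the loaded carrier opens inward and discharges. This choice is
constrained by two experimental signatures: galactonate-jump transients are
*positive*, and the peak-current pH dependence is bell-shaped. Placing the
full -1 on anion binding (a plausible alternative) produces a dominant
negative binding spike that contradicts both.

**Readout model.** SSME senses transport capacitively; no instrument
transfer function is published, so the recording model is a deliberate,
flagged modelling choice: a first-order high-pass (coupling constant 0.3 s)
followed by a first-order rise-time filter (10 ms), with unit gain. A
useful identity: over a phase much longer than the coupling constant, the
integral of the high-passed current telescopes to `tau_c * I_ss`, so
integrated A-phase charge tracks steady-state turnover — which is exactly
what the reversal assay needs (see below). A much slower coupling constant
would let the one-shot occupancy-redistribution transient bias the
reversal point; with the default the crossing sits at the thermodynamic
reversal to three digits.

**Integration.** The master equation is propagated with `deSolve::lsoda`
(error-controlled, stiffness-switching) because the pseudo-first-order
rates span several orders of magnitude; the output sampling interval `dt`
only controls the reporting grid, but a guard rejects `dt` too coarse for
the readout time constants.

## Reversal assay and stoichiometry

The free energy of the coupled reaction is `dG = n dmu_H + m dmu_gal`; the
current reverses at `dG = 0`, where the ratio of chemical-potential
differences `ln(gal_in/gal_out) / ln([H]_out/[H]_in)` equals n/m.
`reversal_assay()` reproduces the protocol: interior pH 7.3 with 0.5 mM
galactonate, external activating solutions at pH 7.6 with galactonate set
so the ratio spans 0–4, NA/A/NA phases of 2/3/3 s, A-phase charge
integration, and a piecewise-linear zero crossing between the two
bracketing ratios (no functional form is imposed on charge vs ratio).

```{r reversal, eval = FALSE}
res <- reversal_assay(ratios = seq(0, 4, by = 0.25))
res$n_over_m   # ~2.0 for the default 2 H+ : 1 galactonate cycle
```

A single-proton variant (`n_protons = 1`, electroneutral substrate) run
through the identical pipeline reverses at ratio 1 — a consistency check
that the estimator measures coupling stoichiometry and not an artifact of
the protocol.

## SSME trace analysis

* `peak_current()` takes the largest-magnitude A-phase sample (sign
  preserved; mutant-like currents can be negative).
* `fit_decay()` fits `I = sum A_i exp(-t/tau_i)` from the peak
  (Levenberg–Marquardt; bi-exponential fits start from log-spaced time
  constants around the mono-exponential solution, best residual wins);
  `k_obs = 1/tau` of the dominant component.
* `pka_fit()` fits the acidic (`I_max/(1+10^(pK-pH))`, pH <= 8) or
  alkaline (`I_max/(1+10^(pH-pK))`, pH >= 7.5) titration curves. The
  published procedure normalizes currents to the fitted `I_max`, which is
  circular if taken literally; fitting `I_max` and `pK` jointly on
  unnormalized peaks reaches the same optimum in one pass, so that is what
  the package does, reporting normalized curves afterwards.
* `fit_induced_fit()` fits `k_obs = k- + k+ gal/(gal + K_D)`. The model is
  linear in `(k-, k+)` at fixed `K_D`, so initialization profiles `K_D` on
  a log grid with weighted linear solves before the nonlinear polish; if
  the polish fails on a flat profile the profiled optimum is returned with
  a Jacobian-based covariance. For data with multiplicative noise, weights
  `1/k_obs^2` are the matching variance model.
* `integrate_charge()` uses the trapezoid over the A phase after
  subtracting a baseline; the baseline window is unstated in the source
  protocol, so the default is the mean of the last 0.2 s of the preceding
  NA phase.
* `lpr_decay_comparison()` reports whether decay times fall with the
  lipid-to-protein ratio (transport signature) or are LPR-independent
  (pre-steady-state signature).

## Synthetic data: what it does and does not emulate

All generators are pure functions of parameters and seed. `gen_ssme_dataset()`
adds white current noise to cycle simulations; `gen_kobs_dataset()` draws
`k_obs` values with multiplicative Gaussian noise, three measurements per
concentration by default (matching the usual per-condition sensor count —
with a single draw per concentration, nonlinear-least-squares bias alone
exceeds 2% on `K_D` at 5% noise, which no fitting choice can remove);
`gen_pka_dataset()` does the same for titration curves.

Langevin sampling (`langevin_sample()`, overdamped Euler–Maruyama, C++
inner loop) on toy potentials stands in for unbiased MD: a double well, a
periodic dihedral-like potential with minima near ±70° and inequivalent
barriers, and a 2D three-well landscape. `lift_to_features()` embeds the
low-dimensional CVs in a high-dimensional noisy feature space through a
random orthonormal affine map, emulating pairwise-distance featurization
with a *known* slow subspace for oracle tests.

What passing these tests shows: the estimators (tICA, MSM, PCCA+,
reweighting, TI) recover known answers from data with the right
statistical structure. What it does not show: anything about force fields,
sampling adequacy of a real protein, or the true free-energy surfaces of
the transporter — those require microsecond MD and QM/MM and are
explicitly out of scope.

**Three-well defaults.** Wells at (-1,0), (1,0), (0,1.6) with depths
26/24.5/22.5 kJ/mol, width 0.45 and a 2 kJ/mol quadratic confinement at
kT = 2.579 kJ/mol (RT at 310.15 K). The ~8 kT barriers give clean
metastability at the saved-frame resolution, and the unequal depths give
distinguishable stationary probabilities (~0.57/0.34/0.10) whose smallest
entry is still estimable to a few percent from ~10^7 steps. Much shallower
wells make hop times comparable to the frame interval and the MSM
eigenvalue structure degenerates — a property of the conditions, not of
the estimators.

## Trajectory analytics

Distances use the minimum-image convention in orthorhombic boxes
(triclinic is out of scope); coordinates are in Å, bins are half-open
`[a, b)`, frames are indexed from 1. "Side chain" means Cβ and beyond —
the atom set is not defined in the source, so it is fixed here.
Gate classification defaults to closed < 13 Å / open > 15 Å for the
gating-helix COM distance, with configurable thresholds (e.g. 12.5 Å or
8 Å for aromatic-lock minimum distances). Hydration profiles count waters
in 2 Å sections along the pore axis (z by default); occupancy maps mark a
grid node occupied when any water lies within half a grid spacing
(Euclidean) of it. `cluster_gromos()` implements the Daura
neighbor-counting algorithm on pairwise RMSD after Kabsch superposition,
ties broken toward the lower frame index; note the 0.04 Å cutoff printed
in the source methods is likely a units slip of 0.04 nm, so the cutoff is
an explicit argument with no default guessed. `block_overlap_convergence()`
computes per-block histogram overlaps with the total distribution
(converged when all blocks >= 0.8).

## Smeared-Ewald electrostatics

`smeared_potential_grid()` computes the reciprocal-space Ewald potential
of Gaussian-smeared charges (inverse width β, default 20 nm^-1) exactly:
the structure factor is evaluated at the true charge positions for every
k-vector of the grid and transformed with
`exp(-k^2/(4 beta^2))/k^2`, dropping k = 0 — this both imposes a zero-mean
convention (the absolute reference of the reference tool is unstated, so
zero-mean is adopted and documented) and neutralizes non-neutral systems
with a uniform background (warned). Only comparisons between chemically
identical groups are meaningful, since the residue-specific short-range
part is excluded by construction. The grid must resolve 1/β: a warning
fires when the Nyquist attenuation is above 1%. Values are in kT/e at
310.15 K (`kTe_to_mV()` converts). Region averages take all grid nodes in
a sphere (min-image), and `hydration_gated_average()` averages a regional
potential over frames whose water occupancy exceeds a threshold.

## Markov state model pipeline

`tica_fit()` solves the symmetrized time-lagged covariance eigenproblem
with diagonal shrinkage (default 1e-10 relative to the trace — lifted
feature spaces are rank-deficient by construction); components are
orthonormal in the covariance metric and two are kept by default.
`cluster_microstates()` is seeded k-means (default k = 100 for toy data);
on long trajectories the centers are fitted on a 50 000-frame seeded
subsample and all frames assigned to the nearest center.
`estimate_reversible_msm()` is the standard maximum-likelihood reversible
estimator: a fixed point on symmetric flux variables restricted to the
largest strongly connected count set, giving detailed balance to machine
precision and the stationary distribution for free. Implied timescales
`-tau/ln lambda` are reported per lag with a plateau verdict (relative
change below 10% between successive lags). `pcca_coarse_grain()` is PCCA+:
simplex vertices among the dominant right eigenvectors located by
farthest-row search with Gram–Schmidt deflation, barycentric memberships
clipped to [0, 1] and row-normalized (degenerate spectra fall back to an
error suggesting fewer macrostates). The Chapman–Kolmogorov test compares
`T(tau)^k` against re-estimated `T(k tau)` on the PCCA sets.
`weighted_fes()` reweights frames by `pi(state)/count(state)`; empty bins
are `NA`, never zero. `adaptive_seed_selection()` returns the frames
nearest a target region (ties to the lower index) — the restart heuristic
used to bridge sampling gaps between conformational basins.

Problem sizes used in the packaged end-to-end validation: 10^7 Langevin
steps (single trajectory in the test, three well-seeded trajectories in
the acceptance script), 50 features, 100 microstates, lag 100 frames;
the recovered macrostate probabilities sit within 10% of Boltzmann
quadrature and the slowest implied timescale within 20% of a fine-grid
Smoluchowski discretization.

## Free-energy estimators

`wtmtd_simulate()` runs well-tempered metadynamics on a 1D CV (heights
1.2 kJ/mol tempered with bias factor 15, sigma 0.35 rad, deposition every
500 steps — standard dihedral settings), with the bias kept on a grid
(400 points) and periodic CVs wrapped on [-pi, pi); non-periodic domains
use reflecting walls. `wtmtd_reweight()` implements time-dependent
reweighting: each frame carries `exp((V(s_t,t) - c(t))/kT)` with the
offset `c(t)` computed from the bias grid at every deposition. One subtle
periodic-grid point: the first and last grid node are the same physical
CV value, so their histogram bins each collect only half a bin of
samples; the implementation merges them (without this, the profile shows
a spurious `kT ln 2` bump at the boundary). The final-bias estimate
`-(gamma/(gamma-1)) V_bias` is provided as an internal cross-check.

`blue_moon_mean_force()` samples the constraint force at a fixed CV
(exactly `dU/ds` plus optional zero-mean bath noise and an equilibration
transient for the toy sampler), discarding an initial fraction (default
25%) and reporting block-averaged (5 blocks) standard errors because
constraint-force samples are correlated. `ti_integrate()` applies the
cumulative trapezoid over windows ordered in CV (0.08 Å spacing in the
reference protocol) with error propagation through the trapezoid weights;
the kinetic correction is omitted, appropriate when the
donor–proton–acceptor angle barely fluctuates. Trapezoid integration is
exact for linear mean forces and O(h^2) otherwise — halving the spacing
cuts the error about fourfold.

## Configuration and reproducibility

`load_config()` validates YAML configurations (unknown keys rejected by
name, stochastic stages require a seed, file hash recorded);
`run_pipeline()` executes a named stage and writes artifacts plus a log
with versions, seed and wall time. Identical configuration and seed give
bit-identical outputs. The package's interface is its functions — the
staged runner exists for scripted reproduction, not as a substitute for
the API.

## Known limitations

* The SSME readout is a two-parameter linear filter; real sensor
  electrodynamics (liposome charging, solution-exchange artifacts) are not
  modelled, and no attempt is made to fit the model's hidden rates to real
  recordings.
* Membrane potential does not feed back on the rates; the cycle is driven
  by concentrations only, as in SSME.
* Minimum-image support is orthorhombic; metadynamics is 1D; MSM
  estimation offers no Bayesian uncertainty.
* Toy Langevin systems validate estimator correctness, not the biology of
  any particular transporter.
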