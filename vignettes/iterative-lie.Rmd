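---
title: "Iterative Boltzmann-weighted LIE models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative Boltzmann-weighted LIE models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iterlie)
```

## The model

The linear interaction energy (LIE) method estimates a ligand's protein
binding free energy from two molecular dynamics (MD) ensemble averages:
the mean electrostatic and van der Waals interaction energies between
the ligand and its surroundings, once simulated bound to the protein and
once free in water.  For a simulation started in pose/conformation $i$,

$$\Delta G_i \;=\; \beta\,\Delta V^{EL}_i \;+\; \alpha\,\Delta V^{VdW}_i,$$

where $\Delta V^{EL}_i$ and $\Delta V^{VdW}_i$ are the bound-minus-free
differences of the two averages (kJ/mol) and $\alpha$, $\beta$ are
empirical coefficients.  Linear response theory suggests $\beta = 0.5$;
in practice both coefficients are calibrated against experiment, and
$\beta$ may come out small or even negative for apolar-dominated
binding.  An alternative "offset" variant fixes $\beta = 0$ and adds a
constant $\gamma$ (kJ/mol): $\Delta G_i = \alpha\,\Delta V^{VdW}_i +
\gamma$.

Flexible enzymes such as the cytochrome P450s undermine the single-
simulation assumption behind this formula: one short MD run cannot
sample all relevant protein conformations and ligand poses.  The
approach implemented here instead runs several independent simulations
per ligand — different protein conformations (e.g. Phe483 rotamers
labelled `P70`/`P170` for CYP 2D6), different docked poses (`M1`/`M2`),
different replicates (`S1`/`S2`) — and combines them through Boltzmann
weights

$$W_i \;=\;
\frac{e^{-\Delta G_i / k_B T}}{\sum_j e^{-\Delta G_j / k_B T}},
\qquad
\Delta G_{calc} \;=\;
\beta \sum_i W_i\,\Delta V^{EL}_i + \alpha \sum_i W_i\,\Delta V^{VdW}_i,$$

so that simulations reaching lower free energy dominate the prediction
automatically, without choosing a binding mode a priori.
$\Delta G_{calc}$ equals the weight-average $\sum_i W_i \Delta G_i$, an
identity the test suite asserts to $10^{-10}$.

Replicate runs started from the *same* configuration can be treated two
ways (`model_spec(scheme = ...)`): `"separate"` gives every replicate
its own weight; `"replicate_averaged"` first averages the replicates'
interaction energies per configuration and weights the configurations.
In the limit of converged sampling the replicate averages coincide and
the two schemes agree exactly — a property the tests check on synthetic
data with zero replicate scatter.

## Self-consistent calibration

The weights depend on $(\alpha, \beta)$, which are themselves obtained
by fitting $\Delta G_{calc}$ to experimental values, so calibration is a
fixed-point problem.  `lie_calibrate()` alternates:

1. evaluate $\Delta G_i$ and the weights at the current coefficients;
2. refit the coefficients by ordinary least squares on the
   weight-averaged differences $(\sum_i W_i \Delta V^{EL}_i,\;
   \sum_i W_i \Delta V^{VdW}_i)$ — no intercept for the standard
   variant, an intercept (= $\gamma$) on the van der Waals term alone
   for the offset variant;

until the largest coefficient change is below `tol` ($10^{-6}$) *and*
the RMSE change is below `rmse_tol` ($10^{-8}$ kJ/mol), both far below
the 3-decimal reporting precision of typical LIE calibrations.  The
objective is the root-mean-square error over ligands with $1/n$
normalization — an error of fit, not an unbiased variance estimate —
and experimental error bars are not used as regression weights.

Two numerical points deserve note:

* **Non-monotone approach.** The fixed point of the weight/refit
  alternation does not coincide exactly with the local RMSE minimum:
  because the weights move with the coefficients, the final approach is
  a damped oscillation in which individual refit steps can raise the
  RMSE by a vanishing amount (typically $10^{-7}$–$10^{-4}$ kJ/mol,
  growing with observation noise).  When a step increases the RMSE the
  optimizer therefore first tries up to 10 step-halvings and, if none
  of the damped steps helps either, keeps the full step: that small
  rise *is* the route to self-consistency.  Genuine oscillation between
  attractors never becomes stationary and is reported as
  non-convergence when `max_iter` (default 500) is exhausted, with the
  full restart log attached to the error condition.
* **Multiple fixed points.** Since the objective is non-convex in the
  weights, the fit is restarted from a $3 \times 3$ grid
  $(\alpha, \beta) \in \{0.1, 0.4, 0.7\}^2$ plus the linear-response
  point $(0.5, 0.5)$; every restart is recorded and the lowest-RMSE
  converged fixed point is returned.  Negative $\beta$ values are
  allowed — they occur in published calibrations.

Weights are computed shift-stably (the per-ligand minimum $\Delta G_i$
is subtracted before exponentiating), so arbitrarily large energy
magnitudes cannot overflow, and in the $k_BT \to 0$ limit the weight
concentrates on the minimum-free-energy simulation, shared equally
among exact ties — the continuous limit of the softmax.

The thermal energy defaults to $k_BT = 0.0083145 \times 300 \approx
2.494$ kJ/mol, matching the usual 300 K simulation temperature; it is a
parameter (`kT`) everywhere because the weighting temperature is in
principle a modelling choice, not a law.

`rmse_surface()` maps the same objective over an $(\alpha, \beta)$ grid
with the weights recomputed at every grid point and *no* refitting
inside a cell; a `weights = "frozen"` mode evaluates the grid at the
weights of a reference parameter set instead, isolating the linear part
of the objective.  Values are reported unclamped; cells above a display
ceiling (5 kJ/mol by default, the top of the conventional 2–5 kJ/mol
contour window) are merely flagged for plotting.

## Outliers and reporting conventions

A ligand is an outlier when $|\Delta G_{calc} - \Delta G_{exp}|$
strictly exceeds 1 kcal/mol = 4.184 kJ/mol (configurable); absolute
errors are reported to 2 decimals, sorted by ligand id.  Model-summary
tables print $\beta$ before $\alpha$, and weight tables print 3
decimals with the per-ligand maximum flagged — the layouts used in the
LIE literature, which eases side-by-side comparison.

## Experimental affinities from IC50 data

Inhibition data are converted as
$$\Delta G_{exp} = R\,T \ln\!\left(\mathrm{IC}_{50}/c^\circ\right),$$
with $R = 0.0083145$ kJ mol$^{-1}$ K$^{-1}$, $T = 300$ K and reference
concentration $c^\circ = 1$ mol/L (both overridable).  These are
*relative* binding free energies: no Cheng–Prusoff correction for
substrate competition is applied (the assay constants needed for one
are not generally available).  The packaged ten-ligand thiourea CYP 2D6
table is reproduced entry-for-entry to ±0.01 kJ/mol by this convention,
which is why it is the default.

The error bars are propagated as
$$\sigma_{\Delta G} = R\,T \ln\!\left(
\frac{\mathrm{IC}_{50}}{\mathrm{IC}_{50} - \sigma}\right),$$
the free-energy shift of lowering the IC50 by one standard deviation.
This rule is *inferred*: it reproduces all ten packaged uncertainties
to ±0.01 kJ/mol, but it is not derived from a stated propagation
formula, and it diverges as $\sigma \to \mathrm{IC}_{50}$ (hence the
hard validation error at $\sigma \ge \mathrm{IC}_{50}$).  Treat
converted uncertainties as descriptive, not inferential.

## What the synthetic generator emulates

`generate_lie_data()` produces data sets on which calibration is
testable because the truth is known.  Its structure mirrors the
hierarchy of a multi-conformation LIE study:

* per ligand, central differences $(\Delta V^{EL}, \Delta V^{VdW})$
  drawn uniformly from $[-60, 0]$ and $[-120, -20]$ kJ/mol —
  magnitudes typical of drug-like CYP binders;
* per starting configuration (2 protein conformations × 2 poses by
  default), Gaussian offsets with `pose_offset_scale` = 8 kJ/mol on
  both components.  Through the coefficients this yields
  per-configuration free-energy spreads of a few $k_BT$, i.e.
  order-of-magnitude contrasts between configuration weights, the
  regime reported for real multi-pose calibrations;
* per replicate (2 by default), Gaussian scatter of the averages with
  `replicate_noise_sd` = 1 kJ/mol, emulating the imperfect convergence
  of ~1 ns runs;
* $\Delta G_{exp}$ = the Boltzmann-weighted combined value at the
  ground-truth coefficients ($\alpha = 0.411$, $\beta = 0.217$ by
  default, representative published values) over all simulations
  treated separately, plus `obs_noise_sd` = 1 kJ/mol observation noise.

Free-state averages are drawn independently and the bound-state values
are constructed as free + difference, so the intended deltas hold
exactly.  Generation is byte-reproducible from the seed and leaves the
caller's RNG stream untouched.

What the generator does **not** emulate: time-correlated frames (only a
minimal AR(1) helper exists, for exercising the block-averaging code),
non-Gaussian tails of interaction-energy distributions, systematic
force-field bias shared between ligands, and any coupling between a
pose's electrostatic and van der Waals offsets.  Passing the recovery
tests therefore demonstrates the *estimator* is correct and
self-consistent — not that real MD energies satisfy the linear model.

With all noise terms at zero the generated affinities satisfy the model
exactly, and calibration recovers the generating coefficients to
$10^{-4}$ with fit RMSE below $10^{-8}$ under both replicate schemes;
with 1 kJ/mol observation noise and 50 ligands the estimates fall
within 3 estimated standard errors of truth across 20 seeds.  These
problem sizes (10–50 ligands, 8 simulations per ligand, 20 seeds) keep
the whole suite comfortably fast while leaving the estimator nowhere to
hide.

## Degenerate inputs and edge cases

* A constant predictor column (all weighted $\Delta V^{VdW}$ equal, for
  instance) is rejected as a degenerate design even when the matrix is
  formally full-rank: the coefficient would only mimic an offset, which
  is physically meaningless in the no-intercept variant.  Proportional
  columns are rejected as collinear, with the offending columns named.
* Duplicate simulations are *not* deduplicated: an extra copy of a
  simulation legitimately shifts the weighted mean unless all of the
  ligand's per-simulation free energies are equal.  Duplicate
  simulation *keys* in an input table, by contrast, are a validation
  error.
* A configuration with a single replicate contributes that run
  unchanged under both combination schemes (with a message under
  averaging).
* `max_iter = 0` returns the initial guess with its RMSE and
  `converged = FALSE`, which gives scripts a cheap way to evaluate a
  parameter set under the calibration bookkeeping.
* Time-series averaging requires at least 2 retained frames and
  strictly increasing times; standard errors use 10-block averaging by
  default (block-count reduced for very short series).  The default
  discard fraction is 0 because stored production data are taken to be
  post-equilibration; the standard errors are reported only — they do
  not enter the fit.

## Known limitations

* The calibration quality on real systems is bounded by the LIE
  linearity assumption and by MD sampling; nothing here fixes either.
* The IC50 conversion ignores assay-specific competition corrections,
  so converted values are comparable within one assay, not across
  assays.
* RMSE surfaces are evaluated for the standard two-coefficient variant
  only; the offset variant has a closed-form profile over $\gamma$ and
  does not need a grid.
* The restart grid covers the physically plausible coefficient range;
  exotic fixed points far outside $[0, 1]$ would need user-supplied
  initial guesses.
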