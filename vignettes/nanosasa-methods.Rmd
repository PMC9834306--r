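---
title: "Surrogate modelling of nanoparticle SASA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling of nanoparticle SASA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Molecular-dynamics (MD) simulation of a drug-carrier nanoparticle — a gold
core functionalized with ligands and drug residues — is the standard in
silico tool for judging whether a candidate design keeps its drug exposed to
solvent. The solvent-accessible surface area (SASA, in Å²) of the particle is
the efficacy proxy: designs whose SASA collapses early bury their payload.
Running hundreds of nanoseconds of MD per candidate is expensive, so
`nanosasa` implements a machine-learning surrogate: observe only a short
prefix of the trajectory, forecast the rest in descriptor space, and read the
SASA of the forecast state off a regression model. A Shapley-style
attribution layer then explains which element-pair interactions drive the
predicted SASA, residue by residue.

The package is organised as a chain of small, separately testable stages:

1. **Trajectory I/O** — PDB snapshots (one per nanosecond) in and out,
   descriptor and SASA tables as CSV.
2. **MBTR descriptor** — each snapshot becomes a fixed-length two-body
   many-body tensor representation vector.
3. **SASA oracle** — a deterministic Shrake–Rupley implementation supplies
   ground truth.
4. **Synthetic data** — a seeded generator of nanoparticle-like trajectories
   with planted compaction dynamics.
5. **Forecasting** — a per-feature gradient-boosted ensemble (primary) and a
   scaled-down attention encoder (baseline).
6. **SASA regression** — descriptor vector to SASA, feed-forward network or
   boosted trees.
7. **Combined inference** — rollout + regression, with a window-size sweep.
8. **Attribution** — per-residue element-pair importances.

## The two-body MBTR descriptor

A snapshot with atoms at positions $R_l$ is encoded per unordered element
pair $(Z_1, Z_2)$. Every atom pair contributes its **inverse distance**
$g_2 = 1/\lVert R_l - R_m\rVert$ (units 1/Å), broadened by a Gaussian kernel
of width $\sigma_2$ and weighted by $w_2 = e^{-s\,d_{lm}}$, where $d_{lm}$ is
the interatomic distance in Å:

$$\mathrm{MBTR}_2^{Z_1,Z_2}(x) \;=\; \sum_{l<m}\; w_2^{l,m}\,
\frac{1}{\sigma_2\sqrt{2\pi}}\, e^{-\tfrac{(x - g_2(R_l,R_m))^2}{2\sigma_2^2}}$$

evaluated at `n_grid` points $x$ evenly spaced on
$[\mathtt{grid\_min}, \mathtt{grid\_max}]$. Blocks are concatenated in a
canonical order (pairs sorted lexicographically by atomic number), giving

$$n_\text{features} = \frac{n_\text{elements}(n_\text{elements}+1)}{2}
\times n_\text{grid},$$

i.e. **72 features** at the defaults (8 elements, 2 grid points). The
encoding is invariant under atom permutation (exactly — atoms are sorted
into a canonical order before accumulation, so even the floating-point
summation order is fixed) and under rigid motion (to ~1e-10, the precision
of the distance computation).

Parameter choices, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `element_vocabulary` | Au, S, H, C, O, N, F, Cl | fixed 8-symbol space shared by all designs so vectors are comparable across designs that use only 6–7 elements |
| `n_grid` | 2 | grid points per pair; selectable by `select_n_grid()` |
| `grid_min`, `grid_max` | 0, 1 Å⁻¹ | covers inverse distances for separations ≥ 1 Å |
| `sigma2` | 0.1 Å⁻¹ | broadening width, chosen so adjacent grid points at `n_grid = 2` see distinct mass |
| `weight_scale` (s) | 0.75 Å⁻¹ | exponential decay of the pair weight |
| `weight_cutoff` | 1e-2 | weights below this are exactly zero; pairs beyond $\ln(100)/0.75 \approx 6.14$ Å contribute nothing |
| `normalize` | off | optional unit-norm variant |

Three choices deserve a note. First, the Gaussian kernel uses the standard
negative exponent; a positive exponent diverges and cannot be a density.
Second, the block value is a weighted **sum**, not an average — the sum is
what the defining equation states and what reference descriptor
implementations compute; the `normalize` flag provides the averaged/unit-norm
variant. Third, the weight argument is the interatomic **distance**, not the
grid coordinate: the weight exists to confine the descriptor to an atom's
neighbourhood, which requires decay in real space.

A subtlety worth knowing: "moving a pair apart never increases its block
mass" holds only when the grid is fine and wide enough to capture the whole
broadened density (the integral is constant, the weight decays). At the
coarse default grid the density is *sampled*, not integrated, and the sampled
value can rise as $g_2$ drifts toward a grid point faster than the weight
decays. The property suite asserts monotonicity on a fine grid for exactly
this reason.

### Grid selection

`select_n_grid()` scores each candidate resolution by the mean absolute
Pearson correlation between descriptor features and the SASA series
(in percent, constant features contributing zero), averaged over designs,
and picks the highest-scoring candidate with ties broken toward the smallest
grid (smallest representation). The aggregation — per-design mean of
per-feature |correlations|, then averaged across designs — is one reasonable
reading of a correlation-sum criterion whose exact aggregation is
underdetermined; absolute scores therefore matter less than the comparison
across candidates, which is how the function is used.

## The Shrake–Rupley SASA oracle

Ground-truth SASA comes from an in-package Shrake–Rupley implementation
(MD workflows usually delegate this to an external analysis program; any
consistent SASA scale works for training and evaluation, so the oracle is
self-contained and the package has no such dependency). Each atom's sphere of radius $r_\mathrm{vdW} + r_\mathrm{probe}$
is sampled at `n_sphere_points` deterministic golden-spiral lattice points; a
point is accessible iff it lies outside every other atom's expanded sphere,
and the per-atom area is $4\pi (r_\mathrm{vdW}+r_\mathrm{probe})^2$ times the
accessible fraction. Defaults: water probe 1.4 Å, 960 points per atom, a
standard van der Waals radii table (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80,
F 1.47, Cl 1.75, Au 1.66 Å). The inner loop is compiled (C++) for speed.

Numerical choices:

* **Deterministic lattice, not random sampling** — SASA values are exactly
  reproducible run to run; quadrature error falls as points are added
  (checked at 96/960/4800 against an independent Monte Carlo estimate).
* **Canonical pose** — the lattice is fixed in the lab frame, so a rigid
  rotation of the molecule would shift individual points across occlusion
  boundaries and change the value by point-quanta. Coordinates are therefore
  first mapped to a canonical pose (centroid at the origin, principal axes
  of the coordinate second-moment matrix aligned to the lab axes, signs
  fixed deterministically). This makes the value invariant under rigid
  motion for any structure with non-degenerate principal axes, while
  remaining fully deterministic.
* No periodic boundaries, no polar/apolar split, atoms only (input
  snapshots are assumed to be solvent-stripped solute).

## Synthetic trajectories

The generator exists so every downstream stage is testable without external
data; it emulates the *shape* of the observed dynamics — SASA predominantly
decreasing over time as the particle compacts — not their physics.

A design is a gold core (residue `AUC`) of `n_core_atoms` atoms on a
spherical lattice, with drug residues (one of the nine catalogued drug codes,
each carrying its element composition, e.g. GEM includes F and NCL includes
Cl) and thiol-anchored `LIG` ligand clusters placed just outside the core
surface. Dynamics per step: attached non-gold residues drift radially inward
by `collapse_rate` (default 0.004 per step — over 120 steps a ~38% radius
contraction, enough for an unambiguous SASA decline); with probability
`detach_prob` (0.002) a residue switches permanently to an outward random
walk (occasional SASA upticks, as real trajectories show); fresh Gaussian
jitter (`jitter_sigma` = 0.05 Å) is added to emitted snapshots without
accumulating, so thermal noise does not mask the compaction trend. All
randomness is seeded; identical seeds give byte-identical manifests.

The default test-bench dataset is **12 designs × 120 steps** (the shortest
of the supported trajectory lengths; roughly a minute of generation on one
CPU), split 80:20 with whole designs on one side of the split and test
designs chosen by stratifying on the midpoint of each design's (min, max)
SASA range so the test set spans the observed SASA scale. A production-shaped
mix of long and short trajectories (300/200/120 steps) is a matter of
passing `duration_mix = c(300, 200, 120)` and a larger `n_designs`.

What passing tests on this generator do **not** show: force-field realism,
solvent structure, energy conservation, or the SASA scale of real
nanoparticle systems (tens of thousands of Å²). They do show that the
descriptor carries SASA-relevant geometric signal, that the forecaster
propagates it, and that the attribution recovers planted drivers — the
properties the surrogate method itself claims.

## Forecasting the descriptor trajectory

`build_window_dataset()` turns per-design descriptor series into sliding
windows: `w_s` consecutive vectors in, the next vector as target, never
crossing design boundaries, with a construction-time assertion that window
timesteps strictly precede the target (no leakage). A design of length $T$
yields exactly $T - w_s$ samples.

The **per-feature ensemble** trains one gradient-boosted regressor per
descriptor feature; model $f$ sees only the `w_s` past values of feature $f$
and predicts its next value, and the 72 outputs are concatenated. Boosting
hyperparameters (100 trees, depth 6, learning rate 0.3) are conventional
defaults — the per-feature protocol, not the tree settings, is what defines
the method — and training is single-threaded with a fixed seed so bundles are
bit-reproducible. Tree models are scale-invariant, so no feature
standardization is applied.

The **attention encoder** is the secondary baseline: one encoder block
(multi-head self-attention — 12 heads of size 256 by default — dropout 0.25,
layer-norm with residual at ε = 1e-6, then a 1×1 convolution stack with 4
and then 1 filters, ReLU on the first), mean-pooled over time and mapped by
a dense layer to the 72 features. The funnel to a single channel before
pooling deliberately bottlenecks the model; it is expected to trail the ensemble on desk-scale
data, and the test suite asserts exactly that ordering (not any absolute
error). Backpropagation through the block is implemented natively and
verified against finite differences in the test suite. Block count beyond 1
is not supported because the funnel output cannot feed a second block.

## SASA regression

`train_sasa_model()` maps one descriptor vector to one SASA value. The
primary model is a feed-forward network — four hidden layers of 256 ReLU
units and a linear output unit, trained 500 epochs with Adam at learning
rate 1e-4, batch size 32. Two numerical choices are internal to the
implementation:

* **Targets are z-scored during training** and predictions mapped back to
  Å². Adam's per-step movement is bounded by the learning rate, so a
  raw-scale target in the thousands is unreachable at lr 1e-4 within the
  default epochs; unit-scale targets make the default settings meaningful.
* **Inputs are raw by default** with an optional `standardize_inputs` flag.
  At the bench scale (ten training designs) the raw-input problem is poorly
  conditioned and the network undertrains; the flag fixes the conditioning,
  and the end-to-end experiment below uses it (with a desk-scale step size,
  lr 1e-3) while keeping the default architecture, epochs and batch size.

A boosted-tree regressor (`sasa_gbm_spec()`) sits behind the same interface
as a shallow baseline; on synthetic data both models must beat the
predict-the-mean baseline, which is the package's demonstration that the
descriptor→SASA signal exists.

## Combined inference and the window sweep

Timesteps are 0-based indices `0..T-1`; the rollout target `t` is the
**1-based ordinal** of the target snapshot, so `t = T` reaches the final
state. A seed window covers indices `0..w_s-1` and `rollout()` forecasts
indices `w_s..t-1` — exactly `t - w_s` steps (a 40-step window rolled to
`t = 300` performs 260 forecast steps, and the saved simulation time is the
300/40 ratio). Off-by-one conventions are easy to get wrong here, so the
invariant `n_steps == t - w_s` is asserted and tested explicitly. `combined_inference()` applies
the SASA regressor to the final rolled-out vector, and `error_sasa()` is the
mean absolute deviation over test designs.

`window_sweep()` runs the window-size protocol: per `w_s` it trains an
ensemble (timed), records one-step test MAE, rolls every test design out to
`t`, and scores `error_sasa`, marking the minima of both columns. The full
exposed sweep set is {10, 20, 40, 60, 80}; the package's bench experiment
uses the subset {10, 20, 40} on the 12 × 120 dataset, keeping the
experiment's runtime in minutes. The qualitative pattern reproduces: the
one-step MAE is essentially flat and smallest at a short window, while the
combined optimum sits at a larger window (40), because longer observed
prefixes shorten the error-accumulating rollout. Pure rollout is used
throughout — each prediction feeds the next window with no ground-truth
re-injection.

Forecast error at this scale is dominated by a structural effect worth
naming: boosted trees cannot extrapolate outside the value range they were
trained on, so a test design whose descriptor levels sit outside the ten
training designs' span drifts toward the training range during rollout. A
production-scale screen (a hundred or more training designs) covers the
level space far more densely; the bench experiment keeps the honest
scaled-down behaviour and
asserts only that the surrogate beats the predict-the-mean baseline, not any
absolute error.

## Attribution

Because chemically similar residues can push SASA in opposite directions
depending on their role, explanation is **per residue**:
`per_residue_dataset()` re-encodes only the atoms of one residue type (same
configuration, so Au-containing blocks of a gold-free residue are exactly
zero) and pairs each row with the design's total SASA.

`shapley_attribution()` has one contract and two engines: the exact
path-dependent tree explainer when the model is tree-backed, and a sampling
kernel estimator otherwise (coalitions drawn from the Shapley kernel
profile, masked features marginalised over a seeded background of at most
200 rows, weighted least squares with the efficiency constraint eliminated
by substitution). Both satisfy local additivity — baseline plus a row's
contributions equals the model's prediction — which the suite checks on
every explained row; for additive models the kernel estimate is exact, not
approximate.

`rank_pairs()` aggregates grid-point features into one signed score per
element pair (mean over grid points of the mean signed contribution across
rows — the aggregation is this package's documented choice) and ranks pairs by |score|, sign carried through:
positive means the pair's interactions raise the predicted SASA. On planted
data (a target driven by one pair block) the block is recovered top-ranked
with the correct sign in ≥ 90% of seeded replicates.

## Problem sizes used by the test suite

The suites run on one CPU: descriptor and oracle checks on ≤ 50-atom random
snapshots; bookkeeping at the production scale of 12 test designs × 300
steps with `w_s = 40` (3120 samples, 260-step rollout); the end-to-end experiment on the 12 × 120
bench dataset with windows {10, 20, 40}; attribution on 20 seeded
replicates of a 150-row planted-signal model. These sizes are the package's
test-bench conditions, chosen so the full suite completes in minutes while
still exercising every stage at a meaningful size.

## Known limitations

* The toy dynamics plant monotone-ish compaction; real trajectories have
  richer kinetics (plateaus, partial re-expansion) that the generator only
  sketches via detachment events.
* The ensemble forecaster cannot extrapolate descriptor levels outside its
  training span (trees); with few training designs this dominates rollout
  error.
* The encoder variant is deliberately small and architecture-faithful; it
  is a baseline for ordering comparisons, not a tuned competitor.
* Kernel attributions assume feature independence when marginalising over
  the background, as kernel estimators generally do; correlated features
  share credit (the tree engine has the same property through its
  path-dependent expectations).
* SASA values are on the oracle's own scale (probe 1.4 Å, the stated radii
  table); they are internally consistent but not calibrated to any external
  program's output.
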