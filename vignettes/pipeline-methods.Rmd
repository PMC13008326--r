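---
title: "Topological summaries and likelihood-free inference for angiogenesis models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological summaries and likelihood-free inference for angiogenesis models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its models and methods: what is
simulated, how networks are summarized, how parameters and models are
inferred, which numerical choices were open and how they were settled, and
what the synthetic experiments do and do not demonstrate.

## The three snail-trail models

All models run on the unit square with the parent vessel along the bottom
edge and the tumour beyond the top edge. VEGF is a static nondimensional
field `c(x, y)` in `[0, 1]`, non-decreasing in `y` (linear `c = y` by
default; an exponential profile `c = exp(-k (1 - y))` is available).
`n_initial_tips` tip cells (default 7) start evenly spaced on `y = 0` and
deposit a stalk-cell trail as they move. Time advances in steps of `dt`
(default 1) for `n_timesteps` (default 300).

* **AC (lattice).** On a lattice of `lattice_resolution` nodes per side
  (default 51, spacing `h = 1/50`) a tip makes one of five moves (stay,
  right, left, up, down) with probabilities obtained by normalizing the
  non-negative weights
  `w_d = max(0, D + chi (c_d - c_0)/h + rho (f_d - f_0)/h)`; `D` is the
  unbiased move weight, `f` the fibronectin field (initially uniform at
  0.25, produced/consumed under tips unless frozen), and moves off the
  lattice get weight zero. Clamping negative weights before normalization
  preserves the probability simplex under strong gradients. The stay
  weight defaults to 0 — tips move every step unless every move is
  clamped.
* **SL (velocity SDE).** Off-lattice tips carry a velocity updated by
  Euler–Maruyama steps of
  `dw = (-beta w + kappa grad c) dt + sigma dW`. The drag is `beta = 0.5`
  per time unit: the explicit update multiplies the velocity by
  `1 - beta dt`, so `beta dt` must stay below 1 for relaxation (at the
  default `dt = 1`, `beta = 0.5` halves the velocity each step; the
  equilibrium chemotactic speed is `kappa / beta = 2 kappa`).
* **PS (discrete headings).** Tips move at constant speed (default one
  lattice spacing per step) with heading `phi` measured from the vertical,
  turning by `phi_hat` (default 30 degrees) with probabilities
  `tau_pm = D_r dt exp(d_c (cos(phi pm phi_hat) - cos(phi)))`: the turn
  that improves alignment with the tumour direction is favoured when
  `d_c > 0`, and `d_c = 0` gives exactly symmetric turning. Configurations
  for which `tau_+ + tau_-` could exceed 1 are rejected with an
  instruction to reduce `dt`; the default priors keep the maximum near
  0.7. Speed is conserved exactly (to floating precision) across turns and
  wall reflections.

Shared rules: side and bottom walls reflect; the top boundary absorbs
(the tip has reached the tumour). A tip whose age exceeds `a_br` *and*
whose local VEGF exceeds `c_br` is eligible to bifurcate and does so with
a per-step probability of 0.05 (configurable); both parent and daughter
ages reset — the symmetric choice — and daughters inherit the parent's
lineage. Always-on firing was rejected because it saturates the tip cap
within a few steps of first eligibility, flattening the response of branch
counts to `(a_br, c_br)` — the very parameters the pipeline infers; a
small per-step hazard keeps the number of branching events graded across
the prior range. Anastomosis follows the snail-trail convention: a tip is
deactivated when it meets a trail laid by a *different* lineage, detected
at the resolution of one lattice spacing (which is also the fusion radius
for the off-lattice models). Tips are capped at 256 per simulation.

Each simulation consumes a single RNG stream seeded explicitly; draws are
taken in a fixed order (movement for all active tips, then branching), so
results are bit-reproducible from `(model, parameters, config, seed)`.

The four inferred parameters per model have independent uniform priors
chosen to span each model's qualitative regimes on the default domain:
`chi, rho` in `[0, 2]` (unbiased to strongly biased walks), `kappa` in
`[0, 0.04]` and `sigma` in `[0, 0.02]` (equilibrium speeds and velocity
noise from zero to a few lattice spacings per step), `d_c` in `[0, 1]`,
`D_r` in `[0, 0.3]`, `a_br` in `[0, 100]` time units (up to a third of the
simulation), `c_br` in `[0, 0.9]` (branching everywhere to only near the
tumour). These ranges are implementation choices, not literature values.

## From trails to summary statistics

The final-time-step trail is rasterized onto a shared occupancy grid
(default: the AC lattice itself, so lattice trails map one-to-one;
off-lattice polylines are traced with a supercover walk that steps one
axis at a time, yielding 4-connected chains). Two families of summaries
are computed:

**Spatially-averaged statistics (18).** Mean, standard deviation, min,
max, range and the 10th/25th/75th/90th percentiles of the x- and
y-coordinates of occupied-cell centres. Occupied cells are deduplicated —
the grid overlay, not the raw trail, is the object being summarized — so
lattice and off-lattice models are directly comparable. Percentiles use
linear interpolation between order statistics (`quantile()` type 7),
fixed because these numbers feed forests and ABC distances and must be
bit-stable.

**Topological statistics.** A cubical complex is built on occupied cells
(vertex per cell, edge between 4-adjacent cells, square per full 2x2
block) and filtered by the cell-centre height — `y` for the vertical
sweep, `x` for the horizontal — with lower-star extension to edges and
squares, realizing the sweeping plane: the sublevel complex at `k`
contains exactly the cells within distance `k` along the sweep axis.
Ordinary persistence of this filtration leaves every component and loop
that survives the sweep with an infinite death. Extended persistence
replaces those infinities by pairing each essential class against the
relative (descending) part of the filtration, computed here by matrix
reduction over `Z/2Z` of the coned complex (cone vertex first, ascending
cells, then coned cells in descending order of minimum vertex value, with
the twist/clearing optimization). Every feature then carries a finite
(birth, death) pair, and its class says what it is:

| class, dim | structure | coordinates |
|---|---|---|
| ExtendedPlus, 0 | connected component | (min, max) height |
| Ordinary, 0 | upward branch | (lowest point, merge height) |
| ExtendedMinus, 1 | loop | (top, bottom) of the loop |
| Relative, 1 | downward branch | (top, split height) |
| Ordinary, 1 | pocket filled by thick trails | (close, fill) |

This class-to-structure reading follows the standard extended-persistence
literature. Diagrams are computed for both sweep directions and split into
the five strata above; each stratum is vectorized two ways:

* **Persistence image:** Gaussian bumps at (birth, |death - birth|) on a
  fixed pixel grid over `[0, L]^2`, weighted linearly by persistence
  (weight 0 at persistence 0), bandwidth `L/20`. The support is fixed by
  the domain rather than fitted to training data, so the featurizer is
  stateless and identical across pipeline stages. The default resolution
  is 5x5 per stratum: each pixel then aggregates a broad, stable region of
  the diagram. (At finer resolutions neighbouring pixels are so correlated
  that forest importance fragments across them, which destabilizes which
  individual pixels different models' selections pick — a problem for the
  model-choice step, which can only use statistics selected for *every*
  model.)
* **Persistence statistics:** for the births, deaths, midpoints and
  lifespans of the stratum: mean, standard deviation (population
  convention — a one-point stratum has spread 0), median, IQR and the
  10/25/75/90th percentiles; plus the persistent entropy of normalized
  lifespans, the number of points, and the total lifespan. Counts are
  included because the numbers of branches and loops are the most direct
  topological read-outs of the branching gate and of model identity.
  Empty strata contribute a zero block (a documented sentinel — forests
  and distances need fixed-length numeric input).

The full feature vector is the concatenation (18 spatial, then all images,
then all statistics blocks, both directions, in a fixed documented column
order) — 618 columns at the defaults.

## Step 1: selecting informative statistics

For each model, `n` parameter vectors are drawn from the prior and
simulated (headline scale `n = 10,000`; the package's experiments use
desk scales of 250–500, which this vignette states as the package's own
choice of problem size). One regression random forest per parameter (500
trees, impurity importance, fixed seed) learns the map from summaries to
that parameter; statistics are ranked by normalized importance with ties
broken lexicographically. The selection walks the four per-parameter
rankings round-robin, skipping duplicates, until `ns = 100` distinct
names are collected — equal shares up to overlap, deterministic given the
rankings. Importance-decay plots (the ranking tibbles) are the diagnostic
for choosing `ns`; no automatic selection of `ns` is attempted.

## Step 2: ABC-SMC

The distance between a candidate simulation and the observed data is the
Euclidean norm of the difference of the selected statistics, each scaled
by its maximum absolute value in the training table (zero-scale statistics
are dropped with a warning), averaged over the observed replicates
(distance averaged, not features — the replicates are 10 independent
simulations of the observed condition). Scaling bounds every training
coordinate in `[-1, 1]`, so rescaling any raw feature leaves all distances
unchanged.

The sampler is sequential importance sampling with a decreasing tolerance:
generation 1 draws from the prior (tolerance infinite by default, i.e. the
prior predictive); generation `t+1` resamples the previous particles by
weight, perturbs with a component-wise Gaussian kernel of variance twice
the weighted empirical variance, rejects proposals outside the prior, and
accepts at the median of the previous generation's accepted distances
(kept strictly decreasing). Weights follow the standard correction
`w_i ∝ pi(theta_i) / sum_j w_j K(theta_i | theta_j)`. A proposal budget
(50N per generation) turns pathological tolerance floors into an early
stop with status `"stopped_early"` rather than a hang. Defaults: N = 200
particles, 4–5 generations.

The final population is summarized by a weighted Gaussian KDE with
diagonal bandwidths from the multivariate Silverman rule using the
effective sample size (the univariate exponent undersmooths badly in four
dimensions). The 95% HPD region is the standard sample-based cut: a point
is inside when its density is at least the weighted 5th percentile of the
density at the particles.

## Step 3: model posterior

A probability classification forest learns the model label from the
*unscaled* statistics common to all three selections (their intersection —
if it is empty the package errors and instructs enlarging `ns`). Each
training record keeps its out-of-bag predicted class; a regression forest
then learns the 0/1 misclassification indicator, and the model posterior
for observed data is `1 - `(predicted misclassification probability),
clamped to `[0, 1]`. The r = 10 observed replicates are classified
separately; the majority model is reported with the mean posterior
probability over the replicates that voted for it, with per-replicate
detail retained. The regressor is trained on the pooled three-model table.

## Synthetic test-cases and what the experiments show

Ground-truth test-cases are 10 replicate simulations at a known parameter
vector; two per model, chosen to span low- and high-branching regimes
(the package's own values — they are configuration, not literature). At
desk scale (n = 250–500 training draws, N = 150–200 particles, 50x50
grid, 300 steps) the package's experiments check that the true parameter
vector falls in the 95% HPD region of its model's ABC-SMC posterior and
that the model posterior ranks the generating model first with mean
probability above one half.

These experiments validate the pipeline's statistical machinery on data
whose generating process is exactly the package's own simulators. They do
not show that the simulators describe real vasculature, that the selected
statistics are sufficient, or that recovery would survive observation
noise, imaging artefacts or model misspecification — all of which real
data would add. Branching-gate parameters (`a_br`, `c_br`) are weakly
identified at desk scale (posteriors contract modestly from the prior);
chemotaxis-type parameters contract strongly.

## Numerical choices and limitations

* Exact movement coefficients beyond the four inferred parameters
  (diffusion/stay weights, drag, speeds, angle increment, fibronectin
  kinetics) are nuisance structure: canonical published forms, every
  coefficient exposed in `angio_control()`, none hard-coded.
* The filtration uses `Z/2Z` coefficients; homology dimensions 0 and 1
  only (2-dimensional voids cannot occur in these planar rasters).
* Diagram points with zero persistence are discarded from the Ordinary
  and Relative classes (they are raster ties, not structure); Extended
  points are always kept — they carry the component/loop counts.
* The anastomosis raster test means fusion cannot distinguish trails
  closer than one lattice spacing; diffusive lattice walks can also close
  raster loops by revisiting without any fusion event, so recorded
  anastomosis counts are not a census of homological loops.
* Determinism: all orderings (cell order, tie-breaks, round-robin,
  selection) are fixed; identical seeds give identical results on one
  platform. Across BLAS/compiler variations the forests may differ in
  tie-order; the contracts tested are statistical, not bit-level, except
  where stated.
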