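---
title: "Multispiral whale optimization for wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispiral whale optimization for wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralFS)
```

## The problem

Wrapper feature selection searches the space of feature subsets of a
classification dataset, scoring each candidate subset by the cross-validated
error of a learning algorithm rather than by a filter statistic. For a
dataset with `d` features the space has `2^d - 1` non-empty subsets, so for
the high-dimensional, small-sample datasets this package targets (hundreds
to tens of thousands of features) exhaustive search is impossible and a
stochastic search heuristic is used instead.

`spiralFS` implements two such heuristics. `woa_run()` is the canonical
whale optimization algorithm (WOA): a population of `N` continuous position
vectors ("agents") in the unit box, each iteration moving every agent by one
of three operators chosen by random draws `p` and `A`:

* **shrinking encirclement** (`p < 0.5`, `|A| < 1`):
  `X' = X* - A |C X* - X|`, a contraction toward the best solution;
* **random search** (`p < 0.5`, `|A| >= 1`): the same move anchored at a
  random other agent, giving exploration;
* **spiral attack** (`p >= 0.5`): `X' = |X* - X| e^{bl} cos(2*pi*l) + X*`,
  a logarithmic-spiral approach of the best solution.

The coefficient schedule `a(t) = 2(1 - t/T)` shrinks `A in [-a, a]` linearly,
so the run moves from exploration to exploitation; the best solution found
so far is retained, making the reported convergence curve non-increasing.

`mswoa_run()` is a multispiral variant addressing three weaknesses of the
baseline: a single leader causes premature clustering; the random-search
move degenerates when agents are close together; early-run solution quality
is poor.

## The three strategies

**Adaptive multipopulation merging.** Each iteration the population is
partitioned into `K(t) = floor(N/2 * exp(-ln(N/2) t/T) + gamma)`
subpopulations that merge exponentially from `floor(N/2 + gamma)` down to 1.
Membership follows a fitness–distance score,
`FD = (1 - fit_norm) + dis_norm` (both min–max normalized over the current
population; 0/0 defined as 0), sorted descending and cut into contiguous
blocks of `M = floor(N/K)`; remainder agents join the last block. Every
`regroup_period` iterations membership is instead a uniformly random
permutation, exchanging information between swarms. Each agent is guided by
its own subpopulation leader, not a global best.

**Double-spiral search.** The exploration branch becomes
`X' = r e^{theta} cos(2*pi*theta) + X_m` with
`r = |W * X_rand - X_m|`, anchored at the agent itself, with the partner
drawn from another subpopulation. Because `e^{theta}` may exceed 1 the move
reaches both inward and outward, so it still produces new candidates when
agents have clustered.

**Baleen neighbourhood exploitation.** During the first 20% of the run
(`bes_fraction = 0.2`) each subpopulation leader is refined: for every
member, a candidate is built by per-dimension quadratic interpolation
through (leader, member, random agent) — the vertex of the parabola through
three (coordinate, fitness) pairs, with a fall-back to the leader coordinate
when the interpolation denominator is below `1e-12` — then crossed with the
leader (interpolated coordinate kept when a fresh uniform draw is at least
0.5), evaluated once, and adopted if strictly better. This costs one extra
objective call per member per iteration while active.

## The subset fitness

Continuous positions are mapped to masks by a strict threshold
(`position > 0.5`). A mask is scored by

```
fitness = alpha * ErrorRate + (1 - alpha) * R / N,    alpha = 0.99
```

where `ErrorRate` is the mean misclassification rate of a k-nearest
neighbour classifier (`k = 5`, Euclidean distance) under stratified 5-fold
cross-validation on the 80% training partition, restricted to the `R`
selected of `N` total features. The empty mask is assigned fitness 1, the
worst attainable value, so the search is repelled without position bias.
Fold assignment is fixed once per run, making the fitness a deterministic
function of the mask (evaluated masks are cached); the held-out 20% is used
exactly once, to report test accuracy. Features are min–max scaled with
training-fold statistics only, so no information leaks from validation
folds; k-NN voting ties break deterministically by the nearest neighbour's
class. Both the 5-fold fitness and the held-out accuracy are reported and
labelled, since protocol descriptions of "classification accuracy" in this
literature are often ambiguous between the two.

## Numerical and design choices

* **Iteration indexing.** Schedules use `t = 0, ..., T-1`, so `a` starts
  exactly at 2 and `K(0)` equals the merged-phase maximum.
* **Branching.** `A` is drawn once per agent per step as a scalar (the
  vector form would leave the `|A| >= 1` branch undefined); `C` and the
  spiral weight `W` are per-dimension vectors. `p = 0.5` exactly takes the
  spiral branch.
* **Boundary handling** is clamping to the box, the common convention.
* **`theta` of the double spiral** is drawn from `U[-1, 1]`, mirroring the
  spiral parameter `l`; a sensitivity sweep over wider ranges changed
  results negligibly, because the branch only fires while `a >= 1` (the
  first half of the run).
* **Regroup period.** The random-regrouping epoch is not fixed by the
  method's description; the package default is 5, the customary epoch of
  dynamic multi-swarm PSO regrouping, which a calibration sweep
  (`R in {3, 5, 10, 20}`, 10 seeds on the reference synthetic problem)
  confirmed as the best mean final fitness.
* **Merged phase.** When `K = 1` the single leader is the best-so-far
  record rather than the current population best: with one subpopulation
  the method degenerates to the baseline, whose guide is that record.
* **Determinism.** All randomness flows from one seeded stream in a fixed
  draw order; two runs with the same seed are bit-identical. In
  `select_features()` the seed also fixes the 80/20 split and the folds,
  and paired-seed benchmarking (`run_trials()`) gives every algorithm the
  same splits per run index.

## What the synthetic generator emulates — and what it does not

`make_classification_data()` builds a two-class matrix with a known
informative block (class-conditional Gaussian shifts), optional redundant
columns (noisy linear combinations of informative ones) and independent
noise columns. Defaults — 150 samples, 30 features, 3 informative, effect
size 2.4 standard deviations per informative column — are calibrated so
that (a) the informative subset is nearly class-separating (attainable
accuracy around 97–98%, the regime of the published wrapper-FS benchmarks
this emulates), and (b) every informative column is individually necessary:
dropping one roughly doubles the attainable error. Both properties were
verified directly on independent splits; they are preconditions for a
parameter-recovery experiment to be meaningful at all. Substantially weaker
effects make noise columns genuinely useful to a fixed-fold k-NN (the
ground truth is then not the fitness optimum); substantially stronger
effects let two informative columns already separate the classes (the
third is then correctly dropped by a minimizing search).

A caveat this generator makes visible: with `alpha = 0.99` and 120 training
samples, one cross-validation misclassification changes the fitness about
25 times more than one extra feature, so small bundles of noise features
that repair fold-level errors by luck can be genuinely fitness-improving.
Found subsets therefore typically carry a few noise features beyond the
informative block. Real microarray-scale data (thousands of features, where
k-NN error degrades systematically with noise dimensions) exhibit this far
less; a green recovery test here certifies search quality in the calibrated
world, not behaviour on any particular real dataset.

`make_imu_recording()` emulates a waist-worn inertial unit: 9 channels
(triaxial acceleration in g, angular velocity in deg/s, pitch/yaw/roll in
degrees) at 20 Hz for 10 s, 14 activity types (8 daily activities, 6 fall
modes). Daily activities are band-limited periodic gait templates
(0.5–3 Hz) or slow posture transitions around 1 g vertical acceleration;
falls are a locomotion prefix, a high-magnitude acceleration and
angular-velocity transient at a random impact time (4–6 s), and a sustained
post-impact pitch/roll change. Channels respect the sensor ranges (16 g,
2000 deg/s, 90/180 degrees). The generator does *not* model soft falls,
near-falls, sensor drift, orientation-estimation error, or inter-subject
variability, so the demonstration pipeline's near-perfect F1 on synthetic
recordings says the pipeline is wired correctly, not that the problem is
solved; published F1 scores on privately collected fall data are not
reproducible from this package.

`extract_features()` emits 27 features per channel, 243 in total. The
counts — 13 time-domain, 6 frequency-domain, 8 time–frequency — are fixed
by the protocol being followed; the concrete lists (moments, extrema,
quartiles, zero-crossing rate; spectral power, dominant frequency,
centroid, bandwidth, entropy, mean frequency on the DC-free magnitude
spectrum; relative energies of the 8 leaves of a 3-level Daubechies-4
wavelet packet transform) are this package's configuration. The
fall-detection fitness replaces k-NN by an RBF-kernel SVM; since no SVM
implementation ships with the supported runtime, the package includes a
minimal deterministic sequential-minimal-optimization solver (validated
against separable and XOR-style layouts) with `C = 1` and
`gamma = 1/d` on min–max-scaled inputs.

## Benchmarking protocol

`run_trials()` repeats `select_features()` with seeds `base_seed + r`,
aggregates accuracy, subset size, fitness and runtime, and exports mean
convergence curves. `significance_label()` compares run-level samples of
two algorithms with a two-sided Wilcoxon rank-sum test at `alpha = 0.05`
(the customary test in this literature; the method description names none):
`+` when the proposed algorithm is significantly better, `-` when worse,
`≈` otherwise, with identical samples defined as `≈`. Its empirical type-I
error is property-tested to lie near the nominal level. `export_tables()`
writes the dataset-by-algorithm tables (CSV and Markdown) with best-per-row
bolding and average/rank rows.

## Known limitations

* Exploration is structurally confined to the first half of the run
  (`|A| >= 1` requires `a >= 1`), so late-run escapes from local optima
  rely on regrouping alone; runs on rugged fitness landscapes can stall
  with a few redundant features retained.
* The k-NN fitness is evaluated on fixed folds for determinism; this
  trades an unbiased (noisier) fitness for a reproducible one and is the
  main source of the lucky-noise-feature effect discussed above.
* The SMO solver is minimal (single kernel, no shrinking, no caching
  across calls) and intended for the small demonstration problems, not as
  a general SVM.
* Runtime is recorded but never asserted on; it is hardware-dependent.
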