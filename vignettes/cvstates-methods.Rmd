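---
title: "From structural ensembles to metastable states: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From structural ensembles to metastable states: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structure-prediction networks run with subsampled multiple sequence
alignments emit *ensembles* of conformations rather than a single model, but
they say nothing about which conformations are important, how they group
into states, or how those states interconvert. `cvstates` closes that gap on
the analysis side: it takes (a) an ensemble of PDB structures carrying
per-atom pLDDT in the B-factor column and (b) time series of collective
variables (CVs) from short simulations started at selected ensemble members,
and produces a small set of informative CVs, a set of metastable-state
labels, and a 2D latent map in which any structure — simulated or predicted —
can be placed.

The stages, run individually or through `run_pipeline()`:

1. **Filter** — superpose every structure onto the highest-pLDDT reference
   (Kabsch) and drop outliers above an RMSD cutoff.
2. **Features** — enumerate pairwise atom distances within a user selection,
   rank them by coefficient of variance, keep the top few percent.
3. **Cluster** — regular-space clustering in the reduced feature space picks
   diverse seed structures for short simulations.
4. **Dynamics** — an external boundary: the package exports seeds and a CV
   watch list and ingests the resulting time series (a built-in toy
   simulator can fill the slot).
5. **AMINO** — prune redundant CVs with a mutual-information distance.
6. **SPIB** — learn state labels and the latent map from time-lagged
   prediction.

## Filtering and feature ranking

The reference is the structure with the highest mean pLDDT over the selected
atoms; ties break to the first structure in input order. Superposition is
Kabsch via SVD with reflections excluded; fewer than three fit atoms or a
collinear fit set is an error rather than a silently arbitrary rotation. The
RMSD filter keeps structures within a user-chosen cutoff of the reference.
The cutoff has no default on purpose: a sensible value depends on the
protein's size and the expected conformational spread, and a wrong silent
default would bias every downstream stage.

Features are interatomic distances. All unordered pairs within the selection
are enumerated, excluding pairs fewer than `min_residue_separation = 3`
residues apart on the same chain — immediate neighbors are rigid at the
backbone level and contribute pure noise. Pairs across chains are always
kept.

The ranking statistic is the **coefficient of variance, defined here as
population variance divided by mean** (units: Å). This is deliberately not
the conventional dimensionless `sd/mean`; the variance-based form weights
large absolute fluctuations more strongly, which is what matters when the
goal is to find distances that move between conformational states. The
conventional quantity is available via `cov_type = "sd"`. Population
variance (divide by *N*) is used because the ensemble is treated as the
complete population of generated hypotheses, and the choice only rescales
all ranks by the same factor. Ties are broken lexicographically by feature
label so the ranking is a deterministic function of the input. The default
retention is `min(ceiling(0.05 * n_features), 200)`: roughly the top 5%,
never more than a couple of hundred, because Euclidean distances in the
clustering step lose contrast as dimensionality grows.

## Regular-space clustering

A single pass over structures in input order: a structure becomes a new
center iff its Euclidean distance (unscaled, over the retained feature
columns) to every existing center is strictly greater than `d_min`; the
first structure is always a center; afterwards every structure is assigned
to its nearest center. The strict inequality means `d_min = 0` makes every
distinct structure a center. No feature standardization is applied — the
top-`m` cap is the dimensionality control, and the features share units (Å).
`suggest_d_min()` bisects the threshold (30 iterations) until the center
count lands in a target range; 5–20 centers is a practical number of seeds
for short simulations. An unreachable target (fewer distinct structures than
the lower bound) returns the best effort with a warning.

## AMINO: mutual-information redundancy removal

Distance features selected purely by variance ranking are heavily redundant:
if residues *m*–*n* move, so do their sequence neighbors. Each CV is binned
into `n_bins = 50` equal-width bins over its pooled range (frames from all
trajectories pooled — redundancy is a static property, so trajectory
boundaries are irrelevant here), and dissimilarity between CVs is

\[ D(X, Y) = 1 - \frac{I(X;Y)}{H(X,Y)} \in [0, 1], \]

with the plug-in (empirical-frequency) estimates of mutual information and
joint entropy in bits. The histogram plug-in was chosen over density
estimators because it is deterministic, fast, and redundancy detection only
needs contrast between near-copies (D well below 1) and unrelated signals
(D near 1), not unbiased MI values; all estimator constants are exposed in
the configuration. Two constant signals have zero joint entropy and are
defined as identical (D = 0, with a warning).

k-medoid clustering under this distance runs for every candidate count
`k = 1..k_max` (seeded k-medoids++ initialization, then PAM-style swap
search; deterministic given the seed). The kept CVs are the medoids at the
`k` selected by the distortion-jump criterion: with distortion `d_k` the
mean squared distance of each CV to its nearest medoid, choose the `k`
maximizing `d_k^{-p} - d_{k-1}^{-p}` with `p = 1` (the distortion is a
scalar, so the usual `p = dims/2` transform reduces to 1), `d_0^{-p} := 0`.
Exact-duplicate groups give zero distortion; the smallest `k` achieving zero
wins, so two identical CVs reduce to one while fully independent CVs are all
retained.

## SPIB: state labels from time-lagged prediction

The State Predictive Information Bottleneck learns a stochastic encoder
`x_t → z` (Gaussian in a low-dimensional latent space) and a decoder that
predicts the state label at `t + Δt` from `z`, minimizing

\[ \mathbb{E}\left[-\log p_\theta(y_{t+\Delta t} \mid z)\right]
   + \beta\, \mathrm{KL}\!\left(q_\phi(z \mid x)\,\|\,r(z)\right), \]

with `r(z)` a learnable mixture of unit-variance Gaussians, one component
per live state. Labels start from seeded k-means (`n_initial_states = 10`,
so refinement prunes downward; the original work does not specify an
initialization) and are periodically refreshed to the argmax decoded state
of each frame's own encoded mean; states that lose all frames are deleted.
Prediction pairs are formed strictly within trajectories — concatenating
two trajectories will never fabricate a transition.

`Δt` (in frames) is the resolution knob: sub-states that interconvert faster
than `Δt` have unpredictable future labels, so the decoder cannot
distinguish them and refinement merges them. Longer lags therefore yield
fewer states, while short lags resolve fast dynamics — scanning `Δt`
(`state_count_scan()`) traces the system's timescale hierarchy.

Architectural defaults (all exposed in `spib_config()`): two tanh hidden
layers of 64 units, a linear head for the latent mean with a learnable
input-independent log-σ, a linear+softmax decoder, `latent_dim = 2` (a
plottable plane that doubles as a CV pair for later enhanced sampling),
`β = 0.01`, Adam at `3 × 10⁻³`, minibatches of 500 drawn from 10⁴ sampled
pairs per epoch, relabeling every epoch after a 5-epoch warm-up, and
convergence declared when fewer than 1% of frames change label for 10
consecutive relabelings (cap: 40 epochs). Inputs are standardized per CV
with training statistics that are stored and reused at projection time.
The network is small enough that the gradients are hand-derived matrix
expressions; they are verified against finite differences in the test
suite, and training is bit-reproducible for a fixed seed on one platform.
Non-finite losses abort with diagnostics; a collapse to a single state is
returned with a warning rather than an error, since one state is the
correct answer for an unstructured system.

`spib_project()` pushes any CV vector (e.g. the feature rows of the original
ensemble) through the deterministic encoder mean and decoder, so structures
never seen in training receive a state and latent position.

## The synthetic-data generators

Every claim above is tested against fixtures with constructed ground truth:

* **Langevin sampler** (`langevin_trajectory()`): overdamped Euler–Maruyama
  dynamics, `dx = -∇U dt + √(2kT dt) dW`, with analytic potentials. The
  harmonic well has closed-form stationary variance `kT/κ` (checked to 5%)
  and its position histogram is χ²-tested against the Boltzmann density.
  The 1D double well `U = h(x²-1)²` with `h = 8 kT` crosses every few
  hundred time units, so a 10⁵-frame trajectory carries a handful of
  genuine transitions. The 2D triple well (three inverted Gaussians plus
  confinement) is built with a deliberate timescale separation: wells A and
  B exchange across a ≈2 kT barrier (mean first passage ≈ 1.7 time units)
  while well C sits behind a ≈4–5 kT barrier (≈ 10 time units), so the SPIB
  state count falls from 3 to 2 to 1 as the lag crosses those scales.
* **Bead-chain ensembles** (`make_ensemble()`): Cα-only chains (3.8 Å
  spacing) bent at a central hinge by a state-specific angle, plus isotropic
  Gaussian coordinate noise (default σ = 0.3 Å against several Å of
  inter-state displacement), with per-state pLDDT written to the B-factor
  column. A warning fires when σ reaches a quarter of the smallest
  inter-state displacement.
* **Redundant CV groups** (`make_redundant_cvs()`): a few independent unit
  Gaussian signals, each duplicated as noisy copies (default 10% noise),
  emulating neighboring residue pairs that track one motion.
* **CV-space surrogate dynamics** (`simulate_cv_watch()`): one harmonic
  Langevin trajectory per cluster center in CV space, standing in for short
  MD runs that sample locally around each seed.

What these fixtures do *not* emulate: anharmonic coupling between many
degrees of freedom, non-Markovian noise, force-field physics, or the
heavy-tailed error modes of predicted structures. Passing tests demonstrate
that the algorithms recover constructed truth under honest noise, not that
any particular protein system will yield clean states.

## Problem sizes and numerical choices

The benchmarks train SPIB on 10⁵-frame trajectories (10⁶ integration steps,
stride 10–20), five seeds per condition, and three lags on the triple well —
sizes chosen so the full validation runs on a single CPU in minutes while
keeping several barrier crossings per trajectory. Degenerate inputs are
handled explicitly rather than by accident: zero-range CVs bin to a single
bin with a warning; an all-zero B-factor ensemble falls back to the first
structure as reference with a warning; identical frames collapse k-means
states with a warning; ties in CoV ranking break lexicographically; the
regular-space threshold comparison is strictly `>`.

The pipeline's per-stage manifests record parameter and input hashes and
output paths (no timestamps), so identical runs produce byte-identical
manifests and unchanged stages are skipped on re-run.

## Known limitations

* The atom-selection language covers chains, residue ranges and atom names
  with boolean combinations — not distance-based or element-based selections.
* mmCIF and binary trajectory formats are not read; time series arrive as
  plain text tables.
* The MI estimator is a fixed-width histogram plug-in; heavily skewed CVs
  may warrant manual bin counts.
* SPIB's label matching utility enumerates permutations and is intended for
  the small state counts (≤ 8) typical of this analysis.
* With `latent_dim = 2` (the default, chosen for direct visualization),
  systems with many more than four states may need a larger latent space;
  the interaction is not explored here.
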