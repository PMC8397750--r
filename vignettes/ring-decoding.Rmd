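---
title: "Episodic activity, gain drift, and the ring representation of movie time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episodic activity, gain drift, and the ring representation of movie time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringtime)
```

## The scientific problem

Chronic two-photon calcium imaging of visual cortex during a repeated
natural movie shows a puzzle: single-neuron responses change substantially
from week to week (representational drift), yet the stimulus, behaviour and
task are constant. `ringtime` implements an analysis chain built around one
resolution of that puzzle: responses are composed of *spiking episodes* —
short, temporally precise windows of elevated firing — whose *gain*
(within-episode rate) fluctuates across trials and drifts across weeks,
while episode *timing* stays fixed. Because timing is preserved, the
population trajectory through state space traces the same closed loop every
trial; gain changes move activity along directions that leave the loop's
time parameterization intact. Time-in-movie can therefore be decoded from
the population without supervision, and its accuracy survives weeks of
drift.

The pipeline has six stages, each usable on its own:

1. **Preprocessing** — neuropil-corrected ΔF/F
   (`neuropil_correct()`, `select_alpha()`, `compute_dff()`), per-neuron
   root-mean-square normalization (`normalize_tensor()`), and week-level
   similarity statistics.
2. **Episode detection** — per-neuron PSTH of inferred spikes, Gaussian
   smoothing, prominence-based peak finding with full-width-at-half-maximum
   extents and merge rule (`detect_episodes()`), and episode-level gain
   stability statistics with Poisson and week-shuffle controls.
3. **Masked nonnegative TCA** — a rank-R canonical polyadic decomposition
   of the (neuron × time × trial) tensor fitted by masked multiplicative
   updates (`tca()`), with holdout cross-validation for the rank
   (`cross_validate()`), a permutation-invariant model-similarity score
   (`model_similarity()`), trial-factor clustering, and factor shuffling for
   controls.
4. **Isomap** — k-nearest-neighbour graph, graph-geodesic distances, and
   classical MDS of the TCA-denoised point cloud (`isomap()`).
5. **SPUD** — a closed piecewise-linear curve with ten knots fitted to the
   embedded ring (`spud()`); each point's arc-length coordinate is aligned
   to movie time by one circular shift/flip chosen on training data, then
   read out as decoded time.
6. **Geometry** — per-time-bin variance decomposed along and perpendicular
   to the local curve tangent (`variance_decomposition()` and its
   week-averaged / within-week variants), manifold radius, and standard
   one-sided rank tests.

## The model assumptions, stage by stage

**ΔF/F.** Somatic fluorescence is corrected by subtracting the mean-centred
neuropil trace scaled by α ∈ [0, 1]; α is chosen on a 0.01 grid to minimise
the absolute residual correlation with the neuropil — a grid is exact here
(the objective is cheap and the constraint box is printed), and 0.01 is far
below any meaningful contamination difference. The baseline F₀ is the mode
of the corrected-fluorescence density, estimated with a Gaussian kernel
density (Silverman bandwidth, 512-point grid); the mode rather than a
percentile makes the baseline insensitive to activity transients that
inflate the upper tail.

**Normalization.** Each neuron is divided by its root mean square over all
times and trials, so every neuron contributes comparably to the squared
error that TCA minimises; without it high-rate neurons dominate the
factorization. The step is idempotent and scale-equivariant, and all-zero
neurons are dropped with a warning rather than propagating NaN.

**Episodes.** Inferred spikes are summed across trials into a PSTH and
smoothed with a Gaussian kernel (SD 0.2 s, reflective boundary). Adaptive
spline smoothers are an alternative for this step, but only the smoothing
role matters for peak finding, so a fixed-bandwidth Gaussian with the
bandwidth exposed as a parameter is used, and the detection results can be
checked for bandwidth sensitivity. Peaks must exceed a topographic prominence of 3 (in
summed-count units on the smoothed PSTH — the trace on which the threshold
is applied; the units are a documented interpretation, and the threshold is
configurable). A peak's extent is its full width at half maximum, with the
half level at half the absolute peak height: PSTHs are zero-baselined, and
this convention is the one under which the merge rule (neighboring peaks
whose FWHM extents overlap become one episode from the first start to the
last end) can actually trigger — a half level referenced to the
prominence base would always stop at the saddle and could never overlap.
Episode intervals are half-open `[start_bin, end_bin)` in 0-based bins so
that `duration = (end - start) * dt` with no off-by-one.

**Masked TCA.** The decomposition minimises
`||M ⊙ (X − Σ_r w_r ∘ b_r ∘ a_r)||²_F` with all factors nonnegative, where
the mask M zeroes entries with negative ΔF/F (measurement noise below
baseline carries no rate information for a nonnegative model). Optimization
is by masked multiplicative updates with a 1e-9 denominator guard: they
preserve nonnegativity without projection and make the masked objective
provably non-increasing, which the tests assert on every fit. Restarts
(default 3) from `|N(0,1)|` initialization guard against poor local optima;
on well-posed synthetic data two independent fits agree with similarity
≥ 0.95. Cross-validation holds out a random half of unmasked entries; when
ranks are scanned in ascending order each fit is warm-started from the
previous rank's factors padded with small random columns, which makes the
training error non-increasing in R by construction rather than by luck.
Model similarity matches components one-to-one with an exact Hungarian
assignment on the product of the three per-mode cosine similarities; scale
drops out per mode, so the score is invariant to component permutation and
per-mode rescaling — the two gauge freedoms of CP decompositions.

**Isomap.** Embedding uses the TCA reconstruction, not raw ΔF/F: the
reconstruction removes independent per-bin noise that would otherwise
corrupt nearest-neighbour assignment. The k-NN graph (Euclidean, ties
broken by point index for determinism) is symmetrized by union; geodesic
distances are shortest paths on this weighted graph (Dijkstra from every
source via igraph; Floyd–Warshall serves only as a test oracle); classical
MDS double-centres the squared geodesics and scales the top eigenvectors by
the square roots of their eigenvalues. For large clouds the top eigenpairs
come from shifted subspace iteration (shift = Frobenius norm, so the
largest algebraic eigenvalues dominate convergence); below 1500 points an
exact `eigen()` is used, and the two routes agree to high precision in the
tests. If the graph is disconnected, the embedding is restricted to the
largest component and the excluded points are reported — geodesics across
components are undefined, and dropping stragglers preserves the metric on
the bulk. Each output dimension's sign is fixed (first nonzero loading
positive) for reproducible orientation.

**SPUD.** Knots are initialized at K-means centroids (10 restarts) of the
training points and connected into a ring by data-point density: each
candidate segment is scored by the number of training points in a tube
around it divided by segment length. The tube radius is a quarter of the
median nearest-knot spacing — a choice that had to be pinned down because
"density between two knots" admits many formalizations; a wider tube (half the spacing) lets chords that skip a
knot hug a curved manifold and outscore adjacent connections, which
reverses the intended ordering. The ring is completed greedily
(best-scoring edges, no degree-3 vertices, no premature cycles) with an
angular-ordering fallback for degenerate inputs. Knot positions then
descend the printed objective — (sum of point-to-curve distances) × (total
curve length) — by finite-difference coordinate descent with backtracking,
accepting only decreasing steps. The multiplicative objective is taken
literally rather than as a penalized sum; it has a degenerate global
minimum at zero curve length, so sensible behaviour depends on initializing
on the manifold (which K-means guarantees) — a property worth knowing
before reusing the optimizer elsewhere. Coordinates are aligned to movie
time by a grid search over 350 circular shifts × flip, minimizing the mean
squared *circular* difference; 350 matches the number of time bins, below
which finer shifts cannot be resolved. The circular form of the error is
used because the latent variable is periodic; a linear MSE would
artificially penalize wrap-around. Decoding error is reported on held-out
points only (default 80/20 split; alternatively train on week-1 odd trials
to test generalization across weeks). For shuffled-control embeddings,
whose manifolds need not support K-means initialization, ten trial-averaged
points evenly distributed in time (`time_average_knots()`) replace the
K-means init.

**Variance geometry.** For each movie-time bin, the bin's points are
centred, the tangent of the fitted curve at the point nearest the centroid
defines the coding direction, and variance splits into the tangential
component and the total residual over the remaining d−1 directions
(unbiased, n−1 denominators, appropriate for the small number of trials per
bin). The tangent is taken once per bin (at the centroid's foot) rather
than per point: one arrow pair per time bin matches how the decomposition
is defined, and per-point tangents would mix segments at bin boundaries.
Tangential projections rather than arc-length differences are used for the
parallel component; the two agree when perpendicular spread is small
relative to curvature, which holds for the fitted rings here. The
decomposition is rotation-equivariant to 1e-10, verified in tests.

## What the synthetic generator emulates — and what it does not

`synth_params()` encodes the study design: 6 weekly sessions × 30 repeats
of a 35-s trial at 10 Hz (350 bins), a 5-s gray screen (50 bins) before a
30-s movie. Each of 100 neurons receives 1–4 non-overlapping episodes in
the movie window with log-normal durations (median 0.65 s, σ_log = 0.35,
the scale typical of such episodes), uniform base rates of
5–20 Hz, Poisson spike counts, and a difference-of-exponentials calcium
kernel (rise 0.1 s, decay 1.5 s — GCaMP6s-like) plus additive Gaussian
ΔF/F noise (SD 0.05).

Three generator choices deserve emphasis because they are where realism
decisions were genuinely open:

* **Gain structure.** Every episode draws one of five week-gain templates —
  stable (all ones), fading (0.65^week), rising, mid-transient, and
  fluctuating — so the population mixes stable and drifting components, as
  the observed trial-factor clusters do. Within a week, each episode's rate
  is multiplied by an independent log-normal trial gain (mean 1,
  CV 0.2). The trial gain is *episode-specific*, not a global per-trial
  scalar: rate fluctuations in the data are episode-level, and a global
  gain would be population-coherent noise that displaces the whole
  trajectory radially on every trial — a noise mode chronic recordings do
  not show, and one that would by itself corrupt the manifold.
* **The looped session.** Within a session the 30 repeats are contiguous in
  time, so calcium transients from the end of one repeat decay through the
  next repeat's gray screen (`spikes_to_dff(..., carryover = TRUE)`, the
  default; strict per-trial truncation is available and tested). This
  matters topologically: with truncation every trial starts cold at exactly
  zero, the population trajectory is an open arc pinned to the origin, and
  no ring exists to decode — the looped session is what closes the curve,
  exactly as in the continuous recordings it emulates.
* **Background spiking** defaults to 0 so the planted structure is exact
  and episode-recovery rates are well-defined; it is configurable when a
  noise floor is wanted.

The generator does **not** emulate: movie-frame-dependent receptive-field
structure (episode times are uniform in the movie window), eye movements or
locomotion, imaging artifacts, slow drift of the optical plane, or
correlated noise across neurons. Consequently, passing tests show that the
*pipeline* recovers planted episodic/gain/ring structure under Poisson and
Gaussian noise — they do not certify behaviour under structured artifacts
real recordings may contain.

## Problem sizes and numerical choices

The reference synthetic session used in the test-suite and in
`scripts/acceptance.R` is 100 neurons × 350 bins × 180 trials (6 weeks ×
30). For the manifold stages the 63,000-point cloud is subsampled *by
trial* (all 350 bins of 17 trials, ≥ 2 per week, ≈ 6000 points): whole
trials preserve the temporal continuity that carries the ring, whereas
thinning time bins fragments the k-NN graph into per-bin islands.
TCA uses rank 20 with one restart and up to 200 iterations (tolerance
1e-5) at this scale; rank 40 — the choice justified by cross-validation on
the full dataset — remains the package default in `validate_config()`.
Planted-recovery checks run 20 seeds at rank 3 on a 60 × 200 × 90 tensor
with 10 % noise and a 20 % mask. Isomap uses k = 20 (k = 100 for
circular-shuffle controls, whose intrinsic dimensionality is higher), d = 2
dimensions; SPUD uses 10 knots, 20 optimization sweeps, an 80/20 split and
period 35 s. These sizes were chosen so a complete run is comfortable on a
single CPU while every qualitative result (ring recovery, fourfold
better-than-chance decoding, variance anisotropy, control collapses) is
stable across seeds.

Degenerate inputs are defined behaviour throughout: all-zero neurons are
dropped at normalization; an all-masked tensor is an error; empty episode
lists are legal; disconnected embedding points are excluded and flagged;
ties (k-NN neighbours, nearest segments) break deterministically toward
lower indices; every randomized operation takes an explicit seed and is
bit-reproducible under it.

## Known limitations

* One control-analysis property does not survive the scale-down: on
  factor-shuffled reconstructions the variance anisotropy (parallel <
  perpendicular) is clearly present in the full N-dimensional state space
  (per-bin one-sided Wilcoxon p ≈ 1e-17 at reference conditions) but is
  *inverted* when measured in the first two Isomap dimensions, because the
  shuffled manifold's perpendicular variability spreads over many intrinsic
  dimensions that a 2-D embedding discards. This is a finite-size effect of
  the scaled-down conditions — larger clouds with more neurons retain more
  perpendicular structure in the leading embedding dimensions — and at this
  package's reference problem size the 2-D measurement fails; the
  corresponding test documents the failure rather than weakening the
  check.

* The SPUD objective taken literally admits curve collapse; only on-manifold
  initialization makes the optimum meaningful (see above).
* Isomap's neighbourhood size must track sampling density: k = 20 is
  matched to clouds of several thousand points and above; very sparse
  clouds need smaller k, very dense shuffled controls need larger (100).
* The decoding floor on synthetic data (median ≈ 1.5 s at reference
  conditions) reflects episode sparsity at 100 neurons and the collapsed
  gray-screen segment of the loop, not an optimizer limit; a noiseless
  planted ring decodes to < 0.05 s.
* Poisson-control and week-shuffle distributions are Gaussian-fitted by
  maximum likelihood; with few qualifying neurons those fits are crude
  summaries of a discrete distribution.

## A minimal run

```{r, eval = FALSE}
library(ringtime)
cfg <- list(
  synthetic = synth_params(n_neurons = 60, n_weeks = 4,
                           trials_per_week = 12, seed = 7),
  tca_rank = 12, tca_restarts = 1, tca_max_iter = 150, tca_tol = 1e-5,
  max_points = 3000, spud_iter = 15, controls = FALSE, seed = 11)
bundle <- run_pipeline(cfg)
bundle$spud$fit                      # decoding summary
head(bundle$geometry$all_trials)     # per-bin variance decomposition
```
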