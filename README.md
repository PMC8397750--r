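# ringtime

Analysis of chronic calcium-imaging population recordings during a repeated
natural movie: temporally precise **spiking episodes** with unstable
**gain**, and the stable low-dimensional **ring representation** of
time-in-movie that survives week-to-week representational drift.

`ringtime` is aimed at systems neuroscientists working with
(neuron × time × trial) ΔF/F tensors from chronic imaging across multiple
sessions. It implements the full chain — episode detection, masked
nonnegative tensor component analysis, Isomap embedding, unsupervised
ring-curve decoding, and variance decomposition along/perpendicular to the
coding direction — together with a synthetic-data generator that plants
known episodic structure and gain drift, so every stage can be validated
against ground truth without access to any specific dataset.

## The model at the core

**Masked nonnegative TCA.** The data tensor `x[n,t,k]` (neuron, time,
trial) is approximated by a sum of R rank-one nonnegative components,

    x[n,t,k]  ≈  Σ_r  w_r[n] · b_r[t] · a_r[k],

fitted by masked multiplicative updates to minimize
`|| M ⊙ (x − x̂) ||²_F`, where the mask `M` zeroes entries with negative
ΔF/F. Neuron factors `w` capture which cells participate in a component,
temporal factors `b` its episode-like time course, and trial factors `a`
its per-trial amplitude — the gain whose week-course characterizes drift.

**Ring decoding (SPUD).** The TCA-reconstructed population activity at each
time point is a point in N-dimensional state space; Isomap (20-NN graph →
graph geodesics → classical MDS) embeds the point cloud in two dimensions,
where the repeated movie traces a closed ring. A piecewise-linear closed
curve `L(y)` with ten knots is fitted by minimizing
`(Σ_i ||L(y) − x_i||) · |L(y)|`; each point's arc-length coordinate
`y ∈ [0,1)` is aligned to movie time by one circular shift/flip chosen on
training data, and decoded time is `α = y · 35 s`. Decoding error is the
circular difference `min(|t − α|, 35 − |t − α|)`; chance level for
independent uniform times is `35/4 = 8.75 s`.

**Variance geometry.** Per movie-time bin, trial-to-trial variance is
decomposed along the local curve tangent (the coding direction) and
perpendicular to it. Episodic timing that is stable across trials confines
variability to the perpendicular (non-coding) directions, which is what
leaves time decoding intact despite gain drift.

## Worked example

```r
library(ringtime)

cfg <- list(
  synthetic = synth_params(n_neurons = 60, n_weeks = 4,
                           trials_per_week = 12, seed = 7),
  tca_rank = 12, tca_restarts = 1, tca_max_iter = 150, tca_tol = 1e-5,
  max_points = 3000, spud_iter = 15, controls = FALSE, seed = 11)
bundle <- run_pipeline(cfg)

bundle$tca$model
#> <tca> R = 12 components, 60 x 350 x 48 tensor
#>   objective 328815 (normalized error 0.3264, 135 iterations)

bundle$spud$fit
#> <spud> 10-knot ring in dims [1,2]; median test decoding error 0.947 s (chance mean 8.75 s)

round(sapply(bundle$geometry[c("all_trials", "week_averaged", "within_week")],
             function(g) c(parallel = median(g$parallel),
                           perpendicular = median(g$perpendicular))), 3)
#>               all_trials week_averaged within_week
#> parallel           0.200         0.176       0.038
#> perpendicular      0.402         0.300       0.071
```

Reading the output: the rank-12 decomposition leaves ~33 % of masked
squared ΔF/F unexplained (single-trial Poisson and measurement noise, which
is the point of denoising); held-out time-in-movie is decoded with 0.95 s
median circular error against an 8.75 s chance mean; and in all three
grouping modes the variance along the coding direction is well below the
variance perpendicular to it — drift and trial noise live in non-coding
directions.

## Package layout

| Stage | Functions |
| --- | --- |
| Synthetic data | `synth_params`, `generate_ground_truth`, `simulate_spikes`, `spikes_to_dff`, `simulate_session`, `write_session` |
| Preprocessing | `neuropil_correct`, `select_alpha`, `compute_dff`, `normalize_tensor`, `week_similarity`, `reliability`, `week_change_vs_baseline` |
| Episodes | `binarize_spikes`, `compute_psth`, `smooth_psth`, `detect_episodes`, `episode_rates`, `episode_rate_stability`, `episode_pair_similarity`, `poisson_control`, `week_shuffle_control` |
| TCA | `build_mask`, `tca`, `reconstruct`, `normalized_error`, `cross_validate`, `model_similarity`, `cluster_trial_factors`, `trial_factor_stability`, `shuffle_factors` |
| Manifold | `tensor_to_points`, `subsample_cloud`, `knn_graph`, `geodesic_distances`, `classical_mds`, `isomap`, `circular_shuffle`, `trajectory_stability` |
| SPUD | `split_train_test`, `init_knots`, `connect_knots`, `optimize_knots`, `project_to_curve`, `align_coordinates`, `decode_time`, `spud`, `time_average_knots` |
| Geometry | `variance_decomposition`, `week_averaged_variance`, `within_week_variance`, `manifold_radius`, `paired_onesided_test` |
| Orchestration | `validate_config`, `run_pipeline` |

The methods vignette (`vignettes/ring-decoding.Rmd`) documents the model
assumptions, the synthetic generator's scope, and every numerical design
choice.
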