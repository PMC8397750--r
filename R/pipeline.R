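# End-to-end orchestration: synthetic session -> preprocessing -> episode
# detection -> TCA -> Isomap (plus circular-shift and factor-shuffle
# controls) -> SPUD decoding -> variance geometry.

#' Validate and normalize a pipeline configuration
#'
#' Fills in the default stage parameters (TCA rank 40, Isomap k = 20 with
#' k = 100 for shuffled controls, 2 embedding dimensions, 10 SPUD knots,
#' 0.8 training fraction, 5 trial-factor clusters) and rejects out-of-range
#' values with messages naming the offending field.
#'
#' @param config named list of overrides; `seed` is mandatory, and either
#'   `synthetic` (a [synth_params()]) or `dff` plus `spikes` must be
#'   supplied to [run_pipeline()].
#' @return the normalized config list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    synthetic = NULL, dff = NULL, spikes = NULL,
    tca_rank = 40L, tca_restarts = 3L, tca_max_iter = 500L, tca_tol = 1e-6,
    isomap_k = 20L, isomap_k_shuffled = 100L, dims = 2L,
    n_knots = 10L, train_frac = 0.8, k_clusters = 5L,
    max_points = 10000L, spud_iter = 30L, period = 35,
    prominence = 3, smooth_bandwidth_s = 0.2,
    seed = NULL, controls = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$seed)) stop("config field 'seed' is mandatory")
  chk <- function(ok, field, what) if (!ok) stop(sprintf("config field '%s' %s", field, what))
  chk(cfg$tca_rank >= 1, "tca_rank", "must be >= 1")
  chk(cfg$isomap_k >= 1, "isomap_k", "must be >= 1")
  chk(cfg$dims >= 2, "dims", "must be >= 2")
  chk(cfg$n_knots >= 3, "n_knots", "must be >= 3")
  chk(cfg$train_frac > 0 && cfg$train_frac < 1, "train_frac",
      "must lie in (0, 1)")
  chk(cfg$k_clusters >= 1, "k_clusters", "must be >= 1")
  chk(cfg$max_points >= 100, "max_points", "must be >= 100")
  chk(cfg$period > 0, "period", "must be > 0")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic session (or user-supplied tensors):
#' tensor normalization and masking, episode detection with rate-stability
#' statistics and Poisson / week-shuffle controls, masked nonnegative TCA
#' with trial-factor clustering and stability, Isomap embedding of the
#' reconstruction with trajectory stability, SPUD decoding (random split
#' and the week-1 generalization protocol), variance decomposition in all
#' three grouping modes, and — when `controls = TRUE` — the circular-shift
#' and factor-shuffle controls with radius comparison. Stage seeds are
#' derived deterministically from the master seed.
#'
#' @param config a [validate_config()]-compatible list.
#' @param out_dir optional directory; when given, per-stage tables are
#'   written as CSV/TSV plus a JSON manifest.
#' @return a list bundle with one element per stage.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  seed <- cfg$seed
  bundle <- list(config = cfg)

  if (!is.null(cfg$synthetic)) {
    stopifnot(inherits(cfg$synthetic, "synth_params"))
    session <- simulate_session(cfg$synthetic)
    dff <- session$dff
    spikes <- session$spikes
    bundle$ground_truth <- session$ground_truth
  } else if (!is.null(cfg$dff)) {
    dff <- cfg$dff
    spikes <- cfg$spikes
  } else {
    stop("config must supply either 'synthetic' params or a 'dff' tensor")
  }
  dt <- dff$dt

  # -- preprocess ----------------------------------------------------------
  norm <- normalize_tensor(dff)
  bundle$preprocess <- list(
    tensor = norm,
    week_similarity = week_similarity(norm))

  # -- episodes ------------------------------------------------------------
  if (is.null(spikes)) spikes <- naive_spike_inference(dff)
  eps <- detect_all_episodes(spikes, prominence = cfg$prominence,
                             bandwidth_s = cfg$smooth_bandwidth_s, dt = dt)
  ep_stage <- list(episodes = eps)
  if (nrow(eps) >= 2) {
    tab <- episode_rates(spikes, eps, dff$week_labels, dt)
    ep_stage$rate_table <- tab
    ep_stage$stability <- episode_rate_stability(tab)
    ep_stage$pair_similarity <- episode_pair_similarity(tab)
    ep_stage$poisson_control <- poisson_control(tab, derive_seed(seed, 11L))
    ep_stage$week_shuffle <- week_shuffle_control(tab, derive_seed(seed, 12L))
  }
  bundle$episodes <- ep_stage

  # -- tca -----------------------------------------------------------------
  R <- min(cfg$tca_rank, prod(dim(norm$values)[1:2]))
  mask <- build_mask(norm)
  model <- tca(norm$values, R, mask = mask, seed = derive_seed(seed, 21L),
               n_restarts = cfg$tca_restarts, max_iter = cfg$tca_max_iter,
               tol = cfg$tca_tol)
  bundle$tca <- list(
    model = model,
    clusters = cluster_trial_factors(model, min(cfg$k_clusters, R),
                                     derive_seed(seed, 22L)),
    stability = trial_factor_stability(model, norm$week_labels))

  # -- manifold ------------------------------------------------------------
  recon <- reconstruct(model)
  cloud <- subsample_cloud(tensor_to_points(recon, norm$week_labels),
                           cfg$max_points, derive_seed(seed, 31L))
  emb <- isomap(cloud, k = cfg$isomap_k, d = cfg$dims)
  bundle$manifold <- list(
    embedding = emb,
    trajectory_stability = trajectory_stability(emb))

  # -- spud ----------------------------------------------------------------
  n_time_bins <- dim(norm$values)[2]
  fit <- spud(emb, n_knots = cfg$n_knots, dims = seq_len(cfg$dims),
              train_frac = cfg$train_frac, seed = derive_seed(seed, 41L),
              n_iter = cfg$spud_iter, period = cfg$period,
              n_time_bins = n_time_bins)
  bundle$spud <- list(fit = fit)
  # generalization protocol: train on alternate week-1 trials (odd-ranked
  # among those kept after subsampling, so the split survives any trial
  # subset), test elsewhere
  w1 <- min(emb$week)
  w1_trials <- sort(unique(emb$trial[emb$week == w1]))
  odd_trials <- w1_trials[seq(1, length(w1_trials), by = 2)]
  odd1 <- which(emb$week == w1 & emb$trial %in% odd_trials)
  if (length(odd1) >= cfg$n_knots * 3) {
    gen <- spud(emb, n_knots = cfg$n_knots, dims = seq_len(cfg$dims),
                seed = derive_seed(seed, 42L), n_iter = cfg$spud_iter,
                period = cfg$period, n_time_bins = n_time_bins,
                train_idx = odd1)
    te <- gen$test_idx
    err <- gen$test$error_s
    same_week <- emb$week[te] == w1
    bundle$spud$generalization <- list(
      fit = gen,
      within_week1_median = stats::median(err[same_week]),
      later_weeks_median = stats::median(err[!same_week]))
  }

  # -- geometry ------------------------------------------------------------
  X <- emb$coords[, seq_len(cfg$dims), drop = FALSE]
  curve <- fit$curve
  bundle$geometry <- list(
    all_trials = variance_decomposition(X, emb$time_bin, curve),
    week_averaged = week_averaged_variance(X, emb$time_bin, emb$week, curve),
    within_week = within_week_variance(X, emb$time_bin, emb$week, curve),
    radius = manifold_radius(X))

  # -- controls ------------------------------------------------------------
  if (isTRUE(cfg$controls)) {
    shuf <- circular_shuffle(recon, derive_seed(seed, 51L))
    cloud_s <- subsample_cloud(tensor_to_points(shuf, norm$week_labels),
                               cfg$max_points, derive_seed(seed, 31L))
    emb_s <- isomap(cloud_s, k = cfg$isomap_k_shuffled, d = cfg$dims)
    fshuf <- shuffle_factors(model, derive_seed(seed, 52L))
    recon_f <- reconstruct(fshuf)
    cloud_f <- subsample_cloud(tensor_to_points(recon_f, norm$week_labels),
                               cfg$max_points, derive_seed(seed, 31L))
    # shuffled data have higher intrinsic dimensionality; embed with the
    # larger shuffled-data neighborhood, as for the circular-shift control
    emb_f <- isomap(cloud_f, k = cfg$isomap_k_shuffled, d = cfg$dims)
    # shuffled manifolds need not support K-means initialization; use the
    # ten per-time-decile trial-averaged points as initial knots
    fit_f <- spud(emb_f, n_knots = cfg$n_knots, dims = seq_len(cfg$dims),
                  train_frac = cfg$train_frac,
                  seed = derive_seed(seed, 41L), n_iter = cfg$spud_iter,
                  period = cfg$period, n_time_bins = n_time_bins,
                  init = time_average_knots(emb_f, cfg$n_knots,
                                            seq_len(cfg$dims)))
    Xf <- emb_f$coords[, seq_len(cfg$dims), drop = FALSE]
    rad_orig <- manifold_radius(X)$radius
    rad_f <- manifold_radius(Xf)$radius
    bundle$controls <- list(
      circular = list(
        embedding = emb_s,
        trajectory_stability = trajectory_stability(emb_s)),
      factor_shuffle = list(
        embedding = emb_f, fit = fit_f,
        all_trials = variance_decomposition(Xf, emb_f$time_bin, fit_f$curve),
        radius = rad_f,
        radius_test = paired_onesided_test(rad_f, rad_orig,
                                           kind = "mann-whitney",
                                           alternative = "less")))
  }

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# light-weight numeric digest for the manifest (no hashing package is a
# dependency): length, sum and sum of squares, rounded
num_digest <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v <- v[is.finite(v)]
  list(n = length(v), sum = signif(sum(v), 12), sumsq = signif(sum(v^2), 12))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  if (!is.null(bundle$episodes$episodes) && nrow(bundle$episodes$episodes)) {
    write_episodes(bundle$episodes$episodes,
                   file.path(out_dir, "episodes.tsv"))
  }
  if (!is.null(bundle$episodes$rate_table)) {
    utils::write.csv(bundle$episodes$rate_table$week_rates,
                     file.path(out_dir, "episode_week_rates.csv"),
                     row.names = FALSE)
  }
  emb <- bundle$manifold$embedding
  utils::write.csv(data.frame(emb$coords, time_bin = emb$time_bin,
                              trial = emb$trial, week = emb$week),
                   file.path(out_dir, "embedding.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(coef(bundle$spud$fit$curve)),
                   file.path(out_dir, "ring_knots.csv"), row.names = FALSE)
  utils::write.csv(bundle$spud$fit$test,
                   file.path(out_dir, "decoding_test.csv"), row.names = FALSE)
  for (mode in c("all_trials", "week_averaged", "within_week")) {
    utils::write.csv(bundle$geometry[[mode]],
                     file.path(out_dir, paste0("variance_", mode, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ringtime")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("synthetic", "dff", "spikes"))],
    stages = list(
      episodes = num_digest(bundle$episodes$episodes$start_bin),
      tca_objective = bundle$tca$model$objective,
      embedding = num_digest(emb$coords),
      decoding_error = num_digest(bundle$spud$fit$test$error_s)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
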