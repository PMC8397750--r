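# Synthetic calcium-imaging data with planted episodic structure and gain
# drift. Every downstream stage of the pipeline can be validated against the
# ground truth planted here.

#' Parameters for the synthetic-data generator
#'
#' Defines a chronic-imaging session structure (trials per week, weeks,
#' 35-s trials sampled at 10 Hz with a 5-s gray-screen lead-in) and the
#' generative model for neural activity: each neuron carries a small number
#' of short spiking episodes at fixed times in the movie; the within-episode
#' firing rate is scaled by a week-level gain trajectory (drawn from a small
#' set of cluster templates) and by per-trial multiplicative gain noise;
#' spikes are Poisson and are turned into DeltaF/F by convolution with a
#' calcium kernel plus additive noise.
#'
#' @param n_neurons number of neurons.
#' @param n_weeks number of weekly sessions.
#' @param trials_per_week movie repeats per session.
#' @param n_timepoints time bins per trial.
#' @param dt seconds per bin.
#' @param gray_bins bins of gray screen before the movie starts.
#' @param episodes_per_neuron integer range `c(min, max)` of planted episodes.
#' @param episode_duration_meanlog,episode_duration_sdlog log-normal
#'   parameters of episode duration in seconds; the default meanlog targets a
#'   median duration of 0.65 s.
#' @param base_rate_range within-episode firing-rate range in Hz (uniform).
#' @param n_gain_clusters number of week-gain cluster templates.
#' @param gain_cluster_profiles optional matrix (n_gain_clusters x n_weeks) of
#'   nonnegative week-gain templates; the default set includes a stable
#'   (all-ones) profile, a fading profile, and rising / transient /
#'   fluctuating profiles.
#' @param within_week_gain_cv coefficient of variation of the log-normal
#'   per-trial gain (mean 1).
#' @param calcium_tau,calcium_rise decay and rise time constants (s) of the
#'   difference-of-exponentials calcium kernel.
#' @param dff_noise_sd SD of additive Gaussian noise on DeltaF/F.
#' @param background_rate uniform background spiking rate in Hz (default 0 so
#'   planted structure is exact).
#' @param seed integer seed; all generator draws are functions of it.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(n_neurons = 100, n_weeks = 6, trials_per_week = 30,
                         n_timepoints = 350, dt = 0.1, gray_bins = 50,
                         episodes_per_neuron = c(1, 4),
                         episode_duration_meanlog = log(0.65),
                         episode_duration_sdlog = 0.35,
                         base_rate_range = c(5, 20),
                         n_gain_clusters = 5,
                         gain_cluster_profiles = NULL,
                         within_week_gain_cv = 0.2,
                         calcium_tau = 1.5, calcium_rise = 0.1,
                         dff_noise_sd = 0.05, background_rate = 0,
                         seed = 1L) {
  stopifnot(n_neurons >= 1, n_weeks >= 1, trials_per_week >= 1,
            n_timepoints >= 1, dt > 0, gray_bins >= 0,
            gray_bins < n_timepoints,
            length(episodes_per_neuron) == 2,
            episodes_per_neuron[1] >= 0,
            episodes_per_neuron[2] >= episodes_per_neuron[1],
            length(base_rate_range) == 2, base_rate_range[1] >= 0,
            within_week_gain_cv >= 0, calcium_tau > 0, calcium_rise > 0,
            dff_noise_sd >= 0, background_rate >= 0)
  if (is.null(gain_cluster_profiles)) {
    gain_cluster_profiles <- default_gain_profiles(n_gain_clusters, n_weeks)
  }
  gain_cluster_profiles <- as.matrix(gain_cluster_profiles)
  stopifnot(nrow(gain_cluster_profiles) == n_gain_clusters,
            ncol(gain_cluster_profiles) == n_weeks,
            all(gain_cluster_profiles >= 0))
  structure(list(
    n_neurons = as.integer(n_neurons), n_weeks = as.integer(n_weeks),
    trials_per_week = as.integer(trials_per_week),
    n_timepoints = as.integer(n_timepoints), dt = dt,
    gray_bins = as.integer(gray_bins),
    episodes_per_neuron = as.integer(episodes_per_neuron),
    episode_duration_meanlog = episode_duration_meanlog,
    episode_duration_sdlog = episode_duration_sdlog,
    base_rate_range = base_rate_range,
    n_gain_clusters = as.integer(n_gain_clusters),
    gain_cluster_profiles = gain_cluster_profiles,
    within_week_gain_cv = within_week_gain_cv,
    calcium_tau = calcium_tau, calcium_rise = calcium_rise,
    dff_noise_sd = dff_noise_sd, background_rate = background_rate,
    seed = as.integer(seed)), class = "synth_params")
}

# Default week-gain templates: stable, fading, rising, mid-transient,
# fluctuating; recycled if more clusters are requested.
default_gain_profiles <- function(n_clusters, n_weeks) {
  w <- seq_len(n_weeks)
  base <- rbind(
    stable      = rep(1, n_weeks),
    fading      = 0.65^(w - 1),
    rising      = rev(0.65^(w - 1)),
    transient   = exp(-0.5 * ((w - (n_weeks + 1) / 2) / (n_weeks / 5))^2),
    fluctuating = ifelse(w %% 2 == 1, 1, 0.4))
  base[rep_len(seq_len(nrow(base)), n_clusters), , drop = FALSE]
}

#' Plant ground-truth episodic structure
#'
#' Assigns each neuron a random number of non-overlapping spiking episodes
#' within the movie window. Each episode gets a log-normal duration, a
#' uniform base rate, and an independently drawn gain cluster whose template
#' is its week-gain trajectory. Per-trial gain multipliers are log-normal
#' with mean 1.
#'
#' @param params a [synth_params()] object.
#' @return an object of class `ground_truth`: `episodes` (data frame with
#'   columns neuron, start_bin, end_bin (0-based, half-open), duration_s
#'   (the continuous pre-binning duration), base_rate, cluster),
#'   `week_gains` (episode x week matrix), `week_labels`, and `trial_gains`
#'   (episode x trial matrix of within-week gain noise).
#' @export
generate_ground_truth <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  movie_bins <- p$n_timepoints - p$gray_bins
  # Durations are truncated at this cap so placement feasibility is checkable.
  cap_bins <- max(1L, min(movie_bins,
                          ceiling(exp(p$episode_duration_meanlog +
                                      3 * p$episode_duration_sdlog) / p$dt)))
  if (p$episodes_per_neuron[2] * cap_bins > movie_bins) {
    stop("episode count x maximum episode duration cannot fit in the movie window without overlap")
  }
  with_seed(p$seed, {
    rows <- vector("list", p$n_neurons)
    for (n in seq_len(p$n_neurons)) {
      n_ep <- if (p$episodes_per_neuron[2] == 0) 0L else
        sample(p$episodes_per_neuron[1]:p$episodes_per_neuron[2], 1)
      if (n_ep == 0) next
      dur_s <- stats::rlnorm(n_ep, p$episode_duration_meanlog,
                             p$episode_duration_sdlog)
      dur_bins <- pmin(pmax(1L, as.integer(round(dur_s / p$dt))), cap_bins)
      # sequential rejection placement of non-overlapping intervals,
      # longest first
      ord <- order(dur_bins, decreasing = TRUE)
      placed <- matrix(NA_real_, 0, 3)
      for (ii in ord) {
        d <- dur_bins[ii]
        ok <- FALSE
        for (try in 1:1000) {
          s <- p$gray_bins + sample.int(movie_bins - d + 1, 1) - 1L
          e <- s + d
          if (nrow(placed) == 0 ||
              all(e <= placed[, 1] | s >= placed[, 2])) {
            placed <- rbind(placed, c(s, e, dur_s[ii])); ok <- TRUE; break
          }
        }
        if (!ok) stop("failed to place non-overlapping episodes; reduce count or duration")
      }
      placed <- placed[order(placed[, 1]), , drop = FALSE]
      rows[[n]] <- data.frame(
        neuron = n, start_bin = as.integer(placed[, 1]),
        end_bin = as.integer(placed[, 2]),
        duration_s = placed[, 3],
        base_rate = stats::runif(nrow(placed), p$base_rate_range[1],
                                 p$base_rate_range[2]),
        cluster = sample.int(p$n_gain_clusters, nrow(placed), replace = TRUE))
    }
    episodes <- do.call(rbind, rows)
    if (is.null(episodes)) {
      episodes <- data.frame(neuron = integer(), start_bin = integer(),
                             end_bin = integer(), duration_s = numeric(),
                             base_rate = numeric(), cluster = integer())
    }
    week_labels <- rep(seq_len(p$n_weeks), each = p$trials_per_week)
    # gain noise is episode-specific: each episode's rate fluctuates
    # independently across trials (log-normal, mean 1). A single global
    # per-trial gain would be population-coherent noise, which chronic
    # recordings do not show; episode-level fluctuation averages out across
    # the population.
    cv <- p$within_week_gain_cv
    sdl <- sqrt(log(1 + cv^2))
    trial_gains <- if (cv > 0 && nrow(episodes) > 0) {
      matrix(stats::rlnorm(nrow(episodes) * length(week_labels),
                           -sdl^2 / 2, sdl),
             nrow(episodes), length(week_labels))
    } else matrix(1, max(nrow(episodes), 1), length(week_labels))
    week_gains <- p$gain_cluster_profiles[episodes$cluster, , drop = FALSE]
    structure(list(episodes = episodes, week_gains = week_gains,
                   week_labels = week_labels, trial_gains = trial_gains,
                   params = p), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted episodes in %d neurons, %d weeks x %d trials\n",
              nrow(x$episodes), x$params$n_neurons, x$params$n_weeks,
              x$params$trials_per_week))
  invisible(x)
}

#' Simulate Poisson spikes from planted ground truth
#'
#' Bin counts inside an episode are Poisson with mean
#' `base_rate * week_gain * trial_gain * dt`; outside episodes the rate is
#' the (default zero) background rate.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param params the matching [synth_params()].
#' @return integer array, neurons x timepoints x trials.
#' @export
simulate_spikes <- function(gt, params) {
  stopifnot(inherits(gt, "ground_truth"), inherits(params, "synth_params"))
  p <- params
  K <- p$n_weeks * p$trials_per_week
  stopifnot(length(gt$week_labels) == K)
  rate <- array(p$background_rate, c(p$n_neurons, p$n_timepoints, K))
  eps <- gt$episodes
  if (nrow(eps) > 0) {
    for (i in seq_len(nrow(eps))) {
      bins <- (eps$start_bin[i] + 1L):eps$end_bin[i]
      g <- gt$week_gains[i, gt$week_labels] * gt$trial_gains[i, ]  # length K
      rate[eps$neuron[i], bins, ] <-
        rate[eps$neuron[i], bins, ] +
        eps$base_rate[i] * rep(g, each = length(bins))
    }
  }
  with_seed(derive_seed(p$seed, 1L), {
    counts <- stats::rpois(length(rate), lambda = rate * p$dt)
    array(as.integer(counts), dim(rate))
  })
}

# Causal difference-of-exponentials calcium kernel on the bin grid,
# normalized to unit peak.
calcium_kernel <- function(tau, rise, dt, n_bins) {
  stopifnot(tau > 0, rise > 0)
  t <- (seq_len(n_bins) - 1) * dt
  k <- exp(-t / tau) - exp(-t / rise)
  pk <- max(k)
  if (pk <= 0) rep(0, n_bins) else k / pk
}

#' Convolve spikes with a calcium kernel to obtain DeltaF/F
#'
#' Each spike contributes a causal difference-of-exponentials transient
#' (rise `calcium_rise`, decay `calcium_tau`), implemented as the difference
#' of two AR(1) filters. With `carryover = TRUE` (the default) the repeats
#' of one weekly session are treated as contiguous in time, as in a
#' continuous recording: transients from the end of one repeat decay into
#' the next repeat's gray period. This closes the trial loop in state space
#' — without it every trial would start cold at exactly zero and the
#' population trajectory would be an open arc instead of a ring. Nothing
#' carries across weeks (separate recordings). With `carryover = FALSE` the
#' convolution is truncated at every trial boundary. Additive Gaussian
#' noise with SD `dff_noise_sd` is applied last.
#'
#' @param spikes nonnegative integer array, neurons x timepoints x trials.
#' @param params the matching [synth_params()].
#' @param carryover carry calcium transients across trial boundaries within
#'   a week (default TRUE).
#' @return a [dff_tensor()] with the session's week labels.
#' @export
spikes_to_dff <- function(spikes, params, carryover = TRUE) {
  stopifnot(inherits(params, "synth_params"), all(spikes >= 0))
  p <- params
  d <- dim(spikes)
  # peak normalization of h(t) = exp(-t/tau) - exp(-t/rise)
  stopifnot(p$calcium_tau > 0, p$calcium_rise > 0)
  tgrid <- (seq_len(d[2]) - 1) * p$dt
  h <- exp(-tgrid / p$calcium_tau) - exp(-tgrid / p$calcium_rise)
  cpk <- max(h)
  a_tau <- exp(-p$dt / p$calcium_tau)
  a_rise <- exp(-p$dt / p$calcium_rise)
  conv1 <- function(x) {
    (stats::filter(x, a_tau, method = "recursive") -
     stats::filter(x, a_rise, method = "recursive")) / cpk
  }
  out <- array(0, d)
  week_labels <- rep(seq_len(p$n_weeks), each = p$trials_per_week)
  if (carryover) {
    for (w in seq_len(p$n_weeks)) {
      tr <- which(week_labels == w)
      for (n in seq_len(d[1])) {
        xcat <- as.vector(spikes[n, , tr])
        out[n, , tr] <- conv1(xcat)
      }
    }
  } else {
    for (k in seq_len(d[3])) {
      for (n in seq_len(d[1])) {
        out[n, , k] <- conv1(spikes[n, , k])
      }
    }
  }
  if (p$dff_noise_sd > 0) {
    out <- out + with_seed(derive_seed(p$seed, 2L),
      array(stats::rnorm(length(out), 0, p$dff_noise_sd), d))
  }
  dff_tensor(out, week_labels, dt = p$dt,
             movie_start_bin = p$gray_bins + 1L)
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper running [generate_ground_truth()],
#' [simulate_spikes()] and [spikes_to_dff()].
#'
#' @param params a [synth_params()] object.
#' @return list with `ground_truth`, `spikes`, `dff`.
#' @export
simulate_session <- function(params = synth_params()) {
  gt <- generate_ground_truth(params)
  spikes <- simulate_spikes(gt, params)
  dff <- spikes_to_dff(spikes, params)
  list(ground_truth = gt, spikes = spikes, dff = dff)
}

#' Write / read a synthetic session as a plain-text dataset directory
#'
#' Datasets are stored as CSV matrices (`dff.csv`, `spikes.csv` with one row
#' per neuron and columns ordered time-within-trial fastest), per-trial
#' `week_labels.csv`, per-bin `time_s.csv`, the ground truth and generator
#' seed as JSON.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (`write_session`); a session list (`read_session`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(session$dff$values)
  utils::write.table(matrix(session$dff$values, d[1], d[2] * d[3]),
                     file.path(dir, "dff.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(session$spikes, d[1], d[2] * d[3]),
                     file.path(dir, "spikes.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(session$dff$week_labels, file.path(dir, "week_labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table((seq_len(d[2]) - 1) * session$dff$dt,
                     file.path(dir, "time_s.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  gt <- session$ground_truth
  jsonlite::write_json(list(
    episodes = gt$episodes, week_gains = gt$week_gains,
    trial_gains = gt$trial_gains, seed = gt$params$seed,
    dt = gt$params$dt, movie_start_bin = session$dff$movie_start_bin),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  week_labels <- as.integer(utils::read.table(
    file.path(dir, "week_labels.csv"))[, 1])
  time_s <- as.numeric(utils::read.table(file.path(dir, "time_s.csv"))[, 1])
  Tn <- length(time_s); K <- length(week_labels)
  dffm <- as.matrix(utils::read.table(file.path(dir, "dff.csv"), sep = ","))
  spkm <- as.matrix(utils::read.table(file.path(dir, "spikes.csv"), sep = ","))
  N <- nrow(dffm)
  list(
    dff = dff_tensor(array(as.numeric(dffm), c(N, Tn, K)), week_labels,
                     dt = meta$dt, movie_start_bin = meta$movie_start_bin),
    spikes = array(as.integer(spkm), c(N, Tn, K)),
    ground_truth_meta = meta)
}
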