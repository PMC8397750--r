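# Spiking-episode detection from the trial-summed PSTH and episode-level
# gain-stability statistics.
#
# Episode intervals are half-open [start_bin, end_bin) in 0-based time-bin
# indices, so duration_s = (end_bin - start_bin) * dt with no off-by-one.

#' Binarize a deconvolved-activity tensor into inferred spikes
#'
#' An entry becomes 1 where the deconvolved value exceeds `threshold_sd`
#' standard deviations above zero; the per-neuron SD is taken about zero
#' (root mean square over all bins and trials).
#'
#' @param x numeric array, neurons x timepoints x trials.
#' @param threshold_sd threshold in per-neuron SD units (default 3).
#' @return integer 0/1 array of the same shape.
#' @export
binarize_spikes <- function(x, threshold_sd = 3) {
  stopifnot(all(is.finite(x)))
  d <- dim(x)
  sd0 <- sqrt(apply(x^2, 1, mean))
  thr <- array(rep(threshold_sd * sd0, d[2] * d[3]), d)
  array(as.integer(x > thr), d)
}

#' Naive fallback spike inference from DeltaF/F
#'
#' Positive first difference of each trace thresholded at 3 SD; a
#' demonstration substitute when no deconvolved-spike tensor is available.
#'
#' @param x a [dff_tensor()].
#' @param threshold_sd threshold in SD units.
#' @return integer 0/1 array of the same shape.
#' @export
naive_spike_inference <- function(x, threshold_sd = 3) {
  v <- x$values
  d <- dim(v)
  diffs <- v
  diffs[, -1, ] <- v[, -1, , drop = FALSE] - v[, -d[2], , drop = FALSE]
  diffs[, 1, ] <- 0
  diffs[diffs < 0] <- 0
  binarize_spikes(diffs, threshold_sd)
}

#' Peristimulus time histogram of one neuron
#'
#' Per-bin sum of inferred spikes across the selected trials.
#'
#' @param spikes integer array, neurons x timepoints x trials.
#' @param neuron neuron index.
#' @param trials trial subset (default all).
#' @return numeric vector of per-bin summed counts.
#' @export
compute_psth <- function(spikes, neuron, trials = seq_len(dim(spikes)[3])) {
  if (length(trials) == 0) stop("empty trial subset")
  m <- spikes[neuron, , trials, drop = FALSE]
  apply(m, 2, sum)
}

#' Smooth a PSTH with a Gaussian kernel
#'
#' Gaussian kernel of SD `bandwidth_s`, reflective boundary handling; the
#' kernel is normalized so total mass is preserved (within boundary effects
#' below 1 percent).
#'
#' @param psth numeric vector of per-bin counts.
#' @param bandwidth_s kernel SD in seconds (default 0.2).
#' @param dt seconds per bin.
#' @return smoothed numeric vector.
#' @export
smooth_psth <- function(psth, bandwidth_s = 0.2, dt = 0.1) {
  stopifnot(bandwidth_s > 0, dt > 0)
  sd_bins <- bandwidth_s / dt
  if (sd_bins < 1e-6) return(psth)
  radius <- max(1L, ceiling(4 * sd_bins))
  kern <- stats::dnorm(-radius:radius, sd = sd_bins)
  kern <- kern / sum(kern)
  n <- length(psth)
  # reflective padding
  pad <- c(rev(psth[seq_len(min(radius, n))]), psth,
           rev(psth[seq.int(n, by = -1, length.out = min(radius, n))]))
  if (radius > n) {  # tiny traces: extend by more reflection cycles
    pad <- c(rep(psth[1], radius - n), pad, rep(psth[n], radius - n))
  }
  out <- stats::filter(pad, kern, method = "convolution", sides = 2)
  as.numeric(out[(radius + 1):(radius + n)])
}

# Topographic prominence of a local maximum at index i: height above the
# higher of the two lowest points on the paths to the nearest higher terrain
# (or the trace boundary).
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i
  while (j > 1) {
    j <- j - 1
    if (x[j] > x[i]) break
    left_min <- min(left_min, x[j])
    if (j == 1) break
  }
  if (j >= 1 && x[j] <= x[i]) left_min <- min(left_min, x[j])
  right_min <- x[i]
  j <- i
  while (j < n) {
    j <- j + 1
    if (x[j] > x[i]) break
    right_min <- min(right_min, x[j])
    if (j == n) break
  }
  if (j <= n && x[j] <= x[i]) right_min <- min(right_min, x[j])
  x[i] - max(left_min, right_min)
}

#' Detect spiking episodes in a smoothed PSTH
#'
#' Finds local maxima with topographic prominence above `prominence`
#' (measured on the smoothed PSTH, in summed-spike-count units). Each peak's
#' extent is its full width at half maximum — the contiguous stretch where
#' the trace stays at or above half the peak height (PSTHs are zero-based,
#' so the half level is absolute; a shoulder between two close peaks that
#' stays above half maximum joins their extents). Overlapping extents are
#' merged into a single episode spanning from the first start to the last
#' end.
#'
#' @param smoothed smoothed PSTH vector.
#' @param prominence minimum topographic prominence (default 3).
#' @param dt seconds per bin.
#' @param neuron optional neuron index recorded in the output.
#' @return data frame with columns `neuron`, `start_bin`, `end_bin` (0-based,
#'   half-open), `peak_bin`, `duration_s`, sorted by start.
#' @export
detect_episodes <- function(smoothed, prominence = 3, dt = 0.1,
                            neuron = NA_integer_) {
  stopifnot(all(is.finite(smoothed)))
  n <- length(smoothed)
  empty <- data.frame(neuron = integer(), start_bin = integer(),
                      end_bin = integer(), peak_bin = integer(),
                      duration_s = numeric())
  if (n < 3) return(empty)
  is_peak <- which(vapply(2:(n - 1), function(i) {
    smoothed[i] > smoothed[i - 1] && smoothed[i] >= smoothed[i + 1]
  }, logical(1))) + 1L
  if (length(is_peak) == 0) return(empty)
  ivs <- matrix(NA_integer_, 0, 3)
  for (i in is_peak) {
    prom <- peak_prominence(smoothed, i)
    if (prom <= prominence) next
    half <- smoothed[i] / 2
    s <- i
    while (s > 1 && smoothed[s - 1] >= half) s <- s - 1
    e <- i
    while (e < n && smoothed[e + 1] >= half) e <- e + 1
    ivs <- rbind(ivs, c(s, e, i))
  }
  if (nrow(ivs) == 0) return(empty)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  # merge overlapping FWHM intervals: first start to last end
  merged <- list()
  cur <- ivs[1, ]
  if (nrow(ivs) > 1) for (r in 2:nrow(ivs)) {
    if (ivs[r, 1] <= cur[2]) {
      cur[2] <- max(cur[2], ivs[r, 2])
      if (smoothed[ivs[r, 3]] > smoothed[cur[3]]) cur[3] <- ivs[r, 3]
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- ivs[r, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  # convert 1-based inclusive [s, e] to 0-based half-open [s-1, e)
  data.frame(neuron = neuron, start_bin = m[, 1] - 1L, end_bin = m[, 2],
             peak_bin = m[, 3] - 1L,
             duration_s = (m[, 2] - m[, 1] + 1L) * dt)
}

#' Detect episodes for every neuron of a spike tensor
#'
#' Computes the across-trial PSTH per neuron, smooths it, and runs
#' [detect_episodes()].
#'
#' @param spikes integer array, neurons x timepoints x trials.
#' @param trials trial subset used for the PSTH (default all).
#' @param prominence,bandwidth_s,dt passed through.
#' @return row-bound episode data frame.
#' @export
detect_all_episodes <- function(spikes, trials = seq_len(dim(spikes)[3]),
                                prominence = 3, bandwidth_s = 0.2, dt = 0.1) {
  out <- lapply(seq_len(dim(spikes)[1]), function(n) {
    ps <- compute_psth(spikes, n, trials)
    detect_episodes(smooth_psth(ps, bandwidth_s, dt), prominence, dt, n)
  })
  do.call(rbind, out)
}

#' Per-trial and per-week mean rates of detected episodes
#'
#' For each episode and trial, the mean inferred spike rate in Hz over the
#' episode window; per week, the trial average of those rates.
#'
#' @param spikes integer array, neurons x timepoints x trials.
#' @param episodes episode data frame from [detect_all_episodes()].
#' @param week_labels per-trial week index.
#' @param dt seconds per bin.
#' @return object of class `episode_rate_table`: `rates` (episode x trial),
#'   `week_rates` (episode x week), `episodes`, `week_labels`.
#' @export
episode_rates <- function(spikes, episodes, week_labels, dt = 0.1) {
  stopifnot(nrow(episodes) >= 1, all(episodes$end_bin <= dim(spikes)[2]))
  K <- dim(spikes)[3]
  rates <- matrix(0, nrow(episodes), K)
  for (i in seq_len(nrow(episodes))) {
    bins <- (episodes$start_bin[i] + 1L):episodes$end_bin[i]
    cnt <- spikes[episodes$neuron[i], bins, , drop = FALSE]
    rates[i, ] <- apply(cnt, 3, sum) / (length(bins) * dt)
  }
  weeks <- sort(unique(week_labels))
  week_rates <- vapply(weeks, function(w) {
    rowMeans(rates[, week_labels == w, drop = FALSE])
  }, numeric(nrow(episodes)))
  week_rates <- matrix(week_rates, nrow(episodes), length(weeks))
  structure(list(rates = rates, week_rates = week_rates,
                 episodes = episodes, week_labels = week_labels,
                 weeks = weeks, dt = dt),
            class = "episode_rate_table")
}

#' @export
print.episode_rate_table <- function(x, ...) {
  cat(sprintf("<episode_rate_table> %d episodes x %d trials (%d weeks)\n",
              nrow(x$rates), ncol(x$rates), length(x$weeks)))
  invisible(x)
}

#' Within-week versus across-week stability of episode rates
#'
#' Across-week CC: for every unordered week pair, the Pearson correlation
#' between the two weeks' episode-rate vectors (one entry per episode),
#' averaged over pairs. Within-week CC: per week, the correlation between
#' the episode-rate vectors computed from even- and odd-indexed trials of
#' that week, averaged over weeks. Constant vectors are excluded pairwise.
#'
#' @param tab an [episode_rates()] table.
#' @return list with `within_week_cc` and `across_week_cc`.
#' @export
episode_rate_stability <- function(tab) {
  stopifnot(inherits(tab, "episode_rate_table"),
            length(tab$weeks) >= 2, nrow(tab$rates) >= 2)
  W <- length(tab$weeks)
  pairs <- utils::combn(W, 2)
  across <- apply(pairs, 2, function(p) {
    safe_cor(tab$week_rates[, p[1]], tab$week_rates[, p[2]])
  })
  within <- vapply(seq_len(W), function(w) {
    tr <- which(tab$week_labels == tab$weeks[w])
    even <- tr[seq_along(tr) %% 2 == 0]
    odd <- tr[seq_along(tr) %% 2 == 1]
    if (length(even) == 0 || length(odd) == 0) return(NA_real_)
    safe_cor(rowMeans(tab$rates[, even, drop = FALSE]),
             rowMeans(tab$rates[, odd, drop = FALSE]))
  }, numeric(1))
  list(within_week_cc = mean(within, na.rm = TRUE),
       across_week_cc = mean(across, na.rm = TRUE))
}

# per-neuron mean pairwise CC between week-mean rate vectors of a set of
# episode x week rows
pairwise_week_cc <- function(week_rates, neuron_of) {
  neurons <- unique(neuron_of)
  out <- vapply(neurons, function(n) {
    idx <- which(neuron_of == n)
    if (length(idx) < 2) return(NA_real_)
    cc <- utils::combn(idx, 2, function(p) {
      safe_cor(week_rates[p[1], ], week_rates[p[2], ])
    })
    mean(cc, na.rm = TRUE)
  }, numeric(1))
  out[!is.na(out)]
}

#' Similarity of week trajectories between a neuron's episodes
#'
#' Per neuron with at least two episodes: the mean over unordered episode
#' pairs of the Pearson correlation between their week-mean rate vectors.
#'
#' @param tab an [episode_rates()] table.
#' @return numeric vector of per-neuron mean CCs.
#' @export
episode_pair_similarity <- function(tab) {
  stopifnot(inherits(tab, "episode_rate_table"), length(tab$weeks) >= 2)
  pairwise_week_cc(tab$week_rates, tab$episodes$neuron)
}

# Gaussian maximum-likelihood fit (mean, SD with 1/n)
gaussian_fit <- function(x) {
  m <- mean(x)
  list(mean = m, sd = sqrt(mean((x - m)^2)))
}

#' Poisson control for episode-pair similarity
#'
#' For each neuron one episode is selected at random; all of the neuron's
#' episodes are then re-simulated as i.i.d. Poisson spike trains sharing the
#' chosen episode's week-specific rates (counts drawn per trial over each
#' episode's own duration), and the episode-pair mean CC is recomputed. The
#' resulting distribution shows the CC expected if episodes shared a single
#' underlying rate trajectory and differed only by Poisson noise.
#'
#' @param tab an [episode_rates()] table.
#' @param seed integer seed.
#' @return list with `cc` (per-neuron mean CCs) and `fit` (Gaussian mean, sd).
#' @export
poisson_control <- function(tab, seed = 1L) {
  stopifnot(inherits(tab, "episode_rate_table"), length(tab$weeks) >= 2)
  eps <- tab$episodes
  dur <- (eps$end_bin - eps$start_bin) * tab$dt
  K <- ncol(tab$rates)
  week_of_trial <- match(tab$week_labels, tab$weeks)
  with_seed(seed, {
    sim_rates <- matrix(NA_real_, nrow(eps), length(tab$weeks))
    for (n in unique(eps$neuron)) {
      idx <- which(eps$neuron == n)
      if (length(idx) < 2) next
      chosen <- idx[sample.int(length(idx), 1)]
      lam_w <- tab$week_rates[chosen, ]  # shared trajectory, Hz
      if (all(lam_w == 0)) next
      for (i in idx) {
        counts <- stats::rpois(K, lam_w[week_of_trial] * dur[i])
        r <- counts / dur[i]
        sim_rates[i, ] <- vapply(seq_along(tab$weeks), function(w) {
          mean(r[week_of_trial == w])
        }, numeric(1))
      }
    }
    keep <- !is.na(sim_rates[, 1])
    cc <- pairwise_week_cc(sim_rates[keep, , drop = FALSE],
                           eps$neuron[keep])
    list(cc = cc, fit = gaussian_fit(cc))
  })
}

#' Week-shuffle control for episode-pair similarity
#'
#' Independently permutes the week order of each episode's week-mean rate
#' vector before computing the per-neuron episode-pair mean CC; the chance
#' distribution when week trajectories carry no shared temporal structure.
#'
#' @param tab an [episode_rates()] table.
#' @param seed integer seed.
#' @return list with `cc` and `fit` (Gaussian mean, sd).
#' @export
week_shuffle_control <- function(tab, seed = 1L) {
  stopifnot(inherits(tab, "episode_rate_table"), length(tab$weeks) >= 2)
  W <- length(tab$weeks)
  with_seed(seed, {
    shuf <- t(apply(tab$week_rates, 1, function(v) v[sample.int(W)]))
    cc <- pairwise_week_cc(shuf, tab$episodes$neuron)
    list(cc = cc, fit = gaussian_fit(cc))
  })
}

#' Export episodes as a BED-like table
#'
#' Tab-separated columns: neuron, start_bin, end_bin, peak_bin, duration_s.
#'
#' @param episodes episode data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  utils::write.table(
    episodes[, c("neuron", "start_bin", "end_bin", "peak_bin", "duration_s")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
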