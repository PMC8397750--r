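# Fluorescence-to-DeltaF/F conversion, tensor normalization, and the
# single-neuron week-similarity statistics.

#' Neuropil correction of a somatic fluorescence trace
#'
#' Subtracts the mean-centered neuropil signal scaled by `alpha`:
#' `F_corrected(n) = F_soma(n) - alpha * (F_neuropil(n) - mean(F_neuropil))`.
#'
#' @param f_soma,f_neuropil equal-length fluorescence traces.
#' @param alpha neuropil contamination coefficient in \[0, 1\].
#' @return corrected fluorescence trace.
#' @export
neuropil_correct <- function(f_soma, f_neuropil, alpha) {
  if (length(f_soma) != length(f_neuropil)) {
    stop("f_soma and f_neuropil must have equal length")
  }
  stopifnot(alpha >= 0, alpha <= 1)
  f_soma - alpha * (f_neuropil - mean(f_neuropil))
}

#' Choose the neuropil coefficient
#'
#' Grid search over alpha in \[0, 1\] (step 0.01) minimizing the absolute
#' Pearson correlation between the corrected trace and the neuropil trace.
#'
#' @inheritParams neuropil_correct
#' @param step grid step.
#' @return the minimizing alpha.
#' @export
select_alpha <- function(f_soma, f_neuropil, step = 0.01) {
  if (stats::sd(f_neuropil) == 0) {
    warning("constant neuropil trace; correlation undefined, returning alpha = 0")
    return(0)
  }
  grid <- seq(0, 1, by = step)
  score <- vapply(grid, function(a) {
    r <- safe_cor(neuropil_correct(f_soma, f_neuropil, a), f_neuropil)
    if (is.na(r)) 0 else abs(r)
  }, numeric(1))
  grid[which.min(score)]
}

#' DeltaF/F from a corrected fluorescence trace
#'
#' Baseline F0 is the mode of the trace's density distribution over the full
#' series, estimated by a Gaussian kernel density (Silverman bandwidth) on a
#' 512-point grid; DeltaF/F = (F - F0) / F0.
#'
#' @param f corrected fluorescence trace.
#' @param f0 optional baseline override.
#' @return list with `dff` and the baseline `f0`.
#' @export
compute_dff <- function(f, f0 = NULL) {
  stopifnot(all(is.finite(f)))
  if (is.null(f0)) {
    f0 <- if (stats::sd(f) == 0) f[1] else {
      dens <- stats::density(f, bw = "nrd0", n = 512)
      dens$x[which.max(dens$y)]
    }
  }
  if (f0 <= 0) stop("baseline F0 <= 0; DeltaF/F undefined")
  list(dff = (f - f0) / f0, f0 = f0)
}

#' Normalize a DeltaF/F tensor to unit per-neuron root mean square
#'
#' Divides each neuron's values by `sqrt(sum(x^2) / (T*K))` so that the RMS
#' over time and trials is exactly 1 for every kept neuron. All-zero neurons
#' are dropped with a warning.
#'
#' @param x a [dff_tensor()].
#' @return the normalized `dff_tensor`; dropped neuron indices (if any) in
#'   attribute `"dropped"`.
#' @export
normalize_tensor <- function(x) {
  stopifnot(inherits(x, "dff_tensor"))
  d <- dim(x$values)
  rms <- sqrt(apply(x$values^2, 1, sum) / (d[2] * d[3]))
  keep <- rms > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d all-zero neuron(s) from normalization",
                    sum(!keep)))
  }
  vals <- x$values[keep, , , drop = FALSE] / rms[keep]
  out <- dff_tensor(vals, x$week_labels, x$dt, x$movie_start_bin)
  attr(out, "dropped") <- which(!keep)
  out
}

# trial-averaged trace per neuron for a subset of trials: N x T matrix
trial_average <- function(x, trials) {
  apply(x$values[, , trials, drop = FALSE], c(1, 2), mean)
}

#' Across-week similarity of trial-averaged responses
#'
#' For each week, the Pearson correlation between a neuron's trial-averaged
#' trace in the reference week and in that week, averaged across neurons.
#' Neurons with a zero-variance mean trace in either week are excluded.
#'
#' @param x a [dff_tensor()].
#' @param reference_week week used as baseline (default first).
#' @return named numeric vector of similarities, one per week.
#' @export
week_similarity <- function(x, reference_week = min(x$week_labels)) {
  weeks <- sort(unique(x$week_labels))
  stopifnot(length(weeks) >= 2, reference_week %in% weeks)
  ref <- trial_average(x, which(x$week_labels == reference_week))
  out <- vapply(weeks, function(w) {
    m <- trial_average(x, which(x$week_labels == w))
    cc <- vapply(seq_len(nrow(ref)),
                 function(n) safe_cor(ref[n, ], m[n, ]), numeric(1))
    mean(cc, na.rm = TRUE)
  }, numeric(1))
  names(out) <- paste0("week", weeks)
  out
}

#' Trial-to-trial reliability of one neuron
#'
#' Mean Pearson correlation over all unordered pairs of the neuron's
#' single-trial traces; zero-variance trials are skipped pairwise.
#'
#' @param x a [dff_tensor()].
#' @param neuron neuron index.
#' @param trials optional trial subset (default all).
#' @return scalar mean pairwise correlation.
#' @export
reliability <- function(x, neuron, trials = seq_len(dim(x$values)[3])) {
  stopifnot(length(trials) >= 2)
  m <- x$values[neuron, , trials]
  cc <- stats::cor(m)
  vals <- cc[upper.tri(cc)]
  mean(vals, na.rm = TRUE)
}

#' Across-week response change versus within-week baseline
#'
#' The first week's trials are split into random halves H1a / H1b; the
#' baseline is each neuron's mean absolute difference between the two
#' half-averaged traces. The across-week change for week w > 1 is the same
#' statistic between a random half of week w's trials and H1a, so both
#' distributions are built from equally sized trial averages and agree under
#' stationarity. Returned along with a two-sided Mann-Whitney comparison.
#'
#' @param x a [dff_tensor()].
#' @param seed seed for the half-splits.
#' @return list with `across`, `baseline`, and `test` (htest).
#' @export
week_change_vs_baseline <- function(x, seed = 1L) {
  weeks <- sort(unique(x$week_labels))
  if (length(weeks) < 2) stop("need at least two weeks")
  ref_trials <- which(x$week_labels == weeks[1])
  with_seed(seed, {
    h1a <- sample(ref_trials, floor(length(ref_trials) / 2))
    ref <- trial_average(x, h1a)
    baseline <- rowMeans(abs(trial_average(x, setdiff(ref_trials, h1a)) - ref))
    across <- unlist(lapply(weeks[-1], function(w) {
      tr <- which(x$week_labels == w)
      half <- sample(tr, floor(length(tr) / 2))
      rowMeans(abs(trial_average(x, half) - ref))
    }))
    test <- stats::wilcox.test(across, baseline, alternative = "two.sided",
                               exact = FALSE)
    list(across = across, baseline = baseline, test = test)
  })
}
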