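# One full pipeline run at the reference synthetic conditions (100 neurons,
# 6 weeks x 30 trials of 350 bins, default gain clusters), shared by the
# acceptance checks. Problem sizes are scaled for a single-CPU run: rank-20
# TCA, clouds subsampled to <= 6000 points (17 trials, all time bins).

acceptance_bundle <- function() {
  memo("acceptance_bundle", {
    cfg <- list(
      synthetic = synth_params(n_neurons = 100, seed = 20260930),
      tca_rank = 20, tca_restarts = 1, tca_max_iter = 200, tca_tol = 1e-5,
      max_points = 6000, spud_iter = 20, seed = 101)
    run_pipeline(cfg)
  })
}

# match planted episodes to detected ones: a planted episode counts as
# recovered when some detected episode of the same neuron has its peak
# within the planted window widened by `slack` bins
episode_recovery <- function(planted, detected, slack = 2) {
  hit <- logical(nrow(planted))
  err <- rep(NA_real_, nrow(planted))
  for (i in seq_len(nrow(planted))) {
    cand <- detected[detected$neuron == planted$neuron[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    inside <- cand$peak_bin >= planted$start_bin[i] - slack &
      cand$peak_bin < planted$end_bin[i] + slack
    hit[i] <- any(inside)
    # distance of the nearest detected peak to the planted window
    d <- pmax(planted$start_bin[i] - cand$peak_bin,
              cand$peak_bin - (planted$end_bin[i] - 1), 0)
    err[i] <- min(d)
  }
  list(rate = mean(hit), peak_err = err)
}
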