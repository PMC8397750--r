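test_that("binarization thresholds at a multiple of the per-neuron SD about zero", {
  set.seed(1)
  x <- array(0, c(2, 50, 2))
  x[1, , ] <- rnorm(100, 0, 1)
  sigma <- sqrt(mean(x[1, , ]^2))
  x[1, 1, 1] <- 4 * sigma
  x[1, 2, 1] <- 2 * sigma
  b <- binarize_spikes(x, 3)
  # recompute sigma with the new entries, as the implementation sees it
  s2 <- sqrt(mean(x[1, , ]^2))
  expect_identical(b[1, 1, 1], as.integer(4 * sigma > 3 * s2))
  expect_identical(b[1, 2, 1], 0L)
  expect_true(all(b[2, , ] == 0))  # all-zero neuron stays all-zero
  # threshold 0 is the indicator of positive entries
  expect_identical(binarize_spikes(x, 0), array(as.integer(x > 0), dim(x)))
})

test_that("PSTH is the per-bin sum over selected trials and is additive over subsets", {
  sp <- array(0L, c(1, 3, 3))
  sp[1, , 1] <- c(1L, 0L, 0L)
  sp[1, , 2] <- c(0L, 0L, 1L)
  sp[1, , 3] <- c(2L, 1L, 0L)
  expect_equal(compute_psth(sp, 1, 1:2), c(1, 0, 1))
  expect_equal(compute_psth(sp, 1, 3), c(2, 1, 0))
  expect_equal(compute_psth(sp, 1, 1:2) + compute_psth(sp, 1, 3),
               compute_psth(sp, 1))
  expect_error(compute_psth(sp, 1, integer(0)), "empty")
})

test_that("Gaussian smoothing preserves mass and has the exact kernel as impulse response", {
  expect_equal(smooth_psth(rep(5, 100), 0.2, 0.1), rep(5, 100),
               tolerance = 1e-9)
  imp <- c(rep(0, 50), 1, rep(0, 49))
  sm <- smooth_psth(imp, 0.2, 0.1)
  expect_lt(abs(sum(sm) - 1), 0.01)
  expect_equal(which.max(sm), 51)
  # matches the normalized discrete Gaussian (kernel-sum oracle)
  r <- ceiling(4 * 2)
  kern <- dnorm(-r:r, sd = 2); kern <- kern / sum(kern)
  expect_equal(sm[(51 - r):(51 + r)], kern, tolerance = 1e-12)
  # vanishing bandwidth returns the input
  expect_equal(smooth_psth(imp, 1e-9, 0.1), imp)
})

test_that("episode detection finds prominent peaks with Gaussian FWHM duration", {
  expect_equal(nrow(detect_episodes(rep(2, 350))), 0)
  # single Gaussian bump, height 10, SD 3 bins: FWHM ~ 2.355*3 ~ 7 bins
  x <- 10 * dnorm(1:200, 100, 3) / dnorm(0, 0, 3)
  ep <- detect_episodes(x, prominence = 3, dt = 0.1)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$peak_bin, 99)  # 0-based
  width_bins <- ep$end_bin - ep$start_bin
  expect_lte(abs(width_bins - 2.355 * 3), 1)
  # sub-threshold prominence is ignored
  expect_equal(nrow(detect_episodes(x * 0.25, prominence = 3)), 0)
})

test_that("overlapping FWHM intervals merge into one episode from first start to last end", {
  x1 <- 10 * dnorm(1:200, 95, 4) / dnorm(0, 0, 4)
  x2 <- 8 * dnorm(1:200, 105, 4) / dnorm(0, 0, 4)
  both <- x1 + x2
  ep <- detect_episodes(both, prominence = 3, dt = 0.1)
  expect_equal(nrow(ep), 1)
  # covers both bumps
  expect_lte(ep$start_bin, 95)
  expect_gte(ep$end_bin, 105)
  # well-separated bumps stay distinct
  x3 <- 10 * dnorm(1:300, 80, 3) / dnorm(0, 0, 3) +
        10 * dnorm(1:300, 220, 3) / dnorm(0, 0, 3)
  expect_equal(nrow(detect_episodes(x3, prominence = 3)), 2)
})

test_that("episode rates are count/duration in Hz, matching a loop oracle", {
  sp <- array(0L, c(1, 20, 4))
  sp[1, 6:10, 1] <- 1L          # 5 spikes in episode window
  sp[1, 8, 2] <- 1L             # 1 spike
  eps <- data.frame(neuron = 1L, start_bin = 5L, end_bin = 10L,
                    peak_bin = 7L, duration_s = 0.5)
  tab <- episode_rates(sp, eps, week_labels = c(1, 1, 2, 2), dt = 0.1)
  expect_equal(tab$rates[1, ], c(10, 2, 0, 0))  # 1 spike / 0.5 s = 2 Hz
  expect_equal(tab$week_rates[1, ], c(6, 0))
  # loop oracle on a random tensor
  set.seed(3)
  sp2 <- array(rpois(2 * 30 * 6, 0.5), c(2, 30, 6))
  eps2 <- data.frame(neuron = c(1L, 2L), start_bin = c(4L, 10L),
                     end_bin = c(12L, 25L), peak_bin = c(6L, 15L),
                     duration_s = c(0.8, 1.5))
  tab2 <- episode_rates(sp2, eps2, week_labels = rep(1:2, each = 3), dt = 0.1)
  for (i in 1:2) for (k in 1:6) {
    cnt <- sum(sp2[eps2$neuron[i], (eps2$start_bin[i] + 1):eps2$end_bin[i], k])
    expect_identical(tab2$rates[i, k],
                     cnt / ((eps2$end_bin[i] - eps2$start_bin[i]) * 0.1))
  }
})

test_that("episode-rate stability separates stable from permuted week structure", {
  s <- stable_session()
  eps <- detect_all_episodes(s$spikes)
  tab <- episode_rates(s$spikes, eps, s$dff$week_labels)
  st <- episode_rate_stability(tab)
  # stable-gain data: across-week CC within 0.1 of within-week CC
  expect_lt(abs(st$across_week_cc - st$within_week_cc), 0.1)
  # independently permuting episode identity within each week destroys the
  # across-week correlation
  tab_perm <- tab
  set.seed(5)
  for (w in seq_along(tab$weeks)) {
    tab_perm$week_rates[, w] <- tab$week_rates[sample(nrow(tab$week_rates)), w]
  }
  st_perm <- episode_rate_stability(tab_perm)
  expect_lt(abs(st_perm$across_week_cc), st$across_week_cc / 2)
})

test_that("episode-pair similarity is 1 / -1 for identical / opposite week trajectories and ~0 for independent ones", {
  mk_tab <- function(week_rates, neuron) {
    structure(list(rates = NULL, week_rates = week_rates,
                   episodes = data.frame(neuron = neuron,
                                         start_bin = 0L,
                                         end_bin = 5L,
                                         duration_s = 0.5),
                   week_labels = rep(seq_len(ncol(week_rates)), each = 2),
                   weeks = seq_len(ncol(week_rates)), dt = 0.1),
              class = "episode_rate_table")
  }
  wr <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))      # identical up to scale
  expect_equal(episode_pair_similarity(mk_tab(wr, c(1L, 1L))), 1)
  wr2 <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))     # opposite
  expect_equal(episode_pair_similarity(mk_tab(wr2, c(1L, 1L))), -1)
  # many neurons with independent random trajectories: mean ~ 0
  set.seed(8)
  n_neu <- 2000
  wr3 <- matrix(runif(2 * n_neu * 6), 2 * n_neu, 6)
  cc <- episode_pair_similarity(mk_tab(wr3, rep(seq_len(n_neu), each = 2)))
  expect_lt(abs(mean(cc)), 0.02)
})

test_that("controls are seeded and calibrated: Poisson control tracks shared trajectories, week shuffle centers at zero", {
  s <- small_session()
  eps <- detect_all_episodes(s$spikes)
  tab <- episode_rates(s$spikes, eps, s$dff$week_labels)
  pc1 <- poisson_control(tab, seed = 7)
  pc2 <- poisson_control(tab, seed = 7)
  expect_identical(pc1, pc2)
  ws1 <- week_shuffle_control(tab, seed = 7)
  expect_identical(ws1, week_shuffle_control(tab, seed = 7))
  expect_lt(abs(ws1$fit$mean), 0.25)  # small sample; the null centers near 0
  # Gaussian fit agrees with the ML oracle
  expect_equal(pc1$fit$mean, mean(pc1$cc), tolerance = 1e-12)
  expect_equal(pc1$fit$sd, sqrt(mean((pc1$cc - mean(pc1$cc))^2)),
               tolerance = 1e-12)
  # very high rates: shared trajectory dominates noise, CC -> 1
  tab_hi <- tab
  tab_hi$week_rates <- tab$week_rates * 400 + 200
  pc_hi <- poisson_control(tab_hi, seed = 3)
  expect_gt(median(pc_hi$cc), 0.9)
})

test_that("per-week episode timing matches across-week timing on stable data", {
  s <- stable_session()
  eps_all <- detect_all_episodes(s$spikes)
  w1 <- which(s$dff$week_labels == 1)
  eps_w1 <- detect_all_episodes(s$spikes, trials = w1)
  # match per-week episodes to across-week ones by nearest peak
  diffs <- unlist(lapply(seq_len(nrow(eps_w1)), function(i) {
    cand <- eps_all[eps_all$neuron == eps_w1$neuron[i], ]
    if (nrow(cand) == 0) return(NULL)
    j <- which.min(abs(cand$peak_bin - eps_w1$peak_bin[i]))
    (cand$end_bin[j] - cand$start_bin[j]) -
      (eps_w1$end_bin[i] - eps_w1$start_bin[i])
  }))
  expect_lte(median(abs(diffs)), 2)
})
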