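test_that("the data mask zeroes exactly the negative entries", {
  set.seed(1)
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  m <- build_mask(x)
  expect_equal(sum(m == 0), sum(x < 0))
  expect_true(all(m[x < 0] == 0))
  expect_true(all(build_mask(abs(x)) == 1))
  x1 <- abs(x); x1[2, 3, 4] <- -0.1
  expect_equal(which(build_mask(x1) == 0), which(x1 < 0))
})

test_that("a planted rank-1 tensor is recovered to machine precision with monotone objective", {
  pl <- planted_cp(20, 30, 15, 1, seed = 2)
  m <- tca(pl$x, 1, seed = 3, n_restarts = 2, max_iter = 600, tol = 1e-13)
  expect_lt(m$norm_error, 1e-6)
  cosv <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosv(m$W[, 1], pl$W[, 1]), 0.999)
  expect_gt(cosv(m$B[, 1], pl$B[, 1]), 0.999)
  expect_gt(cosv(m$A[, 1], pl$A[, 1]), 0.999)
  # masked objective is non-increasing across iterations
  expect_true(all(diff(m$objective_trace) <= 1e-8 * m$objective_trace[1]))
})

test_that("masked fitting completes exactly-low-rank data at held-out entries", {
  pl <- planted_cp(15, 20, 12, 1, seed = 5)
  set.seed(6)
  mask <- array(as.numeric(runif(length(pl$x)) > 0.2), dim(pl$x))
  m <- tca(pl$x, 1, mask = mask, seed = 7, n_restarts = 2,
           max_iter = 800, tol = 1e-13)
  held <- which(mask == 0)
  xhat <- reconstruct(m)
  rel <- sum((pl$x[held] - xhat[held])^2) / sum(pl$x[held]^2)
  expect_lt(rel, 1e-3)
})

test_that("an all-zero tensor yields zero objective", {
  x <- array(0, c(5, 6, 7))
  m <- tca(x, 1, mask = array(1, dim(x)), seed = 1, n_restarts = 1,
           max_iter = 50)
  expect_lt(m$objective, 1e-10)
  expect_error(tca(x, 1, mask = array(0, dim(x))), "masked")
})

test_that("reconstruction equals the brute-force triple loop and is linear in components", {
  set.seed(8)
  W <- matrix(runif(12), 4, 3); B <- matrix(runif(15), 5, 3)
  A <- matrix(runif(18), 6, 3)
  m <- as_tca_model(W, B, A)
  xhat <- reconstruct(m)
  oracle <- array(0, c(4, 5, 6))
  for (n in 1:4) for (t in 1:5) for (k in 1:6) {
    oracle[n, t, k] <- sum(W[n, ] * B[t, ] * A[k, ])
  }
  expect_equal(xhat, oracle, tolerance = 1e-12)
  # unit basis vectors put a single 1 at (i,j,k)
  e <- function(n, i) { v <- numeric(n); v[i] <- 1; v }
  m1 <- as_tca_model(cbind(e(4, 2)), cbind(e(5, 3)), cbind(e(6, 4)))
  x1 <- reconstruct(m1)
  expect_equal(x1[2, 3, 4], 1)
  expect_equal(sum(x1), 1)
  # additivity over components
  ma <- as_tca_model(W[, 1, drop = FALSE], B[, 1, drop = FALSE],
                     A[, 1, drop = FALSE])
  mb <- as_tca_model(W[, 2, drop = FALSE], B[, 2, drop = FALSE],
                     A[, 2, drop = FALSE])
  mab <- as_tca_model(W[, 1:2], B[, 1:2], A[, 1:2])
  expect_equal(reconstruct(ma) + reconstruct(mb), reconstruct(mab),
               tolerance = 1e-12)
})

test_that("normalized error matches a scalar loop oracle and its boundary values", {
  set.seed(9)
  x <- array(abs(rnorm(3 * 4 * 5)), c(3, 4, 5))
  mask <- array(as.numeric(runif(60) > 0.3), c(3, 4, 5))
  m <- tca(x, 2, mask = mask, seed = 1, n_restarts = 1, max_iter = 100)
  xhat <- reconstruct(m)
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + mask[i] * (x[i] - xhat[i])^2
    den <- den + mask[i] * x[i]^2
  }
  expect_equal(normalized_error(x, m, mask), num / den, tolerance = 1e-12)
  expect_equal(normalized_error(x, x, mask), 0)
  expect_equal(normalized_error(x, array(0, dim(x)), mask), 1)
})

test_that("cross-validation flags the planted rank and train error decreases with R", {
  pl <- planted_cp(15, 25, 12, 3, seed = 10)
  cv <- cross_validate(pl$x, R_list = c(1, 3, 5), mask_frac = 0.5,
                       seed = 4, n_restarts = 1, max_iter = 300, tol = 1e-9)
  expect_lt(cv$test_error[cv$R == 3], cv$test_error[cv$R == 1])
  # nested-model property: checked on noisy data where the noise floor,
  # not optimizer residuals, sets the error scale
  pn <- planted_cp(15, 25, 12, 3, noise = 0.1, seed = 10)
  cvn <- cross_validate(pn$x, R_list = c(1, 2, 3, 4), mask_frac = 0.5,
                        seed = 4, n_restarts = 1, max_iter = 300, tol = 1e-9)
  expect_true(all(diff(cvn$train_error) <= 1e-6))
  # different seeds give different splits but comparable errors
  cv2 <- cross_validate(pl$x, R_list = 3, mask_frac = 0.5, seed = 5,
                        n_restarts = 1, max_iter = 300, tol = 1e-9)
  expect_false(identical(cv$test_error[cv$R == 3], cv2$test_error))
})

test_that("model similarity is 1 under permutation and rescaling, low for unrelated models", {
  set.seed(11)
  W <- matrix(abs(rnorm(300)), 50, 6); B <- matrix(abs(rnorm(360)), 60, 6)
  A <- matrix(abs(rnorm(330)), 55, 6)
  m <- as_tca_model(W, B, A)
  expect_equal(model_similarity(m, m), 1, tolerance = 1e-12)
  perm <- sample(6)
  m2 <- as_tca_model(W[, perm] * 3, B[, perm] * 0.2, A[, perm] * 7)
  expect_equal(model_similarity(m, m2), 1, tolerance = 1e-12)
  sims <- replicate(10, {
    mr <- as_tca_model(matrix(abs(rnorm(300)), 50, 6),
                       matrix(abs(rnorm(360)), 60, 6),
                       matrix(abs(rnorm(330)), 55, 6))
    model_similarity(m, mr)
  })
  expect_lt(max(sims), 0.75)
  expect_lt(mean(sims), 0.6)
})

test_that("hungarian assignment matches brute-force enumeration", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, matrix(setdiff(seq_len(n), i)[p], nrow(p)))
    }))
  }
  set.seed(12)
  for (n in c(2, 4, 6)) {
    S <- matrix(runif(n * n), n)
    pm <- perms(n)
    best <- max(apply(pm, 1, function(p) sum(S[cbind(seq_len(n), p)])))
    expect_equal(ringtime:::hungarian_max(S)$score, best, tolerance = 1e-12)
  }
})

test_that("trial-factor clustering recovers planted groups and orders by time-to-peak", {
  set.seed(13)
  R <- 8; K <- 40
  A <- matrix(0, K, R)
  A[1:20, 1:4] <- abs(rnorm(80, 5))     # group 1 active early trials
  A[21:40, 5:8] <- abs(rnorm(80, 5))    # group 2 active late trials
  B <- matrix(0, 50, R)
  for (r in 1:R) B[(r * 5):(r * 5 + 3), r] <- 1
  m <- as_tca_model(matrix(abs(rnorm(30 * R)), 30, R), B, A)
  cl <- cluster_trial_factors(m, k_clusters = 2, seed = 1)
  # planted two groups recovered exactly (label-invariant check)
  expect_equal(length(unique(cl$cluster[1:4])), 1)
  expect_equal(length(unique(cl$cluster[5:8])), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])
  # within each cluster the ordering is by temporal-factor peak
  for (c in unique(cl$cluster)) {
    idx <- cl$order[cl$cluster[cl$order] == c]
    expect_true(!is.unsorted(cl$time_to_peak[idx]))
  }
  expect_identical(cl$cluster,
                   cluster_trial_factors(m, k_clusters = 2, seed = 1)$cluster)
})

test_that("trial-factor stability separates week-specific from shared structure", {
  K <- 24; R <- 4
  week_labels <- rep(1:2, each = 12)
  # identical trial factors: both averages 1
  A1 <- matrix(rep(c(1, 2, 3, 4), each = K), K, R)
  A1 <- A1 + matrix(rep(runif(R), each = K), K, R)  # constant per column
  m1 <- as_tca_model(matrix(1, 10, R), matrix(1, 10, R),
                     matrix(rep(c(1, 5, 2, 7), K), K, R, byrow = TRUE))
  st1 <- trial_factor_stability(m1, week_labels)
  expect_equal(st1$within_week_cc, 1)
  expect_equal(st1$across_week_cc, 1)
  # orthogonal week-specific patterns: across ~ -1 < within = 1
  A2 <- rbind(matrix(rep(c(1, 0, 1, 0), 12), 12, R, byrow = TRUE),
              matrix(rep(c(0, 1, 0, 1), 12), 12, R, byrow = TRUE))
  m2 <- as_tca_model(matrix(1, 10, R), matrix(1, 10, R), A2)
  st2 <- trial_factor_stability(m2, week_labels)
  expect_equal(st2$within_week_cc, 1)
  expect_lt(st2$across_week_cc, 0)
  # brute-force pair loop oracle
  set.seed(14)
  A3 <- matrix(abs(rnorm(K * R)), K, R)
  m3 <- as_tca_model(matrix(1, 5, R), matrix(1, 5, R), A3)
  st3 <- trial_factor_stability(m3, week_labels)
  wsum <- c(); asum <- c()
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    cc <- cor(A3[i, ], A3[j, ])
    if (week_labels[i] == week_labels[j]) wsum <- c(wsum, cc)
    else asum <- c(asum, cc)
  }
  expect_equal(st3$within_week_cc, mean(wsum), tolerance = 1e-12)
  expect_equal(st3$across_week_cc, mean(asum), tolerance = 1e-12)
})

test_that("factor shuffling preserves per-column value multisets and component energy", {
  set.seed(15)
  m <- as_tca_model(matrix(abs(rnorm(80)), 20, 4),
                    matrix(abs(rnorm(120)), 30, 4),
                    matrix(abs(rnorm(100)), 25, 4))
  s <- shuffle_factors(m, seed = 2)
  for (r in 1:4) {
    expect_equal(sort(s$W[, r]), sort(m$W[, r]))
    expect_equal(sort(s$B[, r]), sort(m$B[, r]))
    expect_equal(sort(s$A[, r]), sort(m$A[, r]))
    e0 <- sum(m$W[, r]^2) * sum(m$B[, r]^2) * sum(m$A[, r]^2)
    e1 <- sum(s$W[, r]^2) * sum(s$B[, r]^2) * sum(s$A[, r]^2)
    expect_equal(e1, e0, tolerance = 1e-12)
  }
  expect_identical(shuffle_factors(m, seed = 2)$W, s$W)
  expect_false(identical(shuffle_factors(m, seed = 3)$B, s$B))
})

test_that("fits are reproducible across seeds on well-posed synthetic data", {
  pl <- planted_cp(25, 30, 20, 3, noise = 0.1, seed = 16)
  m1 <- tca(pl$x, 3, seed = 21, n_restarts = 2, max_iter = 400, tol = 1e-10)
  m2 <- tca(pl$x, 3, seed = 99, n_restarts = 2, max_iter = 400, tol = 1e-10)
  expect_gte(model_similarity(m1, m2), 0.95)
  gt <- as_tca_model(pl$W, pl$B, pl$A)
  expect_gte(model_similarity(m1, gt), 0.9)
})
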