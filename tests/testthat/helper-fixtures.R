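# Shared fixtures, built in code. Small sessions are cached per test run so
# several test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small session: 30 neurons, 4 weeks x 10 trials
small_session <- function() {
  memo("small_session", simulate_session(
    synth_params(n_neurons = 30, n_weeks = 4, trials_per_week = 10,
                 seed = 42)))
}

# session with only stable gain (all-ones template): no drift planted
stable_session <- function() {
  memo("stable_session", simulate_session(
    synth_params(n_neurons = 30, n_weeks = 4, trials_per_week = 10,
                 n_gain_clusters = 1,
                 gain_cluster_profiles = matrix(1, 1, 4),
                 within_week_gain_cv = 0.1, seed = 43)))
}

# session with only fading gain
fading_session <- function() {
  memo("fading_session", simulate_session(
    synth_params(n_neurons = 30, n_weeks = 4, trials_per_week = 10,
                 n_gain_clusters = 1,
                 gain_cluster_profiles = matrix(0.55^(0:3), 1, 4),
                 seed = 44)))
}

# planted nonnegative rank-R tensor with optional noise
planted_cp <- function(N, Tn, K, R, noise = 0, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(N * R, 0.2, 1), N, R)
  B <- matrix(runif(Tn * R, 0.2, 1), Tn, R)
  A <- matrix(runif(K * R, 0.2, 1), K, R)
  x <- array(0, c(N, Tn, K))
  for (r in seq_len(R)) {
    x <- x + outer(outer(W[, r], B[, r]), A[, r])
  }
  if (noise > 0) x <- x + array(abs(rnorm(length(x), 0, noise * sd(x))), dim(x))
  list(x = x, W = W, B = B, A = A)
}

as_tca_model <- function(W, B, A) {
  structure(list(W = W, B = B, A = A, R = ncol(W), objective = NA_real_,
                 norm_error = NA_real_), class = "tca")
}

# noisy circle embedded in high dimensions by a random isometry
planted_ring_cloud <- function(n, ambient_dim = 50, noise = 0.03, seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  X2 <- cbind(cos(th), sin(th)) + matrix(rnorm(2 * n, 0, noise), n)
  Q <- qr.Q(qr(matrix(rnorm(ambient_dim * 2), ambient_dim, 2)))
  list(points = X2 %*% t(Q), theta = th)
}

# Floyd-Warshall all-pairs shortest paths: the independent oracle for
# geodesic distances on small graphs
floyd_warshall <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges[e, 1]; j <- g$edges[e, 2]
    D[i, j] <- D[j, i] <- min(D[i, j], g$weights[e])
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Procrustes residual after optimal rigid alignment (rotation/reflection +
# translation + scale) of configuration A onto B
procrustes_residual <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  R <- s$v %*% t(s$u)
  sc <- sum(s$d) / sum(A^2)
  sum((B - sc * A %*% R)^2) / sum(B^2)
}
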