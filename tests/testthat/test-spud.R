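test_that("train/test split is seeded, disjoint and exhaustive", {
  sp <- split_train_test(100, 0.8, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_train_test(100, 0.8, seed = 1), sp)
  expect_false(identical(split_train_test(100, 0.8, seed = 2)$train, sp$train))
  expect_error(split_train_test(1, 0.5), "degenerate")
})

test_that("knot initialization finds planted cluster centers", {
  set.seed(2)
  centers <- cbind(cos(2 * pi * (1:10) / 10), sin(2 * pi * (1:10) / 10)) * 5
  pts <- centers[rep(1:10, each = 60), ] + matrix(rnorm(1200, 0, 0.1), 600)
  kn <- init_knots(pts, 10, seed = 3)
  d <- ringtime:::cross_dist(kn, centers)
  expect_lt(max(apply(d, 2, min)), 0.1)
  expect_identical(init_knots(pts, 10, seed = 3), kn)
  # single knot is the centroid
  expect_equal(init_knots(pts, 1), matrix(colMeans(pts), 1),
               tolerance = 1e-10)
  expect_error(init_knots(pts[1:5, ], 10), "nrow")
})

test_that("knot connection recovers circular order on a ring and falls back gracefully", {
  set.seed(3)
  th <- runif(3000, 0, 2 * pi)
  pts <- cbind(cos(th), sin(th)) + matrix(rnorm(6000, 0, 0.05), 3000)
  kth <- 2 * pi * (0:9) / 10
  knots <- cbind(cos(kth), sin(kth))
  perm <- sample(10)
  ord <- connect_knots(pts, knots[perm, ])
  # recovered ring order must be the circular order of the true angles
  got <- perm[ord]
  start <- which(got == 1)
  rot <- c(got[start:10], got[seq_len(start - 1)])
  expect_true(all(rot == 1:10) || all(rot == c(1, 10:2)))
  # 3 knots: the unique triangle
  expect_equal(connect_knots(pts, knots[1:3, ]), 1:3)
  # degenerate: no points near any segment -> angular fallback
  far <- matrix(rnorm(40, 100, 0.1), 20, 2)
  expect_message(ordf <- connect_knots(far, knots), "fallback|angular")
  expect_setequal(ordf, 1:10)
})

test_that("knot optimization decreases the distance-times-length objective monotonically", {
  set.seed(4)
  th <- runif(1000, 0, 2 * pi)
  pts <- cbind(cos(th), sin(th)) + matrix(rnorm(2000, 0, 0.05), 1000)
  # imperfect initialization: ring through the data with angular jitter
  set.seed(11)
  kth <- sort(runif(10, 0, 2 * pi))
  init <- ring_curve(cbind(cos(kth), sin(kth)) +
                       matrix(rnorm(20, 0, 0.15), 10))
  opt <- optimize_knots(pts, init, n_iter = 25)
  tr <- attr(opt, "objective_trace")
  expect_true(all(diff(tr) <= 0))
  expect_lt(tr[length(tr)], tr[1])
  # mean point-to-curve distance improves
  d0 <- mean(abs(project_to_curve(pts, init)$offset))
  d1 <- mean(abs(project_to_curve(pts, opt)$offset))
  expect_lt(d1, d0)
  # objective matches a brute-force nearest-segment oracle
  obj <- ringtime:::curve_objective(pts, opt$knots)
  m <- nrow(opt$knots)
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(m)) {
    a <- opt$knots[s, ]; b <- opt$knots[if (s == m) 1 else s + 1, ]
    ab <- b - a
    tt <- pmin(pmax(((sweep(pts, 2, a)) %*% ab) / sum(ab^2), 0), 1)
    dd <- sqrt(rowSums((sweep(pts, 2, a) - outer(as.vector(tt), ab))^2))
    dmin <- pmin(dmin, dd)
  }
  expect_equal(obj, sum(dmin) * opt$total_length, tolerance = 1e-10)
})

test_that("projection assigns exact arc-length coordinates, tangents and signed offsets", {
  # unit square ring: perimeter 4
  kn <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  cv <- ring_curve(kn)
  expect_equal(cv$total_length, 4)
  pr <- project_to_curve(rbind(c(0.5, 0), c(1, 0.5), c(0.25, 0)), cv)
  expect_equal(pr$y, c(0.125, 0.375, 0.0625))
  expect_equal(pr$offset, c(0, 0, 0), tolerance = 1e-12)
  # interior point equidistant from bottom and left segments: lower index wins
  pr2 <- project_to_curve(rbind(c(0.2, 0.2)), cv)
  expect_equal(pr2$segment, 1L)
  expect_equal(pr2$y, 0.05)
  # signed offset flips across the curve
  pr3 <- project_to_curve(rbind(c(0.5, 0.1), c(0.5, -0.1)), cv)
  expect_equal(sort(sign(pr3$offset)), c(-1, 1))
  # dense-sampling oracle for foot points
  set.seed(5)
  pts <- matrix(runif(40, -0.5, 1.5), 20, 2)
  pr4 <- project_to_curve(pts, cv)
  ts <- seq(0, 1, length.out = 10000)
  dense <- rbind(
    cbind(ts, 0), cbind(1, ts), cbind(rev(ts), 1), cbind(0, rev(ts)))
  for (i in 1:20) {
    dd <- sqrt(rowSums(sweep(dense, 2, pts[i, ])^2))
    expect_lt(abs(abs(pr4$offset[i]) - min(dd)), 1e-3)
  }
})

test_that("alignment finds exact shift and flip and matches a finer grid", {
  set.seed(6)
  t01 <- runif(400)
  expect_equal(align_coordinates(t01, t01)$mse, 0)
  a1 <- align_coordinates((t01 + 0.3) %% 1, t01)
  expect_false(a1$flip)
  resid <- (a1$shift + 0.3) %% 1
  expect_lt(min(resid, 1 - resid), 1e-2)
  a2 <- align_coordinates((1 - t01) %% 1, t01)
  expect_true(a2$flip)
  expect_lt(a2$mse, 1e-4)
  # coarse grid result is within one grid step of a finer grid's optimum
  y <- (t01 * 0.98 + 0.123) %% 1
  coarse <- align_coordinates(y, t01, 350)
  fine <- align_coordinates(y, t01, 3500)
  expect_lt(coarse$mse - fine$mse, 1e-4)
})

test_that("decoded time wraps circularly with maximum error period/2", {
  al <- list(shift = 0, flip = FALSE, mse = 0)
  d <- decode_time(c(34 / 35, 0.5), al, true_time_s = c(1, 0), period = 35)
  expect_equal(d$error_s, c(2, 17.5))
  d2 <- decode_time(seq(0, 0.99, 0.01), al,
                    true_time_s = seq(0, 0.99, 0.01) * 35)
  expect_true(all(d2$error_s < 1e-10))
  expect_true(all(decode_time(runif(100), al, runif(100) * 35)$error_s
                  <= 17.5))
})

test_that("error summaries match direct recomputation and the uniform chance level", {
  set.seed(7)
  e <- abs(rnorm(200))
  s <- decoding_error_summary(e, week = rep(1:2, each = 100))
  expect_equal(s$median, median(e))
  expect_equal(s$iqr, IQR(e))
  expect_equal(unname(s$per_week[1]), median(e[1:100]))
  # independent uniform decoded vs true times: mean error ~ period/4
  al <- list(shift = 0, flip = FALSE, mse = 0)
  d <- decode_time(runif(20000), al, runif(20000) * 35)
  expect_lt(abs(mean(d$error_s) - 35 / 4), 0.2)
})

test_that("a noiseless planted ring decodes with near-zero median error in 2 to 5 dimensions", {
  set.seed(8)
  n <- 2000
  th <- runif(n, 0, 2 * pi)
  tb <- pmin(350L, 1L + as.integer(th / (2 * pi) * 350))
  for (d in c(2, 5)) {
    Q <- qr.Q(qr(matrix(rnorm(d * 2), d, 2)))
    coords <- cbind(cos(th), sin(th)) %*% t(Q)
    emb <- list(coords = coords, time_bin = tb,
                trial = rep(1:10, length.out = n), week = rep(1L, n))
    fit <- spud(emb, dims = seq_len(d), seed = 9, n_iter = 25)
    expect_lt(fit$test_summary$median, 0.2)
  }
})

test_that("time-decile knots give a valid initial ring for control data", {
  set.seed(10)
  th <- runif(1500, 0, 2 * pi)
  emb <- structure(list(coords = cbind(cos(th), sin(th)),
                        time_bin = pmin(350L, 1L + as.integer(th / (2 * pi) * 350)),
                        trial = rep(1:5, 300), week = rep(1L, 1500)),
                   class = "embedding")
  kn <- time_average_knots(emb, 10)
  expect_equal(dim(kn), c(10, 2))
  # knots wind around the ring monotonically in time order
  ang <- atan2(kn[, 2], kn[, 1])
  d <- diff(ang) %% (2 * pi)
  expect_true(all(d < pi) || all(d > pi))
  fit <- spud(emb, seed = 1, n_iter = 10, init = kn)
  expect_lt(fit$test_summary$median, 0.5)
})
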