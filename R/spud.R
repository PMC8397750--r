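# Spline parameterization for unsupervised decoding (SPUD): fit a closed
# piecewise-linear curve to the embedded ring manifold, read each point's
# arc-length coordinate in [0, 1), and align it to movie time by a circular
# shift/flip chosen on training data only.

#' Random train/test split of point indices
#'
#' Uniform seeded partition over all points (all weeks pooled).
#'
#' @param n_points number of points.
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with disjoint, exhaustive `train` and `test` index vectors.
#' @export
split_train_test <- function(n_points, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  n_train <- round(n_points * train_frac)
  if (n_train < 1 || n_train >= n_points) stop("degenerate split sizes")
  train <- with_seed(seed, sort(sample.int(n_points, n_train)))
  list(train = train, test = setdiff(seq_len(n_points), train))
}

#' Initial knot positions by K-means
#'
#' Centroids of a seeded K-means run (10 restarts, best inertia kept).
#'
#' @param points training points (P x d matrix).
#' @param n_knots number of knots (default 10).
#' @param seed integer seed.
#' @return n_knots x d matrix of knot positions.
#' @export
init_knots <- function(points, n_knots = 10, seed = 1L) {
  stopifnot(nrow(points) >= n_knots)
  if (n_knots == 1) return(matrix(colMeans(points), 1))
  km <- with_seed(seed, stats::kmeans(points, centers = n_knots,
                                      nstart = 10, iter.max = 100))
  km$centers
}

# squared distance of each point to segment a->b, clamped to the segment
seg_dist2 <- function(points, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(points, 2, a)
  t <- if (len2 == 0) rep(0, nrow(points)) else
    pmin(pmax((rel %*% ab) / len2, 0), 1)
  res <- rel - outer(as.vector(t), ab)
  list(d2 = rowSums(res^2), t = as.vector(t))
}

#' Order knots into a ring by data-point density between them
#'
#' Every knot pair is scored by the density of training points in a tube
#' around the connecting segment (count inside the tube divided by segment
#' length; tube radius = a quarter of the median nearest-other-knot
#' spacing). The
#' ring is the greedy maximum-score Hamiltonian cycle: edges are accepted in
#' decreasing score order unless they would create a degree-3 vertex or
#' close a cycle prematurely. If every tube is empty (degenerate input) the
#' knots are ordered by angle around their centroid.
#'
#' @param points training points (P x d).
#' @param knots knot matrix (m x d), m >= 3.
#' @return integer ring ordering of the knot rows.
#' @export
connect_knots <- function(points, knots) {
  m <- nrow(knots)
  stopifnot(m >= 3)
  if (m == 3) return(1:3)
  kd <- cross_dist(knots, knots)
  diag(kd) <- Inf
  # quarter of the median nearest-knot spacing: wide tubes make chords that
  # skip a knot hug the manifold and outscore adjacent connections
  radius <- stats::median(apply(kd, 1, min)) / 4
  score <- matrix(0, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    sd2 <- seg_dist2(points, knots[i, ], knots[j, ])
    cnt <- sum(sd2$d2 < radius^2 & sd2$t > 0 & sd2$t < 1)
    len <- sqrt(sum((knots[i, ] - knots[j, ])^2))
    score[i, j] <- score[j, i] <- if (len > 0) cnt / len else 0
  }
  if (all(score == 0)) {
    message("connect_knots: empty tubes everywhere; falling back to angular ordering")
    return(angular_order(knots))
  }
  # greedy cycle: best-score edges subject to degree <= 2, no early cycle
  idx <- which(upper.tri(score), arr.ind = TRUE)
  idx <- idx[order(score[idx], decreasing = TRUE), , drop = FALSE]
  deg <- integer(m)
  comp <- seq_len(m)  # union-find by relabeling
  adj <- vector("list", m)
  n_edges <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (deg[i] >= 2 || deg[j] >= 2) next
    closing <- comp[i] == comp[j]
    if (closing && n_edges < m - 1L) next
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    comp[comp == comp[j]] <- comp[i]
    n_edges <- n_edges + 1L
    if (n_edges == m) break
  }
  if (n_edges < m) {
    message("connect_knots: greedy cycle incomplete; falling back to angular ordering")
    return(angular_order(knots))
  }
  ord <- integer(m)
  ord[1] <- 1L
  prev <- 0L
  for (s in 2:m) {
    nxt <- setdiff(adj[[ord[s - 1]]], prev)[1]
    prev <- ord[s - 1]
    ord[s] <- nxt
  }
  ord
}

angular_order <- function(knots) {
  ctr <- colMeans(knots)
  order(atan2(knots[, 2] - ctr[2], knots[, 1] - ctr[1]))
}

#' Construct a closed piecewise-linear ring curve
#'
#' @param knots ordered knot matrix (the last knot connects back to the
#'   first).
#' @return object of class `ring_curve`: `knots`, per-segment `lengths`,
#'   `total_length`, cumulative arc length `cum0` at each knot.
#' @export
ring_curve <- function(knots) {
  knots <- as.matrix(knots)
  stopifnot(nrow(knots) >= 3)
  nxt <- rbind(knots[-1, , drop = FALSE], knots[1, , drop = FALSE])
  lengths <- sqrt(rowSums((nxt - knots)^2))
  total <- sum(lengths)
  if (total <= 0) stop("ring curve has zero total length")
  structure(list(knots = knots, lengths = lengths, total_length = total,
                 cum0 = c(0, cumsum(lengths))[seq_len(nrow(knots))]),
            class = "ring_curve")
}

#' @export
print.ring_curve <- function(x, ...) {
  cat(sprintf("<ring_curve> %d knots in %d-D, total length %.4g\n",
              nrow(x$knots), ncol(x$knots), x$total_length))
  invisible(x)
}

#' @export
coef.ring_curve <- function(object, ...) object$knots

# SPUD objective: (sum of point-to-curve distances) x (total curve length)
curve_objective <- function(points, knots) {
  cv <- ring_curve(knots)
  m <- nrow(knots)
  d2 <- matrix(Inf, nrow(points), m)
  for (s in seq_len(m)) {
    a <- knots[s, ]
    b <- knots[if (s == m) 1 else s + 1, ]
    d2[, s] <- seg_dist2(points, a, b)$d2
  }
  sum(sqrt(apply(d2, 1, min))) * cv$total_length
}

#' Optimize knot positions on the SPUD objective
#'
#' Coordinate descent over knots: for each knot a finite-difference gradient
#' of the objective (sum of Euclidean point-to-curve distances multiplied by
#' the total curve length) is estimated and a backtracking step along its
#' negative is accepted only if the objective decreases, so the objective is
#' non-increasing across accepted steps.
#'
#' @param points training points.
#' @param curve initial [ring_curve()].
#' @param n_iter maximum sweeps over all knots.
#' @param step initial step size as a fraction of the data scale.
#' @param rel_tol stop when a full sweep improves the objective by less than
#'   this relative amount.
#' @return the optimized `ring_curve` with attribute `objective_trace`.
#' @export
optimize_knots <- function(points, curve, n_iter = 30, step = 0.05,
                           rel_tol = 1e-6) {
  stopifnot(inherits(curve, "ring_curve"))
  knots <- curve$knots
  scale <- mean(apply(points, 2, stats::sd))
  h <- 1e-4 * scale
  step0 <- step * scale
  obj <- curve_objective(points, knots)
  trace <- obj
  for (it in seq_len(n_iter)) {
    obj_start <- obj
    for (ki in seq_len(nrow(knots))) {
      g <- numeric(ncol(knots))
      for (c in seq_len(ncol(knots))) {
        kp <- knots; kp[ki, c] <- kp[ki, c] + h
        km <- knots; km[ki, c] <- km[ki, c] - h
        g[c] <- (curve_objective(points, kp) -
                 curve_objective(points, km)) / (2 * h)
      }
      gn <- sqrt(sum(g^2))
      if (gn == 0) next
      s <- step0
      for (bt in 1:6) {
        kp <- knots
        kp[ki, ] <- kp[ki, ] - s * g / gn
        new_obj <- curve_objective(points, kp)
        if (new_obj < obj) {
          knots <- kp; obj <- new_obj
          break
        }
        s <- s / 2
      }
    }
    trace <- c(trace, obj)
    if (obj_start - obj < rel_tol * obj_start) break
  }
  out <- ring_curve(knots)
  attr(out, "objective_trace") <- trace
  out
}

#' Project points onto a ring curve
#'
#' Each point is assigned its nearest point on the curve (ties resolved in
#' favor of the lower segment index), the arc-length coordinate
#' `y in [0, 1)` of that foot point, the unit tangent of the segment, and
#' the perpendicular offset (signed by the 2-D cross product when the
#' embedding is two-dimensional, unsigned otherwise).
#'
#' @param points P x d matrix.
#' @param curve a [ring_curve()].
#' @return list with `y`, `foot` (P x d), `tangent` (P x d), `offset`,
#'   `segment`.
#' @export
project_to_curve <- function(points, curve) {
  stopifnot(inherits(curve, "ring_curve"))
  m <- nrow(curve$knots)
  P <- nrow(points)
  d2 <- matrix(Inf, P, m)
  tt <- matrix(0, P, m)
  for (s in seq_len(m)) {
    a <- curve$knots[s, ]
    b <- curve$knots[if (s == m) 1 else s + 1, ]
    sd2 <- seg_dist2(points, a, b)
    d2[, s] <- sd2$d2
    tt[, s] <- sd2$t
  }
  seg <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  tsel <- tt[cbind(seq_len(P), seg)]
  y <- (curve$cum0[seg] + tsel * curve$lengths[seg]) / curve$total_length
  y <- y %% 1
  a <- curve$knots[seg, , drop = FALSE]
  b <- curve$knots[ifelse(seg == m, 1L, seg + 1L), , drop = FALSE]
  tangent <- (b - a) / pmax(curve$lengths[seg], 1e-300)
  foot <- a + tangent * (tsel * curve$lengths[seg])
  resid <- points - foot
  offset <- sqrt(rowSums(resid^2))
  if (ncol(points) == 2) {
    sgn <- sign(tangent[, 1] * resid[, 2] - tangent[, 2] * resid[, 1])
    offset <- offset * ifelse(sgn == 0, 1, sgn)
  }
  list(y = y, foot = foot, tangent = tangent, offset = offset, segment = seg)
}

#' Align arc-length coordinates to rescaled time
#'
#' Grid search over circular shifts (and a flip) minimizing the mean squared
#' circular difference `d(a,b) = min(|a-b|, 1-|a-b|)` between the shifted
#' coordinates and the rescaled actual time on the unit circle.
#'
#' @param y arc-length coordinates in \[0, 1).
#' @param t01 rescaled actual times in \[0, 1).
#' @param n_shift_grid number of candidate shifts (default 350, the number
#'   of time bins per trial — finer shifts cannot be resolved by the data).
#' @return list with `shift`, `flip`, and the minimized `mse`.
#' @export
align_coordinates <- function(y, t01, n_shift_grid = 350L) {
  stopifnot(length(y) == length(t01))
  shifts <- (seq_len(n_shift_grid) - 1) / n_shift_grid
  best <- list(shift = 0, flip = FALSE, mse = Inf)
  for (flip in c(FALSE, TRUE)) {
    yy <- if (flip) (1 - y) %% 1 else y
    for (s in shifts) {
      mse <- mean(circ_diff01((yy + s) %% 1, t01)^2)
      if (mse < best$mse) best <- list(shift = s, flip = flip, mse = mse)
    }
  }
  best
}

apply_alignment <- function(y, alignment) {
  yy <- if (alignment$flip) (1 - y) %% 1 else y
  (yy + alignment$shift) %% 1
}

#' Decode movie time from aligned coordinates
#'
#' `alpha = aligned coordinate x period`; the per-point error is the
#' absolute circular difference `min(|t - alpha|, period - |t - alpha|)`.
#'
#' @param y arc-length coordinates.
#' @param alignment an [align_coordinates()] result (fit on training data).
#' @param true_time_s actual times in seconds.
#' @param period trial period in seconds (default 35).
#' @return data frame with `alpha`, `true_time_s`, `error_s`.
#' @export
decode_time <- function(y, alignment, true_time_s, period = 35) {
  alpha <- apply_alignment(y, alignment) * period
  d <- abs((true_time_s - alpha) %% period)
  err <- pmin(d, period - d)
  data.frame(alpha = alpha, true_time_s = true_time_s, error_s = err)
}

#' Summarize decoding errors
#'
#' @param errors numeric vector of per-point circular errors (seconds).
#' @param week optional per-point week labels for a per-week breakdown.
#' @return list with `median`, `iqr`, `mean`, and optionally `per_week`.
#' @export
decoding_error_summary <- function(errors, week = NULL) {
  stopifnot(length(errors) > 0)
  out <- list(median = stats::median(errors),
              iqr = stats::IQR(errors), mean = mean(errors))
  if (!is.null(week)) {
    out$per_week <- vapply(sort(unique(week)), function(w) {
      stats::median(errors[week == w])
    }, numeric(1))
    names(out$per_week) <- paste0("week", sort(unique(week)))
  }
  out
}

#' Fit the SPUD ring model to an embedding
#'
#' End-to-end unsupervised decoder: train/test split, K-means knot
#' initialization, density-based ring ordering, knot optimization on the
#' (sum of distances) x (curve length) objective, projection of training
#' points, and shift/flip alignment of the training coordinates to movie
#' time. The only supervision is the final alignment, which fixes the
#' arbitrary origin and orientation of the ring.
#'
#' @param embedding an [isomap()] embedding with time labels, or a plain
#'   coordinate matrix plus `time_bin`.
#' @param n_knots number of knots (default 10).
#' @param dims embedding dimensions used (default first 2).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @param n_iter knot-optimization sweeps.
#' @param period trial period in seconds.
#' @param n_time_bins bins per trial (alignment grid resolution).
#' @param train_idx,test_idx optional explicit split (overrides
#'   `train_frac`), e.g. train on week-1 odd trials only.
#' @param init optional initial knot matrix (overrides K-means; used for
#'   shuffled-data controls where K-means initialization fails).
#' @return object of class `spud`: the fitted `curve`, `alignment`, split
#'   indices, train/test [decode_time()] tables and error summaries.
#' @export
spud <- function(embedding, n_knots = 10, dims = 1:2, train_frac = 0.8,
                 seed = 1L, n_iter = 30, period = 35, n_time_bins = 350L,
                 train_idx = NULL, test_idx = NULL, init = NULL) {
  if (inherits(embedding, "embedding")) {
    coords <- embedding$coords
    time_bin <- embedding$time_bin
    week <- embedding$week
  } else {
    coords <- embedding$coords
    time_bin <- embedding$time_bin
    week <- embedding$week
  }
  stopifnot(!is.null(time_bin), ncol(coords) >= max(dims))
  X <- coords[, dims, drop = FALSE]
  if (is.null(train_idx)) {
    sp <- split_train_test(nrow(X), train_frac, seed)
    train_idx <- sp$train; test_idx <- sp$test
  } else if (is.null(test_idx)) {
    test_idx <- setdiff(seq_len(nrow(X)), train_idx)
  }
  Xtr <- X[train_idx, , drop = FALSE]
  knots <- if (is.null(init)) {
    k0 <- init_knots(Xtr, n_knots, seed)
    k0[connect_knots(Xtr, k0), , drop = FALSE]
  } else as.matrix(init)
  curve <- optimize_knots(Xtr, ring_curve(knots), n_iter = n_iter)
  # alignment on training data only
  t01 <- (time_bin - 1) / n_time_bins
  proj_tr <- project_to_curve(Xtr, curve)
  alignment <- align_coordinates(proj_tr$y, t01[train_idx], n_time_bins)
  dt <- period / n_time_bins
  train_dec <- decode_time(proj_tr$y, alignment,
                           (time_bin[train_idx] - 1) * dt, period)
  proj_te <- project_to_curve(X[test_idx, , drop = FALSE], curve)
  test_dec <- decode_time(proj_te$y, alignment,
                          (time_bin[test_idx] - 1) * dt, period)
  structure(list(
    curve = curve, alignment = alignment, dims = dims, period = period,
    train_idx = train_idx, test_idx = test_idx,
    train = train_dec, test = test_dec,
    train_summary = decoding_error_summary(train_dec$error_s,
                                           week[train_idx]),
    test_summary = decoding_error_summary(test_dec$error_s,
                                          week[test_idx]),
    projection_train = proj_tr, projection_test = proj_te),
    class = "spud")
}

#' @export
print.spud <- function(x, ...) {
  cat(sprintf("<spud> %d-knot ring in dims [%s]; median test decoding error %.3g s (chance mean %.3g s)\n",
              nrow(x$curve$knots), paste(x$dims, collapse = ","),
              x$test_summary$median, x$period / 4))
  invisible(x)
}

#' @export
coef.spud <- function(object, ...) object$curve$knots

#' @export
predict.spud <- function(object, newdata, time_bin = NULL, ...) {
  proj <- project_to_curve(as.matrix(newdata)[, seq_along(object$dims),
                                              drop = FALSE], object$curve)
  alpha <- apply_alignment(proj$y, object$alignment) * object$period
  if (is.null(time_bin)) return(alpha)
  dt <- object$period / 350
  decode_time(proj$y, object$alignment, (time_bin - 1) * dt, object$period)
}

#' Evenly time-distributed initial knots for shuffled-data controls
#'
#' Trial-averaged embedded activity at `n_knots` time deciles; used instead
#' of K-means initialization when the control manifold lacks a clean ring.
#'
#' @param embedding an [isomap()] embedding with time labels.
#' @param n_knots number of knots.
#' @param dims dimensions used.
#' @return knot matrix in time order.
#' @export
time_average_knots <- function(embedding, n_knots = 10, dims = 1:2) {
  tb <- embedding$time_bin
  breaks <- stats::quantile(tb, probs = seq(0, 1, length.out = n_knots + 1))
  grp <- cut(tb, unique(breaks), include.lowest = TRUE, labels = FALSE)
  X <- embedding$coords[, dims, drop = FALSE]
  t(vapply(seq_len(max(grp)), function(g) colMeans(X[grp == g, , drop = FALSE]),
           numeric(length(dims))))
}
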