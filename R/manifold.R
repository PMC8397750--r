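# Isomap embedding of population activity: k-nearest-neighbor graph on the
# point cloud of instantaneous population vectors, graph shortest-path
# (geodesic) distances, classical MDS on the double-centred squared
# geodesic distances.

#' Flatten a tensor into a labelled point cloud
#'
#' Each (time, trial) column of the N-neuron tensor becomes one point in
#' N-dimensional state space; the time/trial/week association is kept as
#' labels but ignored during embedding.
#'
#' @param x numeric array N x T x K or [dff_tensor()].
#' @param week_labels per-trial week index (taken from the tensor if a
#'   `dff_tensor` is given).
#' @return object of class `point_cloud`: `points` (P x N matrix with
#'   P = T*K), `time_bin` (1-based), `trial`, `week`.
#' @export
tensor_to_points <- function(x, week_labels = NULL) {
  if (inherits(x, "dff_tensor")) {
    if (is.null(week_labels)) week_labels <- x$week_labels
    x <- x$values
  }
  d <- dim(x)
  stopifnot(length(d) == 3, all(is.finite(x)))
  if (is.null(week_labels)) week_labels <- rep(1L, d[3])
  pts <- t(unfold3(x, 1))  # P x N, rows ordered time-within-trial fastest
  structure(list(
    points = pts,
    time_bin = rep(seq_len(d[2]), times = d[3]),
    trial = rep(seq_len(d[3]), each = d[2]),
    week = rep(as.integer(week_labels), each = d[2])),
    class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Subsample a point cloud uniformly over trials
#'
#' Keeps a seeded random subset of whole trials (stratified by week, at
#' least two per week) with all their time bins, so that the within-trial
#' temporal continuity that carries the ring structure — and every per-bin,
#' per-trial statistic — survives subsampling when the full cloud is too
#' large for all-pairs geodesic computation.
#'
#' @param cloud a [tensor_to_points()] cloud.
#' @param max_points ceiling on the number of points kept.
#' @param seed integer seed.
#' @return the subsampled `point_cloud`, with kept indices in `$index`.
#' @export
subsample_cloud <- function(cloud, max_points = 10000, seed = 1L) {
  P <- nrow(cloud$points)
  if (P <= max_points) {
    cloud$index <- seq_len(P)
    return(cloud)
  }
  bins_per_trial <- max(cloud$time_bin)
  weeks <- sort(unique(cloud$week))
  n_keep <- max(length(weeks) * 2L, floor(max_points / bins_per_trial))
  per_week <- max(2L, floor(n_keep / length(weeks)))
  keep_trials <- with_seed(seed, {
    unlist(lapply(weeks, function(w) {
      tr <- unique(cloud$trial[cloud$week == w])
      sort(sample(tr, min(per_week, length(tr))))
    }))
  })
  idx <- which(cloud$trial %in% keep_trials)
  structure(list(points = cloud$points[idx, , drop = FALSE],
                 time_bin = cloud$time_bin[idx],
                 trial = cloud$trial[idx],
                 week = cloud$week[idx],
                 index = idx), class = "point_cloud")
}

# Euclidean distances between rows of a and rows of b, computed blockwise.
cross_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' k-nearest-neighbor graph of a point cloud
#'
#' Directed k-NN by Euclidean distance (ties broken by lower point index),
#' symmetrized by edge union; edge weights are the Euclidean lengths.
#'
#' @param cloud a `point_cloud` (or plain matrix of points).
#' @param k neighbors per point (default 20).
#' @param block rows per distance block (memory control).
#' @return object of class `neighbor_graph`: `edges` (2-column matrix,
#'   i < j), `weights`, `k`, `n`.
#' @export
knn_graph <- function(cloud, k = 20, block = 1000L) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  P <- nrow(pts)
  stopifnot(P > k)
  ei <- vector("list", ceiling(P / block))
  bi <- 0L
  for (s in seq(1L, P, by = block)) {
    e <- min(P, s + block - 1L)
    D <- cross_dist(pts[s:e, , drop = FALSE], pts)
    rows <- s:e
    nb <- t(vapply(seq_along(rows), function(r) {
      d <- D[r, ]
      d[rows[r]] <- Inf  # exclude self
      order(d, seq_len(P))[seq_len(k)]  # ties -> lower index
    }, integer(k)))
    bi <- bi + 1L
    ei[[bi]] <- cbind(rep(rows, each = k), as.vector(t(nb)),
                      as.vector(t(D[cbind(rep(seq_along(rows), each = k),
                                          as.vector(t(nb)))])))
  }
  ed <- do.call(rbind, ei)
  # symmetrize by union: undirected edge i < j, deduplicated
  i <- pmin(ed[, 1], ed[, 2]); j <- pmax(ed[, 1], ed[, 2])
  key <- (i - 1) * P + j
  keep <- !duplicated(key)
  if (any(ed[keep, 3] == 0)) {
    message(sprintf("knn_graph: %d zero-length edge(s) from duplicate points",
                    sum(ed[keep, 3] == 0)))
  }
  structure(list(edges = cbind(i = i[keep], j = j[keep]),
                 weights = ed[keep, 3], k = k, n = P),
            class = "neighbor_graph")
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  ig <- igraph::add_edges(ig, t(g$edges))
  igraph::E(ig)$weight <- g$weights
  ig
}

#' Geodesic (graph shortest-path) distance matrix
#'
#' All-pairs shortest-path lengths along the weighted neighbor graph
#' (Dijkstra per source); `Inf` marks disconnected pairs.
#'
#' @param g a [knn_graph()] result.
#' @return symmetric numeric matrix.
#' @export
geodesic_distances <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  igraph::distances(as_igraph(g), algorithm = "dijkstra")
}

# Top-d eigenpairs of a dense symmetric matrix by shifted subspace
# iteration (shift by ||B||_F makes the largest algebraic eigenvalues the
# largest in magnitude). Exact eigen() is used for small problems.
top_eigen_sym <- function(Bm, d, n_iter = 200, n_guard = 7, tol = 1e-10) {
  n <- nrow(Bm)
  if (n <= 1500) {
    e <- eigen(Bm, symmetric = TRUE)
    return(list(values = e$values[seq_len(min(d, n))],
                vectors = e$vectors[, seq_len(min(d, n)), drop = FALSE]))
  }
  m <- min(n, d + n_guard)
  shift <- sqrt(sum(Bm^2))
  set.seed(171L)  # fixed internal seed: deterministic subspace start
  X <- qr.Q(qr(matrix(stats::rnorm(n * m), n, m)))
  prev <- rep(Inf, m)
  for (it in seq_len(n_iter)) {
    X <- Bm %*% X + shift * X
    X <- qr.Q(qr(X))
    if (it %% 10 == 0) {
      h <- crossprod(X, Bm %*% X)
      ev <- eigen((h + t(h)) / 2, symmetric = TRUE)$values
      if (max(abs(ev - prev)) < tol * max(abs(ev), 1)) break
      prev <- ev
    }
  }
  h <- crossprod(X, Bm %*% X)
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  list(values = e$values[seq_len(d)],
       vectors = (X %*% e$vectors)[, seq_len(d), drop = FALSE])
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centres the squared distances, takes the top-d eigenpairs with
#' positive eigenvalues, and returns coordinates scaled by the square root
#' of the eigenvalues. The sign of each dimension is fixed by making its
#' first nonzero loading positive.
#'
#' @param D symmetric finite distance matrix.
#' @param d requested embedding dimension.
#' @return object of class `mds_embedding`: `coords` (P x d'),
#'   `eigenvalues` (length d'); d' < d (with a warning) if fewer positive
#'   eigenvalues exist.
#' @export
classical_mds <- function(D, d = 2) {
  stopifnot(is.matrix(D), all(is.finite(D)), nrow(D) == ncol(D))
  n <- nrow(D)
  D2 <- D^2
  # double-centring without forming J explicitly
  rm_ <- rowMeans(D2); gm <- mean(D2)
  Bm <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- top_eigen_sym(Bm, d)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
  if (length(pos) < d) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    length(pos), length(pos)))
  }
  pos <- pos[seq_len(min(d, length(pos)))]
  coords <- sweep(e$vectors[, pos, drop = FALSE], 2,
                  sqrt(e$values[pos]), "*")
  for (c in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, c]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], c] < 0) coords[, c] <- -coords[, c]
  }
  structure(list(coords = coords, eigenvalues = e$values[pos]),
            class = "mds_embedding")
}

#' Isomap embedding of a point cloud
#'
#' k-NN graph, geodesic distances, classical MDS — restricted to the
#' largest connected component of the graph; excluded points are reported
#' in `$excluded`.
#'
#' @param cloud a `point_cloud` (or matrix).
#' @param k neighbors (20 by default; 100 is used for shuffled-control data,
#'   whose intrinsic dimensionality is higher).
#' @param d embedding dimension.
#' @return object of class `embedding`: `coords`, `eigenvalues`, point
#'   labels (`time_bin`, `trial`, `week`) for the kept points, `kept`,
#'   `excluded`, `k`, `d`.
#' @export
isomap <- function(cloud, k = 20, d = 2) {
  is_pc <- inherits(cloud, "point_cloud")
  pts <- if (is_pc) cloud$points else as.matrix(cloud)
  g <- knn_graph(pts, k = k)
  comp <- igraph::components(as_igraph(g))
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < g$n) {
    message(sprintf("isomap: %d point(s) outside the largest graph component excluded",
                    g$n - length(keep)))
    g2 <- knn_graph(pts[keep, , drop = FALSE], k = k)
  } else {
    g2 <- g
  }
  Dg <- geodesic_distances(g2)
  emb <- classical_mds(Dg, d)
  structure(list(
    coords = emb$coords, eigenvalues = emb$eigenvalues,
    time_bin = if (is_pc) cloud$time_bin[keep] else NULL,
    trial = if (is_pc) cloud$trial[keep] else NULL,
    week = if (is_pc) cloud$week[keep] else NULL,
    kept = keep, excluded = setdiff(seq_len(nrow(pts)), keep),
    k = k, d = d), class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d points in %d Isomap dimensions (k = %d)\n",
              nrow(x$coords), ncol(x$coords), x$k))
  if (length(x$excluded)) {
    cat(sprintf("  %d point(s) excluded (disconnected)\n", length(x$excluded)))
  }
  invisible(x)
}

#' @export
plot.embedding <- function(x, color_by = c("time", "week"), ...) {
  color_by <- match.arg(color_by)
  lab <- if (color_by == "time") x$time_bin else x$week
  cols <- grDevices::hcl.colors(max(lab), "viridis")[lab]
  graphics::plot(x$coords[, 1], x$coords[, 2], col = cols, pch = 16,
                 cex = 0.4, xlab = "Isomap dim 1", ylab = "Isomap dim 2", ...)
  invisible(x)
}

#' Circularly shift every (neuron, trial) trace by a random amount
#'
#' The shuffle preserves each single-trial trace's value multiset and
#' autocorrelation but destroys the across-neuron temporal coordination;
#' used as the control that collapses the ring structure.
#'
#' @param x numeric array N x T x K or [dff_tensor()].
#' @param seed integer seed.
#' @return an object of the same type as the input.
#' @export
circular_shuffle <- function(x, seed = 1L) {
  is_dff <- inherits(x, "dff_tensor")
  v <- if (is_dff) x$values else x
  d <- dim(v)
  out <- v
  with_seed(seed, {
    shifts <- matrix(sample.int(d[2], d[1] * d[3], replace = TRUE) - 1L,
                     d[1], d[3])
    for (k in seq_len(d[3])) {
      for (n in seq_len(d[1])) {
        s <- shifts[n, k]
        if (s > 0) out[n, , k] <- c(v[n, (s + 1):d[2], k], v[n, 1:s, k])
      }
    }
  })
  if (is_dff) dff_tensor(out, x$week_labels, x$dt, x$movie_start_bin) else out
}

#' Across-trial stability of embedded trajectories
#'
#' Per embedding dimension: the per-trial time courses of the coordinate
#' are correlated for every unordered trial pair (pairwise-complete time
#' bins when the cloud was subsampled), then averaged.
#'
#' @param e an [isomap()] embedding with time/trial labels.
#' @param min_overlap minimum shared time bins for a trial pair to count.
#' @return numeric vector of mean CCs, one per dimension.
#' @export
trajectory_stability <- function(e, min_overlap = 10L) {
  stopifnot(inherits(e, "embedding"), !is.null(e$trial))
  trials <- sort(unique(e$trial))
  stopifnot(length(trials) >= 2)
  Tmax <- max(e$time_bin)
  vapply(seq_len(ncol(e$coords)), function(dd) {
    M <- matrix(NA_real_, Tmax, length(trials))
    M[cbind(e$time_bin, match(e$trial, trials))] <- e$coords[, dd]
    cc <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
    novl <- crossprod(!is.na(M))
    cc[novl < min_overlap] <- NA
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }, numeric(1))
}
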