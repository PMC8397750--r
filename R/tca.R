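# Nonnegative tensor component analysis (CP decomposition) with missing-data
# masking, fit by masked multiplicative updates. The model approximates a
# DeltaF/F tensor x[n,t,k] by sum_r W[n,r] B[t,r] A[k,r] with all factors
# nonnegative, minimizing || M * (x - xhat) ||_F^2 over unmasked entries.

#' Mask negative DeltaF/F entries
#'
#' Builds the missing-data mask used for nonnegative fitting: mask = 0
#' exactly where the value is negative, 1 elsewhere.
#'
#' @param x a [dff_tensor()] or numeric 3-way array.
#' @return 0/1 array of the same shape.
#' @export
build_mask <- function(x) {
  v <- if (inherits(x, "dff_tensor")) x$values else x
  array(as.numeric(v >= 0), dim(v))
}

# xhat as mode-1 unfolded matrix, then reshaped
cp_reconstruct <- function(W, B, A) {
  d <- c(nrow(W), nrow(B), nrow(A))
  out <- W %*% t(khatri_rao(A, B))
  dim(out) <- d
  out
}

#' Fit a masked nonnegative tensor decomposition
#'
#' Factors are initialized as `|N(0,1)|` draws (seeded) and iterated with
#' masked multiplicative updates, which keep factors nonnegative and make
#' the masked squared error non-increasing. Several random restarts are run
#' and the best final objective is kept.
#'
#' @param x numeric 3-way array (neurons x time x trials) or [dff_tensor()].
#' @param R number of components.
#' @param mask optional 0/1 array; defaults to [build_mask()] of `x`.
#' @param seed integer seed (restart r uses a seed derived from it).
#' @param n_restarts random restarts (default 3).
#' @param max_iter maximum update sweeps per restart.
#' @param tol stop when the relative objective decrease falls below this.
#' @param eps small constant guarding denominators.
#' @param init optional list with factor matrices `W`, `B`, `A` used as one
#'   additional (warm-start) initialization candidate.
#' @return object of class `tca`: factor matrices `W` (N x R), `B` (T x R),
#'   `A` (K x R), the final `objective`, `norm_error`, per-iteration
#'   `objective_trace`, and a `converged` flag.
#' @export
tca <- function(x, R, mask = NULL, seed = 1L, n_restarts = 3,
                max_iter = 500, tol = 1e-6, eps = 1e-9, init = NULL) {
  v <- if (inherits(x, "dff_tensor")) x$values else x
  stopifnot(length(dim(v)) == 3, R >= 1)
  if (is.null(mask)) mask <- build_mask(v)
  stopifnot(identical(dim(mask), dim(v)))
  if (sum(mask) == 0) stop("all entries masked; nothing to fit")
  v[mask == 0] <- 0  # masked-out entries never touched by the objective
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tca_fit_once(v, mask, R, derive_seed(seed, r - 1L),
                        max_iter, tol, eps)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!is.null(init)) {
    fit <- tca_fit_once(v, mask, R, derive_seed(seed, 999L),
                        max_iter, tol, eps, init = init)
    if (fit$objective < best$objective) best <- fit
  }
  denom <- sum((mask * v)^2)
  best$norm_error <- if (denom > 0) best$objective / denom else NA_real_
  best$R <- R
  best$seed <- seed
  class(best) <- "tca"
  best
}

tca_fit_once <- function(v, mask, R, seed, max_iter, tol, eps, init = NULL) {
  d <- dim(v)
  if (is.null(init)) {
    with_seed(seed, {
      W <- matrix(abs(stats::rnorm(d[1] * R)), d[1], R)
      B <- matrix(abs(stats::rnorm(d[2] * R)), d[2], R)
      A <- matrix(abs(stats::rnorm(d[3] * R)), d[3], R)
    })
  } else {
    stopifnot(ncol(init$W) == R, nrow(init$W) == d[1],
              nrow(init$B) == d[2], nrow(init$A) == d[3])
    W <- init$W; B <- init$B; A <- init$A
  }
  mv1 <- unfold3(mask * v, 1)
  mv2 <- unfold3(mask * v, 2)
  mv3 <- unfold3(mask * v, 3)
  objective <- function(xhat) sum((mask * (v - xhat))^2)
  xhat <- cp_reconstruct(W, B, A)
  obj <- objective(xhat)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # mode 1
    Z <- khatri_rao(A, B)
    mh <- unfold3(mask * xhat, 1)
    W <- W * (mv1 %*% Z) / (mh %*% Z + eps)
    xhat <- cp_reconstruct(W, B, A)
    # mode 2
    Z <- khatri_rao(A, W)
    mh <- unfold3(mask * xhat, 2)
    B <- B * (mv2 %*% Z) / (mh %*% Z + eps)
    xhat <- cp_reconstruct(W, B, A)
    # mode 3
    Z <- khatri_rao(B, W)
    mh <- unfold3(mask * xhat, 3)
    A <- A * (mv3 %*% Z) / (mh %*% Z + eps)
    xhat <- cp_reconstruct(W, B, A)
    new_obj <- objective(xhat)
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol * max(obj, .Machine$double.eps)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  list(W = W, B = B, A = A, objective = obj, objective_trace = trace,
       converged = converged, n_iter = length(trace) - 1L)
}

#' @export
print.tca <- function(x, ...) {
  cat(sprintf("<tca> R = %d components, %d x %d x %d tensor\n",
              x$R, nrow(x$W), nrow(x$B), nrow(x$A)))
  cat(sprintf("  objective %.6g (normalized error %.4g, %d iterations%s)\n",
              x$objective, x$norm_error, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @export
summary.tca <- function(object, ...) {
  energy <- vapply(seq_len(object$R), function(r) {
    sum(object$W[, r]^2) * sum(object$B[, r]^2) * sum(object$A[, r]^2)
  }, numeric(1))
  out <- list(R = object$R, norm_error = object$norm_error,
              component_energy = sqrt(energy), converged = object$converged)
  class(out) <- "summary.tca"
  out
}

#' @export
print.summary.tca <- function(x, ...) {
  cat(sprintf("Masked nonnegative TCA, R = %d (normalized error %.4g)\n",
              x$R, x$norm_error))
  cat("component root energies:\n")
  print(signif(sort(x$component_energy, decreasing = TRUE), 3))
  invisible(x)
}

#' Reconstruct the low-rank tensor from a fitted model
#'
#' `xhat[n,t,k] = sum_r W[n,r] B[t,r] A[k,r]`; nonnegative by construction.
#'
#' @param m a [tca()] model.
#' @return numeric array N x T x K.
#' @export
reconstruct <- function(m) {
  stopifnot(inherits(m, "tca"))
  cp_reconstruct(m$W, m$B, m$A)
}

#' @export
fitted.tca <- function(object, ...) reconstruct(object)

#' Normalized masked reconstruction error
#'
#' `||M * (x - xhat)||_F^2 / ||M * x||_F^2`.
#'
#' @param x data array or [dff_tensor()].
#' @param m a [tca()] model (or a reconstruction array).
#' @param mask 0/1 array; defaults to [build_mask()] of `x`.
#' @return scalar normalized error.
#' @export
normalized_error <- function(x, m, mask = NULL) {
  v <- if (inherits(x, "dff_tensor")) x$values else x
  if (is.null(mask)) mask <- build_mask(v)
  xhat <- if (inherits(m, "tca")) reconstruct(m) else m
  denom <- sum((mask * v)^2)
  if (denom == 0) stop("zero-norm data under mask")
  sum((mask * (v - xhat))^2) / denom
}

#' Cross-validated rank selection by random entry holdout
#'
#' Randomly masks out `mask_frac` of the (data-unmasked) entries as a test
#' set, fits the model on the remainder for each candidate rank, and reports
#' normalized train and test errors. A rank overfits when the test error
#' turns upward.
#'
#' @param x data array or [dff_tensor()].
#' @param R_list candidate ranks.
#' @param mask optional data mask.
#' @param mask_frac held-out fraction (default 0.5).
#' @param seed integer seed for the holdout and the fits.
#' @param ... passed to [tca()].
#' @return data frame with columns `R`, `train_error`, `test_error`.
#' @export
cross_validate <- function(x, R_list, mask = NULL, mask_frac = 0.5,
                           seed = 1L, ...) {
  stopifnot(length(R_list) >= 1, mask_frac > 0, mask_frac < 1)
  v <- if (inherits(x, "dff_tensor")) x$values else x
  if (is.null(mask)) mask <- build_mask(v)
  d <- dim(v)
  for (attempt in 1:20) {
    hold <- with_seed(derive_seed(seed, 100L + attempt), {
      array(stats::runif(length(v)) < mask_frac, d)
    })
    train_mask <- mask * !hold
    test_mask <- mask * hold
    ok <- all(apply(train_mask, 1, sum) > 0) &&
      all(apply(train_mask, 2, sum) > 0) &&
      all(apply(train_mask, 3, sum) > 0)
    if (ok) break
    if (attempt == 20) stop("could not draw a holdout without empty fibers")
    warning("holdout left an empty fiber; resampling")
  }
  # ascending ranks are warm-started from the previous fit (padded with
  # small random columns), so the train error is non-increasing in R by
  # construction of the monotone optimizer
  R_sorted <- sort(R_list)
  res <- vector("list", length(R_sorted))
  prev <- NULL
  for (i in seq_along(R_sorted)) {
    R <- R_sorted[i]
    init <- if (!is.null(prev) && prev$R < R) {
      pad <- function(M) {
        sc <- 1e-3 * mean(abs(M))
        cbind(M, matrix(with_seed(derive_seed(seed, 200L + R),
                                  abs(stats::rnorm(nrow(M) * (R - prev$R)))) * sc,
                        nrow(M)))
      }
      list(W = pad(prev$W), B = pad(prev$B), A = pad(prev$A))
    } else NULL
    m <- tca(v, R, mask = train_mask, seed = seed, init = init, ...)
    prev <- m
    res[[i]] <- data.frame(R = R,
                           train_error = normalized_error(v, m, train_mask),
                           test_error = normalized_error(v, m, test_mask))
  }
  out <- do.call(rbind, res)
  out[match(R_list, out$R), , drop = FALSE]
}

#' Similarity between two decompositions
#'
#' Components are matched one-to-one (Hungarian assignment) to maximize the
#' summed per-component score, where a component pair's score is the product
#' over the three modes of the cosine similarity between the matched factor
#' columns (scale therefore drops out). The mean matched score lies in
#' \[0, 1\] for nonnegative models and is 1 for identical models up to
#' component permutation and per-mode rescaling.
#'
#' @param a,b [tca()] models of equal shape and rank.
#' @return scalar similarity.
#' @export
model_similarity <- function(a, b) {
  stopifnot(inherits(a, "tca"), inherits(b, "tca"), a$R == b$R,
            nrow(a$W) == nrow(b$W), nrow(a$B) == nrow(b$B),
            nrow(a$A) == nrow(b$A))
  cosm <- function(X, Y) {
    nx <- sqrt(colSums(X^2)); ny <- sqrt(colSums(Y^2))
    s <- crossprod(X, Y) / (outer(nx, ny) + 1e-300)
    s[nx == 0, ] <- 0; s[, ny == 0] <- 0
    s
  }
  S <- cosm(a$W, b$W) * cosm(a$B, b$B) * cosm(a$A, b$A)
  hungarian_max(S)$score / a$R
}

#' Order components by trial-factor clusters
#'
#' K-means (seeded, 10 restarts) on the trial-factor columns groups
#' components by their across-trial amplitude pattern; within each cluster,
#' components are ordered by the time-to-peak of their temporal factor.
#' Clusters are presented in order of their mean time-to-peak.
#'
#' @param m a [tca()] model.
#' @param k_clusters number of clusters (default 5; 5 or 6 are sensible for
#'   typical trial-factor structure).
#' @param seed integer seed.
#' @return list with `order` (component permutation), `cluster` (per
#'   component, in original order), `time_to_peak`.
#' @export
cluster_trial_factors <- function(m, k_clusters = 5, seed = 1L) {
  stopifnot(inherits(m, "tca"), m$R >= k_clusters)
  feat <- t(m$A)  # rows = components
  km <- with_seed(seed, stats::kmeans(feat, centers = k_clusters,
                                      nstart = 10))
  ttp <- apply(m$B, 2, which.max)
  cl_order <- order(vapply(seq_len(k_clusters),
                           function(c) mean(ttp[km$cluster == c]),
                           numeric(1)))
  ord <- unlist(lapply(cl_order, function(c) {
    idx <- which(km$cluster == c)
    idx[order(ttp[idx])]
  }))
  list(order = ord, cluster = km$cluster, time_to_peak = ttp)
}

#' Trial-factor stability within versus across weeks
#'
#' For every unordered trial pair, the Pearson correlation between the two
#' trials' R-length trial-factor vectors; averaged separately over pairs
#' from the same week and pairs from different weeks.
#'
#' @param m a [tca()] model.
#' @param week_labels per-trial week index.
#' @return list with `within_week_cc` and `across_week_cc`.
#' @export
trial_factor_stability <- function(m, week_labels) {
  stopifnot(inherits(m, "tca"), length(week_labels) == nrow(m$A),
            length(unique(week_labels)) >= 2)
  cc <- suppressWarnings(stats::cor(t(m$A)))
  K <- nrow(m$A)
  same <- outer(week_labels, week_labels, "==")
  ut <- upper.tri(cc)
  list(within_week_cc = mean(cc[ut & same], na.rm = TRUE),
       across_week_cc = mean(cc[ut & !same], na.rm = TRUE))
}

#' Destroy cross-component alignment by shuffling factors
#'
#' Per component, independently: permute the neuron-factor entries,
#' circularly shift the temporal-factor column, and circularly shift the
#' trial-factor column. Column value multisets (hence component energies)
#' are preserved; the temporal coordination between components is not.
#'
#' @param m a [tca()] model.
#' @param seed integer seed.
#' @return a shuffled `tca` model.
#' @export
shuffle_factors <- function(m, seed = 1L) {
  stopifnot(inherits(m, "tca"))
  out <- m
  roll <- function(v, s) if (s == 0) v else c(v[(s + 1):length(v)], v[1:s])
  with_seed(seed, {
    for (r in seq_len(m$R)) {
      out$W[, r] <- m$W[sample.int(nrow(m$W)), r]
      out$B[, r] <- roll(m$B[, r], sample.int(nrow(m$B), 1) - 1L)
      out$A[, r] <- roll(m$A[, r], sample.int(nrow(m$A), 1) - 1L)
    }
  })
  out$objective <- NA_real_
  out$norm_error <- NA_real_
  out
}
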