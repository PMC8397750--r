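# Variance decomposition of manifold points along / perpendicular to the
# fitted ring curve (the coding direction), manifold radius, and the
# standard one-sided significance comparisons.

# decompose a set of points (rows) about their centroid into variance along
# the unit tangent u and total residual variance (n-1 denominators)
decompose_var <- function(pts, u) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  proj <- as.vector(X %*% u)
  par_var <- sum(proj^2) / (n - 1)
  resid <- X - outer(proj, u)
  perp_var <- sum(resid^2) / (n - 1)
  c(parallel = par_var, perpendicular = perp_var)
}

# tangent at the curve point nearest to location x (a single point)
tangent_at_nearest <- function(x, curve) {
  pr <- project_to_curve(matrix(x, 1), curve)
  u <- pr$tangent[1, ]
  u / sqrt(sum(u^2))
}

#' Variance along and perpendicular to the coding direction
#'
#' Per movie-time bin: the bin's points are centered on their centroid, the
#' ring-curve tangent at the curve point nearest the centroid defines the
#' coding (parallel) direction, and the variance is split into the tangent
#' component and the total residual across the remaining directions
#' (unbiased, n-1). Bins with fewer than two points are skipped.
#'
#' @param points P x d coordinate matrix (embedding dimensions used to fit
#'   the curve).
#' @param time_bin per-point movie-time bin.
#' @param curve the fitted [ring_curve()].
#' @return data frame (class `variance_table`) with columns `time_bin`,
#'   `parallel`, `perpendicular`; attribute `mode = "all-trials"`.
#' @export
variance_decomposition <- function(points, time_bin, curve) {
  stopifnot(nrow(points) == length(time_bin))
  bins <- sort(unique(time_bin))
  rows <- lapply(bins, function(b) {
    idx <- which(time_bin == b)
    if (length(idx) < 2) return(NULL)
    v <- decompose_var(points[idx, , drop = FALSE],
                       tangent_at_nearest(colMeans(points[idx, , drop = FALSE]),
                                          curve))
    data.frame(time_bin = b, parallel = v[1], perpendicular = v[2])
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) message(sprintf("variance_decomposition: %d bin(s) with < 2 points skipped", skipped))
  out <- do.call(rbind, rows)
  attr(out, "mode") <- "all-trials"
  class(out) <- c("variance_table", class(out))
  out
}

#' Week-to-week variance of trial-averaged activity
#'
#' Per (time bin, week) the mean point over that week's trials is taken;
#' per time bin the across-week variance of those week means is decomposed
#' along / perpendicular to the curve as in [variance_decomposition()].
#'
#' @inheritParams variance_decomposition
#' @param week per-point week labels.
#' @return a `variance_table` with mode `"week-averaged"`.
#' @export
week_averaged_variance <- function(points, time_bin, week, curve) {
  weeks <- sort(unique(week))
  stopifnot(length(weeks) >= 2)
  bins <- sort(unique(time_bin))
  rows <- lapply(bins, function(b) {
    wm <- t(vapply(weeks, function(w) {
      idx <- which(time_bin == b & week == w)
      if (length(idx) == 0) return(rep(NA_real_, ncol(points)))
      colMeans(points[idx, , drop = FALSE])
    }, numeric(ncol(points))))
    wm <- wm[stats::complete.cases(wm), , drop = FALSE]
    if (nrow(wm) < 2) return(NULL)
    v <- decompose_var(wm, tangent_at_nearest(colMeans(wm), curve))
    data.frame(time_bin = b, parallel = v[1], perpendicular = v[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- "week-averaged"
  class(out) <- c("variance_table", class(out))
  out
}

#' Within-week single-trial variance
#'
#' Per (time bin, week): the decomposition of that week's single-trial
#' points about their centroid; rows for all weeks are pooled. Weeks with a
#' single point in a bin are skipped.
#'
#' @inheritParams week_averaged_variance
#' @return a `variance_table` with mode `"within-week"` and a `week` column.
#' @export
within_week_variance <- function(points, time_bin, week, curve) {
  weeks <- sort(unique(week))
  bins <- sort(unique(time_bin))
  rows <- list()
  for (w in weeks) {
    for (b in bins) {
      idx <- which(time_bin == b & week == w)
      if (length(idx) < 2) next
      v <- decompose_var(points[idx, , drop = FALSE],
                         tangent_at_nearest(colMeans(points[idx, , drop = FALSE]),
                                            curve))
      rows[[length(rows) + 1]] <- data.frame(
        time_bin = b, week = w, parallel = v[1], perpendicular = v[2])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- "within-week"
  class(out) <- c("variance_table", class(out))
  out
}

#' Distance of each point to the manifold center
#'
#' The center is the coordinate-wise mean over all points; radii are
#' Euclidean distances to it.
#'
#' @param coords P x d coordinate matrix.
#' @return data frame with `radius`; the center in attribute `"center"`.
#' @export
manifold_radius <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1)
  ctr <- colMeans(coords)
  out <- data.frame(radius = sqrt(rowSums(sweep(coords, 2, ctr)^2)))
  attr(out, "center") <- ctr
  out
}

#' One-sided paired / unpaired rank test
#'
#' Thin wrapper over [stats::wilcox.test()] recording the direction and
#' sample size: `"wilcoxon-signed-rank"` is the paired signed-rank test,
#' `"mann-whitney"` the unpaired rank-sum test. The alternative is that `a`
#' is shifted below `b` (`alternative = "less"`, the default) or above.
#'
#' @param a,b numeric samples (paired for the signed-rank kind).
#' @param kind `"wilcoxon-signed-rank"` or `"mann-whitney"`.
#' @param alternative `"less"` or `"greater"`.
#' @return list with `statistic`, `p`, `kind`, `alternative`, `n`.
#' @export
paired_onesided_test <- function(a, b,
                                 kind = c("wilcoxon-signed-rank",
                                          "mann-whitney"),
                                 alternative = c("less", "greater")) {
  kind <- match.arg(kind)
  alternative <- match.arg(alternative)
  paired <- kind == "wilcoxon-signed-rank"
  if (paired) stopifnot(length(a) == length(b))
  if (paired && all(a == b)) stop("all pairs tied; test undefined")
  ht <- stats::wilcox.test(a, b, paired = paired,
                           alternative = alternative, exact = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value, kind = kind,
       alternative = alternative,
       n = if (paired) length(a) else c(length(a), length(b)))
}
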