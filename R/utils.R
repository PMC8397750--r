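# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stage seed from a master seed; double arithmetic avoids integer
# overflow and the result stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647)
}

#' Pearson correlation that returns NA (not an error/warning) on constant input
#' @noRd
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Mode-n unfolding of a 3-way array. Mode 1: N x (T*K), columns vary t fastest.
unfold3 <- function(x, mode) {
  d <- dim(x)
  switch(mode,
    `1` = { dim(x) <- c(d[1], d[2] * d[3]); x },
    `2` = { x <- aperm(x, c(2, 1, 3)); dim(x) <- c(d[2], d[1] * d[3]); x },
    `3` = { x <- aperm(x, c(3, 1, 2)); dim(x) <- c(d[3], d[1] * d[2]); x },
    stop("mode must be 1, 2 or 3")
  )
}

# Khatri-Rao product of factor columns: column r is as.vector(B[,r] %o% A[,r]),
# i.e. rows ordered with the B index varying fastest.
khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- as.vector(B[, r] %o% A[, r])
  out
}

# Circular absolute difference on [0, 1).
circ_diff01 <- function(a, b) {
  d <- abs((a - b) %% 1)
  pmin(d, 1 - d)
}

#' Circular correlation coefficient (Jammalamadaka-SenGupta)
#'
#' Association measure between two angular variables in radians; used to
#' verify that embedding angles around a recovered ring track a planted
#' circular variable.
#'
#' @param a,b numeric vectors of angles in radians.
#' @return a scalar in \[-1, 1\].
#' @export
circular_cor <- function(a, b) {
  stopifnot(length(a) == length(b))
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - abar); sb <- sin(b - bbar)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

#' Construct a DeltaF/F tensor object
#'
#' Container for fluorescence-change values on a (neuron, time, trial) grid
#' with per-trial week labels and the sampling interval.
#'
#' @param values numeric array, neurons x timepoints x trials.
#' @param week_labels integer vector, one (non-decreasing) week index per trial.
#' @param dt sampling interval in seconds per time bin.
#' @param movie_start_bin first time bin (1-based) of the movie proper; bins
#'   before it show the gray screen.
#' @return an object of class `dff_tensor`.
#' @export
dff_tensor <- function(values, week_labels, dt = 0.1, movie_start_bin = 1L) {
  stopifnot(length(dim(values)) == 3, all(is.finite(values)))
  week_labels <- as.integer(week_labels)
  stopifnot(length(week_labels) == dim(values)[3], !is.unsorted(week_labels))
  structure(
    list(values = values, week_labels = week_labels, dt = dt,
         movie_start_bin = as.integer(movie_start_bin)),
    class = "dff_tensor")
}

#' @export
print.dff_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dff_tensor> %d neurons x %d timepoints x %d trials (%d weeks, dt = %g s)\n",
              d[1], d[2], d[3], length(unique(x$week_labels)), x$dt))
  invisible(x)
}

#' @export
dim.dff_tensor <- function(x) dim(x$values)
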