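# O(n^3) Hungarian algorithm (potentials / shortest augmenting path form)
# for the linear assignment problem. Used to match components between two
# tensor decompositions; no assignment-problem package is a dependency.

# Minimum-cost perfect assignment of a square cost matrix.
# Returns integer vector p with p[j] = row assigned to column j... we expose
# the more convenient row->column form.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  # 1-based port of the classical potentials algorithm; a[0]-style sentinels
  # are index 1 here, so all matrices are padded by one row/column.
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)   # assignment[row] = column
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

# Maximum-score assignment; returns list(assignment, score).
hungarian_max <- function(score) {
  a <- hungarian_min(max(score) - score)
  list(assignment = a, score = sum(score[cbind(seq_len(nrow(score)), a)]))
}
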