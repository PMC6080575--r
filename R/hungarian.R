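#' Solve a linear assignment problem (Hungarian algorithm)
#'
#' Minimum-cost perfect matching on a square cost matrix, via the O(n^3)
#' Kuhn-Munkres algorithm with dual potentials.
#'
#' @param cost square numeric matrix; entry (i, j) is the cost of assigning
#'   row i to column j.
#' @param maximize if TRUE, maximize total value instead of minimizing cost.
#' @return integer vector \code{perm} with \code{perm[i]} the column
#'   assigned to row i; a bijection of \code{1..n}.
#' @export
solve_assignment <- function(cost, maximize = FALSE) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n)
    dm_stop("assignment cost matrix must be square", "devmeta_validation_error")
  if (maximize) cost <- max(cost) - cost
  if (any(!is.finite(cost)))
    dm_stop("assignment costs must be finite", "devmeta_validation_error")
  V0 <- n + 1L  # virtual column used to start each augmenting path
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[V0] <- i
    j0 <- V0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path back to the virtual column
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V0) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j]] <- j
  perm
}
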