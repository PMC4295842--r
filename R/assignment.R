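# Linear assignment by the Jonker-Volgenant shortest augmenting path
# algorithm (O(n^3)). Square cost matrix; returns, for each row, the column
# assigned to it. Costs may contain Inf for forbidden pairs as long as a
# finite-cost perfect matching exists.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  # potentials and matching; columns indexed 1..n, virtual row/col 0 handled
  # with index n+1 sentinels
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1              # sentinel "column 0"
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      if (!is.finite(delta))
        stop("assignment infeasible: no finite-cost perfect matching")
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assign[p[j]] <- j
  assign
}
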