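# Exact linear assignment (Hungarian / Jonker-Volgenant shortest
# augmenting paths, O(n^3)). Used to resolve factor label switching.
#
# Returns, for each row i, the column assigned to it, minimizing total
# cost. Arrays are padded with a sentinel slot at index 1 (the classic
# "column 0") so the textbook potentials formulation carries over.

solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stopf("cost matrix must be square")
  if (n == 1L) return(1L)
  u <- numeric(n + 1L)        # row potentials  (u[i+1], row 0 = sentinel)
  v <- numeric(n + 1L)        # column potentials (v[j+1])
  p <- integer(n + 1L)        # p[j+1] = row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j + 1L]] <- j
  ans
}
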