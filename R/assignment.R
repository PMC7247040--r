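# Linear assignment by the Jonker-Volgenant shortest-augmenting-path scheme
# (the Hungarian method's O(n^3) form with dual potentials). Used to align
# membership-matrix columns optimally; greedy matching can miss the optimum.

# Returns perm with perm[i] = column assigned to row i, minimizing
# sum(cost[cbind(seq_len(n), perm)]).
lap_min <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1L, !anyNA(cost), all(is.finite(cost)))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials; index 1 is the virtual root
  p <- integer(n + 1L)     # p[j]: row currently matched to column j-1 (0 = free)
  way <- integer(n + 1L)   # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)
      cur <- cost[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {  # augment along the alternating path back to the root
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  perm[p[2:(n + 1L)]] <- seq_len(n)
  perm
}

# Maximum-trace column matching of a (padded square) contingency/overlap
# matrix; returns perm with perm[a] = matched column of the second matrix.
match_columns <- function(overlap) {
  lap_min(-overlap)
}
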