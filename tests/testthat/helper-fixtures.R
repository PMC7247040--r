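# shared fixtures (memoized: meshes and cohorts are deterministic given seeds)

.fixtures <- new.env()

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fixture_mesh <- function(order) {
  memo(paste0("mesh", order), function() icosphere(order))
}

# default-condition cohort at the working scale (order-3 mesh, N = 20)
fixture_cohort3 <- function() {
  memo("cohort3", function() simulate_cohort(cohort_spec(seed = 11L)))
}

# small cohort for fast end-to-end tests
fixture_cohort2 <- function(n = 6L, seed = 13L) {
  memo(sprintf("cohort2_%d_%d", n, seed), function()
    simulate_cohort(cohort_spec(mesh_order = 2L, n_subjects = n, seed = seed)))
}

# all set partitions of n elements as canonical label vectors
# (restricted-growth-string enumeration)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- partition(prefix)
      return(invisible())
    }
    for (v in 0:(mx + 1L)) recurse(c(prefix, v), max(mx, v))
  }
  recurse(integer(0), -1L)
  out
}

# all permutations of 1..n (for brute-force column-permutation minima)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_perms(n - 1L), function(p) c(i, seq_len(n)[-i][p]))
  }))
}

# brute-force permutation-minimal membership distance
brute_partition_distance <- function(ci, cj) {
  l <- max(n_regions(ci), n_regions(cj))
  pi_m <- membership_matrix(ci, l)
  pj_m <- membership_matrix(cj, l)
  min(vapply(all_perms(l), function(p)
    sum((pi_m - pj_m[, p, drop = FALSE])^2), 0))
}

# independent connected-components oracle: plain BFS over an adjacency list
adjacency_list_oracle <- function(m) {
  edges <- mesh_adjacency(m, as = "edges")
  adj <- vector("list", nrow(m$positions))
  for (r in seq_len(nrow(edges))) {
    adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
    adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
  }
  adj
}

bfs_components_oracle <- function(vs, adj) {
  seen <- logical(length(vs))
  ncomp <- 0
  for (i in seq_along(vs)) {
    if (seen[i]) next
    ncomp <- ncomp + 1
    queue <- i
    seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- match(intersect(adj[[vs[v]]], vs), vs)
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ncomp
}

entropy_oracle <- function(sizes) {
  p <- sizes / sum(sizes)
  p <- p[p > 0]
  -sum(p * log(p))
}

rand_partition <- function(k, l, seed) {
  with_seed_test(seed, partition(sample.int(l, k, replace = TRUE) - 1L))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# random shuffle of a partition's label values (relabeled copy)
shuffle_labels <- function(p, seed) {
  lab <- as.integer(p)
  u <- sort(unique(lab))
  new <- with_seed_test(seed, sample(1000L + seq_along(u)))
  partition(new[match(lab, u)])
}

# tiny weighted block-structured connectome: Poisson weights with
# within/between means, independent of the synthetic module's machinery
sbm_connectome <- function(sizes, within, between, seed) {
  k <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  with_seed_test(seed, {
    mu <- ifelse(outer(lab, lab, "=="), within, between)
    w <- matrix(stats::rpois(k * k, mu), k, k)
    w[lower.tri(w, diag = TRUE)] <- 0
    w <- w + t(w)
    dense_connectome(w)
  })
}
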