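#' Binary membership matrix of a partition
#'
#' Encodes a hard partition as a K x L binary matrix with `P[k, l+1] = 1`
#' iff vertex `k` carries (canonical) label `l`. Columns beyond the
#' partition's region count are all-zero padding, so partitions with
#' different region counts can be compared after padding both to the larger
#' column count.
#'
#' @param c a [partition()].
#' @param L column count, at least `n_regions(c)`.
#' @return K x L binary matrix.
#' @export
membership_matrix <- function(c, L = n_regions(c)) {
  c <- relabel_canonical(c)
  l0 <- n_regions(c)
  if (L < l0) stop("L must be at least the number of regions")
  p <- matrix(0, length(c), L)
  p[cbind(seq_along(c), as.integer(c) + 1L)] <- 1
  p
}

#' Permutation-minimal partition distance
#'
#' The squared Frobenius distance between membership matrices, minimized
#' over column permutations:
#' \deqn{d(C_i, C_j) = \min_\pi \lVert P_i - P_j \pi \rVert_F^2.}
#' For hard partitions this equals `2K - 2 max_pi trace` of the permuted
#' contingency table, so the optimal permutation is found by an exact linear
#' assignment solve (never greedily). The distance is 0 iff the partitions
#' are relabel-equivalent, and is symmetric.
#'
#' @param ci,cj partitions over the same vertex set.
#' @return nonnegative distance.
#' @export
partition_distance <- function(ci, cj) {
  if (length(ci) != length(cj)) stop("partitions must cover the same vertex set")
  k <- length(ci)
  ci <- relabel_canonical(ci)
  cj <- relabel_canonical(cj)
  l <- max(n_regions(ci), n_regions(cj))
  tab <- matrix(0, l, l)
  tt <- table(as.integer(ci), as.integer(cj))
  tab[seq_len(nrow(tt)), seq_len(ncol(tt))] <- tt
  perm <- match_columns(tab)
  2 * k - 2 * sum(tab[cbind(seq_len(l), perm)])
}

#' Karcher-mean objective of a candidate consensus partition
#'
#' The sum of permutation-minimal partition distances from the candidate to
#' every cohort member. The consensus (pseudo-Karcher mean) sought by the
#' hard-ensemble algorithm approximately minimizes this objective.
#'
#' @param c_star candidate consensus [partition()].
#' @param cohort nonempty list of partitions on the same vertex set.
#' @return nonnegative objective value.
#' @export
karcher_objective <- function(c_star, cohort) {
  if (length(cohort) == 0L) stop("cohort must be nonempty")
  sum(vapply(cohort, function(ci) partition_distance(c_star, ci), 0))
}

#' Hard-ensemble consensus of a cohort of partitions
#'
#' Greedy successive averaging: the running (row-stochastic) membership
#' matrix starts at the first partition's membership; each next partition is
#' zero-padded to the common column count, optimally column-aligned to the
#' running matrix by linear assignment on the squared column-difference
#' cost, and absorbed with weights `(t-1):1` so after `t` subjects the
#' running matrix is the unweighted mean of the aligned memberships. The
#' final soft matrix is hardened by per-row argmax (ties to the lower column
#' index), empty labels dropped, and the result canonicalized.
#'
#' The procedure is order-dependent; `order_seed` shuffles the cohort first
#' (used by the order-stability experiment), otherwise input order is kept.
#'
#' @param cohort nonempty list of partitions on a common vertex set.
#' @param order_seed optional integer; if given, the cohort order is
#'   shuffled reproducibly before averaging.
#' @return the consensus [partition()].
#' @export
hard_ensemble <- function(cohort, order_seed = NULL) {
  if (length(cohort) == 0L) stop("cohort must be nonempty")
  k <- unique(vapply(cohort, length, 1L))
  if (length(k) != 1L) stop("all partitions must cover the same vertex set")
  if (!is.null(order_seed)) {
    cohort <- with_seed(order_seed, sample(cohort))
  }
  run <- membership_matrix(cohort[[1L]])
  n <- length(cohort)
  if (n > 1L) for (t in 2:n) {
    p <- membership_matrix(cohort[[t]])
    l <- max(ncol(run), ncol(p))
    if (ncol(run) < l) run <- cbind(run, matrix(0, k, l - ncol(run)))
    if (ncol(p) < l) p <- cbind(p, matrix(0, k, l - ncol(p)))
    # cost[a, b] = || run[, a] - p[, b] ||^2, minimized by exact assignment
    cost <- outer(colSums(run^2), colSums(p^2), "+") - 2 * crossprod(run, p)
    perm <- lap_min(cost)
    run <- ((t - 1) * run + p[, perm, drop = FALSE]) / t
  }
  hard <- max.col(run, ties.method = "first")
  relabel_canonical(partition(hard - 1L))
}

#' Vertex co-occurrence (co-association) matrix
#'
#' `S[a, b]` counts the cohort partitions that assign vertices `a` and `b`
#' the same label; the diagonal equals the cohort size.
#'
#' @param cohort nonempty list of partitions on a common vertex set.
#' @return K x K symmetric integer-valued matrix.
#' @export
cooccurrence <- function(cohort) {
  if (length(cohort) == 0L) stop("cohort must be nonempty")
  k <- length(cohort[[1L]])
  s <- matrix(0, k, k)
  for (ci in cohort) {
    mb <- membership_matrix(ci)
    s <- s + tcrossprod(mb)
  }
  s
}

#' CSPA consensus: cluster the co-occurrence graph
#'
#' Cluster-based similarity partitioning: the co-occurrence matrix `S`
#' (diagonal zeroed) is treated as a dense weighted graph and clustered by
#' the same three-level hierarchical Louvain scheme used for individual
#' connectomes. `S` is not thresholded.
#'
#' @param cohort nonempty list of partitions on a common vertex set
#'   (typically the deepest-level individual parcellations).
#' @param config a [parcellation_config()].
#' @return a [hierarchical_partition()].
#' @export
cspa <- function(cohort, config = parcellation_config()) {
  s <- cooccurrence(cohort)
  diag(s) <- 0
  hierarchical_parcellation(dense_connectome(s, subject_id = "cspa"), config)
}

#' Average-graph consensus: cluster the mean connectome
#'
#' Averages the cohort's dense connectomes elementwise and applies the
#' hierarchical parcellation to the mean graph.
#'
#' @param cohort nonempty list of [dense_connectome()]s with equal K.
#' @param config a [parcellation_config()].
#' @return a [hierarchical_partition()].
#' @export
average_graph_parcellation <- function(cohort, config = parcellation_config()) {
  if (length(cohort) == 0L) stop("cohort must be nonempty")
  k <- unique(vapply(cohort, function(w) nrow(w$weights), 1L))
  if (length(k) != 1L) stop("all connectomes must have the same vertex count")
  mean_w <- Reduce(`+`, lapply(cohort, `[[`, "weights")) / length(cohort)
  hierarchical_parcellation(dense_connectome(mean_w, subject_id = "average"),
                            config)
}
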