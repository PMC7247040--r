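#' Piecewise-constant approximation of a dense connectome
#'
#' Replaces the weight of every vertex pair by the mean weight of its block:
#' `gamma[u, v] = omega(E_i, E_j) / (|E_i| * |E_j|)` for `u` in region `i`,
#' `v` in region `j`, with region sizes as vertex counts. Within-region
#' blocks average over their off-diagonal pair count `|E_i| * (|E_i| - 1)`
#' and the diagonal stays zero, so `gamma` is the exact conditional block
#' mean on the off-diagonal support used by [kl_divergence()] (hence KL is
#' zero iff the connectome is block-constant, and a block-constant input is
#' reproduced exactly).
#'
#' @param w a [dense_connectome()].
#' @param c a [partition()] covering all vertices.
#' @return K x K block-constant matrix with zero diagonal.
#' @export
piecewise_constant <- function(w, c) {
  lab <- as.integer(relabel_canonical(c)) + 1L
  cc <- coarsen(w, c)
  sizes <- cc$region_sizes
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1L)
  block_mean <- cc$omega / ifelse(denom > 0, denom, 1)
  block_mean[denom == 0] <- 0
  gamma <- block_mean[lab, lab]
  diag(gamma) <- 0
  gamma
}

#' Kullback-Leibler divergence of a connectome from its block approximation
#'
#' Both matrices are restricted to off-diagonal unordered vertex pairs and
#' normalized to probability distributions; the divergence is
#' `sum(l * log(l / g))` with the `0 log 0 = 0` convention and natural
#' logarithm. Lower values mean the parcellation's block-constant graph is a
#' more faithful compression of the dense connectome; nested refinements
#' never increase it.
#'
#' @param w a [dense_connectome()].
#' @param gamma block-constant matrix of the same shape, e.g. from
#'   [piecewise_constant()]; must be positive wherever `w` is.
#' @return nonnegative divergence (nats).
#' @export
kl_divergence <- function(w, gamma) {
  wt <- w$weights
  if (!identical(dim(wt), dim(gamma))) stop("shape mismatch")
  up <- upper.tri(wt)
  lam <- wt[up]
  gam <- gamma[up]
  if (any(gam == 0 & lam > 0)) {
    stop("gamma must be positive wherever the connectome has weight")
  }
  lam <- lam / sum(lam)
  gam <- gam / sum(gam)
  pos <- lam > 0
  sum(lam[pos] * log(lam[pos] / gam[pos]))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two partitions
#'
#' Builds the contingency table `T[i, j] = |X_i intersect Y_j|` and returns
#' the natural-log mutual information together with both entropies.
#' Computed as `H(X) + H(Y) - H(X, Y)`, which is algebraically identical to
#' the usual double sum and numerically exact for identical partitions.
#'
#' @param x,y partitions over the same vertex set.
#' @return list with `mi`, `h_x`, `h_y`, and the contingency `table`.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("partitions must cover the same vertex set")
  k <- length(x)
  tab <- unclass(table(as.integer(x), as.integer(y)))
  dimnames(tab) <- NULL
  h_x <- entropy_nat(rowSums(tab) / k)
  h_y <- entropy_nat(colSums(tab) / k)
  h_xy <- entropy_nat(as.vector(tab) / k)
  list(mi = h_x + h_y - h_xy, h_x = h_x, h_y = h_y, table = tab)
}

#' Expected mutual information under the permutation model
#'
#' The exact expectation of MI over all relabelings with fixed marginals
#' (the hypergeometric permutation model of Vinh, Epps & Bailey), used to
#' correct MI for chance in [ami()].
#'
#' @param row_marginals,col_marginals cluster sizes of the two partitions;
#'   both must sum to `K`.
#' @param K total number of objects.
#' @return expected MI in nats.
#' @export
expected_mi <- function(row_marginals, col_marginals, K) {
  a <- as.numeric(row_marginals)
  b <- as.numeric(col_marginals)
  if (sum(a) != K || sum(b) != K) stop("marginals must sum to K")
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - K)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      pr <- stats::dhyper(nij, ai, K - ai, bj)
      emi <- emi + sum(pr * (nij / K) * log(K * nij / (ai * bj)))
    }
  }
  emi
}

#' Adjusted mutual information (max normalization)
#'
#' \deqn{AMI = \frac{MI - E[MI]}{\max(H(X), H(Y)) - E[MI]},}
#' with the expectation under the fixed-marginal permutation model. Equals
#' 1 exactly for relabel-equivalent partitions, is close to 0 for unrelated
#' ones, and is symmetric and relabeling-invariant. When the denominator is
#' 0 (both partitions trivial) the value is 1 if they are equivalent, else 0.
#'
#' @param x,y partitions over the same vertex set.
#' @return AMI value in `(-Inf, 1]`.
#' @export
ami <- function(x, y) {
  mi <- mutual_information(x, y)
  k <- length(x)
  emi <- expected_mi(rowSums(mi$table), colSums(mi$table), k)
  den <- max(mi$h_x, mi$h_y) - emi
  if (den == 0) {
    return(if (partitions_equivalent(x, y)) 1 else 0)
  }
  (mi$mi - emi) / den
}

#' Minimal-cover Dice overlap of a region against a partition
#'
#' For a reference region X (e.g. an anatomical atlas region) the minimal
#' cover Y* is the union of all regions of `y` that intersect X — for a hard
#' partition this is the unique smallest union of parcels containing X. The
#' score is `Dice = 2 |X| / (|X| + |Y*|)` (since X is a subset of Y*).
#'
#' @param x_region integer vector of (1-based) vertex indices, nonempty.
#' @param y a [partition()].
#' @return Dice score in (0, 1].
#' @export
dice_min_cover <- function(x_region, y) {
  if (length(x_region) == 0L) stop("x_region must be nonempty")
  lab <- as.integer(y)
  cover_labels <- unique(lab[x_region])
  y_star <- sum(lab %in% cover_labels)
  2 * length(x_region) / (length(x_region) + y_star)
}

#' Hemispheric symmetry of a parcellation
#'
#' AMI between the labels of the left-hemisphere vertices and the labels of
#' their mirror images on the right. 1 means perfectly mirrored parcels.
#'
#' @param c a [partition()] on the mesh vertices.
#' @param m a [surface_mesh()] with a mirror correspondence.
#' @return AMI value.
#' @export
hemispheric_symmetry <- function(c, m) {
  if (length(c) != nrow(m$positions)) stop("partition must cover the mesh")
  left <- which(m$hemisphere == "L")
  ami(partition(as.integer(c)[left]), partition(as.integer(c)[m$mirror[left]]))
}

#' Spatial contiguity of a parcellation
#'
#' Fraction of vertices whose parcel induces exactly one connected component
#' in the mesh adjacency graph (a single contiguous patch of cortex).
#' Relabeling-invariant.
#'
#' @param c a [partition()] on the mesh vertices.
#' @param m a [surface_mesh()].
#' @return fraction in \[0, 1\].
#' @export
contiguity <- function(c, m) {
  if (length(c) != nrow(m$positions)) stop("partition must cover the mesh")
  g <- mesh_adjacency(m)
  lab <- as.integer(c)
  good <- 0L
  for (l in unique(lab)) {
    idx <- which(lab == l)
    sub <- igraph::induced_subgraph(g, idx)
    if (igraph::components(sub)$no == 1L) good <- good + length(idx)
  }
  good / length(lab)
}

#' Weighted graph characteristics of a coarse connectome
#'
#' Clustering coefficient: mean over nodes of the Onnela geometric-mean
#' triangle intensity on weights rescaled by the maximum weight (so it is
#' scale-invariant); nodes with fewer than two neighbours contribute 0.
#' Average path length: mean shortest-path length over connected unordered
#' node pairs with edge lengths `1/weight` (so doubling all weights halves
#' it).
#'
#' @param cc a [coarse_connectome()] with at least 3 regions.
#' @return list with `clustering_coefficient` and `average_path_length`.
#' @export
graph_characteristics <- function(cc) {
  w <- cc$omega
  n <- nrow(w)
  if (n < 3L) stop("clustering coefficient undefined for fewer than 3 nodes")
  diag(w) <- 0
  if (max(w) == 0) stop("graph has no edges")
  wh <- (w / max(w))^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  a <- (w > 0) + 0
  deg <- rowSums(a)
  denom <- deg * (deg - 1)
  cc_node <- ifelse(denom > 0, num / denom, 0)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  d <- igraph::distances(g, weights = 1 / w[idx])
  finite <- d[upper.tri(d)]
  finite <- finite[is.finite(finite)]
  list(clustering_coefficient = mean(cc_node),
       average_path_length = mean(finite))
}

#' Ensemble goodness: mean agreement with the cohort
#'
#' The mean AMI between a consensus partition and every individual
#' partition; 1 iff the consensus matches every subject exactly.
#'
#' @param c_star consensus [partition()].
#' @param cohort nonempty list of partitions on the same vertex set.
#' @return mean AMI.
#' @export
ensemble_goodness <- function(c_star, cohort) {
  if (length(cohort) == 0L) stop("cohort must be nonempty")
  mean(vapply(cohort, function(ci) ami(ci, c_star), 0))
}
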