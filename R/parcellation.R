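#' Parcellation configuration
#'
#' @param n_levels number of hierarchy levels (the default three-level scheme
#'   yields coarse / intermediate / fine parcellations).
#' @param min_parcel_fraction parcels holding fewer than this fraction of all
#'   vertices are never subdivided further (default 0.01).
#' @param seed integer seed controlling the randomized node-visit order of
#'   the community detection; the same seed reproduces the same partitions.
#' @return object of class `parcellation_config`.
#' @export
parcellation_config <- function(n_levels = 3L, min_parcel_fraction = 0.01,
                                seed = 1L) {
  stopifnot(n_levels >= 1L, min_parcel_fraction >= 0,
            min_parcel_fraction < 1)
  structure(list(n_levels = as.integer(n_levels),
                 min_parcel_fraction = min_parcel_fraction,
                 seed = as.integer(seed)),
            class = "parcellation_config")
}

#' Newman modularity of a partition
#'
#' Scores how much within-community edge weight exceeds the degree-based
#' null expectation:
#' \deqn{Q = \frac{1}{m}\sum_{u,v}\left(W_{uv} - \frac{d_u d_v}{m}\right)\delta(c_u,c_v),}
#' with \eqn{d_u = \sum_v W_{uv}} and \eqn{m = \sum_{u,v} W_{uv}} over
#' ordered pairs, so the single-community partition scores exactly 0.
#' Implemented independently of any community-detection backend so delegated
#' optimizer output can be validated against it.
#'
#' @param w a [dense_connectome()].
#' @param c a [partition()] covering all vertices of `w`.
#' @return modularity score in \[-1, 1\].
#' @export
modularity_score <- function(w, c) {
  wt <- w$weights
  if (length(c) != nrow(wt)) stop("partition must cover all vertices")
  d <- rowSums(wt)
  m <- sum(d)
  if (m == 0) stop("modularity is undefined on an empty graph (no edges)")
  lab <- as.integer(relabel_canonical(c)) + 1L
  within <- sum(vapply(split(seq_along(lab), lab), function(idx) {
    sum(wt[idx, idx])
  }, 0))
  dsum <- vapply(split(d, lab), sum, 0)
  within / m - sum(dsum^2) / m^2
}

#' Louvain community detection on a dense connectome
#'
#' Multilevel greedy modularity maximization: greedy node moves followed by
#' contraction of communities into a metagraph, iterated to convergence.
#' Delegates to [igraph::cluster_louvain()] (resolution 1); the seed fixes
#' the randomized node-visit order so results are reproducible. Isolated
#' vertices each form their own community.
#'
#' @param w a [dense_connectome()] with at least one edge.
#' @param seed integer seed.
#' @return a canonical [partition()].
#' @export
louvain_communities <- function(w, seed = 1L) {
  g <- connectome_graph(w)
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)))
  relabel_canonical(partition(as.integer(memb) - 1L))
}

connectome_graph <- function(w) {
  idx <- which(upper.tri(w$weights) & w$weights > 0, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(w$weights) - igraph::vcount(g)))
  igraph::E(g)$weight <- w$weights[idx]
  g
}

#' Three-level hierarchical parcellation of a connectome
#'
#' Level 1 clusters the full connectome by Louvain modularity maximization;
#' each subsequent level re-clusters every parcel's induced subgraph as an
#' independent graph (edges leaving the parcel are dropped). Parcels holding
#' fewer than `min_parcel_fraction * K` vertices, or whose induced subgraph
#' has no edges, are copied unchanged to the next level. The resulting
#' levels are nested refinements by construction.
#'
#' @param w a [dense_connectome()].
#' @param config a [parcellation_config()].
#' @return a nested [hierarchical_partition()].
#' @export
hierarchical_parcellation <- function(w, config = parcellation_config()) {
  k <- nrow(w$weights)
  min_size <- ceiling(config$min_parcel_fraction * k)
  levels <- vector("list", config$n_levels)
  levels[[1]] <- louvain_communities(w, seed = config$seed)
  if (config$n_levels > 1L) for (t in 2:config$n_levels) {
    prev <- as.integer(levels[[t - 1L]])
    lab <- integer(k)
    next_label <- 0L
    for (parcel in sort(unique(prev))) {
      idx <- which(prev == parcel)
      sub <- NULL
      if (length(idx) >= max(min_size, 2L)) {
        swt <- w$weights[idx, idx, drop = FALSE]
        if (any(swt > 0)) {
          sub <- louvain_communities(
            dense_connectome(swt),
            seed = derive_seed(config$seed, t, parcel))
        }
      }
      if (is.null(sub)) {
        lab[idx] <- next_label
        next_label <- next_label + 1L
      } else {
        lab[idx] <- next_label + as.integer(sub)
        next_label <- next_label + n_regions(sub)
      }
    }
    levels[[t]] <- relabel_canonical(partition(lab))
  }
  hierarchical_partition(levels, check_nested = TRUE)
}

#' Coarsen a connectome by a partition
#'
#' Region-level edge weights are block sums of the dense weights:
#' `omega[a, b]` is the total weight between regions `a` and `b` (the
#' expected inter-region tract count under the Poisson model). Total mass is
#' conserved exactly.
#'
#' @param w a [dense_connectome()].
#' @param c a [partition()] covering all vertices.
#' @return object of class `coarse_connectome` with fields `omega` (L x L)
#'   and `region_sizes`.
#' @export
coarsen <- function(w, c) {
  if (length(c) != nrow(w$weights)) stop("partition must cover all vertices")
  lab <- as.integer(relabel_canonical(c)) + 1L
  l <- max(lab)
  mb <- Matrix::sparseMatrix(i = seq_along(lab), j = lab, x = 1,
                             dims = c(length(lab), l))
  omega <- as.matrix(Matrix::crossprod(mb, w$weights %*% mb))
  dimnames(omega) <- NULL
  structure(list(omega = omega, region_sizes = tabulate(lab, l)),
            class = "coarse_connectome")
}

#' @export
print.coarse_connectome <- function(x, ...) {
  cat(sprintf("<coarse_connectome> %d regions, total mass %.4g\n",
              length(x$region_sizes), sum(x$omega)))
  invisible(x)
}
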