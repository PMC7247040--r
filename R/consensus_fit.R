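#' Fit a consensus parcellation to a cohort of dense connectomes
#'
#' The package's main entry point. Each subject's connectome is parcellated
#' by three-level hierarchical Louvain modularity clustering, and the
#' individual parcellations are aggregated — per hierarchy level — into one
#' consensus parcellation:
#'
#' * `"he"` (default): the hard ensemble, a greedy pseudo-Karcher mean under
#'   the permutation-minimal membership distance; label correspondence
#'   across subjects is never required.
#' * `"cspa"`: clustering of the vertex co-occurrence graph built from the
#'   deepest individual parcellations.
#' * `"average"`: hierarchical clustering of the elementwise mean connectome.
#'
#' Consensus levels from `"he"` and `"cspa"` are reported per level and are
#' not forced to nest; subject-level hierarchies always nest.
#'
#' @param connectomes nonempty list of [dense_connectome()]s over a common
#'   vertex set (optionally pre-thresholded with [sparsify()]).
#' @param method consensus method.
#' @param config a [parcellation_config()]; per-subject seeds derive from
#'   `config$seed`.
#' @param order_seed optional seed shuffling the subject order absorbed by
#'   the hard ensemble.
#' @return object of class `consensus_parcellation` with components
#'   `levels` (list of consensus [partition()]s), `individual` (per-subject
#'   [hierarchical_partition()]s), `goodness` (per-level mean AMI to the
#'   individuals), `n_regions`, `method`, `config`.
#' @seealso [predict.consensus_parcellation()] to coarsen new connectomes,
#'   [summary.consensus_parcellation()], [plot.consensus_parcellation()].
#' @examples
#' spec <- cohort_spec(mesh_order = 2L, n_subjects = 4L, seed = 7L)
#' cohort <- simulate_cohort(spec)
#' fit <- consensus_parcellation(cohort$connectomes,
#'                               config = parcellation_config(n_levels = 2L))
#' fit
#' @export
consensus_parcellation <- function(connectomes,
                                   method = c("he", "cspa", "average"),
                                   config = parcellation_config(),
                                   order_seed = NULL) {
  method <- match.arg(method)
  if (length(connectomes) == 0L) stop("cohort must be nonempty")
  k <- unique(vapply(connectomes, function(w) nrow(w$weights), 1L))
  if (length(k) != 1L) stop("all connectomes must share one vertex set")
  individual <- lapply(seq_along(connectomes), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    hierarchical_parcellation(connectomes[[i]], cfg_i)
  })
  levels <- switch(
    method,
    he = lapply(seq_len(config$n_levels), function(l)
      hard_ensemble(lapply(individual, function(h) h$levels[[l]]),
                    order_seed = order_seed)),
    cspa = cspa(lapply(individual, function(h) h$levels[[config$n_levels]]),
                config)$levels,
    average = average_graph_parcellation(connectomes, config)$levels)
  goodness <- vapply(seq_along(levels), function(l)
    ensemble_goodness(levels[[l]],
                      lapply(individual, function(h) h$levels[[min(l, config$n_levels)]])),
    0)
  structure(list(levels = levels, individual = individual,
                 goodness = goodness,
                 n_regions = vapply(levels, n_regions, 1L),
                 method = method, config = config, n_subjects = length(connectomes),
                 n_vertices = k, call = match.call()),
            class = "consensus_parcellation")
}

#' @export
print.consensus_parcellation <- function(x, ...) {
  cat(sprintf("Consensus parcellation (%s), %d subjects, %d vertices\n",
              toupper(x$method), x$n_subjects, x$n_vertices))
  cat(sprintf("  regions per level: %s\n", paste(x$n_regions, collapse = " / ")))
  cat(sprintf("  ensemble goodness: %s\n",
              paste(sprintf("%.3f", x$goodness), collapse = " / ")))
  invisible(x)
}

#' Summarize a consensus parcellation
#'
#' Adds the Karcher-mean objective of each consensus level against the
#' individual partitions of the same level, and region size summaries.
#'
#' @param object a [consensus_parcellation()].
#' @param ... unused.
#' @return object of class `summary.consensus_parcellation`.
#' @export
summary.consensus_parcellation <- function(object, ...) {
  n_lev <- length(object$levels)
  tab <- data.frame(
    level = seq_len(n_lev),
    n_regions = object$n_regions,
    goodness = object$goodness,
    karcher_objective = vapply(seq_len(n_lev), function(l)
      karcher_objective(object$levels[[l]],
                        lapply(object$individual, function(h)
                          h$levels[[min(l, length(h$levels))]])), 0),
    median_region_size = vapply(object$levels, function(p)
      stats::median(tabulate(as.integer(p) + 1L)), 0))
  structure(list(method = object$method, table = tab,
                 n_subjects = object$n_subjects),
            class = "summary.consensus_parcellation")
}

#' @export
print.summary.consensus_parcellation <- function(x, ...) {
  cat(sprintf("Consensus parcellation summary (%s, N = %d)\n",
              toupper(x$method), x$n_subjects))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Apply a fitted consensus parcellation to a connectome
#'
#' Coarsens a (new) dense connectome over the consensus regions, yielding
#' the region-level connectome implied by the group parcellation.
#'
#' @param object a [consensus_parcellation()].
#' @param newdata a [dense_connectome()] on the same vertex set.
#' @param level hierarchy level to use (default: deepest).
#' @param ... unused.
#' @return a [coarsen()]ed `coarse_connectome`.
#' @export
predict.consensus_parcellation <- function(object, newdata,
                                           level = length(object$levels), ...) {
  if (!inherits(newdata, "dense_connectome")) {
    stop("newdata must be a dense_connectome")
  }
  coarsen(newdata, object$levels[[level]])
}

#' Plot a consensus parcellation on its mesh
#'
#' Orthographic projection of each hemisphere (left: x < 0 view, right:
#' mirrored), vertices coloured by consensus region.
#'
#' @param x a [consensus_parcellation()].
#' @param mesh the [surface_mesh()] the cohort lives on.
#' @param level hierarchy level to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.consensus_parcellation <- function(x, mesh, level = length(x$levels), ...) {
  p <- x$levels[[level]]
  lab <- as.integer(p)
  cols <- grDevices::hcl.colors(max(lab) + 1L, "Spectral")
  old <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (h in c("L", "R")) {
    idx <- which(mesh$hemisphere == h)
    pos <- mesh$positions[idx, ]
    front <- pos[, 1] * (if (h == "L") -1 else 1) >= 0
    graphics::plot(pos[front, 2], pos[front, 3], col = cols[lab[idx][front] + 1L],
                   pch = 16, cex = 0.6, axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s hemisphere (level %d)", h, level),
                   asp = 1, ...)
  }
  invisible(x)
}
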