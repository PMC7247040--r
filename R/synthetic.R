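#' Specification of a synthetic connectome cohort
#'
#' Describes a cohort of mirrored, spatially smooth, block-structured
#' connectomes on a subdivided icosahedral sphere pair with a planted
#' two-level regional hierarchy. Edge counts are Poisson draws (the discrete
#' analogue of the Poisson point-process connectivity model) whose mean
#' depends on the deepest shared block of the endpoints; multiplicative
#' lognormal noise models subject-level intensity variability.
#'
#' @param mesh_order icosphere subdivision order (3 gives 642 vertices per
#'   hemisphere, the default working scale).
#' @param n_subjects cohort size N.
#' @param n_super_regions,n_sub_regions planted hierarchy: total level-1
#'   regions across both hemispheres, and subdivisions per level-1 region.
#' @param within_intensity mean edge count inside a deepest-level block.
#' @param between_intensity mean edge count across level-1 regions; must be
#'   below `within_intensity`.
#' @param mid_intensity mean edge count for pairs sharing a level-1 region
#'   but not a level-2 block; defaults to the geometric mean of the within
#'   and between intensities, giving a recoverable two-level structure.
#' @param label_noise fraction of vertices per subject reassigned to a
#'   neighbouring region, in \[0, 1).
#' @param edge_noise lognormal sdlog of the multiplicative edge noise
#'   (mean 1), in \[0, 1).
#' @param mirrored mirror the planted parcellation across hemispheres.
#' @param seed master seed; all cohort randomness derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(mesh_order = 3L, n_subjects = 20L,
                        n_super_regions = 8L, n_sub_regions = 3L,
                        within_intensity = 8, between_intensity = 0.5,
                        mid_intensity = NULL,
                        label_noise = 0.1, edge_noise = 0.1,
                        mirrored = TRUE, seed = 1L) {
  if (is.null(mid_intensity)) {
    mid_intensity <- sqrt(within_intensity * between_intensity)
  }
  stopifnot(within_intensity > between_intensity, between_intensity >= 0,
            label_noise >= 0, label_noise < 1,
            edge_noise >= 0, edge_noise < 1, n_subjects >= 1L)
  structure(list(mesh_order = as.integer(mesh_order),
                 n_subjects = as.integer(n_subjects),
                 n_super_regions = as.integer(n_super_regions),
                 n_sub_regions = as.integer(n_sub_regions),
                 within_intensity = within_intensity,
                 between_intensity = between_intensity,
                 mid_intensity = mid_intensity,
                 label_noise = label_noise, edge_noise = edge_noise,
                 mirrored = mirrored, seed = as.integer(seed)),
            class = "cohort_spec")
}

# farthest-point sampling of n seed vertices on a weighted graph
farthest_point_seeds <- function(dists_fun, n, k, seed) {
  first <- with_seed(seed, sample.int(k, 1L))
  seeds <- first
  dmin <- dists_fun(first)
  while (length(seeds) < n) {
    nxt <- which.max(dmin)
    seeds <- c(seeds, nxt)
    dmin <- pmin(dmin, dists_fun(nxt))
  }
  seeds
}

# graph-Voronoi labels: nearest seed by shortest-path distance, ties to the
# lower seed index; cells are contiguous by construction
voronoi_labels <- function(g, weights, seeds) {
  d <- igraph::distances(g, v = seeds, weights = weights)
  apply(d, 2, which.min) - 1L
}

#' Planted spherical Voronoi parcellation
#'
#' Farthest-point-sampled seed vertices induce graph-Voronoi regions on the
#' mesh (shortest-path distances with Euclidean edge lengths), so every
#' region is spatially contiguous. When `mirrored`, seeds are sampled on the
#' left hemisphere and reflected through the mirror map, producing a
#' perfectly symmetric parcellation (distinct labels per hemisphere).
#'
#' @param m a [surface_mesh()].
#' @param n_regions total region count (even when `mirrored`).
#' @param seed integer seed.
#' @param mirrored mirror left-hemisphere regions onto the right.
#' @return a canonical [partition()].
#' @export
planted_parcellation <- function(m, n_regions, seed = 1L, mirrored = TRUE) {
  k <- nrow(m$positions)
  if (n_regions > k / 2) stop("n_regions must be at most K/2")
  g <- mesh_adjacency(m)
  el <- igraph::as_edgelist(g, names = FALSE)
  wts <- sqrt(rowSums((m$positions[el[, 1], ] - m$positions[el[, 2], ])^2))
  if (mirrored) {
    if (n_regions %% 2L != 0L) stop("mirrored parcellation needs an even n_regions")
    left <- which(m$hemisphere == "L")
    gl <- igraph::induced_subgraph(g, left)
    ell <- igraph::as_edgelist(gl, names = FALSE)
    wl <- sqrt(rowSums((m$positions[left[ell[, 1]], ] -
                          m$positions[left[ell[, 2]], ])^2))
    dfun <- function(v) igraph::distances(gl, v = v, weights = wl)[1, ]
    seeds <- farthest_point_seeds(dfun, n_regions %/% 2L, length(left), seed)
    lab_left <- voronoi_labels(gl, wl, seeds)
    lab <- integer(k)
    lab[left] <- lab_left
    lab[m$mirror[left]] <- lab_left + n_regions %/% 2L
  } else {
    dfun <- function(v) igraph::distances(g, v = v, weights = wts)[1, ]
    seeds <- farthest_point_seeds(dfun, n_regions, k, seed)
    lab <- voronoi_labels(g, wts, seeds)
  }
  relabel_canonical(partition(lab))
}

# subdivide each region of p into n_sub graph-Voronoi cells
subdivide_partition <- function(m, p, n_sub, seed, mirrored = TRUE) {
  g <- mesh_adjacency(m)
  lab <- as.integer(p)
  out <- integer(length(lab))
  next_label <- 0L
  left <- which(m$hemisphere == "L")
  regions <- sort(unique(if (mirrored) lab[left] else lab))
  for (r in regions) {
    idx <- if (mirrored) intersect(which(lab == r), left) else which(lab == r)
    sub <- igraph::induced_subgraph(g, idx)
    el <- igraph::as_edgelist(sub, names = FALSE)
    wl <- sqrt(rowSums((m$positions[idx[el[, 1]], ] -
                          m$positions[idx[el[, 2]], ])^2))
    dfun <- function(v) igraph::distances(sub, v = v, weights = wl)[1, ]
    seeds <- farthest_point_seeds(dfun, min(n_sub, length(idx)),
                                  length(idx), derive_seed(seed, r))
    cells <- voronoi_labels(sub, wl, seeds)
    out[idx] <- next_label + cells
    if (mirrored) out[m$mirror[idx]] <- next_label + length(seeds) + cells
    next_label <- next_label + (1L + mirrored) * length(seeds)
  }
  relabel_canonical(partition(out))
}

#' Planted two-level hierarchy on a mesh
#'
#' Level 1 is a planted Voronoi parcellation with `n_super_regions` regions;
#' level 2 subdivides each region into `n_sub_regions` Voronoi cells. The
#' result is nested by construction.
#'
#' @param m a [surface_mesh()].
#' @param spec a [cohort_spec()].
#' @return a [hierarchical_partition()].
#' @export
planted_hierarchy <- function(m, spec) {
  lvl1 <- planted_parcellation(m, spec$n_super_regions,
                               seed = derive_seed(spec$seed, 1L),
                               mirrored = spec$mirrored)
  lvl2 <- subdivide_partition(m, lvl1, spec$n_sub_regions,
                              seed = derive_seed(spec$seed, 2L),
                              mirrored = spec$mirrored)
  hierarchical_partition(list(lvl1, lvl2), check_nested = TRUE)
}

#' Reassign a fraction of vertices to a neighbouring region
#'
#' Models subject-level departure from the planted parcellation: each
#' selected vertex adopts the (multi-level) labels of a randomly chosen mesh
#' neighbour belonging to a different deepest-level region, so perturbed
#' boundaries move but nesting is preserved.
#'
#' @param h a [hierarchical_partition()] (or a single [partition()]).
#' @param m the [surface_mesh()].
#' @param label_noise fraction of vertices to reassign.
#' @param seed integer seed.
#' @return perturbed object of the same class.
#' @export
perturb_hierarchy <- function(h, m, label_noise, seed = 1L) {
  single <- inherits(h, "partition")
  levels <- if (single) list(h) else h$levels
  labs <- lapply(levels, as.integer)
  deep <- labs[[length(labs)]]
  k <- length(deep)
  n_flip <- round(label_noise * k)
  if (n_flip > 0L) {
    adj <- igraph::as_adj_list(mesh_adjacency(m))
    with_seed(seed, {
      victims <- sample.int(k, n_flip)
      for (v in victims) {
        nb <- as.integer(adj[[v]])
        nb <- nb[deep[nb] != deep[v]]
        if (length(nb) == 0L) next
        donor <- nb[sample.int(length(nb), 1L)]
        for (t in seq_along(labs)) labs[[t]][v] <- labs[[t]][donor]
      }
    })
  }
  out <- lapply(labs, function(x) relabel_canonical(partition(x)))
  if (single) out[[1L]] else hierarchical_partition(out)
}

#' Simulate one subject's dense connectome
#'
#' The subject's own parcellation is the planted hierarchy perturbed by
#' `label_noise`; each unordered vertex pair then receives a Poisson edge
#' count whose mean is `within_intensity` inside a deepest block,
#' `mid_intensity` inside a level-1 region but across level-2 blocks, and
#' `between_intensity` otherwise, scaled by mean-1 lognormal noise. The
#' subject hierarchy actually used is attached as attribute
#' `"subject_hierarchy"`.
#'
#' @param m a [surface_mesh()].
#' @param hierarchy the planted [hierarchical_partition()].
#' @param spec a [cohort_spec()].
#' @param subject_seed per-subject seed; the same seed reproduces the
#'   connectome bit-exactly.
#' @return a [dense_connectome()].
#' @export
simulate_connectome <- function(m, hierarchy, spec, subject_seed) {
  noisy <- perturb_hierarchy(hierarchy, m, spec$label_noise,
                             seed = derive_seed(subject_seed, 1L))
  sup <- as.integer(noisy$levels[[1L]])
  sub <- as.integer(noisy$levels[[length(noisy$levels)]])
  k <- length(sup)
  up <- which(upper.tri(matrix(0, k, k)))
  row_i <- ((up - 1L) %% k) + 1L
  col_j <- ((up - 1L) %/% k) + 1L
  mu <- ifelse(sub[row_i] == sub[col_j], spec$within_intensity,
               ifelse(sup[row_i] == sup[col_j], spec$mid_intensity,
                      spec$between_intensity))
  vals <- with_seed(derive_seed(subject_seed, 2L), {
    x <- stats::rpois(length(mu), mu)
    if (spec$edge_noise > 0) {
      s <- spec$edge_noise
      x <- x * stats::rlnorm(length(mu), meanlog = -s^2 / 2, sdlog = s)
    }
    x
  })
  w <- matrix(0, k, k)
  w[up] <- vals
  w <- w + t(w)
  out <- dense_connectome(w, subject_id = sprintf("sim-%d", subject_seed))
  attr(out, "subject_hierarchy") <- noisy
  out
}

#' Simulate a full cohort with known ground truth
#'
#' Builds the mesh and planted hierarchy, then draws `n_subjects`
#' connectomes with independent per-subject label and edge noise. All
#' randomness derives from `spec$seed`, so the cohort is bit-reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `connectomes`,
#'   `subject_hierarchies`, `truth` (planted hierarchy), `mesh`, `manifest`.
#' @export
simulate_cohort <- function(spec) {
  mesh <- icosphere(spec$mesh_order)
  truth <- planted_hierarchy(mesh, spec)
  subject_seeds <- vapply(seq_len(spec$n_subjects),
                          function(i) derive_seed(spec$seed, 100L, i), 1L)
  connectomes <- lapply(subject_seeds, function(s)
    simulate_connectome(mesh, truth, spec, s))
  structure(list(
    connectomes = lapply(connectomes, function(w) { attr(w, "subject_hierarchy") <- NULL; w }),
    subject_hierarchies = lapply(connectomes, attr, "subject_hierarchy"),
    truth = truth, mesh = mesh,
    manifest = list(spec = unclass(spec), subject_seeds = subject_seeds)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> N = %d, K = %d, planted %d/%d regions\n",
              length(x$connectomes), nrow(x$mesh$positions),
              n_regions(x$truth$levels[[1]]),
              n_regions(x$truth$levels[[2]])))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits Matrix Market connectomes, the PLY mesh with its hemisphere
#' sidecar, ground-truth label TSVs per level, and a manifest JSON holding
#' the spec and all derived seeds.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_mesh(cohort$mesh, file.path(dir, "mesh.ply"))
  for (t in seq_along(cohort$truth$levels)) {
    save_labels(cohort$truth$levels[[t]],
                file.path(dir, sprintf("truth_level%d.tsv", t)))
  }
  for (i in seq_along(cohort$connectomes)) {
    save_connectome(cohort$connectomes[[i]],
                    file.path(dir, sprintf("subject%03d.mtx", i)))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
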