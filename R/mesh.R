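#' Two-hemisphere triangulated surface mesh
#'
#' The cortical domain is modelled as two disjoint topologically spherical
#' hemispheres sharing a vertex-wise left/right mirror correspondence.
#'
#' @param positions K x 3 numeric matrix of vertex coordinates.
#' @param triangles F x 3 integer matrix of 1-based vertex indices.
#' @param hemisphere character vector of `"L"`/`"R"`, one per vertex.
#' @param mirror integer vector: `mirror[i]` is the index of the vertex
#'   mirroring vertex `i` in the opposite hemisphere (an involution).
#' @param validate run the full invariant check (two closed 2-manifold
#'   components, Euler characteristic 2 each, mirror bijection).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(positions, triangles, hemisphere, mirror,
                         validate = TRUE) {
  positions <- as.matrix(positions)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  k <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(hemisphere) == k,
            length(mirror) == k)
  hemisphere <- as.character(hemisphere)
  if (!all(hemisphere %in% c("L", "R"))) stop("hemisphere must be 'L' or 'R'")
  mirror <- as.integer(mirror)
  m <- structure(list(positions = positions, triangles = triangles,
                      hemisphere = hemisphere, mirror = mirror),
                 class = "surface_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices (%d L / %d R), %d triangles\n",
              nrow(x$positions), sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"), nrow(x$triangles)))
  invisible(x)
}

#' Validate surface-mesh invariants
#'
#' Checks that the mesh splits into exactly two connected components, each a
#' closed triangulated surface with Euler characteristic 2, and that the
#' mirror map is an involution between equal-sized hemispheres.
#'
#' @param m a [surface_mesh()].
#' @return `TRUE` invisibly; errors describe the violated invariant.
#' @export
validate_mesh <- function(m) {
  k <- nrow(m$positions)
  if (any(m$triangles < 1L) || any(m$triangles > k)) {
    stop("triangle indices out of range")
  }
  if (!identical(m$mirror[m$mirror], seq_len(k))) {
    stop("mirror map must be an involution (a bijection between hemispheres)")
  }
  if (any(m$hemisphere[m$mirror] == m$hemisphere)) {
    stop("mirror map must connect opposite hemispheres")
  }
  if (sum(m$hemisphere == "L") != sum(m$hemisphere == "R")) {
    stop("hemispheres must have equal vertex counts")
  }
  edges <- mesh_edges(m)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no != 2L) stop("mesh must have exactly two connected components")
  # per-component Euler characteristic V - E + F = 2 (closed genus-0 surface)
  tri_comp <- comp$membership[m$triangles[, 1L]]
  edge_comp <- comp$membership[edges[, 1L]]
  for (cc in 1:2) {
    v <- sum(comp$membership == cc)
    e <- sum(edge_comp == cc)
    f <- sum(tri_comp == cc)
    if (v - e + f != 2L) {
      stop(sprintf("component %d: Euler characteristic %d != 2", cc, v - e + f))
    }
  }
  invisible(TRUE)
}

# unique undirected triangle edges as a 2-column matrix (u < v)
mesh_edges <- function(m) {
  tr <- m$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency of a surface mesh
#'
#' Two vertices are adjacent iff they share a triangle edge.
#'
#' @param m a [surface_mesh()].
#' @param as how to return the adjacency: an igraph graph or the unique
#'   edge matrix.
#' @return an `igraph` graph on the mesh vertices, or a 2-column matrix.
#' @export
mesh_adjacency <- function(m, as = c("igraph", "edges")) {
  as <- match.arg(as)
  edges <- mesh_edges(m)
  if (as == "edges") return(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::add_vertices(g, max(0L, nrow(m$positions) - igraph::vcount(g)))
}

#' Subdivided icosahedral sphere mesh (two hemispheres)
#'
#' Builds a regular icosahedron, subdivides each triangle `order` times
#' (each subdivision splits every triangle in four), and projects vertices
#' to the unit sphere. Two such spheres form the LEFT and RIGHT hemispheres;
#' the right sphere is the mirror image (x -> -x, shifted to x+3) and the
#' mirror map pairs vertices by construction index. Per sphere,
#' V = 10*4^order + 2, E = 30*4^order, F = 20*4^order; a fifth-order sphere
#' has the 10,242 vertices commonly used for resampled cortical surfaces.
#'
#' @param order subdivision order, 0 (icosahedron) to 7.
#' @return a [surface_mesh()] with `2 * (10*4^order + 2)` vertices.
#' @export
icosphere <- function(order) {
  order <- as.integer(order)
  if (order < 0L) stop("order must be >= 0")
  if (order > 7L) stop("order > 7 refused (mesh would be excessively large)")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(order)) {
    # split each edge once; midpoint indices shared between adjacent faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- e[, 1] * (nrow(v) + 1) + e[, 2]
    ue <- !duplicated(key)
    mid_id <- nrow(v) + cumsum(ue)[match(key, key)]
    mids <- (v[e[ue, 1], , drop = FALSE] + v[e[ue, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m13 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]),
               cbind(m12, m23, m13))
  }
  v <- v / sqrt(rowSums(v^2))
  k1 <- nrow(v)
  right <- v
  right[, 1] <- -right[, 1]  # mirror image; vertices stay on the unit sphere
  positions <- rbind(v, right)
  # reflected triangles are re-oriented so both components are consistently wound
  triangles <- rbind(f, f[, c(1, 3, 2)] + k1)
  surface_mesh(positions, triangles,
               hemisphere = rep(c("L", "R"), each = k1),
               mirror = c(seq_len(k1) + k1, seq_len(k1)))
}

#' Read / write a surface mesh as ascii PLY with a hemisphere sidecar
#'
#' The PLY file stores vertex coordinates and triangular faces. Hemisphere
#' assignment and the mirror correspondence have no standard PLY slot and
#' travel in a sidecar TSV (`<path>.hemi.tsv`) with columns `vertex_id`,
#' `hemisphere`, `mirror_vertex_id` (0-based ids).
#'
#' @param m a [surface_mesh()].
#' @param path the `.ply` path; the sidecar is derived from it.
#' @return [load_mesh()]: a [surface_mesh()].
#' @export
save_mesh <- function(m, path) {
  k <- nrow(m$positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment conparc surface mesh",
               sprintf("element vertex %d", k),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(m$positions, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, m$triangles - 1L), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- paste0(path, ".hemi.tsv")
  utils::write.table(
    data.frame(vertex_id = seq_len(k) - 1L,
               hemisphere = ifelse(m$hemisphere == "L", "LEFT", "RIGHT"),
               mirror_vertex_id = m$mirror - 1L),
    side, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_provenance(path, list(kind = "surface_mesh", n_vertices = k,
                              n_triangles = nrow(m$triangles)))
  invisible(path)
}

#' @rdname save_mesh
#' @export
load_mesh <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  header_end <- match("end_header", lines)
  if (is.na(header_end)) stop("PLY header missing end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)))
  body <- lines[-(seq_len(header_end))]
  pos <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  fl <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.integer))
  if (any(fl[, 1] != 3L)) stop("only triangular faces are supported")
  side <- paste0(path, ".hemi.tsv")
  if (!file.exists(side)) stop("hemisphere sidecar not found: ", side)
  tab <- utils::read.table(side, sep = "\t",
                           col.names = c("vertex_id", "hemisphere", "mirror_vertex_id"))
  ord <- order(tab$vertex_id)
  tab <- tab[ord, ]
  surface_mesh(pos, fl[, 2:4] + 1L,
               hemisphere = ifelse(tab$hemisphere == "LEFT", "L", "R"),
               mirror = tab$mirror_vertex_id + 1L)
}
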