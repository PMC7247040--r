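#' Hard partitions of mesh vertices
#'
#' A partition assigns every vertex exactly one integer label. Two partitions
#' are considered equivalent when one is a relabeling of the other; the
#' canonical form uses consecutive labels `0 ... L-1` in order of first
#' appearance, so equivalence can be tested with `identical()` after
#' [relabel_canonical()].
#'
#' Label values are 0-based (the canonical form starts at 0, matching the
#' on-disk TSV format); vertex positions are ordinary 1-based R indices.
#'
#' @param labels integer vector of nonnegative labels, one per vertex.
#' @return An object of class `partition`: an integer vector with attribute
#'   `n_regions`.
#' @examples
#' p <- partition(c(2, 2, 2, 5, 5))
#' relabel_canonical(p)  # 0 0 0 1 1
#' @export
partition <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("partition must cover at least one vertex")
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be nonnegative integers with no missing values")
  }
  structure(labels, n_regions = length(unique(labels)), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d vertices, %d regions\n", length(x), n_regions(x)))
  invisible(x)
}

#' Number of distinct regions in a partition
#' @param p a [partition()].
#' @return integer count of distinct labels.
#' @export
n_regions <- function(p) {
  length(unique(as.integer(p)))
}

#' Canonical relabeling of a partition
#'
#' Maps labels to consecutive integers `0 ... L-1` in order of first
#' appearance. Idempotent; two partitions are relabel-equivalent iff their
#' canonical forms are identical.
#'
#' @param p a [partition()] or integer label vector.
#' @return a canonical [partition()].
#' @export
relabel_canonical <- function(p) {
  lab <- as.integer(p)
  partition(match(lab, unique(lab)) - 1L)
}

#' Test relabel-equivalence of two partitions
#' @param x,y partitions over the same vertex set.
#' @return logical.
#' @export
partitions_equivalent <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  identical(as.integer(relabel_canonical(x)), as.integer(relabel_canonical(y)))
}

#' Hierarchical (multi-level) partition
#'
#' An ordered list of partitions from coarse to fine. Subject-level
#' parcellations are nested by construction (every finer region lies inside
#' one coarser region); consensus parcellations built per level are not
#' guaranteed to nest, so nesting is validated only on request.
#'
#' @param levels list of [partition()]s over a common vertex set.
#' @param check_nested assert that each level refines the previous one.
#' @return object of class `hierarchical_partition`.
#' @export
hierarchical_partition <- function(levels, check_nested = FALSE) {
  stopifnot(is.list(levels), length(levels) >= 1L)
  levels <- lapply(levels, function(p) if (inherits(p, "partition")) p else partition(p))
  k <- unique(vapply(levels, length, 1L))
  if (length(k) != 1L) stop("all levels must cover the same vertex set")
  obj <- structure(list(levels = levels), class = "hierarchical_partition")
  if (check_nested && !is_nested(obj)) stop("levels are not nested refinements")
  obj
}

#' @export
print.hierarchical_partition <- function(x, ...) {
  cat(sprintf("<hierarchical_partition> %d levels: %s regions\n",
              length(x$levels),
              paste(vapply(x$levels, n_regions, 1L), collapse = " / ")))
  invisible(x)
}

#' Does each level refine the previous one?
#' @param h a [hierarchical_partition()].
#' @return logical.
#' @export
is_nested <- function(h) {
  lv <- h$levels
  if (length(lv) < 2L) return(TRUE)
  for (t in seq_len(length(lv) - 1L)) {
    coarse <- as.integer(lv[[t]])
    fine <- as.integer(lv[[t + 1L]])
    # every fine region must sit inside exactly one coarse region
    if (anyDuplicated(unique(cbind(fine, coarse))[, 1L])) return(FALSE)
  }
  TRUE
}

#' Read / write per-vertex label TSV
#'
#' Format: two whitespace-delimited columns `vertex_id` (0-based) and
#' `label`, one row per vertex, `#` comments allowed. Labels are
#' canonicalized on load.
#'
#' @param path file path.
#' @param n_vertices optional expected vertex count; mismatch is an error.
#' @return [load_labels()]: a canonical [partition()].
#' @export
load_labels <- function(path, n_vertices = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("vertex_id", "label"),
                           colClasses = "integer")
  k <- nrow(tab)
  if (!is.null(n_vertices) && k != n_vertices) {
    stop(sprintf("expected %d vertex records, found %d", n_vertices, k))
  }
  ids <- tab$vertex_id
  if (anyDuplicated(ids)) stop("duplicate vertex ids in ", path)
  if (!setequal(ids, 0:(k - 1L))) stop("vertex ids must be 0 ... K-1 with none missing")
  lab <- integer(k)
  lab[ids + 1L] <- tab$label
  relabel_canonical(partition(lab))
}

#' @rdname load_labels
#' @param p a [partition()].
#' @param provenance optional named list recorded in a JSON sidecar.
#' @export
save_labels <- function(p, path, provenance = list()) {
  p <- relabel_canonical(p)
  utils::write.table(
    data.frame(vertex_id = seq_along(p) - 1L, label = as.integer(p)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_provenance(path, c(provenance, list(kind = "labels",
                                            n_vertices = length(p),
                                            n_regions = n_regions(p))))
  invisible(path)
}
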