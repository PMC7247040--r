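#' Dense vertex-resolution connectome
#'
#' A symmetric nonnegative K x K weight matrix over the mesh vertices, the
#' discrete analogue of the continuous connectivity intensity over the
#' cortical surface. The diagonal is structurally zero (no self-connections).
#'
#' @param weights symmetric nonnegative numeric matrix (base or `Matrix`);
#'   nonzero diagonal entries are dropped with a warning.
#' @param sparsity_fraction fraction of the heaviest edges retained, in
#'   (0, 1]; 1 means unthresholded.
#' @param subject_id optional identifier.
#' @return object of class `dense_connectome`.
#' @export
dense_connectome <- function(weights, sparsity_fraction = 1, subject_id = NA_character_) {
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop("weights must be square")
  if (anyNA(w)) stop("weights contain missing values")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (!isSymmetric(unname(w), tol = 0)) stop("weights must be exactly symmetric")
  if (any(diag(w) != 0)) {
    warning("nonzero diagonal entries dropped (self-connections are not modelled)")
    diag(w) <- 0
  }
  if (sparsity_fraction <= 0 || sparsity_fraction > 1) {
    stop("sparsity_fraction must be in (0, 1]")
  }
  dimnames(w) <- NULL
  structure(list(weights = w, sparsity_fraction = sparsity_fraction,
                 subject_id = subject_id),
            class = "dense_connectome")
}

#' @export
print.dense_connectome <- function(x, ...) {
  k <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<dense_connectome> %s: %d vertices, %d edges, sparsity %.2f\n",
              ifelse(is.na(x$subject_id), "(unnamed)", x$subject_id), k, nz,
              x$sparsity_fraction))
  invisible(x)
}

#' Read / write a dense connectome
#'
#' Matrix Market symmetric coordinate is the canonical on-disk format; a
#' whitespace-delimited edge list with columns `u v w` (0-based vertex ids,
#' `#` comments) is accepted as a dialect. If only one triangle is stored
#' the matrix is symmetrized by the elementwise maximum; diagonal entries
#' are dropped with a warning.
#'
#' @param path file path.
#' @param format `"auto"` detects Matrix Market by its `%%MatrixMarket`
#'   banner.
#' @param n_vertices vertex count K, required for edge lists whose largest
#'   referenced vertex is below K-1; optional otherwise.
#' @return [load_connectome()]: a [dense_connectome()].
#' @export
load_connectome <- function(path, format = c("auto", "matrix-market", "tsv-edgelist"),
                            n_vertices = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (startsWith(readLines(path, n = 1L), "%%MatrixMarket")) {
      "matrix-market"
    } else "tsv-edgelist"
  }
  if (format == "matrix-market") {
    w <- as.matrix(Matrix::readMM(path))
    w <- pmax(w, t(w))
  } else {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    bad <- which(lengths(fields) != 3L)
    if (length(bad)) {
      stop(sprintf("parse error at line %d of %s: expected 'u v w'",
                   which(keep)[bad[1]], path))
    }
    rec <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
    if (anyNA(rec)) {
      stop(sprintf("parse error at line %d of %s: non-numeric field",
                   which(keep)[which(rowSums(is.na(rec)) > 0)[1]], path))
    }
    if (any(rec[, 3] < 0)) stop("negative edge weight in ", path)
    k <- if (is.null(n_vertices)) max(rec[, 1:2]) + 1L else as.integer(n_vertices)
    if (any(rec[, 1:2] < 0) || any(rec[, 1:2] >= k)) {
      stop("vertex indices out of range [0, K)")
    }
    w <- matrix(0, k, k)
    w[rec[, 1:2, drop = FALSE] + 1L] <- rec[, 3]
    w <- pmax(w, t(w))
  }
  if (any(diag(w) != 0)) {
    warning("diagonal entries in ", path, " dropped")
    diag(w) <- 0
  }
  dense_connectome(w, subject_id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname load_connectome
#' @param w a [dense_connectome()].
#' @param provenance optional named list recorded in a JSON sidecar.
#' @export
save_connectome <- function(w, path, format = c("matrix-market", "tsv-edgelist"),
                            provenance = list()) {
  format <- match.arg(format)
  if (format == "matrix-market") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(w$weights, sparse = TRUE),
                                            "symmetricMatrix"), "CsparseMatrix"),
                    path)
  } else {
    idx <- which(upper.tri(w$weights) & w$weights > 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(u = idx[, 1] - 1L, v = idx[, 2] - 1L,
                 w = w$weights[idx]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_provenance(path, c(provenance,
                           list(kind = "dense_connectome",
                                n_vertices = nrow(w$weights),
                                sparsity_fraction = w$sparsity_fraction,
                                subject_id = w$subject_id)))
  invisible(path)
}

#' Retain the heaviest fraction of edges
#'
#' Keeps the heaviest fraction `q` of the nonzero off-diagonal (unordered)
#' edges, thresholding at the per-subject global weight quantile over the
#' upper triangle. All edges tied with the threshold weight are kept, so the
#' retained set can slightly exceed `q` and is monotone in `q`.
#'
#' @param w a [dense_connectome()].
#' @param q fraction of edges to keep, in (0, 1].
#' @return a [dense_connectome()] with `sparsity_fraction = q`.
#' @export
sparsify <- function(w, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1) {
    stop("q must be a single fraction in (0, 1]")
  }
  wt <- w$weights
  up <- wt[upper.tri(wt)]
  nz <- up[up > 0]
  if (q < 1 && length(nz)) {
    keep_n <- ceiling(q * length(nz))
    thr <- sort(nz, decreasing = TRUE)[keep_n]
    wt[wt < thr] <- 0
  }
  dense_connectome(wt, sparsity_fraction = q, subject_id = w$subject_id)
}
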