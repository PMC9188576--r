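# Vietoris-Rips simplicial complexes from point clouds and distance matrices.
#
# Orientation convention: every stored simplex is the ascending-index tuple of
# its vertices.  Hodge Laplacian spectra do not depend on this choice, so one
# fixed canonical orientation suffices throughout the package.

#' Ordered point cloud
#'
#' Bundles 3D coordinates with an ordered set of vertex labels.  The order of
#' the rows is meaningful: it is the chain-sequence order (residue order for
#' proteins, nucleotide order for nucleic acids) that fixes the signs of the
#' distance edge flows used by [edge_flow_from_coordinates()].
#'
#' @param coords Numeric matrix with one row per point and 3 columns
#'   (Angstrom).  A vector of length 3 is treated as a single point.
#' @param ids Optional character vector of unique vertex labels, one per
#'   point; defaults to `"1"`, `"2"`, ...
#' @return An object of class `point_cloud`: a list with elements `coords`
#'   (n x 3 numeric matrix) and `ids` (character vector).
#' @examples
#' pc <- point_cloud(cbind(0:2 * 3.8, 0, 0))
#' pc
#' @export
point_cloud <- function(coords, ids = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("'coords' must have 3 columns (x, y, z)")
  if (nrow(coords) < 1L)
    stop("a point cloud needs at least one point")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in point cloud")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  ids <- as.character(ids)
  if (length(ids) != nrow(coords))
    stop("'ids' must have one entry per point")
  if (anyDuplicated(ids))
    stop("vertex ids must be unique")
  structure(list(coords = coords, ids = ids), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$coords), "points\n")
  invisible(x)
}

#' @export
length.point_cloud <- function(x) nrow(x$coords)

# canonical string key for each row of a simplex matrix
.skey <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]), sep = " "))
}

# lexicographic row order for a simplex matrix
.lex_order <- function(m) {
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Construct a simplicial complex from explicit simplices
#'
#' Builds a simplicial complex from its maximal (or any generating) simplices;
#' all faces are added automatically so the result is closed under taking
#' faces.  Simplices are stored in canonical ascending-vertex orientation and
#' each dimension is sorted lexicographically.
#'
#' @param simplices List of integer vectors, each a set of vertex indices
#'   (1-based).  Singletons are allowed; isolated vertices up to
#'   `n_vertices` are always included as 0-simplices.
#' @param n_vertices Total number of vertices (defaults to the largest index
#'   seen).
#' @param ids Optional character vertex labels.
#' @return An object of class `simplicial_complex` with elements
#'   `n_vertices`, `max_dim`, `ids` and `simplices` — a list whose
#'   `(k+1)`-th entry is an integer matrix with `k+1` columns, one
#'   k-simplex per row.
#' @seealso [build_rips()], [guanine_graph()]
#' @export
simplicial_complex <- function(simplices, n_vertices = NULL, ids = NULL) {
  if (length(simplices) == 0L && is.null(n_vertices))
    stop("empty complex: supply simplices or 'n_vertices'")
  verts <- unlist(simplices)
  if (length(verts) && (any(verts != as.integer(verts)) || any(verts < 1L)))
    stop("vertex indices must be positive integers")
  if (is.null(n_vertices)) n_vertices <- max(verts)
  n_vertices <- as.integer(n_vertices)
  if (length(verts) && max(verts) > n_vertices)
    stop("simplex refers to vertex beyond 'n_vertices'")
  if (any(vapply(simplices, anyDuplicated, 0L) > 0L))
    stop("simplex with repeated vertex")
  max_dim <- if (length(simplices)) max(lengths(simplices)) - 1L else 0L
  # closure under faces: seed every dimension with the faces of all larger
  # generating simplices
  by_dim <- vector("list", max_dim + 1L)
  by_dim[[1L]] <- matrix(seq_len(n_vertices), ncol = 1L)
  for (k in seq_len(max_dim)) {
    rows <- list()
    for (s in simplices) {
      s <- sort(as.integer(s))
      if (length(s) >= k + 1L) {
        sub <- utils::combn(s, k + 1L)
        rows[[length(rows) + 1L]] <- t(sub)
      }
    }
    m <- if (length(rows)) unique(do.call(rbind, rows)) else
      matrix(integer(0), ncol = k + 1L)
    by_dim[[k + 1L]] <- m[.lex_order(m), , drop = FALSE]
  }
  new_simplicial_complex(by_dim, n_vertices, ids)
}

# internal constructor: trusts that 'by_dim' is face-closed, sorted, unique
new_simplicial_complex <- function(by_dim, n_vertices, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_len(n_vertices))
  structure(
    list(n_vertices = as.integer(n_vertices),
         max_dim = length(by_dim) - 1L,
         simplices = by_dim,
         ids = as.character(ids)),
    class = "simplicial_complex")
}

#' Number of simplices per dimension
#'
#' @param K A `simplicial_complex`.
#' @return Integer vector `c(n0, n1, ...)` of simplex counts by dimension.
#' @export
n_simplices <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  vapply(K$simplices, nrow, 0L)
}

#' @export
print.simplicial_complex <- function(x, ...) {
  ns <- n_simplices(x)
  cat("simplicial_complex: ",
      paste(sprintf("%d %d-simplices", ns, seq_along(ns) - 1L),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# clique enumeration under a strict-threshold adjacency matrix
.rips_from_adjacency <- function(A, max_dim, ids) {
  n <- nrow(A)
  diag(A) <- FALSE
  by_dim <- list(matrix(seq_len(n), ncol = 1L))
  if (max_dim >= 1L) {
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    edges <- matrix(as.integer(idx), ncol = 2L)
    edges <- edges[.lex_order(edges), , drop = FALSE]
    by_dim[[2L]] <- edges
  }
  if (max_dim >= 2L) {
    edges <- by_dim[[2L]]
    tri <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      ks <- which(A[i, ] & A[j, ])
      ks <- ks[ks > j]
      if (length(ks))
        tri[[e]] <- cbind(i, j, as.integer(ks), deparse.level = 0)
    }
    tri <- if (any(lengths(tri) > 0)) do.call(rbind, tri) else
      matrix(integer(0), ncol = 3L)
    storage.mode(tri) <- "integer"
    by_dim[[3L]] <- tri[.lex_order(tri), , drop = FALSE]
  }
  if (max_dim >= 3L) {
    tris <- by_dim[[3L]]
    tet <- vector("list", nrow(tris))
    for (e in seq_len(nrow(tris))) {
      i <- tris[e, 1L]; j <- tris[e, 2L]; k <- tris[e, 3L]
      ls <- which(A[i, ] & A[j, ] & A[k, ])
      ls <- ls[ls > k]
      if (length(ls))
        tet[[e]] <- cbind(i, j, k, as.integer(ls), deparse.level = 0)
    }
    tet <- if (any(lengths(tet) > 0)) do.call(rbind, tet) else
      matrix(integer(0), ncol = 4L)
    storage.mode(tet) <- "integer"
    by_dim[[4L]] <- tet[.lex_order(tet), , drop = FALSE]
  }
  list(by_dim = by_dim, n = n, ids = ids)
}

#' Vietoris-Rips complex of a point cloud
#'
#' A k-simplex is included iff all pairwise Euclidean distances among its
#' `k+1` vertices are strictly below `cutoff`; the complex is closed under
#' faces by the clique construction.  Distances exactly equal to the cutoff do
#' not create a simplex.
#'
#' @param points A [point_cloud()] (or a bare coordinate matrix).
#' @param cutoff Positive distance threshold in the units of the coordinates
#'   (Angstrom for structures).
#' @param max_dim Highest simplex dimension to enumerate, between 0 and 3.
#'   The default 2 (triangles) covers HodgeRank curl flows; use 3 when the
#'   second Betti number (cavities) is needed.
#' @return A `simplicial_complex`.
#' @examples
#' chain <- straight_chain(5, spacing = 1)
#' build_rips(chain, cutoff = 1.5)
#' @export
build_rips <- function(points, cutoff, max_dim = 2L) {
  if (!inherits(points, "point_cloud")) points <- point_cloud(points)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("'cutoff' must be a single positive number")
  max_dim <- as.integer(max_dim)
  if (max_dim < 0L || max_dim > 3L)
    stop("'max_dim' must be between 0 and 3")
  D <- as.matrix(stats::dist(points$coords))
  r <- .rips_from_adjacency(D < cutoff, max_dim, points$ids)
  K <- new_simplicial_complex(r$by_dim, r$n, r$ids)
  attr(K, "cutoff") <- cutoff
  K
}

#' Vietoris-Rips complex from a distance matrix
#'
#' Same strict-threshold clique rule as [build_rips()], but over supplied
#' dissimilarities — typically the alpha-reciprocal distances of a Hi-C
#' contact matrix (see [contact_to_distance()]).  Entries may be `Inf`,
#' meaning the pair can never form an edge.
#'
#' @param dist Square symmetric numeric matrix, nonnegative off the diagonal.
#' @param cutoff Positive distance threshold (strict `<`).
#' @param max_dim Highest simplex dimension, 0 to 3.
#' @param ids Optional vertex labels.
#' @return A `simplicial_complex`.
#' @export
build_rips_from_distances <- function(dist, cutoff, max_dim = 2L, ids = NULL) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist))
    stop("distance matrix must be square")
  if (nrow(dist) < 1L)
    stop("distance matrix needs at least one point")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("'cutoff' must be a single positive number")
  max_dim <- as.integer(max_dim)
  if (max_dim < 0L || max_dim > 3L)
    stop("'max_dim' must be between 0 and 3")
  off <- dist[upper.tri(dist) | lower.tri(dist)]
  if (any(is.na(off)) || any(off < 0))
    stop("off-diagonal distances must be nonnegative (Inf allowed)")
  fin <- is.finite(dist) & is.finite(t(dist))
  if (any(abs(dist[fin] - t(dist)[fin]) >
          1e-8 * max(1, max(dist[fin], 0))))
    stop("distance matrix is not symmetric")
  A <- dist < cutoff
  A[!is.finite(dist)] <- FALSE
  A <- A & t(A)
  if (is.null(ids)) ids <- rownames(dist)
  r <- .rips_from_adjacency(A, max_dim, ids %||% as.character(seq_len(nrow(dist))))
  K <- new_simplicial_complex(r$by_dim, r$n, r$ids)
  attr(K, "cutoff") <- cutoff
  K
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# row index of simplex 's' within the dimension-k table of K, NA if absent
.simplex_row <- function(K, s) {
  s <- sort(as.integer(s))
  k <- length(s) - 1L
  if (k > K$max_dim) return(NA_integer_)
  match(paste(s, collapse = " "), .skey(K$simplices[[k + 1L]]))
}

#' Upper degree of a simplex
#'
#' The number of `(k+1)`-simplices of the complex having the given k-simplex
#' as a face.
#'
#' @param K A `simplicial_complex`.
#' @param s Integer vector of vertex indices identifying a simplex of `K`.
#' @return Integer count.
#' @export
upper_degree <- function(K, s) {
  stopifnot(inherits(K, "simplicial_complex"))
  s <- sort(as.integer(s))
  if (is.na(.simplex_row(K, s)))
    stop("simplex [", paste(s, collapse = ","), "] is not in the complex")
  k <- length(s) - 1L
  if (k + 1L > K$max_dim) return(0L)
  up <- K$simplices[[k + 2L]]
  if (nrow(up) == 0L) return(0L)
  sum(apply(up, 1L, function(r) all(s %in% r)))
}

#' Write a simplicial complex as TSV
#'
#' One simplex per line: dimension, then tab-separated vertex indices.
#'
#' @param K A `simplicial_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex_tsv <- function(K, path) {
  stopifnot(inherits(K, "simplicial_complex"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in 0:K$max_dim) {
    m <- K$simplices[[k + 1L]]
    for (r in seq_len(nrow(m)))
      writeLines(paste(c(k, m[r, ]), collapse = "\t"), con)
  }
  invisible(path)
}
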