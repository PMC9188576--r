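# Boundary matrices, combinatorial Hodge Laplacians and their spectra.

#' Signed boundary matrix B_k
#'
#' The matrix of the boundary map from k-chains to (k-1)-chains under the
#' canonical ascending-vertex orientation: the column of a k-simplex
#' `[u0, ..., uk]` carries `(-1)^i` in the row of the face obtained by
#' dropping vertex `ui`.  Rows are indexed by the (k-1)-simplices of the
#' complex, columns by its k-simplices, both in stored (lexicographic) order.
#'
#' @param K A `simplicial_complex`.
#' @param k Dimension, `1 <= k <= K$max_dim`.
#' @return A sparse `Matrix::sparseMatrix` with entries in \{-1, 0, 1\}.
#' @examples
#' tri <- simplicial_complex(list(1:3))     # filled triangle
#' as.matrix(boundary_matrix(tri, 2))
#' @export
boundary_matrix <- function(K, k) {
  stopifnot(inherits(K, "simplicial_complex"))
  k <- as.integer(k)
  if (k < 1L || k > K$max_dim)
    stop("'k' must be between 1 and max_dim = ", K$max_dim)
  lower <- K$simplices[[k]]
  upper <- K$simplices[[k + 1L]]
  nr <- nrow(lower)
  nc <- nrow(upper)
  if (nc == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nr, 0L)))
  keys <- .skey(lower)
  ii <- jj <- xx <- vector("list", k + 1L)
  for (drop in seq_len(k + 1L)) {
    face <- upper[, -drop, drop = FALSE]
    ii[[drop]] <- match(.skey(face), keys)
    jj[[drop]] <- seq_len(nc)
    xx[[drop]] <- rep((-1)^(drop - 1L), nc)
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  if (anyNA(i))
    stop("complex is not face-closed")   # cannot happen for package-built complexes
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nr, nc))
}

#' Combinatorial Hodge Laplacian L_k
#'
#' `L_0 = B_1 B_1^T` (the graph Laplacian of the 1-skeleton);
#' `L_k = B_k^T B_k + B_{k+1} B_{k+1}^T` for intermediate dimensions; the
#' upper term vanishes at the top dimension.  The matrix is symmetric
#' positive semi-definite and its spectrum does not depend on the orientation
#' convention.
#'
#' @param K A `simplicial_complex`.
#' @param k Dimension, `0 <= k <= K$max_dim`.
#' @return A symmetric sparse Matrix over the k-simplices of `K`.
#' @export
hodge_laplacian <- function(K, k) {
  stopifnot(inherits(K, "simplicial_complex"))
  k <- as.integer(k)
  if (k < 0L || k > K$max_dim)
    stop("'k' must be between 0 and max_dim = ", K$max_dim)
  nk <- nrow(K$simplices[[k + 1L]])
  L <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nk, nk))
  if (k >= 1L) {
    Bk <- boundary_matrix(K, k)
    L <- L + Matrix::crossprod(Bk)
  }
  if (k < K$max_dim) {
    Bk1 <- boundary_matrix(K, k + 1L)
    L <- L + Matrix::tcrossprod(Bk1)
  }
  L
}

#' Eigendecomposition of a Hodge Laplacian
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order.
#' The multiplicity of the (numerically) zero eigenvalue is the Betti number
#' of the corresponding dimension: the number of connected components for
#' `L_0`, of independent loops for `L_1`, of cavities for `L_2`.
#'
#' @param L Symmetric matrix, as returned by [hodge_laplacian()].
#' @param zero_tol Threshold below which an eigenvalue counts as zero.
#'   Default `1e-8 * max(1, lambda_max)`, a relative threshold that is robust
#'   across complex sizes.
#' @return An object of class `hl_spectrum`: list with `values` (ascending),
#'   `vectors` (orthonormal columns, matching order), `zero_tol` and `betti`.
#' @examples
#' sq <- simplicial_complex(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
#' hodge_spectrum(hodge_laplacian(sq, 1))$betti   # one loop
#' @export
hodge_spectrum <- function(L, zero_tol = NULL) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("'L' must be square")
  if (nrow(L) == 0L)
    return(structure(list(values = numeric(0),
                          vectors = matrix(0, 0, 0),
                          zero_tol = zero_tol %||% 1e-8, betti = 0L),
                     class = "hl_spectrum"))
  if (max(abs(L - t(L))) > 1e-8 * max(1, max(abs(L))))
    stop("'L' is not symmetric")
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(e$values))      # eigen() returns decreasing
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  if (is.null(zero_tol)) zero_tol <- 1e-8 * max(1, values[length(values)])
  if (values[1L] < -zero_tol)
    stop("matrix is not positive semi-definite within tolerance")
  betti <- sum(abs(values) < zero_tol)
  structure(list(values = values, vectors = vectors,
                 zero_tol = zero_tol, betti = as.integer(betti)),
            class = "hl_spectrum")
}

#' @export
print.hl_spectrum <- function(x, ...) {
  cat("hl_spectrum:", length(x$values), "eigenvalues, betti =", x$betti, "\n")
  invisible(x)
}

#' Homology generators (zero-eigenvalue eigenvectors)
#'
#' Returns the entrywise magnitudes of the eigenvectors spanning the kernel
#' of the Laplacian.  For `L_1` the large-magnitude entries localise on the
#' edges of the loops the generator represents.  When the zero eigenvalue is
#' degenerate the individual vectors are an arbitrary orthonormal basis of
#' the kernel; compare kernels via their projectors, not vector by vector.
#'
#' @param S An `hl_spectrum`.
#' @return List of numeric magnitude vectors, one per zero eigenvalue
#'   (empty when the Betti number is 0).
#' @export
homology_generators <- function(S) {
  stopifnot(inherits(S, "hl_spectrum"))
  if (S$betti == 0L) return(list())
  lapply(seq_len(S$betti), function(i) abs(S$vectors[, i]))
}

#' Eigenvectors of the smallest nonzero eigenvalues
#'
#' The non-homological low end of the spectrum; for `L_0` the first of these
#' is the Fiedler vector, whose sign pattern splits the complex into
#' communities (spectral clustering).
#'
#' @param S An `hl_spectrum`.
#' @param count Number of eigenvectors requested.
#' @return List of `count` eigenvectors in ascending eigenvalue order.
#' @export
nonhomology_eigenvectors <- function(S, count) {
  stopifnot(inherits(S, "hl_spectrum"))
  count <- as.integer(count)
  avail <- length(S$values) - S$betti
  if (count < 0L || count > avail)
    stop("'count' exceeds the ", avail, " nonzero eigenvalues available")
  lapply(seq_len(count), function(i) S$vectors[, S$betti + i])
}

#' Write a spectrum as TSV
#'
#' One row per eigenvalue; with `vectors = TRUE` the eigenvector components
#' follow in additional columns.
#'
#' @param S An `hl_spectrum`.
#' @param path Output file path.
#' @param vectors Include eigenvector columns?
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(S, path, vectors = FALSE) {
  stopifnot(inherits(S, "hl_spectrum"))
  tab <- data.frame(eigenvalue = S$values)
  if (vectors && length(S$values))
    tab <- cbind(tab, as.data.frame(t(S$vectors)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
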