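# HodgeRank: sequence-signed edge flows, the gradient/curl/harmonic
# orthogonal decomposition, and the total/average inconsistency indices.
#
# Edge flows are stored as one value per canonical edge [i, j] with i < j in
# sequence order; the value on the reversed edge is its negative
# (antisymmetry), so a single number per unordered edge suffices.

#' Distance edge flow of an ordered chain
#'
#' For each edge `[i, j]` (`i < j` in sequence order) of the complex, the
#' flow value is the Euclidean distance `|r_i - r_j|`.  Flows are therefore
#' positive along the chain sequence and negative against it, which encodes
#' the chain ordering into the flow signs.  A perfectly straight chain yields
#' a pure gradient flow (potential = arclength position) and hence zero
#' inconsistency downstream.
#'
#' @param points A [point_cloud()]; row order is the sequence order.
#' @param K A `simplicial_complex` on the same vertices, typically from
#'   [build_rips()].
#' @return Numeric vector, one value per edge of `K` in stored edge order
#'   (class `edge_flow`).
#' @export
edge_flow_from_coordinates <- function(points, K) {
  stopifnot(inherits(points, "point_cloud"), inherits(K, "simplicial_complex"))
  if (K$n_vertices != nrow(points$coords))
    stop("complex and point cloud disagree on the number of vertices")
  edges <- K$simplices[[2L]]
  if (is.null(edges)) stop("complex has no edge dimension")
  d <- sqrt(rowSums((points$coords[edges[, 1L], , drop = FALSE] -
                     points$coords[edges[, 2L], , drop = FALSE])^2))
  zero <- which(d <= 1e-12)
  if (length(zero))
    stop("coincident vertices on edge [",
         paste(edges[zero[1L], ], collapse = ","),
         "]: distance flow (and TI) undefined")
  structure(d, class = "edge_flow")
}

# conjugate gradient for consistent PSD systems.  The right-hand sides here
# lie in range(A) up to rounding; the rounding component sits in the kernel
# and makes CG semi-convergent (the residual bottoms out near machine
# precision and then drifts up), so the best iterate is tracked and
# returned.  'atol' is an absolute residual target: for a flow whose curl
# (or gradient) content is exactly zero, b itself is rounding noise and a
# residual relative to |b| would be meaningless.
.cg_solve <- function(amul, b, atol, maxit = length(b) * 10L) {
  x <- numeric(length(b))
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = x, resid = 0, iter = 0L))
  r <- b
  p <- r
  rs <- sum(r * r)
  best_x <- x
  best_rs <- rs
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Ap <- amul(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break                 # numerical kernel direction
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(r * r)
    if (rs2 < best_rs) { best_rs <- rs2; best_x <- x }
    if (sqrt(rs2) <= atol || iter >= maxit) break
    if (rs2 > 1e8 * best_rs) break      # semi-convergent drift: give up
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  list(x = best_x, resid = sqrt(best_rs), iter = iter)
}

# connected components of the 1-skeleton (label per vertex)
.components <- function(K) {
  n <- K$n_vertices
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  edges <- K$simplices[[2L]]
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, 0L)
}

#' HodgeRank decomposition of an edge flow
#'
#' Orthogonally splits an edge flow `Y` into a gradient part
#' `Y^g` (the flow of a vertex potential, globally consistent), a curl part
#' `Y^c` (supported on triangles, locally cyclic) and a harmonic remainder
#' `Y^h` (divergence-free and curl-free, one dimension per independent
#' 1-cycle).  The gradient part solves the least-squares potential problem
#' on the graph Laplacian; the curl part projects onto the image of the
#' triangle boundary map.  With no 2-simplices the curl part is identically
#' zero.
#'
#' Both projections are computed by conjugate gradients on the (consistent,
#' positive semi-definite) normal equations; relative residuals are returned
#' and a failure to converge raises an error.
#'
#' @param Y Numeric edge flow, one value per edge of `K` (canonical `i < j`
#'   orientation).
#' @param K A `simplicial_complex` with at least one edge.
#' @param tol Relative conjugate-gradient tolerance.
#' @param maxit Maximum iterations (default `10 *` number of edges).
#' @return Object of class `hodge_decomposition`: list with `gradient`,
#'   `curl`, `harmonic` (edge vectors), `potential` (vertex scores, zero
#'   mean within each connected component) and `residuals`.
#' @examples
#' tri <- simplicial_complex(list(1:3))
#' hodge_decompose(c(2, -1, 1), tri)$curl     # (4/3, -4/3, 4/3)
#' @export
hodge_decompose <- function(Y, K, tol = 1e-12, maxit = NULL) {
  stopifnot(inherits(K, "simplicial_complex"))
  if (K$max_dim < 1L) stop("complex has no edges")
  edges <- K$simplices[[2L]]
  m <- nrow(edges)
  if (m == 0L) stop("complex has no edges")
  Y <- as.numeric(Y)
  if (length(Y) != m)
    stop("flow length ", length(Y), " does not match ", m, " edges")
  if (!all(is.finite(Y))) stop("non-finite flow values")
  if (is.null(maxit)) maxit <- max(100L, 10L * m)

  nY <- sqrt(sum(Y * Y))
  atol <- tol * max(1, nY)
  B1 <- boundary_matrix(K, 1L)                     # vertices x edges
  L0 <- Matrix::tcrossprod(B1)
  # potential convention: Y^g on edge [i,j] = s_i - s_j (ranking order),
  # i.e. gradient operator G = -B1^T; normal equations L0 s = -B1 Y
  b <- -as.numeric(B1 %*% Y)
  sol_g <- .cg_solve(function(x) as.numeric(L0 %*% x), b, atol, maxit)
  if (sol_g$resid > 1e-8 * max(1, nY))
    stop("gradient projection did not converge (residual ",
         format(sol_g$resid), ")")
  s <- sol_g$x
  comp <- .components(K)
  s <- s - stats::ave(s, comp)                     # zero mean per component
  Yg <- -as.numeric(Matrix::crossprod(B1, s))

  if (K$max_dim >= 2L && nrow(K$simplices[[3L]]) > 0L) {
    B2 <- boundary_matrix(K, 2L)                   # edges x triangles
    b2 <- as.numeric(Matrix::crossprod(B2, Y))
    sol_c <- .cg_solve(function(x)
      as.numeric(Matrix::crossprod(B2, B2 %*% x)), b2, atol, maxit)
    if (sol_c$resid > 1e-8 * max(1, nY))
      stop("curl projection did not converge (residual ",
           format(sol_c$resid), ")")
    Yc <- as.numeric(B2 %*% sol_c$x)
    res_c <- sol_c$resid
  } else {
    Yc <- numeric(m)
    res_c <- 0
  }
  structure(list(gradient = Yg, curl = Yc, harmonic = Y - Yg - Yc,
                 potential = s,
                 residuals = c(gradient = sol_g$resid, curl = res_c)),
            class = "hodge_decomposition")
}

#' @export
print.hodge_decomposition <- function(x, ...) {
  nrm <- function(v) sqrt(sum(v^2))
  cat("hodge_decomposition over", length(x$gradient), "edges\n")
  cat(sprintf("  |Y^g| = %.4g  |Y^c| = %.4g  |Y^h| = %.4g\n",
              nrm(x$gradient), nrm(x$curl), nrm(x$harmonic)))
  invisible(x)
}

#' Total and average inconsistency of an edge flow
#'
#' `TI = sum over edges of |(Y^c + Y^h) / Y|`, each unordered edge counted
#' once (the absolute value makes the orientation irrelevant), and
#' `AI = TI / N` with `N` the number of vertices of the complex.  TI is zero
#' exactly when the flow is a pure gradient — for distance flows, when the
#' chain has no curvedness or folding — and grows with the cyclic
#' (curl + harmonic) content of the flow, i.e. with the compactness of the
#' structure.
#'
#' @param Y The original edge flow.
#' @param D Its [hodge_decompose()] result.
#' @param K The `simplicial_complex` the flow lives on.
#' @return Object of class `inconsistency_scores`: list with `TI`, `AI`,
#'   `N`, `n_edges`, `n_triangles`.
#' @export
total_inconsistency <- function(Y, D, K) {
  stopifnot(inherits(D, "hodge_decomposition"),
            inherits(K, "simplicial_complex"))
  Y <- as.numeric(Y)
  eps <- 1e-12
  bad <- which(abs(Y) <= eps)
  if (length(bad)) {
    e <- K$simplices[[2L]][bad[1L], ]
    stop("flow magnitude below ", eps, " on edge [",
         paste(e, collapse = ","), "]: inconsistency undefined")
  }
  TI <- sum(abs((D$curl + D$harmonic) / Y))
  N <- K$n_vertices
  structure(list(TI = TI, AI = TI / N, N = N,
                 n_edges = nrow(K$simplices[[2L]]),
                 n_triangles = if (K$max_dim >= 2L) nrow(K$simplices[[3L]]) else 0L),
            class = "inconsistency_scores")
}

#' @export
print.inconsistency_scores <- function(x, ...) {
  cat(sprintf(
    "TI = %.6g  AI = %.6g  (N = %d, %d edges, %d triangles)\n",
    x$TI, x$AI, x$N, x$n_edges, x$n_triangles))
  invisible(x)
}

#' One-call inconsistency of a structure
#'
#' Convenience pipeline: Rips complex at `cutoff` (dimension 2), distance
#' edge flow, HodgeRank decomposition, TI/AI.
#'
#' @param points A [point_cloud()] in chain-sequence order.
#' @param cutoff Rips cutoff distance (Angstrom).
#' @param max_dim Highest simplex dimension (default 2).
#' @return An `inconsistency_scores` object.
#' @examples
#' structure_inconsistency(straight_chain(20), cutoff = 11)$TI   # 0
#' @export
structure_inconsistency <- function(points, cutoff, max_dim = 2L) {
  K <- build_rips(points, cutoff, max_dim)
  Y <- edge_flow_from_coordinates(points, K)
  D <- hodge_decompose(Y, K)
  total_inconsistency(Y, D, K)
}

#' Inconsistency profile along a trajectory
#'
#' Applies [structure_inconsistency()] to each frame of a conformational
#' trajectory (e.g. a folding pathway); frames are processed independently
#' and must share the same chain ordering.
#'
#' @param trajectory List of [point_cloud()] frames.
#' @param cutoff Rips cutoff distance (Angstrom).
#' @param max_dim Highest simplex dimension (default 2).
#' @return `data.frame` with one row per frame: `frame`, `TI`, `AI`, `N`,
#'   `n_edges`, `n_triangles`.
#' @export
folding_profile <- function(trajectory, cutoff, max_dim = 2L) {
  stopifnot(length(trajectory) >= 1L)
  rows <- lapply(seq_along(trajectory), function(f) {
    sc <- structure_inconsistency(trajectory[[f]], cutoff, max_dim)
    data.frame(frame = f, TI = sc$TI, AI = sc$AI, N = sc$N,
               n_edges = sc$n_edges, n_triangles = sc$n_triangles)
  })
  do.call(rbind, rows)
}

#' Write a decomposition as TSV
#'
#' One row per edge: vertex indices `i`, `j` and the flow values `Y`, `Yg`,
#' `Yc`, `Yh`.
#'
#' @param K The complex.
#' @param Y The original flow.
#' @param D Its decomposition.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_decomposition_tsv <- function(K, Y, D, path) {
  edges <- K$simplices[[2L]]
  tab <- data.frame(i = edges[, 1L], j = edges[, 2L], Y = as.numeric(Y),
                    Yg = D$gradient, Yc = D$curl, Yh = D$harmonic)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
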