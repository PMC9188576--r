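# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force subset enumeration for Rips
# complexes, the entrywise adjacency table for Hodge Laplacians, and dense
# SVD pseudo-inverse projections for the flow decomposition.

# brute-force Rips: every vertex subset of size <= max_dim + 1 whose pairwise
# distances are all strictly below the cutoff
brute_rips <- function(D, cutoff, max_dim) {
  n <- nrow(D)
  out <- list(matrix(seq_len(n), ncol = 1L))
  for (k in seq_len(max_dim)) {
    keep <- list()
    if (n >= k + 1) {
      subsets <- utils::combn(n, k + 1)
      for (c0 in seq_len(ncol(subsets))) {
        s <- subsets[, c0]
        pd <- D[s, s][upper.tri(diag(length(s)))]
        if (all(pd < cutoff)) keep[[length(keep) + 1L]] <- s
      }
    }
    m <- if (length(keep)) do.call(rbind, keep) else
      matrix(integer(0), ncol = k + 1L)
    storage.mode(m) <- "integer"
    out[[k + 1L]] <- m[do.call(order, lapply(seq_len(ncol(m)),
                                             function(j) m[, j])), ,
                       drop = FALSE]
  }
  out
}

simplex_keys <- function(m) apply(m, 1L, paste, collapse = " ")

# entrywise Hodge Laplacian from the simplex-adjacency rules (diagonal =
# upper degree + k + 1; off-diagonal +/-1 by lower-adjacency and orientation
# similarity, 0 when upper-adjacent); independent of boundary products
entrywise_laplacian <- function(K, k) {
  S <- K$simplices[[k + 1L]]
  nk <- nrow(S)
  L <- matrix(0, nk, nk)
  upper <- if (k + 1L <= K$max_dim) K$simplices[[k + 2L]] else
    matrix(integer(0), ncol = k + 2L)
  upkeys <- simplex_keys(upper)
  updeg <- function(s) {
    if (nrow(upper) == 0L) return(0L)
    sum(apply(upper, 1L, function(r) all(s %in% r)))
  }
  if (k == 0L) {
    for (i in seq_len(nk)) L[i, i] <- updeg(S[i, ])
    edges <- if (K$max_dim >= 1L) K$simplices[[2L]] else
      matrix(integer(0), ncol = 2L)
    for (e in seq_len(nrow(edges))) {
      L[edges[e, 1L], edges[e, 2L]] <- -1
      L[edges[e, 2L], edges[e, 1L]] <- -1
    }
    return(L)
  }
  for (i in seq_len(nk)) {
    L[i, i] <- updeg(S[i, ]) + k + 1L
    for (j in seq_len(nk)) {
      if (i == j) next
      si <- S[i, ]; sj <- S[j, ]
      shared <- intersect(si, sj)
      if (length(shared) != k) next                      # not lower adjacent
      un <- sort(union(si, sj))
      if (length(un) == k + 2L &&
          paste(un, collapse = " ") %in% upkeys) next    # upper adjacent
      pa <- which(si == setdiff(si, shared))
      pb <- which(sj == setdiff(sj, shared))
      L[i, j] <- if ((pa + pb) %% 2L == 0L) 1 else -1
    }
  }
  L
}

# orthogonal projector onto the column space of A (dense SVD)
colspace_project <- function(A, y) {
  A <- as.matrix(A)
  if (ncol(A) == 0L) return(numeric(length(y)))
  sv <- svd(A)
  r <- sum(sv$d > 1e-10 * max(sv$d, 1))
  U <- sv$u[, seq_len(r), drop = FALSE]
  as.numeric(U %*% crossprod(U, y))
}

# decomposition oracle: explicit projections using stacked dense bases
oracle_decompose <- function(Y, K) {
  B1 <- as.matrix(boundary_matrix(K, 1L))
  G <- -t(B1)
  Yg <- colspace_project(G, Y)
  if (K$max_dim >= 2L && nrow(K$simplices[[3L]]) > 0L) {
    B2 <- as.matrix(boundary_matrix(K, 2L))
    Yc <- colspace_project(B2, Y)
  } else Yc <- numeric(length(Y))
  list(gradient = Yg, curl = Yc, harmonic = Y - Yg - Yc)
}

mat_rank <- function(A) {
  A <- as.matrix(A)
  if (length(A) == 0L) return(0L)
  qr(A)$rank
}

# random point cloud + Rips complex (small, for property sweeps)
random_rips <- function(seed, n_max = 12L, max_dim = 2L) {
  withr::with_seed(seed, {
    n <- sample(4:n_max, 1L)
    coords <- matrix(stats::runif(3L * n), ncol = 3L)
    cutoff <- stats::runif(1L, 0.3, 0.9)
    list(points = point_cloud(coords), cutoff = cutoff,
         K = build_rips(point_cloud(coords), cutoff, max_dim))
  })
}

# carry a physical edge flow across a vertex relabeling: vertex v of the
# permuted complex is original vertex perm[v]; the stored value flips sign
# when the permutation reverses the canonical order of the pair
relabel_flow <- function(Y, K, perm, K2) {
  edges2 <- K2$simplices[[2L]]
  keys1 <- simplex_keys(K$simplices[[2L]])
  Y2 <- numeric(nrow(edges2))
  for (e in seq_len(nrow(edges2))) {
    a <- perm[edges2[e, 1L]]
    b <- perm[edges2[e, 2L]]
    idx <- match(paste(sort(c(a, b)), collapse = " "), keys1)
    Y2[e] <- if (a < b) Y[idx] else -Y[idx]
  }
  Y2
}

# kernel projector of a spectrum's zero eigenspace
kernel_projector <- function(S) {
  if (S$betti == 0L) return(matrix(0, nrow(S$vectors), nrow(S$vectors)))
  V <- S$vectors[, seq_len(S$betti), drop = FALSE]
  tcrossprod(V)
}
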