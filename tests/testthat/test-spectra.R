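test_that("boundary matrices follow the alternating-sign rule", {
  K <- fixture_filled_triangle()
  B2 <- as.matrix(boundary_matrix(K, 2L))
  # edges stored as [1,2], [1,3], [2,3]; boundary of [1,2,3] = [2,3] - [1,3] + [1,2]
  expect_equal(as.numeric(B2), c(1, -1, 1))

  B1 <- as.matrix(boundary_matrix(fixture_path3(), 1L))
  expect_equal(B1, rbind(c(-1, 0), c(1, -1), c(0, 1)), ignore_attr = TRUE)

  expect_error(boundary_matrix(K, 0L), "between 1 and")
  expect_error(boundary_matrix(K, 3L), "between 1 and")
})

test_that("the composite boundary map vanishes (del o del = 0)", {
  for (seed in c(2, 13, 31)) {
    K <- random_rips(seed, max_dim = 3L)$K
    for (k in seq_len(K$max_dim - 1L)) {
      Bk <- boundary_matrix(K, k)
      Bk1 <- boundary_matrix(K, k + 1L)
      if (ncol(Bk) && ncol(Bk1))
        expect_lt(max(abs(Bk %*% Bk1)), 1e-12)
    }
  }
})

test_that("L_0 is the graph Laplacian", {
  L0 <- as.matrix(hodge_laplacian(fixture_path3(), 0L))
  expect_equal(L0, rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
})

test_that("Laplacians from boundary products match the entrywise table", {
  # hollow triangle: no upper simplices, diagonal d(sigma) + 2 = 2
  K <- fixture_hollow_triangle()
  expect_equal(as.matrix(hodge_laplacian(K, 1L)), entrywise_laplacian(K, 1L),
               ignore_attr = TRUE)
  expect_equal(diag(entrywise_laplacian(K, 1L)), rep(2, 3))

  for (seed in 1:20) {
    K <- random_rips(seed, n_max = 12L, max_dim = 2L)$K
    for (k in 0:2)
      expect_equal(as.matrix(hodge_laplacian(K, k)),
                   entrywise_laplacian(K, k), ignore_attr = TRUE,
                   tolerance = 1e-12)
  }
})

test_that("zero-eigenvalue multiplicities are Betti numbers", {
  # 4-cycle: one component, one loop
  sq <- fixture_square()
  expect_equal(hodge_spectrum(hodge_laplacian(sq, 0L))$betti, 1L)
  expect_equal(hodge_spectrum(hodge_laplacian(sq, 1L))$betti, 1L)

  # filling the triangle kills the loop
  expect_equal(hodge_spectrum(hodge_laplacian(fixture_filled_triangle(), 1L))$betti, 0L)

  # guanine: two fused rings
  g <- guanine_graph()
  expect_equal(hodge_spectrum(hodge_laplacian(g, 1L))$betti, 2L)
})

test_that("spectra are PSD, ascending, and orientation invariant", {
  for (seed in c(4, 17, 23)) {
    K <- random_rips(seed)$K
    for (k in 0:K$max_dim) {
      L <- hodge_laplacian(K, k)
      if (nrow(L) == 0L) next
      S <- hodge_spectrum(L)
      expect_true(all(diff(S$values) >= -1e-12))
      expect_gt(min(S$values), -1e-9 * max(1, max(S$values)))
      # flip the orientation of a random subset of k-simplices and of
      # (k+1)-simplices: the spectrum must not move
      if (k >= 1L) {
        nk <- nrow(K$simplices[[k + 1L]])
        flip <- withr::with_seed(seed, sample(c(-1, 1), nk, replace = TRUE))
        Bk <- boundary_matrix(K, k) %*% Matrix::Diagonal(x = flip)
        L2 <- Matrix::crossprod(Bk)
        if (k < K$max_dim) {
          Bk1 <- Matrix::Diagonal(x = flip) %*% boundary_matrix(K, k + 1L)
          L2 <- L2 + Matrix::tcrossprod(Bk1)
        }
        S2 <- hodge_spectrum(L2)
        expect_equal(S2$values, S$values, tolerance = 1e-9)
      }
    }
  }
})

test_that("Betti numbers agree with rank-nullity and component counts", {
  for (seed in 1:50) {
    K <- random_rips(seed, n_max = 12L, max_dim = 2L)$K
    ns <- n_simplices(K)
    ranks <- c(0L, vapply(seq_len(K$max_dim), function(k)
      mat_rank(boundary_matrix(K, k)), 0L), 0L)
    for (k in 0:K$max_dim) {
      betti_rank <- ns[k + 1L] - ranks[k + 1L] - ranks[k + 2L]
      S <- hodge_spectrum(hodge_laplacian(K, k))
      expect_equal(S$betti, as.integer(betti_rank))
    }
    # beta0 = connected components of the 1-skeleton (independent library)
    gr <- igraph::graph_from_edgelist(K$simplices[[2L]], directed = FALSE)
    gr <- igraph::add_vertices(gr, K$n_vertices - igraph::vcount(gr))
    expect_equal(hodge_spectrum(hodge_laplacian(K, 0L))$betti,
                 igraph::components(gr)$no)
  }
})

test_that("Euler characteristic matches the alternating Betti sum", {
  for (seed in c(6, 14, 28)) {
    K <- random_rips(seed, n_max = 10L, max_dim = 3L)$K
    ns <- n_simplices(K)
    betti <- vapply(0:K$max_dim, function(k)
      hodge_spectrum(hodge_laplacian(K, k))$betti, 0L)
    signs <- (-1)^(0:K$max_dim)
    expect_equal(sum(signs * ns), sum(signs * betti))
  }
})

test_that("homology generators localise on loops", {
  # 4-cycle: unique generator with magnitude 1/2 on every edge
  S <- hodge_spectrum(hodge_laplacian(fixture_square(), 1L))
  gen <- homology_generators(S)
  expect_length(gen, 1L)
  expect_equal(gen[[1L]], rep(0.5, 4), tolerance = 1e-10)

  # two disjoint triangles: kernel is 2-dimensional; compare projectors,
  # since any rotation of the basis within the eigenspace is valid
  two <- simplicial_complex(list(c(1, 2), c(1, 3), c(2, 3),
                                 c(4, 5), c(4, 6), c(5, 6)))
  S2 <- hodge_spectrum(hodge_laplacian(two, 1L))
  expect_equal(S2$betti, 2L)
  # expected kernel: cyclic flow on each triangle, normalised
  c1 <- c(1, -1, 1, 0, 0, 0) / sqrt(3)   # edges 12,13,23 then 45,46,56
  c2 <- c(0, 0, 0, 1, -1, 1) / sqrt(3)
  P_exp <- tcrossprod(cbind(c1, c2))
  expect_equal(kernel_projector(S2), P_exp, tolerance = 1e-9)

  # guanine zero eigenspace has dimension 2 and each generator concentrates
  # its mass on ring edges (not on the exocyclic O6/N2 bonds)
  g <- guanine_graph()
  Sg <- hodge_spectrum(hodge_laplacian(g, 1L))
  expect_length(homology_generators(Sg), 2L)
  edges <- g$simplices[[2L]]
  exo <- which(apply(edges, 1L, function(e)
    any(g$ids[e] %in% c("O6", "N2"))))
  for (v in homology_generators(Sg))
    expect_lt(max(v[exo]), min(sort(v, decreasing = TRUE)[1:5]))
})

test_that("empty eigenspace yields no generators", {
  S <- hodge_spectrum(hodge_laplacian(fixture_filled_triangle(), 1L))
  expect_equal(homology_generators(S), list())
})

test_that("smallest nonzero eigenvectors split communities", {
  # path graph: Fiedler vector changes sign once, splitting the two halves
  path6 <- simplicial_complex(lapply(1:5, function(i) c(i, i + 1L)))
  S <- hodge_spectrum(hodge_laplacian(path6, 0L))
  fied <- nonhomology_eigenvectors(S, 1L)[[1L]]
  expect_equal(sum(diff(sign(fied)) != 0), 1L)

  # two triangles joined at a vertex: Fiedler sign separates them
  bow <- simplicial_complex(list(c(1, 2), c(1, 3), c(2, 3),
                                 c(3, 4), c(3, 5), c(4, 5)))
  f2 <- nonhomology_eigenvectors(hodge_spectrum(hodge_laplacian(bow, 0L)), 1L)[[1L]]
  expect_true(all(sign(f2[c(1, 2)]) == sign(f2[1])))
  expect_true(all(sign(f2[c(4, 5)]) == -sign(f2[1])))

  # against the dense eigendecomposition oracle on a barbell graph
  barbell <- simplicial_complex(c(
    list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))))
  L <- as.matrix(hodge_laplacian(barbell, 0L))
  S3 <- hodge_spectrum(L)
  e <- eigen(L, symmetric = TRUE)
  v_oracle <- e$vectors[, length(e$values) - 1L]
  v_pkg <- nonhomology_eigenvectors(S3, 1L)[[1L]]
  expect_equal(abs(v_pkg), abs(v_oracle), tolerance = 1e-9)

  expect_error(nonhomology_eigenvectors(S3, 99L), "exceeds")
})

test_that("non-symmetric input is rejected", {
  expect_error(hodge_spectrum(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("spectrum TSV export writes eigenvalues in order", {
  S <- hodge_spectrum(hodge_laplacian(fixture_square(), 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(S, path)
  tab <- read.delim(path)
  expect_equal(tab$eigenvalue, S$values, tolerance = 1e-12)
})
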