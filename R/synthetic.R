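# Synthetic fixtures: collinear chains, a straight-line -> helix folding
# trajectory, the guanine covalent graph, and block-structured TAD-like
# contact matrices.  Every generator is deterministic under its seed.

#' Collinear chain of points
#'
#' `n` points on the x-axis at multiples of `spacing` — the geometry of a
#' fully unfolded peptide chain.  Its distance edge flow is a pure gradient
#' at any cutoff, so TI = 0 downstream.
#'
#' @param n Number of points (`>= 2`).
#' @param spacing Consecutive-point spacing in Angstrom (default 3.8, the
#'   C-alpha virtual bond length).
#' @return A [point_cloud()].
#' @export
straight_chain <- function(n, spacing = 3.8) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2")
  if (spacing <= 0) stop("'spacing' must be positive")
  point_cloud(cbind((seq_len(n) - 1L) * spacing, 0, 0))
}

# turn angle per residue for a helix of given radius/pitch and bond length
.helix_turn <- function(bond, radius, pitch) {
  f <- function(th) (2 * radius * sin(th / 2))^2 + (pitch * th / (2 * pi))^2 -
    bond^2
  if (f(pi) < 0)
    stop("infeasible helix: bond length ", bond,
         " too long for radius ", radius, " and pitch ", pitch)
  stats::uniroot(f, c(1e-9, pi), tol = 1e-12)$root
}

#' Straight-line to helix folding trajectory
#'
#' A surrogate for a steered-MD (un)folding pathway: frame 1 is a straight
#' chain and the last frame an ideal helix of the given radius and pitch;
#' intermediate frames scale the per-residue turn angle linearly while the
#' rise is adjusted so that the consecutive-point spacing stays exactly at
#' `bond` in every frame.  Curvature therefore increases smoothly from 0 to
#' the helix value, and the TI of the distance edge flow grows with the
#' frame index.
#'
#' @param n Points per frame (`>= 3`).
#' @param n_frames Number of frames (`>= 2`).
#' @param bond Consecutive-point spacing in Angstrom (default 3.8).
#' @param radius Helix radius in Angstrom (default 2.3, chosen with the
#'   default pitch so that an 11 Angstrom cutoff produces triangle-rich
#'   complexes for chains of ~60 points).
#' @param pitch Helix rise per full turn in Angstrom (default 5.4).
#' @param seed Integer seed; only consumed when `jitter_sd > 0`, but always
#'   part of the configuration so trajectories are replayable.
#' @param jitter_sd Standard deviation of optional Gaussian coordinate
#'   jitter in Angstrom (default 0, exact geometry).
#' @return List of `n_frames` [point_cloud()] objects.
#' @export
folding_trajectory <- function(n = 60L, n_frames = 20L, bond = 3.8,
                               radius = 2.3, pitch = 5.4, seed = 0L,
                               jitter_sd = 0) {
  n <- as.integer(n); n_frames <- as.integer(n_frames)
  if (n < 3L) stop("'n' must be at least 3")
  if (n_frames < 2L) stop("'n_frames' must be at least 2")
  theta_f <- .helix_turn(bond, radius, pitch)
  i <- seq_len(n) - 1L
  frames <- lapply(seq_len(n_frames), function(f) {
    t <- (f - 1) / (n_frames - 1)
    th <- t * theta_f
    if (th < 1e-12) {
      coords <- cbind(radius, 0, i * bond)
    } else {
      chord2 <- (2 * radius * sin(th / 2))^2
      rise <- sqrt(bond^2 - chord2)
      coords <- cbind(radius * cos(i * th), radius * sin(i * th), i * rise)
    }
    coords
  })
  if (jitter_sd > 0) {
    frames <- withr::with_seed(as.integer(seed), lapply(frames, function(m)
      m + matrix(stats::rnorm(length(m), sd = jitter_sd), nrow(m))))
  }
  lapply(frames, point_cloud)
}

#' Covalent graph of guanine (heavy atoms)
#'
#' The 11 heavy atoms of guanine and their 12 covalent bonds form a graph
#' whose fused five- and six-membered purine rings give two independent
#' 1-cycles: the first Betti number of its Hodge 1-Laplacian is 2, and the
#' two zero-eigenvalue eigenvectors localise on the two rings.
#'
#' @return A `simplicial_complex` of dimension 1 (11 vertices, 12 edges)
#'   with atom-name vertex ids.
#' @export
guanine_graph <- function() {
  atoms <- c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6", "N7", "C8", "N9")
  bonds <- list(
    c("N1", "C2"), c("C2", "N2"), c("C2", "N3"), c("N3", "C4"),
    c("C4", "C5"), c("C5", "C6"), c("C6", "N1"), c("C6", "O6"),
    c("C5", "N7"), c("N7", "C8"), c("C8", "N9"), c("N9", "C4"))
  edges <- lapply(bonds, function(b) match(b, atoms))
  simplicial_complex(edges, n_vertices = length(atoms), ids = atoms)
}

#' Synthetic block-structured Hi-C matrix
#'
#' Emulates the diagonal square regions of elevated contact frequency that
#' define TADs: a background mean everywhere, dense blocks along the
#' diagonal, truncated-at-zero Gaussian noise, symmetric by construction,
#' diagonal set to the largest entry.  Deterministic under `seed`.
#'
#' Defaults model a 60-bin map at 40 kb resolution with one 15-bin
#' (600 kb) TAD-like block: in-block mean 150 maps to an alpha-reciprocal
#' distance of about 0.29 (well under both conventional cutoffs 0.4 and
#' 0.5), while the background mean 8 sits near distance 0.59 so that only
#' occasional noise-driven contacts cross the 0.5 threshold — mirroring the
#' small nonzero AI of real non-TAD regions.
#'
#' @param n_bins Matrix size (default 60).
#' @param blocks List of blocks, each a list/vector with elements `start`,
#'   `end` (1-based inclusive bins) and `mean` contact frequency.  Blocks
#'   must not overlap.  The default places one block of about a quarter of
#'   the map, starting after the first sixth (bins 11-25 for 60 bins).
#' @param background_mean Mean contact frequency outside blocks (default 8).
#' @param noise_sd Gaussian noise standard deviation (default 4).
#' @param seed Integer seed.
#' @param bin_size Bin size in bp (default 40000).
#' @return A [contact_matrix()].
#' @export
synthetic_hic <- function(n_bins = 60L, blocks = NULL,
                          background_mean = 8, noise_sd = 4, seed = 0L,
                          bin_size = 40000) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 3L) stop("'n_bins' must be at least 3")
  if (is.null(blocks)) {
    s <- round(n_bins / 6) + 1L
    e <- min(n_bins, s + max(3L, round(n_bins / 4)) - 1L)
    blocks <- list(list(start = s, end = e, mean = 150))
  }
  if (background_mean <= 0) stop("'background_mean' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  mu <- matrix(background_mean, n_bins, n_bins)
  covered <- integer(0)
  for (b in blocks) {
    b <- as.list(b)
    s <- as.integer(b$start); e <- as.integer(b$end); m <- as.numeric(b$mean)
    if (is.na(s) || is.na(e) || s < 1L || e > n_bins || s > e)
      stop("block [", s, ", ", e, "] outside the matrix")
    if (m <= 0) stop("block mean must be positive")
    if (any(s:e %in% covered)) stop("overlapping blocks")
    covered <- c(covered, s:e)
    mu[s:e, s:e] <- m
  }
  M <- withr::with_seed(as.integer(seed), {
    noise <- matrix(0, n_bins, n_bins)
    ut <- upper.tri(noise)
    noise[ut] <- stats::rnorm(sum(ut), sd = noise_sd)
    X <- pmax(mu + noise, 0)
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    X
  })
  diag(M) <- max(M)
  contact_matrix(M, bin_size = bin_size)
}
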