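---
title: "Hodge Laplacian spectra and HodgeRank inconsistency for molecular folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hodge Laplacian spectra and HodgeRank inconsistency for molecular folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hodgeflow)
```

## The model

A biomolecular structure — a protein's C-alpha trace, a nucleic acid's
phosphorus backbone, or the binned loci of a Hi-C contact map — is
represented as a Vietoris–Rips simplicial complex: a k-simplex is formed by
any `k + 1` vertices whose pairwise distances are all *strictly* below a
cutoff. Vertices and edges recover the usual molecular graph; triangles
(2-simplices) and tetrahedra capture higher-order proximity that graphs
miss. `build_rips()` constructs the complex from coordinates,
`build_rips_from_distances()` from any dissimilarity matrix.

Two analyses are built on this representation.

### Hodge Laplacian spectra

With simplices in canonical ascending-vertex orientation, the boundary
matrix $B_k$ encodes the alternating-sign boundary map from k-simplices to
their faces, and the combinatorial Hodge Laplacian is

$$L_k = B_k^T B_k + B_{k+1} B_{k+1}^T,$$

with $L_0 = B_1 B_1^T$ the familiar graph Laplacian. $L_k$ is symmetric
positive semi-definite and its spectrum is independent of the orientation
convention. The multiplicity of the zero eigenvalue equals the Betti number
$\beta_k$: components for $k = 0$, independent loops for $k = 1$, cavities
for $k = 2$. Zero-eigenvalue eigenvectors are homology generators — their
large-magnitude entries sit on the edges of the loops they represent — while
the low nonzero end of the spectrum (Fiedler vector and friends) encodes
community structure. The guanine covalent graph (`guanine_graph()`, 11 heavy
atoms, 12 bonds, fused five- and six-ring) is the canonical small example:
$\beta_1 = 2$, one generator per ring.

### HodgeRank inconsistency

The edge space of the complex decomposes orthogonally into

$$C^1 = \underbrace{\mathrm{Im}(\delta_0)}_{\text{gradient}} \oplus
       \underbrace{\ker(\Delta_1)}_{\text{harmonic}} \oplus
       \underbrace{\mathrm{Im}(\delta_1^*)}_{\text{curl}}.$$

An edge flow assigns a signed scalar to each oriented edge. For a chain
molecule, the sequence provides a natural vertex order, and the *distance
edge flow* sets $Y_{[i,j]} = |\mathbf r_i - \mathbf r_j|$ for $i < j$ in
sequence order (negated against the sequence). If three vertices are
collinear, the flow around their triangle sums to zero; for a perfectly
straight chain the whole flow is the gradient of the arclength potential.
Curvedness and folding show up as curl (locally cyclic, supported on
triangles) and harmonic (globally cyclic) content, which
`hodge_decompose()` extracts. The summary indices are

$$\mathrm{TI} = \sum_{[i,j] \in K}
   \left|\frac{(Y^c + Y^h)_{[i,j]}}{Y_{[i,j]}}\right|,
  \qquad \mathrm{AI} = \mathrm{TI}/N,$$

each unordered edge counted once and $N$ the number of vertices. TI is zero
exactly for unfolded (collinear) chains and grows as the structure becomes
compact; AI makes structures of different sizes comparable.

For Hi-C maps, contact frequencies are converted to proxy distances by the
alpha-reciprocal transform $d(i,j) = 1/M_{ij}^\alpha$, the complex is built
at a cutoff $\gamma$, and either the distance-based flow
($Y_{[i,j]} = d(i,j)$) or the constant flow ($Y_{[i,j]} = 1$) is
decomposed. Dense diagonal blocks — TAD-like regions — yield many triangles
and high AI; sparse regions yield few edges and AI near zero. `score_region()`
scores one window, `scan_diagonal()` profiles a whole map.

## Parameters that matter

* **Rips cutoff** (Angstrom). Protein C-alpha traces are typically analysed
  at 8–14 Å (11 Å default in the examples); phosphorus backbones at
  10–20 Å. A bare B-DNA helix forms no triangles below about 12 Å, so its
  TI vanishes there — the index activates exactly when the representation
  can see folding. Larger cutoffs enlarge the complex and, empirically,
  increase TI; we treat that as an observed regularity, not a theorem, and
  test it on synthetic helices.
* **`max_dim`** defaults to 2: curl flows live on triangles, and dimensions
  above 2 do not change TI/AI. Use 3 only for $\beta_2$ (cavity) queries.
* **`alpha`** in $(0, 1]$, default 0.25, controls how sharply contact
  frequency maps to distance; **`gamma`** (0.4 and 0.5 are the two
  conventional choices at 40 kb resolution) sets the edge threshold.
  Ties at the threshold are excluded (strict `<` everywhere).
* **`zero_tol`** for Betti counting defaults to
  $10^{-8} \max(1, \lambda_{\max})$ — a relative threshold that behaves
  consistently across complex sizes. It is exposed because heavily
  near-degenerate spectra (barely-connected components) may warrant a
  looser or tighter value.

## Numerical choices

* Boundary matrices are sparse throughout. Eigendecompositions use the
  dense symmetric solver: every complex in the package's intended scope
  (up to a few thousand simplices per dimension) is comfortably within
  dense range, and the full ascending spectrum makes Betti counting and
  generator extraction trivial. This is a deliberate simplification over a
  sparse shift-invert path.
* The two projections in `hodge_decompose()` solve the normal equations
  $L_0 s = -B_1 Y$ (gradient potential) and
  $B_2^T B_2 z = B_2^T Y$ (curl potential) by conjugate gradients with an
  *absolute* residual target of $10^{-12}\max(1, \lVert Y\rVert)$. Both
  systems are singular but consistent; the right-hand side's rounding
  component lies in the kernel, which makes CG semi-convergent, so the best
  iterate is tracked and returned and a residual above
  $10^{-8}\max(1, \lVert Y\rVert)$ is an error, never a silent degradation.
  The absolute (not relative-to-$b$) target matters: for a pure-gradient
  flow the curl right-hand side is itself rounding noise.
* Potentials are fixed to zero mean within each connected component; this
  is a determinism choice only and does not affect $Y^g$.
* Degenerate eigenspaces (e.g. guanine's two ring generators) are reported
  as any orthonormal basis; comparisons should use the kernel projector,
  never individual vectors.
* Edges with $|Y| \le 10^{-12}$ are an error, not silently skipped: the TI
  summand is undefined there. Distance flows can only trigger this through
  coincident atoms, which is a data problem worth surfacing.

## Ordering, relabeling, and what is actually invariant

The stored flow value lives on the canonical edge $[i, j]$, $i < j$; the
reversed orientation carries the negated value. Relabeling the vertices and
carrying the *same physical flow* across (re-signing where the permutation
reverses a pair's order) leaves TI and AI unchanged to solver precision —
this is the order-independence the indices enjoy, and it is what the test
suite verifies. Note the distinction: *recomputing* a distance flow under an
arbitrary new numbering defines a different flow (the chain sequence is part
of the model — already for three points, the cycle sums $|a + c - b|$ and
$|a + b - c|$ differ), so the sequence should always be the biological
chain order. Full sequence reversal flips every sign and is therefore also
TI-invariant, which is why multi-chain orderings that differ only in chain
direction do not affect the scores.

## What the synthetic generators emulate

* `straight_chain()` is the unfolded-chain limit: TI identically zero.
* `folding_trajectory()` morphs a straight chain into an ideal helix
  (default radius 2.3 Å, pitch 5.4 Å, bond 3.8 Å — alpha-helix-like
  geometry) by scaling the per-residue turn angle linearly while solving
  the rise so consecutive-point spacing stays exactly at the bond length.
  It stands in for a steered-MD unfolding trajectory replayed in reverse:
  TI rises from 0 to its folded value almost monotonically (the suite
  checks Spearman rank correlation with frame index above 0.9 at n = 60,
  20 frames, 11 Å). It has no excluded volume, no side chains and no
  metastable plateaus, so it demonstrates the index's monotone response to
  curvature, not the kinetics of real folding.
* `synthetic_hic()` generates a background-plus-diagonal-block contact
  matrix with truncated-at-zero Gaussian noise. The defaults are the study
  conditions used by the acceptance checks: 60 bins at 40 kb, one 15-bin
  (600 kb, mid-range TAD size) block of mean 150, background mean 8, noise
  sd 4. At $\alpha = 0.25$ the block sits at distance
  $150^{-0.25} \approx 0.29$, inside both conventional cutoffs, while the
  background sits at $\approx 0.59$ with only occasional noise-driven
  contacts crossing $\gamma = 0.5$ — mirroring the small but nonzero AI
  that real non-TAD regions show. Real Hi-C additionally has
  distance-dependent decay, compartment structure and coverage biases; the
  generator makes no attempt at these, so passing the separation check
  shows the index responds to block density, not that it calls TADs on
  real data.

## Problem sizes

The shipped checks run on: 50–60-point chains and helices (hundreds of
edges, up to a few thousand triangles), 60-bin contact maps, and sweeps of
50 random complexes on up to 12 points for the algebraic invariants
(boundary-composition zero, entrywise-Laplacian equality, rank-nullity
Betti agreement, orthogonality of the decomposition). Atomic-level analyses
of real structures (a 22-P DNA helix up to a 692-P tetranucleosome) run in
minutes on one CPU; the corresponding table reproduction requires the PDB
entries to be supplied locally, as coordinate files are not shipped with
the package.

## Known limitations

* TI/AI require every edge flow to be nonzero; constant flows on arbitrary
  graphs satisfy this trivially, distance flows require distinct atom
  positions.
* The Rips construction is metric-blind beyond the cutoff: no periodic
  boundaries, no chain-topology awareness.
* Hi-C matrices are scored as supplied; ICE/KR normalisation, if wanted,
  must happen upstream.
* TAD *calling* (boundary detection) is out of scope; `scan_diagonal()`
  profiles likelihood but draws no boundaries.
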