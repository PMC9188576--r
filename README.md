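# hodgeflow

Discrete Hodge theory for biomolecular structure and Hi-C analysis in R.

Structural biologists and genome-architecture researchers often need a
*quantitative* answer to a qualitative question: how folded is this chain?
How TAD-like is this region of a contact map? `hodgeflow` answers both with
one machinery. Structures are represented as Vietoris–Rips simplicial
complexes — graphs extended with triangles and tetrahedra — on which two
classical objects are computed:

* **Hodge Laplacian spectra.** With boundary matrices $B_k$ in canonical
  orientation, $L_k = B_k^T B_k + B_{k+1} B_{k+1}^T$ (and
  $L_0 = B_1 B_1^T$, the graph Laplacian). The multiplicity of the zero
  eigenvalue of $L_k$ is the Betti number $\beta_k$ (components, loops,
  cavities); zero-eigenvalue eigenvectors are homology generators that
  localise on loop edges, and the low nonzero spectrum drives spectral
  clustering.
* **HodgeRank inconsistency.** A chain's sequence order signs a distance
  edge flow $Y_{[i,j]} = |\mathbf r_i - \mathbf r_j|$ ($i < j$ in sequence),
  which decomposes orthogonally into gradient + curl + harmonic parts. The
  **total inconsistency**
  $\mathrm{TI} = \sum_{[i,j]} |(Y^c + Y^h)_{[i,j]} / Y_{[i,j]}|$ and the
  **average inconsistency** $\mathrm{AI} = \mathrm{TI}/N$ are zero for an
  unfolded (collinear) chain and grow with compactness — a folding index
  for proteins and DNA, and a TAD-likelihood score for Hi-C regions after
  the $d(i,j) = 1/M_{ij}^\alpha$ contact-to-distance transform.

PDB input (C-alpha / phosphorus / heavy-atom selections with correct
chain-sequence ordering) is supported through `bio3d`; Hi-C maps are read
from dense whitespace/CSV text. Synthetic generators (straight chains,
chain-to-helix trajectories, the guanine covalent graph, block-structured
contact matrices) make every analysis reproducible without downloads.

## Worked example

```r
library(hodgeflow)

# --- topology: guanine's fused rings -------------------------------------
g <- guanine_graph()
#> simplicial_complex: 11 0-simplices, 12 1-simplices
hodge_spectrum(hodge_laplacian(g, 1))
#> hl_spectrum: 12 eigenvalues, betti = 2
```

`betti = 2`: the five- and six-membered rings each contribute one homology
generator; `homology_generators()` returns per-edge magnitudes that peak on
the ring edges.

```r
# --- folding: unfolded chain vs helix ------------------------------------
structure_inconsistency(straight_chain(50), cutoff = 11)
#> TI = 1.84297e-13  AI = 3.68594e-15  (N = 50, 97 edges, 48 triangles)

traj <- folding_trajectory(n = 60, n_frames = 20, seed = 0)
prof <- folding_profile(traj, cutoff = 11)
round(prof$TI[c(1, 5, 10, 15, 20)], 3)
#> [1]  0.000  0.046  3.542 27.501 69.875
```

TI is numerically zero for the straight chain (pure gradient flow) and
rises monotonically as the chain winds into a helix.

```r
# --- Hi-C: TAD-like block vs background ----------------------------------
M <- synthetic_hic(seed = 0)            # 60 bins, dense block at 11..25
score_region(M, 11, 25, "distance", gamma = 0.5)
#> bins [11, 25] distance flow (alpha=0.25, gamma=0.5): TI=48.9447 AI=3.2630
score_region(M, 40, 54, "distance", gamma = 0.5)
#> bins [40, 54] distance flow (alpha=0.25, gamma=0.5): TI=0.0000 AI=0.0000
```

The dense diagonal block scores AI ≈ 3.3 — in the range real TADs exhibit —
while the sparse background region scores ≈ 0, the non-TAD signature.
`scan_diagonal()` applies this windowed along a whole chromosome.

A command-line wrapper with subcommands `complex`, `spectrum`, `ti`, `hic`
and `synth` is installed at
`system.file("cli", "hodgeflow.R", package = "hodgeflow")`.

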