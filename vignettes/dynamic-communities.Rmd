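---
title: "Dynamic communities from elastic network models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic communities from elastic network models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncomm)
```

## The model

A protein's equilibrium fluctuations are modelled by the coarse-grained
Gaussian network model (GNM): one node per residue at its C$\alpha$
position, and a harmonic spring of force constant $\gamma$ between every
pair of residues within a cutoff $r_c$.  The potential is
$V = \tfrac{\gamma}{2}\sum_{ij}\Gamma_{ij}(\Delta R_i-\Delta R_j)^2$ with
$\Gamma$ the Kirchhoff matrix: $\Gamma_{ij}=-1$ for contacting pairs
($R_{ij}\le r_c$, boundary inclusive), $0$ otherwise, and
$\Gamma_{ii}=-\sum_{j\ne i}\Gamma_{ij}$.  Under this Gaussian model the
covariance of residue fluctuations is proportional to the pseudoinverse
$\Gamma^{-1}=\sum_{i\ge 2}\lambda_i^{-1}u_iu_i^{\mathsf T}$, where the
single zero mode (rigid-body translation of a connected network) is
excluded.  Cross-correlations
$C_{ij}=\Gamma^{-1}_{ij}/\sqrt{\Gamma^{-1}_{ii}\Gamma^{-1}_{jj}}$ are
mapped to the *dynamic distance*

$$D_{ij}=\sqrt{2\,(1-C_{ij})}\in[0,2],$$

which is $0$ for perfectly correlated residues and $2$ for perfectly
anticorrelated ones.  Because $C$ is positive semidefinite, $D$ is a
Euclidean-embeddable metric (the test suite verifies the doubly-centred
Gram matrix of $-D^2/2$ is PSD on random fixtures), so minimum-variance
(Ward) clustering of $D$ is well posed.  A *dynamic community* is a cluster
of the Ward tree: a group of residues moving coherently, which need not be
spatially contiguous.

The number of communities is chosen by cutting the tree at every
$k\in[k_{\min},k_{\max}]$ and maximising the Calinski--Harabasz (CH) score
$\big[\mathrm{tr}(B)/(k-1)\big]\big/\big[\mathrm{tr}(W)/(N-k)\big]$, the
degrees-of-freedom-normalised ratio of between- to within-cluster
dispersion.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| GNM cutoff | 7.0 | Å | standard C$\alpha$ contact radius for the GNM; captures first-shell packing |
| $\gamma$ | 1.0 | — | overall spring scale; cancels in $C$, so it only rescales fluctuations |
| $k_{\min}..k_{\max}$ | 2..20 | — | community counts swept; raise $k_{\max}$ (up to $N-1$) to explore finer partitions |
| ANM cutoff | 15.0 | Å | directional models need a larger radius for a stable, 6-zero-mode Hessian |
| zero-mode tolerance | $10^{-8}$ | relative | eigenvalues below this fraction of the largest count as rigid-body modes |
| recovery threshold | 0.5 | Jaccard | a domain counts as recovered when its claimed community overlaps it at least this much |

`dyncomm()` clamps $k_{\max}$ to $N-1$ for small structures, since the CH
score is undefined at $k=N$; the lower-level `select_communities()` keeps
the strict precondition and errors instead.

## Feature representation for clustering and scoring

Clustering "on the dynamic distance matrix" admits two readings, and the
package implements both:

* **`rows` (default):** row $i$ of $D$ is residue $i$'s feature vector;
  Ward operates on Euclidean distances between rows, and the CH score uses
  the same vectors.  This matches toolchains whose Ward variant accepts
  only feature vectors, and is the representation most likely to reproduce
  CH magnitudes reported by such pipelines.
* **`lw`:** the Ward (Lance--Williams) recurrence applied to $D$ directly
  as pairwise dissimilarities.  CH is still scored on rows of $D$, the only
  vector representation available.

Both run through `stats::hclust(method = "ward.D2")`, whose merge sequence
is verified in the tests against naive re-computation oracles (explicit
minimum-variance costs, and the explicit Lance--Williams recurrence) on
random matrices with $N\le 10$.

## Numerical choices

* **Symmetric eigendecomposition** (`eigen(symmetric = TRUE)`) is used for
  $\Gamma$ and the ANM Hessian; for symmetric PSD matrices it coincides
  with an SVD but has deterministic ordering.  Eigenvalues are sorted
  ascending; each eigenvector's sign is fixed by making its
  largest-magnitude component positive, so cached intermediates are
  bit-reproducible (signs cancel in the pseudoinverse regardless).
* **Exactly one GNM mode is excluded.**  If more than one eigenvalue is
  numerically zero the contact network is disconnected; the run stops and
  reports the component count rather than silently dropping modes.  The ANM
  analogue requires exactly six near-zero modes and refuses disconnected or
  collinear geometries.
* **Degenerate CH cases use sentinels, not exceptions**, so a sweep never
  aborts mid-run: zero total dispersion scores 0; zero within-cluster
  dispersion with positive separation scores the largest finite double.
* **Argmax ties** over $k$ break towards fewer communities (parsimony).
  Alternative arrangements are reported both as all $k$ ranked by CH and as
  the strict local maxima of the CH-vs-$k$ curve (endpoints included).
* $C$ is clipped to $[-1,1]$ before the square root in $D$ to absorb
  rounding.
* **Parsing policy:** first MODEL only; HETATM excluded by default (with a
  by-name include list, e.g. `MSE`); highest-occupancy altloc kept, ties to
  altloc `A`; nonstandard residues in ATOM records kept — the model is
  geometry-only.

## The synthetic generators

The generators provide fixtures whose correct answer is known by
construction, so every stage is testable without deposited structures:

* `make_path_chain()` — collinear C$\alpha$'s whose contact graph is the
  path graph, with a closed-form Laplacian pseudoinverse (the $3$-residue
  case is worked by hand in the tests: $\Gamma^{-1}_{13}=-4/9$,
  $C_{13}=-0.8$, $D_{13}=\sqrt{3.6}$).
* `make_two_domain()` — two compact cubic-lattice blobs (lattice constant
  4 Å, internally connected at the 7 Å cutoff) bridged by a two-residue
  linker across a 12 Å gap, with uniform jitter of 0.5 Å from R's
  Mersenne--Twister under a fixed seed.  The planted bipartition is the
  expected answer; the two linker residues sit on the hinge and are
  excluded from exactness checks, since their assignment is genuinely
  ambiguous.
* `make_block_correlation()` — a block-constant correlation matrix
  (within 0.9, between $-0.2$ in the standard fixture), bypassing the GNM
  so the clustering stage is tested in isolation; PSD-validated at
  construction.

These fixtures emulate the *topology* real proteins present to the
pipeline — connected contact graphs, separated packing blocks, hinge
ambiguity — but not realistic protein geometry (no Ramachandran validity,
no secondary structure, no density gradients).  Passing tests therefore
demonstrate algorithmic correctness, not that any particular protein's
published community count will be reproduced; that depends on the
deposited coordinates and selections used.

## Motion trajectories

The ANM Hessian uses the standard super-element
$H_{ij}=-\gamma\,r_{ij}r_{ij}^{\mathsf T}/|r_{ij}|^2$ for connected pairs
(the only consistent second-derivative form of the pairwise harmonic
potential at equilibrium; the tests confirm it against finite differences).
A single internal mode $\nu_i$ (1-based, mode 1 = slowest) generates
conformers $R' = R + s\,\nu_i$ over a symmetric amplitude sweep
$s\in[-s_{\max},s_{\max}]$ with an odd frame count, so the central frame is
the input structure exactly.  By default $s_{\max}$ is chosen so the
largest per-residue displacement is 2 Å — large enough to see, small enough
not to distort bonded geometry visibly.  Combining modes, and mode overlap
metrics, are out of scope.

## Problem sizes used in validation

The shipped validation uses sizes where independent oracles are exact and
fast: brute-force Ward comparisons at $N\le 10$ over 50 random matrices,
finite-difference Hessians at $N=8$, property suites over 100 seeded
random chain-globules at $N=10$, and planted-partition fits at $N=42$.
The pipeline itself is dense-matrix throughout and is routinely used at a
few thousand residues; memory grows as $O(N^2)$ and the eigendecomposition
as $O(N^3)$.

## Known limitations

* Single-structure, single-conformation input: no ensemble averaging, no
  mmCIF, no biological-assembly expansion.
* Uniform springs only: no distance-weighted or sequence-specific force
  constants, and no per-chain block analysis.
* The CH selection inherits Ward's preference for compact, similar-sized
  clusters; elongated or highly unbalanced communities may be split or
  merged relative to expert annotation, which is why the domain-recovery
  metric exposes its Jaccard threshold rather than hard-coding a
  criterion.
* Validation against deposited structures requires the user to supply the
  PDB files (see the README); the package ships only synthetic fixtures.
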