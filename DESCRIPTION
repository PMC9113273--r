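Package: dyncomm
Title: Dynamic Community Decomposition of Protein Structures with Elastic
    Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes a protein structure into dynamic communities:
    groups of residues that move coherently according to a coarse-grained
    Gaussian network model (GNM).  Residue cross-correlations derived from
    the mode-truncated pseudoinverse of the Kirchhoff matrix are mapped to
    a Euclidean dynamic distance, clustered by Ward agglomerative
    hierarchical clustering, and the number of communities is selected by
    the Calinski-Harabasz score.  Also provides anisotropic network model
    (ANM) normal modes and mode-displaced multi-model PDB trajectories for
    visualising motions relative to community boundaries, synthetic
    structure generators with planted community structure, and a metric
    for agreement between communities and external domain annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
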