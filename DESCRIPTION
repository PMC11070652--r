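Package: shellscore
Title: Shell-Graph Transformer Scoring of Protein-Ligand Docking Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein-ligand docking poses by predicting the root mean
    square deviation (RMSD) of each pose from the native ligand conformation.
    The binding interface is partitioned into concentric shells centred on the
    whole ligand; each shell becomes a bipartite protein-ligand graph with
    fixed one-hot atom and edge features, encoded by a graph transformer whose
    self-attention is biased by shortest-path hop counts (spatial encoding)
    and by learnable projections of the edge features along shortest paths
    (edge encoding). Per-shell embeddings are concatenated and regressed onto
    RMSD with a multilayer perceptron trained by AdamW under a step-halved
    learning-rate schedule with early stopping and a four-part
    complex-disjoint ensemble. Includes structure readers (PDB, Mol2, SDF),
    dataset curation predicates, symmetry-corrected RMSD, docking evaluation
    metrics (docking power, hit rate, enrichment factor, RMSE, Pearson and
    Spearman correlation, Jensen-Shannon divergence of RMSD distributions),
    and synthetic fixture generators with analytically exact RMSD labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
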