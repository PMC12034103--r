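Package: rnaloopclust
Title: Clustering RNA Structural Motif Candidates with Graph Network Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clustering RNA loop regions (internal and hairpin loop
    motif candidates) by joint base-interaction and backbone-geometry
    similarity. Loops are encoded as strongly connected directed attributed
    graphs carrying one-hot nucleotide node features and 23-element edge
    features (inter-nucleotide distance, 18 Leontis-Westhof base-pair classes,
    4 base-stacking classes). A graph isomorphism network (GIN) classifier is
    trained on labelled motif families and its 128-dimensional graph
    embeddings are clustered by seeded K-means (with silhouette /
    Davies-Bouldin / single-motif-cluster-ratio model selection) followed by
    per-cluster hierarchical agglomerative subclustering. Includes subcluster
    quality (Q) scores, supervised evaluation (cluster-to-family mapping,
    motif clustering accuracy, RMSD purity analysis), annotation merging with
    frequency-based conflict resolution, and a synthetic labelled-loop
    generator so the whole pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    cluster,
    mclust,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
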