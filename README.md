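# rnaloopclust

Clustering of RNA loop regions (hairpin and internal loops — "motif
candidates") by joint base-interaction and 3D-structure similarity, for
structural bioinformaticians who want to group loops into structural motif
families and surface candidates for new families without all-against-all
structural alignment.

## What it does

RNA structural motifs are recurrent 3D arrangements of nucleotides with
conserved non-canonical base pairs (Leontis–Westhof classes), stacking
contacts and backbone shape. `rnaloopclust` implements a
graph-embedding-based clustering pipeline:

1. **Graph encoding.** Each loop becomes a strongly connected directed
   graph: N nodes with 4-element base one-hots, all N(N−1) ordered-pair
   edges, each edge carrying a 23-element feature vector
   (inter-nucleotide distance in Å; one-hot over the 18 directional LW
   base-pair classes; one-hot over 4 stacking directions). Backbone
   geometry enters through the distances between per-nucleotide geometric
   centers of up to six backbone atoms (C3′, C4′, C5′, O3′, O5′, P),
   with a Kabsch-RMSD distance mode as an alternative.
2. **GIN embeddings.** A graph isomorphism network — three message-passing
   layers updating `h_v = MLP((1+ε)·h_v + Σ_{u∈N(v)} m(h_u, e_uv))` with
   ε = 0 — is trained as a family classifier on labelled motifs
   (categorical cross-entropy over softmax, Adam, best-validation
   checkpointing) and then used to produce a 128-dimensional embedding per
   loop.
3. **Two-stage clustering.** Seeded K-means over the embeddings, with K
   chosen by silhouette and Davies–Bouldin scores among candidates whose
   Single Motif Cluster Ratio (fraction of singleton clusters) stays below
   5%; then hierarchical agglomerative subclustering (average linkage,
   distance threshold) *within* each cluster, so heterogeneous clusters
   split and tight ones survive intact.
4. **Scoring and evaluation.** Per-subcluster Q-scores
   `Q_i = (SXQ_i + TMQ_i)/2` combining normalised interaction-alignment
   and structure-alignment statistics with member count; majority
   (>60%) subcluster-to-family mapping, per-family precision/recall/F1,
   motif clustering accuracy (MCA), ARI/AMI, and a mean+2·SD RMSD purity
   analysis. An annotation-merging module reconciles two annotation
   sources with corpus-frequency conflict resolution.

A synthetic-loop generator (8 labelled family templates with controllable
coordinate jitter and annotation noise) makes the entire pipeline runnable
and testable with zero downloads. See `vignette("motif-clustering")` for
the model, parameter meanings and design decisions.

## Worked example

```r
library(rnaloopclust)

ds     <- generate_dataset(builtin_templates()[c("SR", "KT", "GL")], 20L,
                           noise_spec(), seed = 1L)
graphs <- lapply(ds$loops, encode_loop)
model  <- gin_train(graphs, ds$split,
                    gin_config(hidden_dim = 32L, embed_dim = 32L,
                               epochs = 25L, seed = 1L))
model
#> <gin_model> 3 GIN layers, hidden 32, embedding 32, edge_mode=project_add
#>   classes: GL, KT, SR
#>   best validation accuracy 1.000 (epoch 16), test accuracy 1.000

emb <- gin_embed(model, graphs)
sel <- select_k(emb, k_grid = 2:6, seed = 0L)
sel
#> <k_selection> chosen K = 3 (SMCR < 0.05 satisfied)
#>  k silhouette        dbi smcr
#>  2  0.7948237 0.30190107    0
#>  3  0.9636864 0.05352681    0
#>  4  0.8525748 0.25159557    0
#>  5  0.6889996 0.47036766    0
#>  6  0.6962427 0.45340012    0

cl <- kmeans_cluster(emb, sel$chosen_k, seed = 0L)
sc <- subcluster(emb, cl, distance_threshold = 6)
agree <- compare_clusterings(setNames(sc$subcluster, sc$loop_id), ds$labels)
sprintf("ARI %.3f  AMI %.3f  SMCR %.1f%%", agree$ari, agree$ami, 100 * smcr(cl))
#> "ARI 0.911  AMI 0.909  SMCR 0.0%"
```

Reading the output: the classifier separates the three synthetic families
perfectly on held-out loops; the K selector picks K = 3 (highest
silhouette 0.96, lowest DBI 0.054, no singleton clusters); and the final
subcluster partition agrees with the true family labels with ARI 0.91.

The same workflow is available stage-by-stage from the shell via
`inst/cli/rnaloopclust` (`simulate`, `encode`, `train`, `embed`,
`select-k`, `cluster`, `subcluster`, `qscore`, `evaluate`, `run-all`),
with every intermediate artifact as documented CSV/TSV/JSON-lines files.

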