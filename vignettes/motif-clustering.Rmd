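---
title: "Clustering RNA loop motif candidates: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering RNA loop motif candidates: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Recurrent three-dimensional arrangements of nucleotides — RNA structural
motifs — occur in the loop regions of nonhomologous RNAs and are
characterised jointly by their non-canonical base-pair interactions
(Leontis–Westhof classes), base-stacking contacts, and backbone shape.
Grouping loop candidates into motif families by hand is slow; methods that
use only base interactions or only backbone geometry each miss part of the
signal. `rnaloopclust` clusters hairpin- and internal-loop candidates using
both sources of evidence at once: loops become attributed directed graphs,
a graph isomorphism network (GIN) trained on labelled families turns each
graph into a 128-dimensional embedding, and the embeddings are clustered in
two stages (seeded K-means, then per-cluster agglomerative subclustering).

## Graph representation

Each nucleotide is a node carrying a 4-element one-hot over A/C/G/U;
modified or unknown bases get an all-zero row, since the node vocabulary
covers only the four standard bases. Every ordered pair of nucleotides
carries one directed edge, so an N-nucleotide loop yields N(N−1) edges and
the graph is strongly connected by construction. The 23-element edge
feature vector holds:

* element 1 — the inter-nucleotide distance in Å;
* elements 2–19 — a one-hot over the 18 directional LW base-pair classes
  (cWW, cWH, cHW, cWS, cSW, cHH, cHS, cSH, cSS and their trans
  counterparts);
* elements 20–23 — a one-hot over the four stacking directions (upward,
  downward, inward, outward).

Annotations are directional: a pair (i, j, cWH) sets cWH on the edge i→j
and its edge-swapped form cHW on j→i. For stacking we use the reversal
upward↔downward with inward and outward self-symmetric; this reading of the
four-class stacking scheme is centralised in one table
(`stack_transpose()`) so it can be audited or changed in one place.

**Distance definition.** The description of nucleotide distance in terms of
both "Euclidean distance of geometric centers" and "Kabsch RMSD" is
genuinely ambiguous, so both are implemented: `center_euclidean` (default)
is the Euclidean distance between the backbone-center points — cheapest and
well defined for a single point per nucleotide — and `kabsch_backbone` is
the Kabsch superposition RMSD over the backbone atoms two nucleotides share.
The default is a package choice, not a claim about which definition is
"the" correct one. Distances stay in Å; no normalisation is applied before
encoding, and any scaling is left to the model configuration.

The backbone is summarised by up to six atoms per nucleotide (C3′, C4′,
C5′, O3′, O5′, P); the geometric center is the mean of whichever of those
atoms are present, so a residue missing its phosphate is still usable.
Residue numbering follows author numbering with inclusive ranges; insertion
codes are carried opaquely (appended to the residue token after a caret)
and never used for arithmetic, because location strings in the wild do not
specify an arithmetic for them.

## The GIN model

Node representations are updated for `num_layers = 3` rounds of message
passing:

h_v^k = MLP((1 + ε)·h_v^{k−1} + Σ_{u∈N(v)} m(h_u^{k−1}, e_{uv}))

with ε fixed at 0 (a learnable-ε flag exists but is off by default) and
N(v) the in-neighbours over the complete directed graph. The plain GIN
update has no edge term, yet the encoding carries 23-dimensional edge
features; how to inject them is an open design point, so the edge message m
is configurable:

* `project_add` (default) — neighbour representation plus a learned linear
  projection of the 23-vector, i.e. a GINE-style additive edge term;
* `ignore` — the plain GIN update, kept for ablation and for the
  hand-verifiable oracle tests.

Each layer's MLP is an affine map followed by LeakyReLU (negative slope
0.01, a common default). Readout is interpreted as: mean of node
representations within each layer, the three layer means summed, LeakyReLU,
then a linear projection to the 128-dimensional embedding. "Averaging the
summation of node representations from the same iterations" admits more
than one reading; this one — mean per layer, sum across layers — is fixed
and documented rather than left implicit. The classifier head is a linear
map to the family logits with softmax and categorical cross-entropy.

Training uses Adam (learning rate 1e-3, batch size 32, 200 epochs by
default), all implemented in base R matrix algebra with hand-derived
gradients: loop graphs are small (4–20 nodes) and training corpora are a
few hundred graphs, so a deep-learning backend is unnecessary and the
dependency-free implementation keeps the whole pipeline deterministic from
a single seed (initialisation, shuffling, and K-means all derive from it).
The validation accuracy is evaluated every epoch and the weights of the
best-validation epoch are retained; the stored `best_val_accuracy` always
equals the maximum of the logged per-epoch accuracies. Hairpin and
internal loops are trained as separate models by default (`loop_type` in
the pipeline), with `both` available to combine them.

## Two-stage clustering

Embeddings are clustered by K-means with a fixed random state so repeated
runs agree. K is chosen by sweeping a candidate grid and scoring each
clustering with the mean silhouette width, the Davies–Bouldin index (DBI),
and the Single Motif Cluster Ratio (SMCR — the fraction of clusters
containing exactly one loop). Only K with SMCR < 5% are admissible; among
those the selector takes the highest silhouette, breaking ties by lowest
DBI and then smallest K. The tie rule is a package choice: the selection
metrics can agree on a single K, but nothing guarantees it. If no K meets
the SMCR constraint the minimum-SMCR K is returned and flagged.

The default K grid is all of 2…10 plus a geometric sweep up to ⌈n/4⌉. An
alternative considered — starting the grid near n/20 — cannot reach small
true cluster counts at moderate n (at n = 300 it starts at K = 15, above a
6-family ground truth), which would make family recovery structurally
impossible; the grid therefore always includes the small-K regime.

Because K is fixed in advance, a K-means cluster can still mix dissimilar
loops. Each cluster is therefore re-clustered independently with
hierarchical agglomerative clustering (Euclidean metric, average linkage)
cut at a distance threshold (default 6, in embedding units — a value tuned
on a specific embedding space, hence exposed as a parameter). Tight
clusters survive as single subclusters; heterogeneous ones split. Since
subclustering runs within clusters, it strictly refines the K-means
partition.

Features are clustered raw (no standardisation) by default, with a flag to
standardise; the embedding dimensions are produced by a single trained head
and share a scale, so rescaling is not obviously justified and is left off.

Partition agreement is reported as the standard adjusted Rand index and
adjusted mutual information. Both are chance-corrected and can be negative
for worse-than-chance agreement (despite occasionally being described as
0-to-1 quantities); the standard definitions are implemented, AMI with the
exact hypergeometric expected-MI and the arithmetic-mean normaliser. ARI is
delegated to `mclust`; AMI and DBI are implemented here because no
installed package provides them, and both are tested against
direct-definition oracles.

## Subcluster quality (Q) scores

For subcluster i with M_i members, average pairwise interaction-alignment
statistics (score SXsc_i, RMSD SXd_i, alignment length SXal_i) and average
pairwise structure-alignment statistics (TMsc_i, TMd_i, TMal_i), with
maxima over all subclusters in the run:

SXQ_i = SXsc_i/SXsc_max + SXal_i/SXal_max + M_i/M_max − SXd_i/SXd_max

TMQ_i = TMsc_i/TMsc_max + TMal_i/TMal_max + M_i/M_max − TMd_i/TMd_max

Q_i = (SXQ_i + TMQ_i)/2

Averages run over unordered non-self member pairs (C(M_i, 2) of them);
singletons are flagged and zeroed. A ratio with a zero maximum is defined
as 0, covering degenerate corpora. Q is scale-invariant in each score
column and monotone non-increasing in a subcluster's own RMSD.

The per-pair statistics come from pluggable backends. The internal
backends are deliberately simple, fully documented scores — a greedy
LW-class multiset matching for interactions (2 points per matched pair, 0.5
per matched stacking) and a sequence-order Kabsch superposition of
backbone centers for structure (score mean 1/(1+(d_k/d0)²) with d0 = 4 Å —
a fixed constant rather than a length-dependent d0, because 4–20-nucleotide
loops sit below the calibration regime of length-dependent structural
scores). They are *not* reimplementations of external alignment tools; the
`external_table` backend reproduces a tool-based workflow exactly when
per-pair outputs of such tools are supplied as a TSV.

## Supervised evaluation

Subclusters map to families by strict majority: a subcluster is assigned to
a family only when that family holds **more than** 60% of its labelled
members (so an exact 3:2 split stays unassigned), computed over labelled
members only and after a caller-supplied exclusion list (outliers, loops
with missing or conflicting annotations). A Hungarian one-to-one mode is
also provided for classification-report-style evaluation where the
majority map's many-to-one ambiguity matters; the assignment solver is a
potential-based O(n³) Hungarian implementation, tested against brute-force
permutation search. Motif clustering accuracy (MCA) for a family is the
fraction of its known motifs that land in subclusters assigned to that
family. The purity analysis computes, per multi-member subcluster, the
average pairwise RMSD and reports the fraction below a bound obtained as
mean + 2·SD of known-family pairwise RMSDs; singletons are excluded since
they have no pairs.

## Annotation merging

Base-interaction annotations from two tools rarely agree perfectly. The
merge takes two normalised record sets (adapter dialects for FR3D-style and
DSSR-style tables; spelling variants such as `cW-W` are canonicalised, and
FR3D-style stacking codes s35/s53/s33/s55 map to
upward/downward/inward/outward), unions them, and resolves two conflict
shapes: the same unordered pair with different classes, and the same LW
edge (W, H or S side) of one nucleotide claimed by two partners. Each
conflict is decided by corpus frequency of the (base_i, base_j, class)
pattern — which is why the records carry base identities — with a
deterministic tie rule (FR3D source first, then the lexicographically
smaller class token) so merges are reproducible even with an empty corpus.
Stacking records are treated as non-conflicting. Every dropped record
produces one conflict-log row, so the log length always equals the number
of drops, and merging a set with itself is the identity.

## The synthetic generator

The generator exists so the full pipeline — files, graphs, training,
clustering, scoring, evaluation — runs with zero downloads. Eight family
templates (six internal-loop, two hairpin, named after the families they
stand in for: SR, KT, TS, HT, EL, CL, TL, GL) each fix strand lengths, a
sequence, a base-pair and stacking pattern, and a parametric backbone: a
per-strand helix (rise, twist, radius) with an optional kink, the second
strand antiparallel at a fixed offset. Kink-turn-like templates get a
pronounced kink; tetraloop-like templates a tight turn. Six backbone atoms
sit at fixed offsets (summing to zero) around each nucleotide center, so
both distance modes are exercised.

Noise: isotropic Gaussian jitter on each center (default SD 0.3 Å —
small against the >2 Å separation between template shapes, emulating
coordinate uncertainty well below family-level structural differences),
plus annotation noise (each base pair dropped with probability 0.05 and a
surviving pair's class flipped with probability 0.05 — the order of the
annotation disagreement rates seen between real annotation tools). The
built-in templates keep a documented separability floor: the minimum
inter-template center-RMSD exceeds five default jitter SDs, so
nearest-template classification of generated loops stays above 95% and the
end-to-end recovery tests measure the pipeline, not fixture luck.

What the generator does **not** emulate: real ribose/phosphate
stereochemistry, sequence variability within a family, inter-family
structural overlap (e.g. kink-sharing families), length variation within a
family, and multiloops. Passing the synthetic recovery tests therefore
demonstrates that the machinery is correct and deterministic, not that
real-corpus accuracy figures transfer; on real data the families are far
less separable and accuracy is correspondingly lower.

## Problem sizes and numerical choices

The synthetic study used throughout the tests and the acceptance script is
6 internal-loop families × 50 loops (n = 300, split 86/7/7% per family,
mirroring the 253/20/20-style proportions of typical known-motif corpora),
with the GIN at its default widths (hidden 128, embedding 128) trained for
60 epochs — the model converges on this corpus within a handful of epochs,
and the best-validation checkpoint is retained regardless. Unit tests use
smaller widths and corpora chosen for the same reason.

Other numerical choices: LeakyReLU slope 0.01; Glorot-uniform weight
initialisation (edge projections damped ×0.1 so the untrained distance
channel does not swamp the one-hot messages); Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8); softmax computed with max-subtraction; K-means with 10 random
starts and the classic fixed-state convention; `K = n` handled as the
trivial all-singleton partition; zero-maximum Q-score ratios defined as 0;
`two_sd_upper` of a constant vector equals that constant (zero variance).

## Known limitations

* The GIN trainer is CPU-bound, single-threaded base R: ideal for corpora
  of hundreds to a few thousand small graphs, not for atlas-scale runs.
* The internal similarity backends are intentionally crude; Q-scores meant
  for publication-grade subcluster ranking should use the
  `external_table` backend with real alignment-tool outputs.
* Insertion-code-bearing residues are carried but never reordered;
  heterogeneous author numbering inside a segment is not detected.
* Multiloops (three or more segments) parse and encode, but no templates,
  trained models or evaluation conventions are provided for them.
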