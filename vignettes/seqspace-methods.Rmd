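---
title: "Methods and design notes for seqspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for seqspace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models, conventions and numerical choices behind
`seqspace`, at the level of detail a maintainer or reviewer needs. The
README shows the surface; this is the reasoning underneath.

## The clustering model

`seqspace` treats a protein superfamily as a weighted graph: sequences are
nodes, and any pair with a significant local alignment (E-value < 1e-3)
contributes an edge weighted by the alignment bitscore (BLOSUM62). Bitscore
rather than E-value is the canonical similarity: E-values saturate at the
reporting floor of search tools and depend on database size, while
bitscores keep resolving differences between close homologs.

A *neighborhood at cut-off t* is a connected component of the subgraph with
edges of bitscore ≥ t. The threshold is **inclusive** (≥, not >): cut-offs
are typically reported as integers, and inclusivity keeps ties at the
printed threshold inside the cluster. Because the edge set at a higher
cut-off is a subset of the edge set at a lower one, components across an
increasing cut-off ladder nest, giving a refinement hierarchy: coarse
clusters act as parent neighborhoods of the finer clusters that separate
inside them. This single-linkage-like definition is deliberately the
simplest scalable one; its known weakness — one spurious edge merges two
otherwise distinct clusters — is accepted and documented rather than
patched with community detection, which would break the nesting guarantee.

### Streaming components

Component finding is exact and streaming. The edge file is consumed in
chunks of `chunk_edges` edges; each chunk is clustered into a local
disjoint-set forest over only the ids it mentions, and the local clusters
are merged into a global forest (union by smallest index, path halving) by
unioning every member with its local root. The merge is associative and
commutative, so the partition is independent of chunk size and processing
order — a property the test suite checks against an independent in-memory
implementation over randomized graphs and chunkings, including
one-edge-per-chunk. Peak memory is O(nodes + chunk_edges). Multi-cutoff
runs keep one forest per cut-off and apply each edge to every forest whose
cut-off it reaches, so one pass over the file yields the whole hierarchy.
Cluster labels are canonical: each cluster is named after its
lexicographically smallest member, which makes outputs byte-reproducible
across chunkings and input orderings.

### Edge hygiene

Search output is normalized before clustering: self-hits are removed, hits
with E-value ≥ 1e-3 are removed, and the two directions of a reciprocal
hit (or duplicate hits) are merged into one undirected edge. The merged
edge keeps the **maximum** bitscore of its copies. The choice matters only
at threshold boundaries; maximum is used because component clustering asks
whether *any* connection at or above the cut-off exists, and an alignment
achieving a score is evidence that the pair relates at that strength.
Normalization is idempotent and never increases the edge count.

### Cut-off placement

Cut-offs default to the 10/25/50/75/90 percentiles of the bitscore
distribution, estimated from a single-pass reservoir sample (default cap
10⁶ bitscores) so the edge file never needs to be loaded. Quantiles use
linear interpolation between order statistics (R's type 7, the common
default); the estimator choice moves thresholds by at most ~1 bit at
realistic sample sizes. Results are rounded to integer bitscores with
half-up rounding (50.5 → 51), matching how such cut-offs are reported, and
duplicate thresholds after rounding collapse with a warning.

## Embedding-based clustering

Per-residue language-model states (L × d matrices) are mean-pooled to one
vector per sequence and reduced to 30 dimensions by PCA before clustering.
The model itself stays behind an adapter: vectors enter from files or from
the synthetic generator, so the package never needs a GPU or network. PCA
components have a fixed sign convention (largest-magnitude loading
positive) to make reductions bit-reproducible; the reduction is fit on
whatever matrix is supplied, and that fact is recorded in the provenance
field rather than hidden.

### Hierarchy-consistent bisecting K-means

Off-the-shelf bisecting K-means returns flat labels for one K; labels
produced independently at different K need not nest, which breaks any
multi-level visualization. `seqspace` therefore retains the full bisecting
tree: starting from one cluster, the leaf with the largest SSE (sum of
squared Euclidean distances to the leaf centroid — the "spread") is split
by 2-means until `k_max` leaves exist. Each parent→child branch gets length
SSE(parent) − SSE(child), the spread removed by that split. The K_max
leaves then become items of a single-linkage agglomeration whose item
distance is the **branch-length path through the bisecting tree**. The
merge structure is flattened with maxclust semantics — replay merges until
at most K clusters remain, which under monotone heights equals cutting at
the smallest height with ≤ K clusters. Cuts at different K are nested by
construction, and flatten(K_max) reproduces the bisecting leaves exactly.

Two conventions here were genuinely open and are fixed as follows. The
item distance for the single-linkage conversion could have been split
order instead of path length; path length is chosen because it is the
natural tree-induced metric and uses the branch lengths the tree already
defines. And 2-means uses 10 restarts (k-means++-style seeding from
`stats::kmeans`), 300 iterations, with per-split seeds derived from the
master seed, so whole trees are reproducible; ties in leaf SSE break
toward the leaf containing the smallest member index; a leaf with fewer
than two distinct points splits deterministically (first member vs rest)
since 2-means is undefined there.

### Weighted agglomeration and tree summaries

The agglomerative route uses WPGMA ("weighted") linkage over cosine
distances (1 − cosine similarity): a merged cluster's distance to any
third cluster is the plain average of its two parts' distances, which
keeps small, newly merged clusters from being swamped by large ones.
WPGMA over cosine can produce height inversions; heights are made
monotone with a running maximum because maxclust flattening requires
monotone heights. The full pairwise distance matrix is needed, so inputs
are capped (default 50,000 vectors) and larger datasets must be
redundancy-reduced first, with `project_labels()` restoring full-universe
partitions afterwards.

Merge trees export to Newick (leaves at height 0, branch length = height
difference). `summarize_tree(tree, k)` collapses to k clades by repeatedly
opening the internal node nearest the root; a collapsed leaf's branch is
its original incoming branch plus the longest path from the clade root to
any member, so root-to-leaf distances in the summary report worst-case
depths — a conservative summary that never understates how deep a clade
goes. Each clade's subtree remains retrievable at full resolution.

## Agreement metrics

ARI and AMI are implemented from their contingency-table definitions. AMI
uses the permutation-model expected mutual information with log-factorial
guards, normalized by the **arithmetic mean** of the two partition
entropies — the common default among the several published normalizations,
fixed here explicitly because nothing in the pipeline pins it down.
Identical partitions are detected structurally and scored exactly 1,
sidestepping round-off in the EMI sum; two trivial single-cluster
partitions also score 1 by convention. The test suite pins the
implementation to a brute-force hypergeometric evaluation on small tables
and to an empirical null (independent random partitions of 1,000 items
score ≈ 0).

## The hierarchical cluster plot

The layout gives every cluster a circle of area exactly proportional to
its size within its sibling group (radius = sqrt(size/π)), packs sibling
groups, and nests each group inside its parent:

* Packing starts from a seeded sunflower spiral and relaxes overlaps
  iteratively: each overlapping pair is pushed apart along its center line
  by half the overlap each, with a centripetal pull toward the group
  centroid during the first 150 iterations for compactness. Iteration
  stops when the deepest overlap is below `tol = 1e-3 × min(radius)`; a
  radial-inflation fallback guarantees termination. A bespoke relaxer is
  used instead of a physics-engine dependency because the contract —
  overlap-free, compact, deterministic under a seed — is what downstream
  code relies on, not any particular dynamics.
* Nesting translates a packed group so its area-weighted centroid sits on
  the parent center, then rescales uniformly so every child fits within
  0.95 × the parent radius. The 0.95 margin and the tolerance are layout
  constants, not scientific quantities; uniform rescaling preserves exact
  within-group area proportionality, and the per-group scale factor is
  persisted so absolute sizes remain recoverable.
* Filtering (minimum size, or must-contain-sequence) always retains the
  ancestors of kept clusters so the nesting stays well formed.

The persisted TSV layout is the exchange surface; rendering (ggplot via
`autoplot()`) is a convenience on top, not part of the contract.

## Representatives and their evaluation

Two selection routes. The profile route aligns the cluster (mafft when
lengths differ; the alignment may also be supplied), builds a profile, and
returns the best-scoring member: with HMMER3 present this is
hmmbuild/hmmsearch full-sequence bitscore; the pure fallback scores
match-column log-odds (match columns = columns with < 50% gaps, Laplace
pseudocount 1, uniform 1/20 background, gaps scoring 0). Fallback and
HMMER scores are different scales and are never mixed in one report. The
vector route returns the member nearest (Euclidean) the cluster's mean
vector. All ties break to the smaller id; singletons represent themselves
with score 0.

Global percent identity — used for all evaluation metrics — is fixed as:
Needleman–Wunsch global alignment, BLOSUM62, affine gaps open 11 / extend
1, identity = identical columns / alignment length including all gap
columns (terminal gaps count), × 100. The convention shifts absolute
percentages, not orderings, and is applied uniformly. Representative
evaluation reports (i) the median member→representative %ID minus the
median of seeded random member pairs (capped at 10,000 pairs, since full
pairwise %ID is quadratic), (ii) the representative's percentile rank
among all members' median-%IDs (1 = most central), and (iii) representative
length minus median member length. Cluster property tables (size,
within/between %ID, genus counts) consider clusters of ≥ 5 members, the
conventional floor below which such statistics are noise.

## Even sampling for phylogenetics

The sampler walks the homology hierarchy from a base cut-off of 150
bitscore in +10 steps up to 400, taking one representative from every
neighborhood of 100–1,000 sequences, re-splitting larger neighborhoods at
the next cut-off, and skipping smaller ones; representatives outside
100–300 residues are excluded and logged. When anchor sequences are given,
only descendants of the anchor-containing neighborhoods at bitscore 102
are visited. One open case had to be decided: a neighborhood still larger
than 1,000 sequences at the final cut-off. It yields one flagged
representative rather than none — dropping it would leave a visible region
of sequence space unsampled, defeating the purpose of even coverage; the
flag (`unresolved_at_max_cutoff`) keeps the compromise auditable.

## What the synthetic world does and does not emulate

`make_world()` plants the two-level organization the methods assume:
superfamily ancestors are random proteins; family centers are ancestors
point-mutated at rate 0.3; members are centers mutated at rate 0.05
(substitutions only, so family members share a length). Homology edges are
*drawn*, not aligned: within-family pairs get bitscores ~N(250, 15),
between-family pairs within a superfamily ~N(120, 15) (sparse, plus a
spanning chain so superfamilies are connected), cross-superfamily pairs
get no edge, emulating the E-value filter. Embeddings come from a
hierarchical Gaussian mixture in which `sep_super`, `sep_fam` and
`noise_sd` are expected Euclidean distances (center–center, family–super,
member–family), so `sep_fam/noise_sd` reads directly as the planted
separation-to-noise ratio; defaults 60/10/1 describe a cleanly separable
world.

A green test on this world establishes that the algorithms recover planted
structure whose separations exceed the noise — it does not establish
performance on real superfamilies, where bitscore distributions are
heavy-tailed and overlapping, families differ by orders of magnitude in
size, domain architecture varies within clusters, and embedding geometry
is not Gaussian. Drawn bitscores also mean the fixture cannot detect
errors in alignment scoring itself; the %ID machinery is instead tested
on real alignments of mutated sequences.

## Known limitations

* Component clustering inherits single-linkage sensitivity: one spurious
  significant hit merges two neighborhoods. Percentile ladders mitigate
  (the merge usually dissolves at the next cut-off) but do not remove this.
* WPGMA requires the full distance matrix; beyond the configured budget the
  user must downsample, and agreement comparisons then depend on
  `project_labels()` coverage.
* The fallback profile scorer is a position-specific scoring matrix, not a
  full profile HMM (no insert/delete states, no E-values); it exists so
  selection is testable without binaries, and its choices agree with HMMER
  on well-behaved clusters, not adversarial ones.
* `evaluate_representative()` computes all-pairs identities for the rank
  metric and is quadratic in cluster size; it is an evaluation tool for
  sampled clusters, not a bulk operation.
* The even sampler assumes the hierarchy is computable across the full
  cut-off range in one pass; extremely dense graphs make the multi-forest
  pass memory-heavy (one forest per cut-off, 26 by default).
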