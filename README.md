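# seqspace

Hierarchical clustering and exploration of protein sequence space.

Protein superfamilies organize hierarchically: highly divergent sequences
form superfamilies, which subdivide into isofunctional families at higher
homology. The standard tool for mapping this landscape — the sequence
similarity network (SSN), with sequences as nodes and pairwise alignment
bitscores as edges — struggles at modern dataset sizes (hundreds of
thousands of sequences, 10⁸+ edges) and can only show one similarity
cut-off at a time, even though different families separate at different
cut-offs. `seqspace` is aimed at protein bioinformaticians and enzyme
engineers who need to survey such superfamilies on desktop hardware: it
finds sequence neighborhoods at many cut-offs at once, visualizes the whole
hierarchy in one figure, and reduces neighborhoods to single representative
sequences for downstream work (annotation transfer, phylogenetics, library
design).

## What it computes

* **Homology neighborhoods.** For each bitscore cut-off *t*, the
  neighborhoods are the connected components of the SSN restricted to edges
  with bitscore ≥ *t*. Components are computed by a streaming, chunked
  union-find: the edge file is read in chunks, each chunk is clustered into
  a local disjoint-set forest, and chunk results are merged by unioning
  clusters that share a member — peak memory is O(nodes + chunk), never
  O(edges), and the result is provably independent of chunking. Because the
  surviving edge set shrinks as *t* grows, the partitions at an increasing
  cut-off ladder *t₁ < t₂ < …* nest into a cluster hierarchy. Cut-offs are
  placed at percentiles (default 10/25/50/75/90) of the sampled bitscore
  distribution.
* **Embedding neighborhoods.** Mean-pooled protein language-model vectors
  (read from disk or generated synthetically; reduced to 30 PCA dimensions)
  are clustered two ways: (i) bisecting K-means — repeatedly 2-means-split
  the leaf with the largest SSE — keeping the full split tree so that
  single-linkage over tree-path distances plus maxclust flattening yields
  flat clusterings that are *hierarchy-consistent* (the cut at K₂ > K₁
  always refines the cut at K₁); (ii) WPGMA ("weighted") agglomeration over
  cosine distances, exportable to Newick and collapsible to K clades whose
  branch lengths report the longest distance to any member sequence.
* **Agreement.** Adjusted Rand index and adjusted mutual information
  (permutation-model expected MI, mean-entropy normalization) over every
  pair of levels of two hierarchies.
* **Hierarchical cluster plot.** Each cluster becomes a circle with area ∝
  size; siblings are packed by iterative overlap relaxation and nested
  inside their parent circle. The layout persists to a TSV any renderer can
  draw; `autoplot()` gives a ggplot view.
* **Representatives.** Per cluster, either the member scoring highest
  against the cluster's profile HMM (HMMER3 when available, a pure
  log-odds profile scorer otherwise) or the member nearest the embedding
  centroid, with evaluation metrics (identity gain over random pairs,
  centrality rank, length bias) and per-cluster property tables
  (size, within/between global %ID, genus diversity).
* **Even sampling for phylogenetics.** Walk the hierarchy from a base
  cut-off, taking one representative from every neighborhood of 100–1,000
  sequences and re-splitting larger ones in +10-bitscore steps (up to 400),
  with a 100–300 residue length filter — even coverage of sequence space
  instead of BLAST-neighborhood oversampling.

Seeded generators (`make_world()`, `synth_embeddings()`,
`make_edge_bands()`) produce complete synthetic datasets — sequences with
planted superfamily/family structure, banded m8 edge files, matching
embedding vectors, annotations — so everything is testable offline.

## Worked example

```r
library(seqspace)

w <- make_world(n_super = 4, fam_per_super = 3, members_per_fam = 20, seed = 42)
#> <planted_world> 240 sequences, 4 superfamilies x 3 families, 2302 edges (seed 42)

percentile_cutoffs(sample_bitscores(w$store, seed = 42), c(25, 75))
#> <cutoff_set> 239, 260 (percentiles 25, 75 of 2302 bitscores)

hier <- components_multi(w$store, c(100, 185))
glance(hier)
#> # A tibble: 2 × 5
#>   level        n_clusters n_singletons max_size median_size
#> 1 bitscore:100          4            0       60          60
#> 2 bitscore:185         12            0       20          20

ari(hier$levels[[2]], tibble::tibble(id = w$truth$id, cluster = w$truth$family))
#> [1] 1

bt <- bisecting_kmeans(w$embeddings, k_max = 12, seed = 42)
km <- project_labels(flatten_clusters(tree_to_linkage(bt), 12), leaf_membership(bt))
ari(hier$levels[[2]], km)
#> [1] 1

fam <- hier$levels[[2]]
vector_representative(fam$id[fam$cluster == "S01F01M001"], w$embeddings)
#> # A tibble: 1 × 3
#>   representative method  score
#> 1 S01F01M009     vector -0.760
```

The fixture plants 4 superfamilies (edge band ~N(120, 15) between families
of a superfamily) each holding 3 families (~N(250, 15) within). At bitscore
100 the components are exactly the 4 superfamilies (60 sequences each); at
185 — between the bands — they are exactly the 12 planted families, and the
agreement between the homology partition and the planted truth (and the
hierarchy-consistent K-means partition at K = 12) is ARI = 1. The chosen
representative's score is minus its Euclidean distance to the family's
embedding centroid. `build_layout(hier, seed = 42)` then packs those
clusters into the nested-circle layout, and `autoplot()` draws it.

A thin CLI over the same functions ships at `inst/scripts/pck`
(`pck network | cutoffs | cluster | agree | layout | reps | sample | run`).

## Acceptance script

`scripts/acceptance.R` regenerates a seeded synthetic world, runs the whole
pipeline against it from scratch (edge normalization → percentile cut-offs →
multi-cutoff components → hierarchy-consistent K-means → layout →
representative selection → cluster property statistics), verifies every
stage completes, and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
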