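node_sse <- function(x) {
  if (nrow(x) <= 1) return(0)
  ctr <- colMeans(x)
  sum(sweep(x, 2, ctr, `-`)^2)
}

# 2-means split of one leaf; seeded, with a deterministic fallback when the
# leaf has fewer than two distinct points (kmeans cannot split those).
split_two <- function(x, seed, n_init, iter_max) {
  distinct_rows <- nrow(unique(round(x, 12)))
  if (distinct_rows < 2) {
    return(c(1L, rep(2L, nrow(x) - 1L)))
  }
  set.seed(seed)
  km <- tryCatch(
    kmeans(x, centers = 2L, nstart = n_init, iter.max = iter_max),
    error = function(e) NULL
  )
  if (is.null(km)) {
    # duplicate rows can break random center sampling; seed Lloyd from the
    # two most distant distinct rows instead
    ctrs <- unique(round(x, 12))
    d1 <- rowSums(sweep(ctrs, 2, ctrs[1, ], `-`)^2)
    far <- which.max(d1)
    km <- tryCatch(
      kmeans(x, centers = ctrs[c(1L, far), , drop = FALSE],
             iter.max = iter_max),
      error = function(e) NULL
    )
  }
  if (is.null(km)) return(c(1L, rep(2L, nrow(x) - 1L)))
  km$cluster
}

#' Bisecting K-means with a retained split tree
#'
#' Divisive clustering over embedding vectors: starting from one cluster
#' holding every sequence, the leaf with the largest within-cluster spread
#' (SSE, sum of squared Euclidean distances to the leaf centroid) is
#' repeatedly split with seeded 2-means until `k_max` leaves exist. Unlike
#' off-the-shelf implementations that discard it, the full bisecting tree is
#' retained — every node keeps its member set and SSE — because the tree is
#' what guarantees hierarchy-consistent flat clusterings at every smaller K
#' (see [tree_to_linkage()] and [flatten_clusters()]).
#'
#' @param embeddings An [embedding_matrix()].
#' @param k_max Number of leaves to produce (2..n).
#' @param seed Master seed; each split draws its own sub-seed so the whole
#'   tree is reproducible.
#' @param n_init Random restarts per 2-means split.
#' @param iter_max Maximum Lloyd iterations per split.
#' @return An object of class `bisecting_tree`: `nodes` (list with
#'   `members`, `sse`, `children`, `parent`, `branch` = SSE(parent) -
#'   SSE(node)), `leaves` (node indices), `ids` (sequence ids).
#' @export
bisecting_kmeans <- function(embeddings, k_max, seed = 1L, n_init = 10L,
                             iter_max = 300L) {
  x <- unclass(embeddings)
  n <- nrow(x)
  if (k_max < 2 || k_max > n) {
    stop_dimension("k_max must lie in [2, number of sequences]")
  }
  set.seed(seed)
  split_seeds <- sample.int(2147483646L, k_max)
  nodes <- list(list(members = seq_len(n), sse = node_sse(x),
                     children = NULL, parent = NA_integer_, branch = 0))
  leaves <- 1L
  n_splits <- 0L
  while (length(leaves) < k_max) {
    splittable <- leaves[vapply(leaves, function(i) {
      length(nodes[[i]]$members) > 1L
    }, logical(1))]
    if (length(splittable) == 0) break
    sse <- vapply(splittable, function(i) nodes[[i]]$sse, numeric(1))
    minm <- vapply(splittable, function(i) min(nodes[[i]]$members), integer(1))
    pick <- splittable[order(-sse, minm)][1]
    n_splits <- n_splits + 1L
    mem <- nodes[[pick]]$members
    assign2 <- split_two(x[mem, , drop = FALSE], split_seeds[n_splits],
                         n_init, iter_max)
    # stable side labels: side containing the smallest member index is child 1
    if (assign2[1] != 1L) assign2 <- 3L - assign2
    for (side in 1:2) {
      child_members <- mem[assign2 == side]
      child_sse <- node_sse(x[child_members, , drop = FALSE])
      nodes[[length(nodes) + 1L]] <- list(
        members = child_members, sse = child_sse,
        children = NULL, parent = pick,
        branch = max(nodes[[pick]]$sse - child_sse, 0)
      )
    }
    nodes[[pick]]$children <- c(length(nodes) - 1L, length(nodes))
    leaves <- c(setdiff(leaves, pick), length(nodes) - 1L, length(nodes))
  }
  structure(
    list(nodes = nodes, leaves = sort(leaves), ids = rownames(x),
         k_max = length(leaves), seed = seed),
    class = "bisecting_tree"
  )
}

#' @export
print.bisecting_tree <- function(x, ...) {
  cat("<bisecting_tree> ", x$k_max, " leaves over ", length(x$ids),
      " sequences (root SSE ", format(x$nodes[[1]]$sse, digits = 6), ")\n",
      sep = "")
  invisible(x)
}

#' Leaf membership of a bisecting tree
#'
#' @param tree A `bisecting_tree`.
#' @return Tibble with columns `item` (leaf label: smallest member id) and
#'   `id` (sequence id).
#' @export
leaf_membership <- function(tree) {
  stopifnot(inherits(tree, "bisecting_tree"))
  purrr::map_dfr(tree$leaves, function(i) {
    ids <- tree$ids[tree$nodes[[i]]$members]
    tibble(item = min(ids), id = ids)
  }) |>
    arrange(.data$item, .data$id)
}

# cumulative branch length from the root for every node
node_heights <- function(tree) {
  h <- numeric(length(tree$nodes))
  for (i in seq_along(tree$nodes)) {
    p <- tree$nodes[[i]]$parent
    h[i] <- if (is.na(p)) 0 else h[p] + tree$nodes[[i]]$branch
  }
  h
}

#' Convert a bisecting tree to a single-linkage merge structure
#'
#' Treats the bisecting leaves as items. The distance between two items is
#' the branch-length path between them in the bisecting tree, where each
#' branch length is the drop in spread from parent to child
#' (SSE(parent) - SSE(child)). Single-linkage agglomeration over that
#' tree-induced metric yields a merge structure whose flat cuts are
#' consistent with the bisecting hierarchy at every K.
#'
#' @param tree A `bisecting_tree`.
#' @return A `merge_linkage` object (see [merge_linkage()]).
#' @export
tree_to_linkage <- function(tree) {
  stopifnot(inherits(tree, "bisecting_tree"))
  k <- length(tree$leaves)
  labels <- vapply(tree$leaves, function(i) {
    min(tree$ids[tree$nodes[[i]]$members])
  }, character(1))
  if (k == 1) {
    return(merge_linkage(matrix(numeric(0), 0, 2), numeric(0), labels,
                         method = "single"))
  }
  h <- node_heights(tree)
  anc <- lapply(tree$leaves, function(i) {
    path <- i
    while (!is.na(tree$nodes[[path[length(path)]]]$parent)) {
      path <- c(path, tree$nodes[[path[length(path)]]]$parent)
    }
    path
  })
  D <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      common <- intersect(anc[[a]], anc[[b]])
      lca <- common[which.max(h[common])]
      D[a, b] <- D[b, a] <- (h[tree$leaves[a]] - h[lca]) +
        (h[tree$leaves[b]] - h[lca])
    }
  }
  dimnames(D) <- list(labels, labels)
  hc <- hclust(as.dist(D), method = "single")
  merge_linkage(hc$merge, hc$height, labels, method = "single")
}

#' Merge linkage: an agglomeration record over items
#'
#' Stores the (n_items - 1) merges of a hierarchical agglomeration in hclust
#' form (negative entries reference items, positive entries earlier merges)
#' with non-decreasing heights. Heights are made monotone with a running
#' maximum — weighted linkage over cosine distances can produce inversions,
#' and monotone heights are what make "cut into at most K clusters"
#' (maxclust) well defined.
#'
#' @param merge Integer (n-1) x 2 hclust-style merge matrix.
#' @param height Numeric merge heights.
#' @param labels Item labels.
#' @param method Linkage method name (provenance).
#' @return An object of class `merge_linkage`.
#' @export
merge_linkage <- function(merge, height, labels, method = "unknown") {
  if (length(height) > 0 && any(diff(height) < 0)) height <- cummax(height)
  structure(
    list(merge = merge, height = height, labels = labels,
         n_items = length(labels), method = method),
    class = "merge_linkage"
  )
}

#' @export
print.merge_linkage <- function(x, ...) {
  cat("<merge_linkage> ", x$n_items, " items, method ", x$method, "\n",
      sep = "")
  invisible(x)
}

#' Flatten a merge linkage into at most K clusters
#'
#' Maxclust semantics: the merge sequence is replayed from the start and
#' stopped after `n_items - k` merges, which under monotone heights is
#' exactly a cut at the smallest height yielding at most `k` clusters. Cuts
#' at different K are nested by construction — the hierarchy-consistency
#' property the bisecting-tree route exists to guarantee. `k = n_items`
#' reproduces the items (for a bisecting tree, its leaves) exactly.
#'
#' @param linkage A `merge_linkage`.
#' @param k Target number of clusters (1..n_items).
#' @return Partition tibble (`id` = item label, `cluster` = smallest item
#'   label in the group) with level attribute `"K:<k>"`.
#' @export
flatten_clusters <- function(linkage, k) {
  stopifnot(inherits(linkage, "merge_linkage"))
  n <- linkage$n_items
  if (k < 1 || k > n) stop_dimension("k must lie in [1, n_items]")
  grp <- seq_len(n)
  if (n - k >= 1) {
    merge_grp <- integer(n - 1L)
    for (m in seq_len(n - k)) {
      pick <- function(v) if (v < 0) grp[-v] else merge_grp[v]
      ga <- pick(linkage$merge[m, 1])
      gb <- pick(linkage$merge[m, 2])
      keep <- min(ga, gb)
      grp[grp == ga | grp == gb] <- keep
      merge_grp[m] <- keep
    }
  }
  labs <- vapply(split(linkage$labels, grp), min, character(1))
  new_partition(linkage$labels, unname(labs[as.character(grp)]),
                level = paste0("K:", k))
}

#' Project cluster labels from representatives to their members
#'
#' After clustering a reduced set (bisecting leaves, redundancy-reduced
#' representatives), every member inherits the cluster of its
#' representative, restoring a partition over the full id universe.
#'
#' @param partition Partition tibble over representative ids.
#' @param membership Tibble with columns `item` (representative id, present
#'   in `partition`) and `id` (member sequence id).
#' @return Partition tibble over member ids, same level attribute.
#' @export
project_labels <- function(partition, membership) {
  stopifnot(all(c("item", "id") %in% names(membership)))
  miss <- setdiff(membership$item, partition$id)
  if (length(miss) > 0) {
    stop_coverage(paste0("member(s) with no representative in the partition: ",
                         paste(head(miss, 5), collapse = ", ")))
  }
  out <- tibble(
    id = membership$id,
    cluster = partition$cluster[match(membership$item, partition$id)]
  ) |>
    arrange(.data$id)
  attr(out, "level") <- attr(partition, "level")
  out
}

#' Weighted-linkage (WPGMA) agglomerative clustering over cosine distances
#'
#' Hierarchical agglomeration of embedding vectors using cosine distance
#' (1 - cosine similarity) and the "weighted" linkage rule, in which a
#' merged cluster's distance to any other cluster is the simple average of
#' its two parts' distances. The full pairwise distance matrix is required,
#' so the number of vectors is capped (`max_n`); beyond it the caller must
#' reduce redundancy first (e.g. cluster to 70% identity representatives and
#' project labels back with [project_labels()]).
#'
#' @param embeddings An [embedding_matrix()].
#' @param max_n Memory budget: maximum number of vectors.
#' @return List with `linkage` (a `merge_linkage`) and `tree` (the
#'   equivalent rooted `phylo`, branch lengths = height differences).
#' @export
agglomerative_clustering <- function(embeddings, max_n = 50000L) {
  x <- unclass(embeddings)
  n <- nrow(x)
  if (n > max_n) {
    stop_memory_budget(paste0(
      n, " vectors exceed the ", max_n, "-vector distance-matrix budget; ",
      "reduce redundancy (e.g. 70% identity representatives) first"))
  }
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop_parameter("zero vectors have no cosine direction")
  S <- tcrossprod(x / nrm)
  D <- pmin(pmax(1 - S, 0), 2)
  diag(D) <- 0
  dimnames(D) <- list(rownames(x), rownames(x))
  hc <- hclust(as.dist(D), method = "mcquitty")
  linkage <- merge_linkage(hc$merge, hc$height, rownames(x),
                           method = "weighted/cosine")
  list(linkage = linkage, tree = linkage_to_phylo(linkage))
}

#' Convert a merge linkage to a rooted phylo tree
#'
#' Leaves sit at height 0, each merge node at its (monotone) merge height,
#' and every branch length is the height difference between parent and
#' child, so root-to-leaf distances equal the root merge height.
#'
#' @param linkage A `merge_linkage`.
#' @return An `ape::phylo` tree.
#' @export
linkage_to_phylo <- function(linkage) {
  n <- linkage$n_items
  stopifnot(n >= 2)
  n_merge <- n - 1L
  node_of_merge <- n + 1L + (n_merge - seq_len(n_merge))
  edges <- matrix(0L, 2L * n_merge, 2L)
  lens <- numeric(2L * n_merge)
  row <- 0L
  for (m in seq_len(n_merge)) {
    for (j in 1:2) {
      ch <- linkage$merge[m, j]
      child_node <- if (ch < 0) -ch else node_of_merge[ch]
      child_h <- if (ch < 0) 0 else linkage$height[ch]
      row <- row + 1L
      edges[row, ] <- c(node_of_merge[m], child_node)
      lens[row] <- max(linkage$height[m] - child_h, 0)
    }
  }
  tree <- structure(
    list(edge = edges, edge.length = lens, tip.label = linkage$labels,
         Nnode = n_merge),
    class = "phylo", order = "postorder"
  )
  ape::reorder.phylo(tree, "cladewise")
}

#' Summarize a tree into K collapsed clades
#'
#' Cuts a rooted tree with branch lengths into `k` clades by repeatedly
#' opening the internal node closest to the root, then collapses each clade
#' to a single leaf. A collapsed leaf's branch length is its original
#' incoming branch plus the longest path from the clade root to any leaf
#' inside it — i.e. the longest distance from the cut point to any single
#' sequence in the collapsed clade — so root-to-leaf distances in the
#' summary tree report worst-case depths. Each clade's original subtree
#' remains retrievable for higher-resolution views.
#'
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @param k Number of clades (1..number of leaves).
#' @return List with `tree` (collapsed `phylo`; for `k = 1` a single-leaf
#'   tree whose edge is the tree height), `membership` (tibble `id`,
#'   `cluster`), and `nodes` (tibble `cluster`, `node` giving each clade's
#'   root node in the original tree).
#' @export
summarize_tree <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (k < 1 || k > n_tip) stop_dimension("k must lie in [1, leaf count]")
  depth <- ape::node.depth.edgelength(tree)
  root <- n_tip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  incoming <- setNames(tree$edge.length, tree$edge[, 2])

  open <- root
  while (length(open) < k) {
    internal <- open[open > n_tip]
    pick <- internal[order(depth[internal], internal)][1]
    open <- c(setdiff(open, pick), children[[as.character(pick)]])
  }

  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  clades <- lapply(open, tips_under)
  labels <- vapply(clades, function(t) min(tree$tip.label[t]), character(1))
  ord <- order(labels)
  open <- open[ord]; clades <- clades[ord]; labels <- labels[ord]

  membership <- purrr::map_dfr(seq_along(open), function(i) {
    tibble(id = tree$tip.label[clades[[i]]], cluster = labels[i])
  }) |> arrange(.data$id)

  leaf_len <- vapply(seq_along(open), function(i) {
    inc <- if (open[i] == root) 0 else unname(incoming[as.character(open[i])])
    inc + max(depth[clades[[i]]]) - depth[open[i]]
  }, numeric(1))

  if (k == 1) {
    collapsed <- structure(
      list(edge = matrix(c(2L, 1L), 1, 2), edge.length = leaf_len,
           tip.label = labels, Nnode = 1L),
      class = "phylo", order = "cladewise")
  } else {
    build <- function(node) {
      i <- match(node, open)
      if (!is.na(i)) {
        return(paste0(labels[i], ":", format(leaf_len[i], digits = 12)))
      }
      key <- as.character(node)
      kids <- vapply(children[[key]], build, character(1))
      inc <- if (node == root) 0 else unname(incoming[key])
      paste0("(", paste(kids, collapse = ","), "):",
             format(inc, digits = 12))
    }
    collapsed <- read_newick(paste0(build(root), ";"))
  }
  list(tree = collapsed, membership = membership,
       nodes = tibble(cluster = labels, node = open))
}

#' Extract the original subtree of a collapsed clade
#'
#' @param tree The original `phylo` passed to [summarize_tree()].
#' @param summary The [summarize_tree()] result.
#' @param cluster A clade label from `summary$nodes`.
#' @return The clade's `phylo` subtree (a single-tip tree for leaf clades).
#' @export
cluster_subtree <- function(tree, summary, cluster) {
  node <- summary$nodes$node[match(cluster, summary$nodes$cluster)]
  if (is.na(node)) stop_parameter(paste0("unknown cluster: ", cluster))
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) {
    return(structure(
      list(edge = matrix(c(2L, 1L), 1, 2), edge.length = 0,
           tip.label = tree$tip.label[node], Nnode = 1L),
      class = "phylo", order = "cladewise"))
  }
  ape::extract.clade(tree, node)
}
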