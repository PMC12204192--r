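two_masses <- function(n_side = 5, gap = 10) {
  x <- matrix(c(rep(0, n_side), rep(gap, n_side)), ncol = 1)
  rownames(x) <- sprintf("m%02d", seq_len(2 * n_side))
  embedding_matrix(x)
}

test_that("bisecting_kmeans splits two point masses with closed-form SSE", {
  em <- two_masses()
  bt <- bisecting_kmeans(em, k_max = 2, seed = 1)
  expect_equal(bt$k_max, 2L)
  leaf_members <- lapply(bt$leaves, function(i) bt$nodes[[i]]$members)
  expect_setequal(lapply(leaf_members, sort), list(1:5, 6:10))
  # root SSE: 10 points at distance 5 from the grand mean
  expect_equal(bt$nodes[[1]]$sse, 10 * 25)
  for (i in bt$leaves) {
    expect_equal(bt$nodes[[i]]$sse, 0)
    expect_equal(bt$nodes[[i]]$branch, 250)
  }
})

test_that("k_max = n gives singleton leaves with zero SSE", {
  set.seed(2)
  x <- matrix(rnorm(12 * 3), 12)
  rownames(x) <- sprintf("p%02d", 1:12)
  bt <- bisecting_kmeans(embedding_matrix(x), k_max = 12, seed = 3)
  expect_equal(bt$k_max, 12L)
  expect_true(all(vapply(bt$leaves, function(i) {
    length(bt$nodes[[i]]$members) == 1 && bt$nodes[[i]]$sse == 0
  }, logical(1))))
  expect_error(bisecting_kmeans(embedding_matrix(x), k_max = 13),
               class = "seqspace_dimension")
})

test_that("bisecting K-means recovers a planted 8-family fixture", {
  z <- synth_embeddings(n_super = 4, fam_per_super = 2, members_per_fam = 10,
                        sep_fam = 10, noise_sd = 1, seed = 4)
  bt <- bisecting_kmeans(z$embeddings, k_max = 8, seed = 5)
  part <- project_labels(
    flatten_clusters(tree_to_linkage(bt), 8), leaf_membership(bt))
  expect_equal(ari(part, tibble::tibble(id = z$truth$id,
                                        cluster = z$truth$family)), 1)
})

test_that("tree_to_linkage reproduces single linkage over tree path distances", {
  em <- two_masses()
  bt <- bisecting_kmeans(em, k_max = 2, seed = 1)
  lk <- tree_to_linkage(bt)
  expect_equal(lk$n_items, 2L)
  # single merge at the summed branch lengths (250 + 250)
  expect_equal(lk$height, 500)

  # caterpillar-ish random trees: naive single linkage on the path metric
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(30 * 3), 30)
    rownames(x) <- sprintf("p%02d", 1:30)
    bt <- bisecting_kmeans(embedding_matrix(x), k_max = 6, seed = s)
    lk <- tree_to_linkage(bt)
    h <- seqspace:::node_heights(bt)
    leaves <- bt$leaves
    D <- matrix(0, 6, 6)
    anc <- lapply(leaves, function(i) {
      path <- i
      while (!is.na(bt$nodes[[path[length(path)]]]$parent)) {
        path <- c(path, bt$nodes[[path[length(path)]]]$parent)
      }
      path
    })
    for (a in 1:5) for (b in (a + 1):6) {
      lca <- intersect(anc[[a]], anc[[b]])
      lca <- lca[which.max(h[lca])]
      D[a, b] <- D[b, a] <- h[leaves[a]] + h[leaves[b]] - 2 * h[lca]
    }
    expect_equal(sort(lk$height), naive_single_linkage_heights(D),
                 tolerance = 1e-10)
    expect_true(all(diff(lk$height) >= 0))
  }
})

test_that("flatten_clusters honors maxclust semantics and nests across k", {
  em <- two_masses()
  bt <- bisecting_kmeans(em, k_max = 2, seed = 1)
  lk <- tree_to_linkage(bt)
  p1 <- flatten_clusters(lk, 1)
  expect_equal(dplyr::n_distinct(p1$cluster), 1L)
  p2 <- flatten_clusters(lk, 2)
  expect_equal(dplyr::n_distinct(p2$cluster), 2L)
  expect_error(flatten_clusters(lk, 3), class = "seqspace_dimension")

  # k = K_max reproduces the bisecting leaves exactly
  set.seed(6)
  x <- matrix(rnorm(40 * 4), 40)
  rownames(x) <- sprintf("p%02d", 1:40)
  bt <- bisecting_kmeans(embedding_matrix(x), k_max = 10, seed = 7)
  lk <- tree_to_linkage(bt)
  mem <- leaf_membership(bt)
  flat <- project_labels(flatten_clusters(lk, 10), mem)
  leaves_part <- canonical_labels(
    tibble::tibble(id = mem$id, cluster = mem$item))
  expect_true(partition_equal(dplyr::arrange(flat, id),
                              dplyr::arrange(leaves_part, id)))
})

test_that("WPGMA/cosine linkage matches the naive recurrence", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(10 * 5), 10)
    rownames(x) <- sprintf("v%02d", 1:10)
    res <- agglomerative_clustering(embedding_matrix(x))
    nrm <- sqrt(rowSums(x^2))
    D <- 1 - tcrossprod(x / nrm)
    diag(D) <- 0
    naive <- naive_wpgma_heights(D)
    expect_equal(res$linkage$height, cummax(naive), tolerance = 1e-10)
  }
})

test_that("agglomerative handles identical and orthogonal vectors", {
  x <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 5, 0))
  rownames(x) <- c("a", "b", "c")
  res <- agglomerative_clustering(embedding_matrix(x))
  expect_equal(res$linkage$height[1], 0)
  first <- sort(-res$linkage$merge[1, ])
  expect_equal(first, c(1, 2))  # the identical pair merges first

  y <- diag(4)
  rownames(y) <- letters[1:4]
  res4 <- agglomerative_clustering(embedding_matrix(y))
  expect_equal(res4$linkage$height[1], 1)

  big <- matrix(rnorm(20), 10, 2,
                dimnames = list(sprintf("r%02d", 1:10), NULL))
  expect_error(agglomerative_clustering(embedding_matrix(big), max_n = 5),
               class = "seqspace_memory_budget")
})

test_that("linkage_to_phylo round-trips through Newick with consistent depths", {
  set.seed(8)
  x <- matrix(rnorm(12 * 4), 12)
  rownames(x) <- sprintf("v%02d", 1:12)
  res <- agglomerative_clustering(embedding_matrix(x))
  tree <- res$tree
  expect_s3_class(tree, "phylo")
  # all leaves at depth = root height (ultrametric by construction)
  depths <- ape::node.depth.edgelength(tree)[seq_len(12)]
  expect_equal(max(abs(depths - max(res$linkage$height))), 0,
               tolerance = 1e-10)
  back <- read_newick(write_newick(tree))
  d1 <- ape::cophenetic.phylo(tree)
  d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("summarize_tree collapses clades with worst-case branch lengths", {
  set.seed(9)
  tree <- ape::rtree(12)
  full <- summarize_tree(tree, 12)
  expect_setequal(full$tree$tip.label, tree$tip.label)
  d1 <- ape::cophenetic.phylo(tree)
  d2 <- ape::cophenetic.phylo(full$tree)[rownames(d1), colnames(d1)]
  expect_lt(max(abs(d1 - d2)), 1e-9)

  one <- summarize_tree(tree, 1)
  expect_equal(length(one$tree$tip.label), 1L)
  expect_equal(one$tree$edge.length,
               max(ape::node.depth.edgelength(tree)[1:12]))

  s <- summarize_tree(tree, 5)
  expect_equal(nrow(s$nodes), 5L)
  expect_setequal(s$membership$id, tree$tip.label)
  # collapsed root-to-leaf distance = max original root-to-leaf in clade
  depth <- ape::node.depth.edgelength(tree)
  cdepth <- ape::node.depth.edgelength(s$tree)
  for (i in seq_len(5)) {
    lab <- s$tree$tip.label[i]
    members <- s$membership$id[s$membership$cluster == lab]
    want <- max(depth[match(members, tree$tip.label)])
    expect_equal(cdepth[i], want, tolerance = 1e-9)
  }
  # subtrees retrievable
  sub <- cluster_subtree(tree, s, s$nodes$cluster[1])
  expect_s3_class(sub, "phylo")
})

test_that("project_labels lifts representative labels and checks coverage", {
  part <- tibble::tibble(id = c("r1", "r2"), cluster = c("c1", "c2"))
  membership <- tibble::tibble(item = rep(c("r1", "r2"), each = 3),
                               id = paste0("s", 1:6))
  lifted <- project_labels(part, membership)
  expect_equal(nrow(lifted), 6L)
  expect_equal(dplyr::n_distinct(lifted$cluster), 2L)
  # identity membership leaves the partition unchanged
  idm <- tibble::tibble(item = part$id, id = part$id)
  expect_equal(project_labels(part, idm)$cluster, part$cluster)
  expect_error(
    project_labels(part, tibble::tibble(item = "r9", id = "s9")),
    class = "seqspace_coverage")
})
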