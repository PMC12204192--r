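test_that("components_at_cutoff matches hand-derived partitions", {
  edges <- tibble::tibble(id1 = c("A", "B"), id2 = c("B", "C"),
                          bitscore = c(200, 90))
  st <- edge_store(edges, nodes = c("A", "B", "C", "D"))
  p <- components_at_cutoff(st, 100)
  expect_equal(p$cluster, c("A", "A", "C", "D"))
  expect_equal(partition_level(p), "bitscore:100")

  # cutoff above every bitscore: all singletons
  p2 <- components_at_cutoff(st, 1000)
  expect_equal(p2$cluster, p2$id)

  # threshold is inclusive: an edge exactly at the cutoff survives
  p3 <- components_at_cutoff(st, 200)
  expect_equal(p3$cluster, c("A", "A", "C", "D"))
})

test_that("streaming components equal the igraph oracle across chunkings", {
  for (s in 1:5) {
    edges <- random_graph(300, 900, seed = s)
    nodes <- sort(unique(c(edges$id1, edges$id2, sprintf("iso%02d", 1:5))))
    st <- edge_store(edges, nodes = nodes)
    cutoff <- 150
    want <- oracle_components(edges, nodes, cutoff)
    for (chunk in c(1, 37, 10000, Inf)) {
      got <- components_at_cutoff(st, cutoff, chunk_edges = chunk)
      expect_true(partition_equal(got, want))
    }
  }
})

test_that("file-backed streaming matches in-memory results", {
  edges <- random_graph(200, 600, seed = 11)
  st_mem <- edge_store(edges)
  f <- withr::local_tempfile(fileext = ".tsv")
  st_file <- write_edge_store(st_mem, f)
  for (cutoff in c(80, 160, 240)) {
    expect_true(partition_equal(
      components_at_cutoff(st_mem, cutoff, chunk_edges = 100),
      components_at_cutoff(st_file, cutoff, chunk_edges = 100)))
  }
})

test_that("shuffled edge order yields byte-identical canonical cluster maps", {
  edges <- random_graph(150, 500, seed = 21)
  set.seed(99)
  shuffled <- edges[sample(nrow(edges)), ]
  p1 <- components_at_cutoff(edge_store(edges), 120, chunk_edges = 53)
  p2 <- components_at_cutoff(edge_store(shuffled), 120, chunk_edges = 53)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_cluster_map(dplyr::mutate(p1, level = "L"), f1)
  write_cluster_map(dplyr::mutate(p2, level = "L"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("components_multi builds a refining hierarchy with parent maps", {
  edges <- tibble::tibble(id1 = c("A", "B"), id2 = c("B", "C"),
                          bitscore = c(250, 150))
  st <- edge_store(edges)
  h <- components_multi(st, c(100, 200))
  expect_equal(h$levels[["bitscore:100"]]$cluster, c("A", "A", "A"))
  expect_equal(h$levels[["bitscore:200"]]$cluster, c("A", "A", "C"))
  pm <- h$parents[[1]]
  expect_equal(pm$parent[pm$child == "A"], "A")
  expect_equal(pm$parent[pm$child == "C"], "A")

  # single cutoff identical to components_at_cutoff
  h1 <- components_multi(st, 150)
  expect_true(partition_equal(h1$levels[[1]],
                              components_at_cutoff(st, 150)))

  # monotone coarsening on random graphs
  for (s in 1:3) {
    edges <- random_graph(400, 1500, seed = 30 + s)
    h <- components_multi(edge_store(edges), c(80, 130, 180, 230),
                          chunk_edges = 200)
    n_clusters <- vapply(h$levels, function(p) dplyr::n_distinct(p$cluster),
                         integer(1))
    max_size <- vapply(h$levels, function(p) max(table(p$cluster)),
                       integer(1))
    expect_true(all(diff(n_clusters) >= 0))
    expect_true(all(diff(max_size) <= 0))
  }
})

test_that("canonical_labels is canonical and idempotent", {
  p <- tibble::tibble(id = c("B", "A", "C"), cluster = c("x", "x", "y"))
  cl <- canonical_labels(p)
  expect_equal(cl$cluster, c("A", "A", "C"))
  expect_equal(canonical_labels(cl), cl)
})

test_that("build_parent_map detects refinement violations", {
  coarse <- tibble::tibble(id = c("A", "B", "C", "D"),
                           cluster = c("g1", "g1", "g2", "g2"))
  fine <- tibble::tibble(id = c("A", "B", "C", "D"),
                         cluster = c("f1", "f1", "f2", "f2"))
  expect_equal(build_parent_map(coarse, fine),
               tibble::tibble(child = c("f1", "f2"),
                              parent = c("g1", "g2")))
  # identical partitions -> identity map
  idm <- build_parent_map(coarse, coarse)
  expect_equal(idm$child, idm$parent)
  # crossing partitions
  crossing <- tibble::tibble(id = c("A", "B", "C", "D"),
                             cluster = c("h1", "h2", "h1", "h2"))
  err <- expect_error(build_parent_map(coarse, crossing),
                      class = "seqspace_refinement")
  expect_match(conditionMessage(err), "h1|h2")
  # universe mismatch
  expect_error(build_parent_map(coarse, fine[1:3, ]),
               class = "seqspace_universe")
})

test_that("hierarchy_table reports sizes and parents", {
  edges <- tibble::tibble(id1 = c("A", "B"), id2 = c("B", "C"),
                          bitscore = c(250, 150))
  h <- components_multi(edge_store(edges, nodes = c("A", "B", "C", "D")),
                        c(100, 200))
  ht <- hierarchy_table(h)
  expect_equal(nrow(ht), 2L + 3L)
  expect_equal(ht$size[ht$level == "bitscore:100" & ht$cluster == "A"], 3L)
  expect_equal(ht$parent[ht$level == "bitscore:200" & ht$cluster == "C"], "A")
})
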