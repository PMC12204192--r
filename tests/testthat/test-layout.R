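toy_hierarchy <- function() {
  edges <- tibble::tibble(
    id1 = c("a1", "a2", "a3", "b1", "a1"),
    id2 = c("a2", "a3", "a4", "b2", "b1"),
    bitscore = c(250, 250, 250, 250, 120))
  components_multi(edge_store(edges, nodes = c(paste0("a", 1:4),
                                               paste0("b", 1:2), "c1")),
                   c(100, 200))
}

test_that("filter_clusters applies size/membership criteria and keeps ancestors", {
  h <- toy_hierarchy()
  full <- filter_clusters(h)
  expect_equal(nrow(full), nrow(hierarchy_table(h)))

  by_size <- filter_clusters(h, min_size = 5)
  # only the 6-member root at the low cutoff passes
  expect_equal(by_size$cluster[by_size$level == "bitscore:100"], "a1")
  expect_equal(nrow(by_size[by_size$level == "bitscore:200", ]), 0L)

  by_member <- filter_clusters(h, must_contain = "b1")
  expect_equal(by_member$cluster[by_member$level == "bitscore:200"], "b1")
  # ancestor chain retained
  expect_equal(by_member$cluster[by_member$level == "bitscore:100"], "a1")
})

test_that("pack_siblings yields exact area proportionality and no overlaps", {
  single <- pack_siblings(7, seed = 1)
  expect_equal(single, tibble::tibble(x = 0, y = 0, radius = sqrt(7 / pi)))

  # two equal siblings: tangent and symmetric about the origin
  two <- pack_siblings(c(4, 4), seed = 2)
  gap <- sqrt(diff(two$x)^2 + diff(two$y)^2) - sum(two$radius)
  tol <- 1e-3 * min(two$radius)
  expect_gte(gap, -tol)
  expect_lt(abs(gap), 3 * tol)
  expect_equal(two$x[1], -two$x[2], tolerance = 1e-9)
  expect_equal(two$y[1], -two$y[2], tolerance = 1e-9)

  set.seed(3)
  sizes <- sample(1:500, 100, replace = TRUE)
  pk <- pack_siblings(sizes, seed = 4)
  # area ratios equal size ratios to 1e-9
  expect_equal(pk$radius^2 / pk$radius[1]^2, sizes / sizes[1],
               tolerance = 1e-9)
  d <- as.matrix(dist(pk[c("x", "y")]))
  overlap <- outer(pk$radius, pk$radius, `+`) - d
  diag(overlap) <- 0
  expect_lt(max(overlap), 1e-3 * min(pk$radius))

  # permuting sibling order permutes, but does not change, the radii
  pk2 <- pack_siblings(rev(sizes), seed = 4)
  expect_equal(sort(pk2$radius), sort(pk$radius))
})

test_that("nest_in_parent centers, contains, and preserves geometry", {
  parent <- list(x = 10, y = -5, radius = 4)
  child <- pack_siblings(3, seed = 5)
  nested <- nest_in_parent(parent, child)
  expect_equal(c(nested$x, nested$y), c(10, -5))
  expect_equal(nested$scale_factor, 1)

  kids <- pack_siblings(c(30, 20, 10), seed = 6)
  nested <- nest_in_parent(parent, kids)
  extent <- max(sqrt((nested$x - 10)^2 + (nested$y + 5)^2) + nested$radius)
  expect_equal(extent, 0.95 * 4, tolerance = 1e-9)
  # similarity transform: pairwise overlaps/gaps scale uniformly
  d_before <- as.matrix(dist(kids[c("x", "y")]))
  d_after <- as.matrix(dist(nested[c("x", "y")]))
  s <- nested$scale_factor[1]
  expect_equal(d_after, d_before * s, tolerance = 1e-9)
  expect_equal(nested$radius, kids$radius * s, tolerance = 1e-12)
})

test_that("build_layout nests circles within parents deterministically", {
  h <- toy_hierarchy()
  lay <- build_layout(h, seed = 7)
  expect_s3_class(lay, "hcp_layout")
  kids <- lay[!is.na(lay$parent_id), ]
  par <- lay[match(kids$parent_id, lay$cluster_id), ]
  reach <- sqrt((kids$x - par$x)^2 + (kids$y - par$y)^2) + kids$radius
  expect_true(all(reach <= par$radius * (1 + 1e-6)))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_layout(build_layout(h, seed = 7), f1)
  write_layout(build_layout(h, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))

  # filtered clusters are absent
  lay2 <- build_layout(h, min_size = 5, seed = 7)
  expect_false("b1" %in% lay2$cluster_id)

  # round-trip
  back <- read_layout(f1)
  expect_equal(as.data.frame(back), as.data.frame(lay),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("annotate_layout summarizes majority fills and outline sets", {
  h <- toy_hierarchy()
  lay <- build_layout(h, seed = 8)
  ann <- tibble::tibble(
    id = c("a1", "a2", "a3", "b1", "b2"),
    fun = c("oxidase", "oxidase", "hydrolase", "transport", "transport"),
    taxon_genus = c("Bacillus", "Vibrio", "Bacillus", "Vibrio", "Vibrio"))
  styled <- annotate_layout(lay, tidy(h), ann)
  a_fine <- styled[styled$level == "bitscore:200" &
                     styled$cluster_id == "a1", ]
  expect_equal(a_fine$fill_label, "oxidase")
  expect_true(a_fine$mixed)
  expect_equal(a_fine$outline_labels, "Bacillus;Vibrio")
  b_fine <- styled[styled$level == "bitscore:200" &
                     styled$cluster_id == "b1", ]
  expect_equal(b_fine$fill_label, "transport")
  expect_false(b_fine$mixed)
  # unannotated cluster -> null style
  c_fine <- styled[styled$level == "bitscore:200" &
                     styled$cluster_id == "c1", ]
  expect_true(is.na(c_fine$fill_label))
  expect_true(is.na(c_fine$fill_color))
})

test_that("autoplot renders a layout without error", {
  h <- toy_hierarchy()
  p <- ggplot2::autoplot(build_layout(h, seed = 9))
  expect_s3_class(p, "ggplot")
})
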