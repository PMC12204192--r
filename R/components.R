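# Chunk-local clustering + global merge. Each chunk is clustered into a
# local disjoint-set forest over only the nodes it mentions; the local
# clusters are then merged into the global forest by unioning every member
# with its local cluster root (clusters sharing any member collapse). The
# merge is associative and commutative, so the final partition is
# independent of chunk size and processing order.
merge_chunk <- function(parent, ia, ib) {
  if (length(ia) == 0) return(invisible(NULL))
  nodes <- unique(c(ia, ib))
  local <- uf_init(length(nodes))
  uf_union_batch(local, match(ia, nodes), match(ib, nodes))
  roots <- uf_roots(local)
  uf_union_batch(parent, nodes[roots], nodes)
  invisible(NULL)
}

new_partition <- function(ids, cluster, level = NULL) {
  out <- tibble(id = ids, cluster = cluster)
  attr(out, "level") <- level
  out
}

#' Level label of a partition
#' @param partition A partition tibble.
#' @return The level label, or `NA` if unset.
#' @export
partition_level <- function(partition) {
  attr(partition, "level") %||% NA_character_
}

#' Connected components of the SSN at one bitscore cut-off
#'
#' Streams the edge store in chunks, keeps every edge with
#' `bitscore >= cutoff` (inclusive, so printed integer cut-offs keep ties),
#' builds a disjoint-set forest per chunk and merges chunk results into a
#' global forest. Sequences in the node universe with no surviving edge
#' become singleton clusters. The result is independent of `chunk_edges` and
#' of chunk order, and cluster ids are canonical (lexicographically smallest
#' member id).
#'
#' @param store An [edge_store()].
#' @param cutoff Bitscore threshold (> 0).
#' @param chunk_edges Edges per streamed chunk.
#' @return A partition tibble (`id`, `cluster`) with a `"level"` attribute
#'   `"bitscore:<cutoff>"`.
#' @export
components_at_cutoff <- function(store, cutoff, chunk_edges = 1e6L) {
  stopifnot(inherits(store, "edge_store"), cutoff > 0)
  parent <- uf_init(length(store$ids))
  iterate_edges(store, chunk_edges, function(ia, ib, bits) {
    keep <- bits >= cutoff
    merge_chunk(parent, ia[keep], ib[keep])
  })
  roots <- uf_roots(parent)
  new_partition(store$ids, store$ids[roots],
                level = paste0("bitscore:", format(cutoff, trim = TRUE)))
}

#' Multi-cutoff components and the cross-cutoff cluster hierarchy
#'
#' One pass over the edge file maintaining one disjoint-set forest per
#' cut-off: every edge is applied to all cut-offs at or below its bitscore.
#' Because the surviving edge set at a higher cut-off is a subset of that at
#' a lower cut-off, each finer partition refines the coarser one by
#' construction, and clusters at lower cut-offs act as parent neighborhoods
#' of the clusters that separate at higher cut-offs.
#'
#' @inheritParams components_at_cutoff
#' @param cutoffs A [percentile_cutoffs()] result or strictly increasing
#'   numeric vector of bitscore thresholds.
#' @return A [cluster_hierarchy()] ordered coarse to fine.
#' @export
components_multi <- function(store, cutoffs, chunk_edges = 1e6L) {
  cuts <- as_cutoffs(cutoffs)
  if (length(cuts) == 0 || any(diff(cuts) <= 0) || any(cuts <= 0)) {
    stop_parameter("cutoffs must be strictly increasing and positive")
  }
  parents <- lapply(cuts, function(.) uf_init(length(store$ids)))
  iterate_edges(store, chunk_edges, function(ia, ib, bits) {
    for (k in seq_along(cuts)) {
      keep <- bits >= cuts[k]
      merge_chunk(parents[[k]], ia[keep], ib[keep])
    }
  })
  partitions <- lapply(seq_along(cuts), function(k) {
    roots <- uf_roots(parents[[k]])
    new_partition(store$ids, store$ids[roots],
                  level = paste0("bitscore:", format(cuts[k], trim = TRUE)))
  })
  names(partitions) <- vapply(partitions, partition_level, character(1))
  cluster_hierarchy(partitions)
}

#' Canonical cluster labels
#'
#' Relabels every cluster to its lexicographically smallest member id, which
#' is deterministic across runs, chunkings and input orderings.
#'
#' @param partition A partition tibble (`id`, `cluster`).
#' @return The relabeled partition.
#' @export
canonical_labels <- function(partition) {
  lab <- partition |>
    group_by(.data$cluster) |>
    summarise(canon = min(.data$id), .groups = "drop")
  out <- partition |>
    left_join(lab, by = "cluster") |>
    mutate(cluster = .data$canon) |>
    select("id", "cluster")
  attr(out, "level") <- attr(partition, "level")
  out
}

#' Parent map between two nested partitions
#'
#' Maps every fine cluster to the coarse cluster containing its members.
#' Works for any nested partitions regardless of how they were generated
#' (homology components, K-means levels, tree cuts). A fine cluster whose
#' members span two coarse clusters violates refinement and raises an error
#' naming it.
#'
#' @param coarse,fine Partition tibbles over the same id universe.
#' @return Tibble with columns `child` (fine cluster) and `parent` (coarse
#'   cluster).
#' @export
build_parent_map <- function(coarse, fine) {
  if (!setequal(coarse$id, fine$id)) {
    stop_universe("partitions are over different id universes")
  }
  joined <- inner_join(fine, coarse, by = "id",
                       suffix = c("_fine", "_coarse"))
  map <- joined |>
    distinct(.data$cluster_fine, .data$cluster_coarse)
  bad <- map$cluster_fine[duplicated(map$cluster_fine)]
  if (length(bad) > 0) {
    stop_refinement(paste0("fine cluster '", bad[1],
                           "' spans multiple coarse clusters"))
  }
  tibble(child = map$cluster_fine, parent = map$cluster_coarse) |>
    arrange(.data$child)
}

#' Cluster hierarchy: nested partitions over ordered levels
#'
#' Bundles partitions ordered coarse to fine with parent maps between
#' adjacent levels. Construction validates the refinement invariant: every
#' finer cluster must sit inside exactly one coarser cluster.
#'
#' @param partitions Named list of partition tibbles, coarse first. Names
#'   default to each partition's level attribute.
#' @return An object of class `cluster_hierarchy` with elements `levels`
#'   (named list of partitions) and `parents` (list of parent-map tibbles,
#'   one per adjacent level pair).
#' @export
cluster_hierarchy <- function(partitions) {
  stopifnot(is.list(partitions), length(partitions) >= 1)
  nms <- names(partitions) %||%
    vapply(partitions, partition_level, character(1))
  if (is.null(names(partitions))) names(partitions) <- nms
  if (anyDuplicated(nms)) stop_duplicate_id("duplicate level labels")
  parents <- list()
  if (length(partitions) > 1) {
    for (k in 2:length(partitions)) {
      parents[[paste0(nms[k], "->", nms[k - 1])]] <-
        build_parent_map(partitions[[k - 1]], partitions[[k]])
    }
  }
  structure(list(levels = partitions, parents = parents),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  sizes <- vapply(x$levels, function(p) n_distinct(p$cluster), integer(1))
  cat("<cluster_hierarchy> ", length(x$levels), " level(s), ",
      nrow(x$levels[[1]]), " sequences\n", sep = "")
  for (k in seq_along(x$levels)) {
    cat("  ", names(x$levels)[k], ": ", sizes[k], " clusters\n", sep = "")
  }
  invisible(x)
}

#' Summary table of a hierarchy's clusters
#'
#' One row per cluster per level with its size and (where applicable) its
#' parent cluster at the previous, coarser level.
#'
#' @param hierarchy A `cluster_hierarchy`.
#' @return Tibble with columns `level`, `cluster`, `parent`, `size`.
#' @export
hierarchy_table <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "cluster_hierarchy"))
  nms <- names(hierarchy$levels)
  purrr::map_dfr(seq_along(nms), function(k) {
    p <- hierarchy$levels[[k]]
    sizes <- count(p, .data$cluster, name = "size")
    parent <- if (k == 1) {
      tibble(cluster = sizes$cluster, parent = NA_character_)
    } else {
      pm <- hierarchy$parents[[k - 1]]
      tibble(cluster = sizes$cluster,
             parent = pm$parent[match(sizes$cluster, pm$child)])
    }
    tibble(level = nms[k], cluster = sizes$cluster,
           parent = parent$parent, size = sizes$size)
  }) |>
    arrange(match(.data$level, nms), .data$cluster)
}
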