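#' Tidy a cluster hierarchy into a long assignment table
#'
#' @param x A [cluster_hierarchy()].
#' @param ... Unused.
#' @return Tibble with columns `id`, `level`, `cluster`, one row per
#'   sequence per level, coarse levels first.
#' @export
tidy.cluster_hierarchy <- function(x, ...) {
  purrr::map_dfr(names(x$levels), function(lv) {
    p <- x$levels[[lv]]
    tibble(id = p$id, level = lv, cluster = p$cluster)
  })
}

#' Per-level summary of a cluster hierarchy
#'
#' @param x A [cluster_hierarchy()].
#' @param ... Unused.
#' @return Tibble with columns `level`, `n_clusters`, `n_singletons`,
#'   `max_size`, `median_size`.
#' @export
glance.cluster_hierarchy <- function(x, ...) {
  purrr::map_dfr(names(x$levels), function(lv) {
    sizes <- count(x$levels[[lv]], .data$cluster)$n
    tibble(level = lv, n_clusters = length(sizes),
           n_singletons = sum(sizes == 1), max_size = max(sizes),
           median_size = median(sizes))
  })
}

#' Tidy a bisecting tree into a node table
#'
#' @param x A `bisecting_tree` from [bisecting_kmeans()].
#' @param ... Unused.
#' @return Tibble with one row per tree node: `node`, `parent`, `size`,
#'   `sse`, `branch` (SSE drop from the parent), `leaf`.
#' @export
tidy.bisecting_tree <- function(x, ...) {
  purrr::map_dfr(seq_along(x$nodes), function(i) {
    nd <- x$nodes[[i]]
    tibble(node = i, parent = nd$parent, size = length(nd$members),
           sse = nd$sse, branch = nd$branch,
           leaf = is.null(nd$children))
  })
}

#' One-row summary of a bisecting tree
#'
#' @param x A `bisecting_tree`.
#' @param ... Unused.
#' @return Tibble with `n`, `k_max`, `root_sse`, `leaf_sse_total` (the
#'   within-cluster spread retained at the leaves).
#' @export
glance.bisecting_tree <- function(x, ...) {
  leaf_sse <- sum(vapply(x$leaves, function(i) x$nodes[[i]]$sse, numeric(1)))
  tibble(n = length(x$ids), k_max = x$k_max,
         root_sse = x$nodes[[1]]$sse, leaf_sse_total = leaf_sse)
}

#' Tidy a merge linkage into its merge records
#'
#' @param x A [merge_linkage()].
#' @param ... Unused.
#' @return Tibble with `step`, `left`, `right` (negative = item index,
#'   positive = earlier merge), `height`, `size` of the merged cluster.
#' @export
tidy.merge_linkage <- function(x, ...) {
  if (x$n_items < 2) {
    return(tibble(step = integer(), left = integer(), right = integer(),
                  height = numeric(), size = integer()))
  }
  sizes <- integer(x$n_items - 1L)
  sz <- function(v) if (v < 0) 1L else sizes[v]
  for (m in seq_len(x$n_items - 1L)) {
    sizes[m] <- sz(x$merge[m, 1]) + sz(x$merge[m, 2])
  }
  tibble(step = seq_len(x$n_items - 1L), left = x$merge[, 1],
         right = x$merge[, 2], height = x$height, size = sizes)
}
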