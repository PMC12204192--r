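#' Filter a hierarchy's clusters for plotting
#'
#' Keeps clusters that meet a minimum size or contain one of a set of
#' sequences (criteria are OR-ed), then adds back every ancestor of a kept
#' cluster so the nesting stays well formed. With no criteria the full
#' cluster table is returned.
#'
#' @param hierarchy A [cluster_hierarchy()].
#' @param min_size Keep clusters with at least this many sequences.
#' @param must_contain Keep clusters containing any of these sequence ids.
#' @return Tibble (`level`, `cluster`, `parent`, `size`) restricted to kept
#'   clusters, level order preserved.
#' @export
filter_clusters <- function(hierarchy, min_size = NULL, must_contain = NULL) {
  ht <- hierarchy_table(hierarchy)
  if (is.null(min_size) && is.null(must_contain)) return(ht)
  keep <- rep(FALSE, nrow(ht))
  if (!is.null(min_size)) keep <- keep | ht$size >= min_size
  if (!is.null(must_contain)) {
    hits <- purrr::map_dfr(names(hierarchy$levels), function(lv) {
      p <- hierarchy$levels[[lv]]
      tibble(level = lv,
             cluster = unique(p$cluster[p$id %in% must_contain]))
    })
    keep <- keep | (paste(ht$level, ht$cluster) %in%
                      paste(hits$level, hits$cluster))
  }
  ht$keep <- keep
  lv_names <- names(hierarchy$levels)
  for (k in rev(seq_along(lv_names))[-length(lv_names)]) {
    kept_parents <- unique(ht$parent[ht$level == lv_names[k] & ht$keep])
    sel <- ht$level == lv_names[k - 1] & ht$cluster %in% kept_parents
    ht$keep[sel] <- TRUE
  }
  ht |> filter(.data$keep) |> select(-"keep")
}

#' Pack sibling circles by overlap relaxation
#'
#' Lays out one group of sibling clusters as circles whose areas are exactly
#' proportional to their sizes. Circles start on a seeded sunflower spiral
#' and are relaxed iteratively: overlapping pairs are pushed apart along
#' their center line by half the overlap each, with an early centripetal
#' pull toward the group centroid for compactness. Iteration stops when the
#' deepest remaining overlap is below `tol_factor * min(radius)`; if
#' relaxation stalls the configuration is inflated radially, which always
#' terminates. Deterministic given the seed.
#'
#' @param sizes Positive cluster sizes.
#' @param seed Integer seed.
#' @param tol_factor Overlap tolerance as a fraction of the smallest radius.
#' @param pull_iter Iterations during which the centripetal pull applies.
#' @param max_iter Hard iteration cap before radial inflation.
#' @return Tibble with columns `x`, `y`, `radius` (area = size exactly),
#'   area-weighted centroid at the origin.
#' @export
pack_siblings <- function(sizes, seed = 1L, tol_factor = 1e-3,
                          pull_iter = 150L, max_iter = 4000L) {
  stopifnot(length(sizes) >= 1, all(sizes > 0))
  n <- length(sizes)
  r <- sqrt(sizes / pi)
  if (n == 1) return(tibble(x = 0, y = 0, radius = r))
  set.seed(seed)
  golden <- pi * (3 - sqrt(5))
  theta <- seq_len(n) * golden + runif(1, 0, 2 * pi)
  rho <- mean(r) * 0.5 * sqrt(seq_len(n))
  x <- rho * cos(theta)
  y <- rho * sin(theta)
  tol <- tol_factor * min(r)
  rsum <- outer(r, r, `+`)
  w <- sizes / sum(sizes)
  for (it in seq_len(max_iter)) {
    dx <- outer(x, x, `-`)
    dy <- outer(y, y, `-`)
    d <- sqrt(dx^2 + dy^2)
    ov <- rsum - d
    diag(ov) <- 0
    if (max(ov) < tol) break
    # degenerate coincident centers: separate along a deterministic angle
    zero <- which(d == 0 & ov > 0, arr.ind = TRUE)
    if (nrow(zero) > 0) {
      ang <- (zero[, 1] + zero[, 2]) * golden
      d[zero] <- 1e-9
      dx[zero] <- 1e-9 * cos(ang)
      dy[zero] <- 1e-9 * sin(ang)
    }
    push <- ov > 0
    diag(push) <- FALSE
    f <- ifelse(push, ov / (2 * pmax(d, 1e-9)), 0)
    x <- x + rowSums(f * dx)
    y <- y + rowSums(f * dy)
    if (it <= pull_iter) {
      cx <- sum(w * x); cy <- sum(w * y)
      x <- x - 0.05 * (x - cx)
      y <- y - 0.05 * (y - cy)
    }
    if (it == max_iter) {
      # guaranteed-terminating fallback: inflate about the centroid
      repeat {
        dx <- outer(x, x, `-`); dy <- outer(y, y, `-`)
        ov <- rsum - sqrt(dx^2 + dy^2)
        diag(ov) <- 0
        if (max(ov) < tol) break
        cx <- sum(w * x); cy <- sum(w * y)
        x <- cx + (x - cx) * 1.05
        y <- cy + (y - cy) * 1.05
      }
    }
  }
  cx <- sum(w * x); cy <- sum(w * y)
  tibble(x = x - cx, y = y - cy, radius = r)
}

#' Place packed children inside their parent circle
#'
#' Translates a packed sibling group so its area-weighted centroid sits on
#' the parent center, then rescales positions and radii uniformly by the
#' largest factor s <= 1 that keeps every child within `fit * R_parent`.
#' Being a similarity transform, this preserves relative geometry and the
#' within-group area proportionality.
#'
#' @param parent One-row tibble or list with `x`, `y`, `radius`.
#' @param children Tibble from [pack_siblings()].
#' @param fit Containment factor (children fit inside `fit * radius`).
#' @return `children` translated/rescaled, with a `scale_factor` column.
#' @export
nest_in_parent <- function(parent, children, fit = 0.95) {
  w <- children$radius^2 / sum(children$radius^2)
  cx <- sum(w * children$x)
  cy <- sum(w * children$y)
  x0 <- children$x - cx
  y0 <- children$y - cy
  extent <- max(sqrt(x0^2 + y0^2) + children$radius)
  s <- if (extent > 0) min(1, fit * parent$radius / extent) else 1
  tibble(
    x = parent$x + s * x0,
    y = parent$y + s * y0,
    radius = s * children$radius,
    scale_factor = s
  )
}

#' Build the hierarchical cluster-plot layout
#'
#' Computes the nested-circle layout for a (filtered) cluster hierarchy:
#' the coarsest level is packed in the plane, then each sibling group is
#' packed locally and nested inside its parent circle, recursively. Every
#' circle records its level, parent, size and the per-group scale factor, so
#' any renderer can draw the plot from the persisted layout alone. Reruns
#' with the same seed are byte-identical.
#'
#' @param hierarchy A [cluster_hierarchy()].
#' @param min_size,must_contain Optional filters (see [filter_clusters()]).
#' @param seed Integer master seed; each sibling group derives its own.
#' @param fit Containment factor passed to [nest_in_parent()].
#' @return A tibble of class `hcp_layout` with columns `level`, `cluster_id`,
#'   `parent_id`, `x`, `y`, `radius`, `size`, `scale_factor`.
#' @export
build_layout <- function(hierarchy, min_size = NULL, must_contain = NULL,
                         seed = 1L, fit = 0.95) {
  ht <- filter_clusters(hierarchy, min_size = min_size,
                        must_contain = must_contain)
  lv_names <- names(hierarchy$levels)
  lv_names <- lv_names[lv_names %in% unique(ht$level)]
  out <- list()
  for (k in seq_along(lv_names)) {
    lv <- ht |> filter(.data$level == lv_names[k]) |> arrange(.data$cluster)
    if (k == 1) {
      packed <- pack_siblings(lv$size, seed = derive_seed(seed, lv_names[k]))
      out[[k]] <- tibble(
        level = lv_names[k], cluster_id = lv$cluster,
        parent_id = NA_character_, x = packed$x, y = packed$y,
        radius = packed$radius, size = lv$size, scale_factor = 1
      )
    } else {
      placed <- lv |>
        group_by(.data$parent) |>
        dplyr::group_map(function(grp, key) {
          par_row <- out[[k - 1]] |>
            filter(.data$cluster_id == key$parent)
          packed <- pack_siblings(
            grp$size,
            seed = derive_seed(seed, paste(lv_names[k], key$parent)))
          nested <- nest_in_parent(par_row, packed, fit = fit)
          tibble(level = lv_names[k], cluster_id = grp$cluster,
                 parent_id = key$parent, x = nested$x, y = nested$y,
                 radius = nested$radius, size = grp$size,
                 scale_factor = nested$scale_factor)
        }) |>
        bind_rows()
      out[[k]] <- placed |> arrange(.data$cluster_id)
    }
  }
  layout <- bind_rows(out)
  attr(layout, "seed") <- seed
  class(layout) <- c("hcp_layout", class(layout))
  layout
}

#' Write / read a layout file
#'
#' The layout file is the exchange surface between the layout engine and any
#' renderer: tab-separated columns `level`, `cluster_id`, `parent_id`, `x`,
#' `y`, `radius`, `size`, `scale_factor`.
#'
#' @param layout An `hcp_layout` tibble.
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` the
#'   layout tibble.
#' @export
write_layout <- function(layout, path) {
  out <- as_tibble(layout)[c("level", "cluster_id", "parent_id", "x", "y",
                             "radius", "size", "scale_factor")]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    level = "c", cluster_id = "c", parent_id = "c", .default = "d"),
    progress = FALSE)
  class(tbl) <- c("hcp_layout", class(tbl))
  tbl
}

#' Annotate layout circles with functions and taxonomy
#'
#' Summarizes per-sequence annotations at the cluster level for styling: the
#' fill is the majority `fun` (function) label, clusters with more than one
#' annotated function are flagged mixed, and the outline collects the sorted
#' set of genera. Colors are deterministic per category.
#'
#' @param layout An `hcp_layout`.
#' @param assignment Long assignment tibble (`id`, `level`, `cluster`), e.g.
#'   `tidy()` of a hierarchy.
#' @param annotations Tibble with column `id` and optional columns `fun`
#'   and `taxon_genus`.
#' @param seed Seed for the color hash.
#' @return The layout with added columns `fill_label`, `fill_color`,
#'   `mixed`, `outline_labels`, `n_annotated`.
#' @export
annotate_layout <- function(layout, assignment, annotations, seed = 0L) {
  stopifnot(all(c("id", "level", "cluster") %in% names(assignment)))
  ann <- assignment |>
    left_join(annotations, by = "id")
  has_fun <- "fun" %in% names(ann)
  has_tax <- "taxon_genus" %in% names(ann)
  summ <- ann |>
    group_by(.data$level, .data$cluster) |>
    summarise(
      fill_label = if (!has_fun) NA_character_ else {
        f <- .data$fun[!is.na(.data$fun)]
        if (length(f) == 0) NA_character_ else
          names(sort(table(f), decreasing = TRUE))[1]
      },
      mixed = if (!has_fun) FALSE else
        n_distinct(.data$fun[!is.na(.data$fun)]) > 1,
      outline_labels = if (!has_tax) NA_character_ else {
        g <- sort(unique(.data$taxon_genus[!is.na(.data$taxon_genus)]))
        if (length(g) == 0) NA_character_ else paste(g, collapse = ";")
      },
      n_annotated = if (!has_fun) 0L else sum(!is.na(.data$fun)),
      .groups = "drop"
    )
  pal <- category_colors(summ$fill_label[!is.na(summ$fill_label)], seed = seed)
  summ$fill_color <- ifelse(is.na(summ$fill_label), NA_character_,
                            unname(pal[summ$fill_label]))
  out <- as_tibble(layout) |>
    left_join(summ, by = c(level = "level", cluster_id = "cluster"))
  class(out) <- c("hcp_layout", class(out))
  out
}
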