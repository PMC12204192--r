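circle_polygon <- function(x, y, r, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  tibble(px = x + r * cos(th), py = y + r * sin(th))
}

#' Plot a hierarchical cluster-plot layout
#'
#' Draws the nested circles of a layout, one ring of transparency per
#' level; annotated layouts (see [annotate_layout()]) are filled by their
#' majority function color.
#'
#' @param object An `hcp_layout` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcp_layout <- function(object, ...) {
  tbl <- as_tibble(object)
  polys <- purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    mutate(circle_polygon(tbl$x[i], tbl$y[i], tbl$radius[i]),
           grp = paste(tbl$level[i], tbl$cluster_id[i]),
           level = tbl$level[i],
           fill_color = if ("fill_color" %in% names(tbl))
             tbl$fill_color[i] else NA_character_)
  })
  p <- ggplot2::ggplot(polys, ggplot2::aes(.data$px, .data$py,
                                           group = .data$grp)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (all(is.na(polys$fill_color))) {
    p + ggplot2::geom_polygon(ggplot2::aes(color = .data$level),
                              fill = NA, linewidth = 0.3)
  } else {
    p + ggplot2::geom_polygon(ggplot2::aes(fill = .data$fill_color),
                              color = "grey30", alpha = 0.4,
                              linewidth = 0.2) +
      ggplot2::scale_fill_identity()
  }
}

#' Heatmap of an agreement sweep
#'
#' @param sweep Result of [agreement_sweep()].
#' @param metric `"ari"` or `"ami"`.
#' @return A ggplot object.
#' @export
plot_agreement_grid <- function(sweep, metric = c("ari", "ami")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = factor(.data$level_a, levels = unique(.data$level_a)),
    y = factor(.data$level_b, levels = unique(.data$level_b)),
    fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[metric]])), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
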