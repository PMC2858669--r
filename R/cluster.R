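# Hierarchical clustering of property profiles and heat-map export.
# Rows are clustered by Euclidean distance on the z-scored matrix; the
# heat map shows rows in dendrogram leaf order with the color scale
# clipped at +/- 3 SD (values beyond the clip render at the clip color;
# the exported numeric table is never clipped).

#' Cluster the rows of a property matrix
#'
#' Agglomerative hierarchical clustering with Euclidean distance.
#'
#' @param matrix A z-scored `property_matrix` with at least 2 rows.
#' @param linkage One of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"` (Ward's criterion on squared distances).
#' @return A `row_clustering` object: the `hclust` tree, `leaf_order`
#'   (row ids in dendrogram order), `metric` and `linkage`.
#' @export
cluster_rows <- function(matrix,
                         linkage = c("average", "single", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (!inherits(matrix, "property_matrix") ||
      !identical(attr(matrix, "normalization"), "zscored")) {
    abort("`matrix` must be a z-scored property_matrix")
  }
  if (nrow(matrix) < 2) abort("clustering needs at least 2 rows")
  values <- matrix_values(matrix)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(dist(values, method = "euclidean"), method = method)
  structure(
    list(
      tree = tree,
      leaf_order = rownames(values)[tree$order],
      metric = "euclidean",
      linkage = linkage
    ),
    class = "row_clustering"
  )
}

#' @export
print.row_clustering <- function(x, ...) {
  cat(sprintf(
    "<row_clustering> %d leaves, %s linkage, %s distance\n",
    length(x$leaf_order), x$linkage, x$metric
  ))
  invisible(x)
}

#' Property matrix reordered to dendrogram leaf order
#'
#' Returns the (unclipped) numeric table with rows in the order of the
#' clustering's dendrogram leaves — the table a heat map displays.
#'
#' @param matrix A `property_matrix`.
#' @param clustering A [cluster_rows()] result for that matrix.
#' @return The reordered `property_matrix` tibble.
#' @export
heatmap_table <- function(matrix, clustering) {
  if (!setequal(clustering$leaf_order, matrix$id)) {
    abort("clustering leaf order does not match matrix row ids")
  }
  matrix[match(clustering$leaf_order, matrix$id), ]
}

#' Heat map of a clustered property matrix
#'
#' Rows in dendrogram leaf order, one tile per protein x property, fill
#' clipped at `clip` standard deviations above/below the column mean
#' (values beyond the clip saturate at the end colors).
#'
#' @param matrix A z-scored `property_matrix`.
#' @param clustering A [cluster_rows()] result; when `NULL` one is
#'   computed with default (average) linkage.
#' @param clip Clip level in SD units (default 3).
#' @return A ggplot object.
#' @export
plot_property_heatmap <- function(matrix, clustering = NULL, clip = 3) {
  clustering <- clustering %||% cluster_rows(matrix)
  ordered <- heatmap_table(matrix, clustering)
  props <- setdiff(names(ordered), c("id", "label"))
  long <- ordered |>
    tidyr::pivot_longer(dplyr::all_of(props),
                        names_to = "property", values_to = "value") |>
    dplyr::mutate(
      id = factor(.data$id, levels = rev(clustering$leaf_order)),
      property = factor(.data$property, levels = props),
      value = pmin(pmax(.data$value, -clip), clip)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$property, y = .data$id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "green3", mid = "black", high = "red2",
      limits = c(-clip, clip),
      name = sprintf("z (clipped ±%g SD)", clip)
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @method autoplot property_matrix
#' @export
autoplot.property_matrix <- function(object, clustering = NULL, clip = 3, ...) {
  plot_property_heatmap(object, clustering = clustering, clip = clip)
}

#' Export a clustered heat map to files
#'
#' Writes the reordered (unclipped) numeric table as TSV and, optionally,
#' the clipped heat-map image.
#'
#' @inheritParams plot_property_heatmap
#' @param table_path Output path for the TSV table.
#' @param image_path Optional output path for the image (PNG/SVG/PDF by
#'   extension, via [ggplot2::ggsave()]).
#' @return The reordered table, invisibly.
#' @export
export_heatmap <- function(matrix, clustering = NULL, table_path,
                           image_path = NULL, clip = 3) {
  clustering <- clustering %||% cluster_rows(matrix)
  ordered <- heatmap_table(matrix, clustering)
  readr::write_tsv(tibble::as_tibble(ordered), table_path)
  if (!is.null(image_path)) {
    p <- plot_property_heatmap(matrix, clustering, clip = clip)
    ggplot2::ggsave(image_path, p, width = 8, height = 6, dpi = 150)
  }
  invisible(ordered)
}
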