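# The 2D reduced property space: net charge at intracellular pH against
# aggregate hydrophobicity. Transport receptors and receptor-cargo
# complexes occupy the negatively-charged, hydrophobic corner; typical
# cargos and FG-nucleoporin domains the positively-charged, hydrophilic
# one.

#' Two-dimensional charge / hydrophobicity property space
#'
#' @param profiles A profile tibble (raw values) with a `net_charge`
#'   column, from [profile_proteins()] / [profile_complexes()] (rows may
#'   be combined).
#' @param pca A [hydrophobicity_pca()] fit supplying the aggregate axis.
#' @return A `property_space` tibble: `id`, `label`, `net_charge` (e),
#'   `aggregate_hydrophobicity`.
#' @export
property_space <- function(profiles, pca) {
  if (!"net_charge" %in% names(profiles)) {
    abort("`profiles` must contain a 'net_charge' column")
  }
  agg <- aggregate_hydrophobicity(profiles, pca)
  out <- tibble::tibble(
    id = profiles$id,
    label = profiles$label %||% "unknown",
    net_charge = profiles$net_charge,
    aggregate_hydrophobicity = agg$aggregate_hydrophobicity
  )
  class(out) <- c("property_space", class(out))
  out
}

#' Scatter plot of the charge / hydrophobicity property space
#'
#' @param space A [property_space()] tibble.
#' @param thresholds Optional [compute_thresholds()] result; when given,
#'   the quadrant boundaries are drawn.
#' @return A ggplot object.
#' @export
plot_property_space <- function(space, thresholds = NULL) {
  p <- ggplot2::ggplot(space, ggplot2::aes(
    x = .data$aggregate_hydrophobicity, y = .data$net_charge,
    color = .data$label
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "aggregate hydrophobicity (PC1)",
      y = "net charge at pH (e)",
      color = NULL
    ) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$charge, linetype = 2) +
      ggplot2::geom_vline(xintercept = thresholds$hydrophobicity, linetype = 2)
  }
  p
}

#' @method autoplot property_space
#' @export
autoplot.property_space <- function(object, thresholds = NULL, ...) {
  plot_property_space(object, thresholds = thresholds)
}
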