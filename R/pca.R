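# Aggregate hydrophobicity axis: principal component analysis over the
# panel of empirical hydrophobicity scales. The scales are strongly
# correlated, so the first component (PC1) captures most of the variance
# and serves as a single aggregate hydrophobicity coordinate. PCA is run
# on z-scored columns (correlation structure), because the scales have
# incommensurate units; PC1's sign is oriented so that its loading on a
# designated reference scale is positive ("hydrophobic = high").

#' PCA of the hydrophobicity scale panel
#'
#' @param matrix A z-scored `property_matrix` (from
#'   [build_property_matrix()]) with at least 3 rows.
#' @param registry The `scale_registry` that produced the matrix, used to
#'   select the hydrophobicity-category columns.
#' @param reference Name of the reference hydrophobicity scale used to fix
#'   PC1's sign (default the Kyte-Doolittle accession `"KYTJ820101"`).
#' @return A `hydrophobicity_pca` object: orthonormal `loadings`
#'   (scales x components), `variance_fraction` (non-increasing, sums
#'   to 1), `columns`, z-scoring `center`/`scale` carried over from the
#'   fitted matrix, `reference`, and training `scores` (tibble of `id` and
#'   `aggregate_hydrophobicity`).
#' @export
hydrophobicity_pca <- function(matrix, registry = default_scales(),
                               reference = "KYTJ820101") {
  if (!inherits(matrix, "property_matrix") ||
      !identical(attr(matrix, "normalization"), "zscored")) {
    abort("`matrix` must be a z-scored property_matrix (normalize = 'zscored')")
  }
  if (nrow(matrix) < 3) abort("PCA needs at least 3 rows")
  hydro <- registry$scale[registry$category == "hydrophobicity"]
  missing <- setdiff(hydro, names(matrix))
  if (length(missing) > 0) {
    abort(sprintf("matrix lacks hydrophobicity column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!reference %in% hydro) {
    abort(sprintf("reference scale '%s' is not a hydrophobicity column", reference))
  }
  values <- matrix_values(matrix)[, hydro, drop = FALSE]
  fit <- prcomp(values, center = FALSE, scale. = FALSE)
  loadings <- fit$rotation
  # PCA sign is arbitrary; orient PC1 by the reference scale's loading
  if (loadings[reference, 1] < 0) loadings[, 1] <- -loadings[, 1]
  scores <- values %*% loadings
  variance <- fit$sdev^2
  structure(
    list(
      loadings = loadings,
      variance_fraction = variance / sum(variance),
      columns = hydro,
      center = attr(matrix, "center")[hydro],
      scale = attr(matrix, "scale")[hydro],
      reference = reference,
      scores = tibble::tibble(
        id = rownames(values),
        aggregate_hydrophobicity = unname(scores[, 1])
      )
    ),
    class = "hydrophobicity_pca"
  )
}

#' @export
print.hydrophobicity_pca <- function(x, ...) {
  cat(sprintf(
    "<hydrophobicity_pca> %d scales, PC1 variance fraction %.1f%%\n",
    length(x$columns), 100 * x$variance_fraction[1]
  ))
  invisible(x)
}

#' Aggregate hydrophobicity of new subjects
#'
#' Projects the hydrophobicity sub-vector of each profile onto the fitted
#' PC1 axis, after z-scoring with the statistics of the training matrix.
#' Projecting the training profiles reproduces their PC1 scores.
#'
#' @param profiles A profile tibble (raw values, from
#'   [profile_proteins()] / [profile_complexes()]).
#' @param pca A [hydrophobicity_pca()] fit.
#' @return A tibble with `id` and `aggregate_hydrophobicity`.
#' @export
aggregate_hydrophobicity <- function(profiles, pca) {
  missing <- setdiff(pca$columns, names(profiles))
  if (length(missing) > 0) {
    abort(sprintf("profiles lack hydrophobicity column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  values <- as.matrix(profiles[, pca$columns])
  z <- sweep(sweep(values, 2, pca$center), 2, pca$scale, "/")
  tibble::tibble(
    id = profiles$id,
    aggregate_hydrophobicity = unname(drop(z %*% pca$loadings[, 1]))
  )
}

#' Signed squared Pearson correlation
#'
#' `sign(r) * r^2`, the convention used when a squared correlation is
#' reported with the sign of the underlying relationship (e.g. the
#' polarity / aggregate-hydrophobicity anticorrelation).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' signed_squared_correlation(1:10, -(1:10))  # -1
signed_squared_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input")
  r <- cor(x, y)
  sign(r) * r^2
}
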