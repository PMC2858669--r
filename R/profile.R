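# Physicochemical profiling: per-residue scale means, net charge and
# isoelectric point, for single chains and for multi-chain complexes.
#
# Per-residue properties are composition-determined (length-normalized
# sums), so they are invariant under sequence shuffling. Net charge is
# extensive: for a complex it is the copy-weighted sum over member chains,
# each chain keeping its own termini.

#' Mean scale value of a sequence
#'
#' Length-normalized sum of per-residue values: the arithmetic mean of the
#' scale over the residues of the sequence.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param scale A named numeric vector over the 20 residues, a one-row
#'   `scale_registry` slice, or a registry plus `name`.
#' @param name When `scale` is a multi-row registry, the scale name to use.
#' @return Numeric vector of means (scale units per residue).
#' @export
#' @examples
#' kd <- scale_values(default_scales(), "KYTJ820101")
#' scale_mean("AIL", kd)
scale_mean <- function(sequence, scale, name = NULL) {
  if (is.data.frame(scale)) {
    if (!is.null(name)) {
      scale <- scale_values(scale, name)
    } else if (nrow(scale) == 1L) {
      scale <- unlist(scale[1, AMINO_ACIDS])
    } else {
      abort("`scale` has several rows; supply `name` to pick one")
    }
  }
  if (is.null(names(scale)) || !all(AMINO_ACIDS %in% names(scale))) {
    abort("`scale` must supply a value for each of the 20 standard residues")
  }
  sequence <- normalize_sequence(sequence)
  counts <- residue_counts(sequence)
  unname(drop(counts %*% scale[AMINO_ACIDS]) / nchar(sequence))
}

#' Property profiles of proteins
#'
#' For each protein: the mean of every registry scale, the net charge at
#' `pH` (extensive, in e) and the isoelectric point. One row per protein,
#' one column per property.
#'
#' @param proteins Data frame with columns `id`, `sequence` and optionally
#'   `label`.
#' @param registry A `scale_registry` (default [default_scales()]).
#' @param ionization An [ionization_model()].
#' @param pH pH for the net-charge column (default 7.2, intracellular).
#' @return A tibble: `id`, `label`, one column per scale, `net_charge`,
#'   `pI`. The `extensive` attribute flags which properties scale with
#'   copy number (`net_charge` only).
#' @export
profile_proteins <- function(proteins, registry = default_scales(),
                             ionization = ionization_model(), pH = 7.2) {
  proteins <- check_proteins(proteins)
  proteins$sequence <- normalize_sequence(proteins$sequence, id = proteins$id)
  counts <- residue_counts(proteins$sequence)
  len <- nchar(proteins$sequence)
  means <- counts %*% t(registry_matrix(registry)) / len
  ion_counts <- ionizable_counts(proteins$sequence, ionization)
  out <- dplyr::bind_cols(
    tibble::tibble(id = proteins$id, label = proteins$label),
    tibble::as_tibble(means),
    tibble::tibble(
      net_charge = charge_from_counts(ion_counts, rep(pH, nrow(counts)), ionization),
      pI = bisect_pI(ion_counts, ionization)
    )
  )
  props <- setdiff(names(out), c("id", "label"))
  attr(out, "extensive") <- setNames(props == "net_charge", props)
  attr(out, "pH") <- pH
  out
}

#' Property profiles of receptor-cargo complexes
#'
#' Net charge is the copy-weighted sum of member net charges (each chain
#' keeps both termini; association is non-covalent). Per-residue scale
#' means are copy-and-length weighted, equivalent to profiling the
#' concatenated residues. The complex pI is the pH at which the summed
#' charge crosses zero.
#'
#' @param manifest A manifest tibble (`complex`, `member`, `copies`), see
#'   [read_complex_manifest()].
#' @param proteins Protein table resolving every member id.
#' @inheritParams profile_proteins
#' @return A tibble with the same property columns as
#'   [profile_proteins()], one row per complex, labelled `complex`.
#' @export
profile_complexes <- function(manifest, proteins, registry = default_scales(),
                              ionization = ionization_model(), pH = 7.2) {
  proteins <- check_proteins(proteins)
  manifest <- validate_manifest(manifest, proteins)
  seqs <- setNames(normalize_sequence(proteins$sequence, id = proteins$id), proteins$id)

  one <- function(members, copies) {
    counts <- residue_counts(seqs[members]) * copies
    total_counts <- matrix(colSums(counts), nrow = 1,
                           dimnames = list(NULL, AMINO_ACIDS))
    total_len <- sum(nchar(seqs[members]) * copies)
    means <- total_counts %*% t(registry_matrix(registry)) / total_len
    ion <- ionizable_counts(seqs[members], ionization) * copies
    total_ion <- matrix(colSums(ion), nrow = 1,
                        dimnames = list(NULL, colnames(ion)))
    tibble::tibble(
      !!!as.list(drop(means)),
      net_charge = charge_from_counts(total_ion, pH, ionization),
      pI = bisect_pI(total_ion, ionization)
    )
  }

  out <- manifest |>
    dplyr::group_by(.data$complex) |>
    dplyr::group_modify(~ one(.x$member, .x$copies)) |>
    dplyr::ungroup() |>
    dplyr::rename(id = "complex") |>
    dplyr::mutate(label = "complex", .after = "id")
  props <- setdiff(names(out), c("id", "label"))
  attr(out, "extensive") <- setNames(props == "net_charge", props)
  attr(out, "pH") <- pH
  out
}

#' Assemble a normalized property matrix
#'
#' Stacks protein (and complex) profiles into a proteins-by-properties
#' matrix and optionally normalizes each property column over the whole
#' set: `"centered"` subtracts the column mean, `"zscored"` additionally
#' divides by the column standard deviation (so every column has mean 0
#' and SD 1). Centering/scaling statistics are kept as attributes so new
#' subjects can be projected consistently.
#'
#' @param profiles A profile tibble from [profile_proteins()] /
#'   [profile_complexes()] (rows may be combined with
#'   [dplyr::bind_rows()]).
#' @param normalize One of `"zscored"` (default), `"centered"`, `"raw"`.
#' @return A `property_matrix` tibble (`id`, `label`, property columns)
#'   with attributes `normalization`, `center`, `scale`.
#' @export
build_property_matrix <- function(profiles,
                                  normalize = c("zscored", "centered", "raw")) {
  normalize <- match.arg(normalize)
  if (!all(c("id", "label") %in% names(profiles))) {
    abort("`profiles` must have 'id' and 'label' columns")
  }
  props <- setdiff(names(profiles), c("id", "label"))
  values <- as.matrix(profiles[, props])
  if (!is.numeric(values)) abort("property columns must be numeric")
  center <- setNames(rep(0, length(props)), props)
  scale_ <- setNames(rep(1, length(props)), props)
  if (normalize != "raw") {
    if (nrow(values) < 2) {
      abort(sprintf("normalization '%s' needs at least 2 subjects", normalize))
    }
    center <- colMeans(values)
    values <- sweep(values, 2, center)
    if (normalize == "zscored") {
      scale_ <- apply(values, 2, sd)
      zero <- scale_ == 0 | is.na(scale_)
      if (any(zero)) {
        abort(sprintf(
          "cannot z-score zero-variance column(s): %s",
          paste(props[zero], collapse = ", ")
        ))
      }
      values <- sweep(values, 2, scale_, "/")
    }
  }
  out <- dplyr::bind_cols(
    profiles[, c("id", "label")],
    tibble::as_tibble(values)
  )
  structure(
    out,
    class = c("property_matrix", class(out)),
    normalization = normalize,
    center = center,
    scale = scale_
  )
}

# numeric part of a property matrix, rows named by id
matrix_values <- function(matrix) {
  props <- setdiff(names(matrix), c("id", "label"))
  m <- as.matrix(matrix[, props])
  rownames(m) <- matrix$id
  m
}

#' Write a property table to a tab-separated file
#'
#' @param x A profile tibble or `property_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
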