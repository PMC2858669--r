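# Regime classification of the 2D property space. The charge boundary is
# 0 e (the natural physical boundary); "high" hydrophobicity means above
# the median of a designated background set. Points below the charge
# boundary and above the hydrophobicity boundary are translocation
# competent; the opposite quadrant holds typical cargos (soluble
# proteins) or the FG-barrier (nucleoporin-labelled subjects). Boundary
# ties classify as "other".

NUCLEOPORIN_LABELS <- c("nucleoporin_scaffold", "nucleoporin_fg", "fg_domain")

#' Regime thresholds from a background set
#'
#' @param background A [property_space()] tibble with at least one row.
#' @param charge Charge boundary in e (default 0).
#' @return A `regime_thresholds` object with elements `charge` and
#'   `hydrophobicity` (the background median aggregate hydrophobicity).
#' @export
compute_thresholds <- function(background, charge = 0) {
  if (!is.data.frame(background) || nrow(background) == 0) {
    abort("`background` must be a non-empty property-space table")
  }
  if (!"aggregate_hydrophobicity" %in% names(background)) {
    abort("`background` must contain an 'aggregate_hydrophobicity' column")
  }
  structure(
    list(
      charge = charge,
      hydrophobicity = median(background$aggregate_hydrophobicity)
    ),
    class = "regime_thresholds"
  )
}

#' @export
print.regime_thresholds <- function(x, ...) {
  cat(sprintf("<regime_thresholds> charge %.3g e, hydrophobicity %.3g\n",
              x$charge, x$hydrophobicity))
  invisible(x)
}

#' Classify points of the property space into regimes
#'
#' Adds a `regime` column: `translocation_competent` (charge below the
#' boundary, hydrophobicity above), `cargo_like` / `fg_barrier_like`
#' (charge above, hydrophobicity below; the latter for
#' nucleoporin-labelled subjects), otherwise `other`. Points exactly on a
#' boundary are `other`.
#'
#' @param space A [property_space()] tibble.
#' @param thresholds A [compute_thresholds()] result.
#' @return `space` with an added `regime` column.
#' @export
classify_regimes <- function(space, thresholds) {
  if (!inherits(thresholds, "regime_thresholds")) {
    abort("`thresholds` must come from compute_thresholds()")
  }
  q <- space$net_charge
  h <- space$aggregate_hydrophobicity
  barrier <- space$label %in% NUCLEOPORIN_LABELS
  regime <- dplyr::case_when(
    q < thresholds$charge & h > thresholds$hydrophobicity ~ "translocation_competent",
    q > thresholds$charge & h < thresholds$hydrophobicity & barrier ~ "fg_barrier_like",
    q > thresholds$charge & h < thresholds$hydrophobicity ~ "cargo_like",
    .default = "other"
  )
  dplyr::mutate(space, regime = regime)
}

#' Predict self-translocating proteins
#'
#' Flags subjects that classify as translocation competent — predicted to
#' pass the NPC without a transport receptor — and notes which of them
#' exceed the passive-diffusion size limit (these are the interesting
#' predictions: large proteins, like beta-catenin, that should not pass
#' by diffusion yet carry translocation-competent surface properties).
#'
#' @param space A [property_space()] tibble.
#' @param thresholds A [compute_thresholds()] result.
#' @param proteins Optional protein table with sequences, used to compute
#'   molecular weight; without it the size note is `NA`.
#' @param size_limit_kda Passive-diffusion limit in kDa (default 40).
#' @return The flagged rows with `regime`, `mass_kda` and
#'   `above_passive_limit` columns.
#' @export
predict_self_translocators <- function(space, thresholds, proteins = NULL,
                                       size_limit_kda = 40) {
  classified <- classify_regimes(space, thresholds)
  flagged <- dplyr::filter(classified, .data$regime == "translocation_competent")
  mass <- rep(NA_real_, nrow(flagged))
  if (!is.null(proteins) && nrow(flagged) > 0) {
    proteins <- check_proteins(proteins)
    idx <- match(flagged$id, proteins$id)
    mass[!is.na(idx)] <- molecular_weight(proteins$sequence[idx[!is.na(idx)]]) / 1000
  }
  dplyr::mutate(flagged,
    mass_kda = mass,
    above_passive_limit = .data$mass_kda > size_limit_kda
  )
}
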